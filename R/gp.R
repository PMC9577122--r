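# Gaussian-process binary classification for slide-level risk.
#
# Squared-exponential (RBF) kernel, probit likelihood, Laplace
# approximation to the posterior over latent function values; kernel
# hyperparameters (length-scale, signal sd) are chosen by maximizing the
# Laplace approximate log marginal likelihood from a small fixed set of
# restarts (deterministic).  The probit likelihood gives an exact Gaussian
# integral for the predictive class probability.

rbf_kernel <- function(X1, X2, lengthscale, sigma_f) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  sigma_f^2 * exp(-d2 / (2 * lengthscale^2))
}

# Laplace mode finding (Rasmussen & Williams alg. 3.1), probit likelihood.
# y in {-1, +1}.  Returns mode f, grad at mode, sqrt(W), chol factor L and
# the approximate log marginal likelihood.
gp_laplace <- function(K, y, max_iter = 100, tol = 1e-10) {
  n <- length(y)
  f <- rep(0, n)
  obj_old <- -Inf
  I <- diag(n)
  for (it in seq_len(max_iter)) {
    z <- y * f
    lZ <- pnorm(z, log.p = TRUE)
    g <- y * exp(dnorm(z, log = TRUE) - lZ)          # grad of log lik
    W <- g^2 + f * g                                  # -Hessian (probit)
    W[W < 1e-12] <- 1e-12
    sW <- sqrt(W)
    B <- I + (sW %o% sW) * K
    L <- chol(B)
    b <- W * f + g
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f <- as.numeric(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(pnorm(y * f, log.p = TRUE))
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  z <- y * f
  lZ <- pnorm(z, log.p = TRUE)
  g <- y * exp(dnorm(z, log = TRUE) - lZ)
  W <- g^2 + f * g
  W[W < 1e-12] <- 1e-12
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * K)
  a <- g  # at the mode, K^{-1} f = grad log lik
  lml <- -0.5 * sum(a * f) + sum(lZ) - sum(log(diag(L)))
  list(f = f, grad = g, sW = sW, L = L, lml = lml)
}

#' Fit the Gaussian-process slide-risk classifier
#'
#' @param ratios List of `wsi_ratio` objects (or a numeric feature matrix).
#' @param labels Character vector of `"low_risk"`/`"high_risk"` slide
#'   labels (at least 2 slides per class).
#' @param feature_mode `"combined"` (default) or `"per_class"`; see
#'   [ratio_features()].
#' @param seed Integer seed (kept for interface stability; the fit itself
#'   is deterministic).
#' @param restarts Matrix of hyperparameter starts (rows:
#'   `log(lengthscale)`, `log(sigma_f)`); defaults to a fixed grid.
#' @return A `wsi_gp` model.
#' @export
fit_slide_classifier <- function(ratios, labels,
                                 feature_mode = c("combined", "per_class"),
                                 seed = 1L, restarts = NULL) {
  feature_mode <- match.arg(feature_mode)
  X <- if (is.matrix(ratios)) ratios else ratio_features(ratios, feature_mode)
  assert_that(all(labels %in% wsi_risk_levels()),
              "labels must be 'low_risk' or 'high_risk'")
  assert_that(nrow(X) == length(labels), "one label per slide required")
  tab <- table(factor(labels, levels = wsi_risk_levels()))
  if (any(tab < 2))
    stop("need at least 2 slides per risk class to fit the slide classifier",
         call. = FALSE)
  y <- ifelse(labels == "high_risk", 1, -1)

  if (is.null(restarts))
    restarts <- rbind(c(log(0.5), log(1)),
                      c(log(1),   log(2)),
                      c(log(0.2), log(1)))
  nlml <- function(theta) {
    K <- rbf_kernel(X, X, exp(theta[1]), exp(theta[2])) + diag(1e-8, nrow(X))
    fit <- try(gp_laplace(K, y), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$lml)) 1e10 else -fit$lml
  }
  best <- NULL
  for (i in seq_len(nrow(restarts))) {
    opt <- optim(restarts[i, ], nlml, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- best$par
  lengthscale <- exp(theta[1]); sigma_f <- exp(theta[2])
  K <- rbf_kernel(X, X, lengthscale, sigma_f) + diag(1e-8, nrow(X))
  fit <- gp_laplace(K, y)
  structure(list(X = X, y = y, feature_mode = feature_mode,
                 lengthscale = lengthscale, sigma_f = sigma_f,
                 grad = fit$grad, sW = fit$sW, L = fit$L, lml = fit$lml,
                 seed = seed),
            class = "wsi_gp")
}

#' Predict slide-level risk from a ratio vector
#'
#' The predictive probability of high risk is the probit-likelihood
#' Gaussian integral `pnorm(mu / sqrt(1 + var))` under the Laplace
#' posterior.  Risk is called by the 0.5 threshold; a probability of
#' exactly 0.5 resolves to high risk (clinically conservative).
#'
#' @param model A `wsi_gp` from [fit_slide_classifier()].
#' @param ratio A `wsi_ratio`, list of them, or feature matrix matching the
#'   training `feature_mode`.
#' @param slide_id Optional ids carried into the result.
#' @return data.frame with `slide_id`, `prob_high`, `risk`.
#' @export
predict_slide <- function(model, ratio, slide_id = NULL) {
  stopifnot(inherits(model, "wsi_gp"))
  Xs <- if (is.matrix(ratio)) ratio
        else ratio_features(ratio, model$feature_mode)
  if (ncol(Xs) != ncol(model$X))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 ncol(model$X), ncol(Xs)), call. = FALSE)
  Ks <- rbf_kernel(model$X, Xs, model$lengthscale, model$sigma_f)
  mu <- as.numeric(crossprod(Ks, model$grad))
  v <- forwardsolve(t(model$L), model$sW * Ks)
  var <- pmax(model$sigma_f^2 - colSums(v^2), 1e-12)
  p <- pnorm(mu / sqrt(1 + var))
  data.frame(slide_id = slide_id %||% paste0("slide", seq_along(p)),
             prob_high = p,
             risk = ifelse(p >= 0.5, "high_risk", "low_risk"),
             stringsAsFactors = FALSE)
}

#' Aggregate slide predictions to patient level
#'
#' A patient's high-risk probability is the maximum over their slides'
#' probabilities (a patient is as risky as their riskiest slide); risk is
#' called by the 0.5 threshold.
#'
#' @param slide_predictions data.frame with `patient_id` and `prob_high`.
#' @return data.frame with `patient_id`, `prob_high`, `risk`.
#' @export
aggregate_patient <- function(slide_predictions) {
  assert_that(is.data.frame(slide_predictions) &&
              all(c("patient_id", "prob_high") %in% names(slide_predictions)),
              "expected columns patient_id and prob_high")
  assert_that(nrow(slide_predictions) >= 1, "no slides to aggregate")
  agg <- stats::aggregate(prob_high ~ patient_id, data = slide_predictions, FUN = max)
  agg$risk <- ifelse(agg$prob_high >= 0.5, "high_risk", "low_risk")
  agg
}

#' Save / load the GP slide classifier (JSON sidecar with hyperparameters)
#' @param model A `wsi_gp`.
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
save_slide_classifier <- function(model, path) {
  payload <- list(feature_mode = model$feature_mode,
                  lengthscale = model$lengthscale, sigma_f = model$sigma_f,
                  X = list(dim = dim(model$X), data = as.numeric(model$X)),
                  y = model$y, lml = model$lml, seed = model$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_slide_classifier
#' @export
load_slide_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(p$X$data, nrow = p$X$dim[1])
  y <- as.numeric(p$y)
  K <- rbf_kernel(X, X, p$lengthscale, p$sigma_f) + diag(1e-8, nrow(X))
  fit <- gp_laplace(K, y)
  structure(list(X = X, y = y, feature_mode = p$feature_mode,
                 lengthscale = p$lengthscale, sigma_f = p$sigma_f,
                 grad = fit$grad, sW = fit$sW, L = fit$L, lml = fit$lml,
                 seed = p$seed),
            class = "wsi_gp")
}
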