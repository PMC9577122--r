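# Internal helpers: seeded evaluation, substream derivation, validation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All package randomness funnels through
# this so that a global seed plus named substreams fully determine a run.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named random substream seed from a global seed
#'
#' Stage seeds (tiling, sampler, weight init, bootstrap, GP, simulation) are
#' derived from the single pipeline seed by hashing the stream name, so that
#' adding a consumer to one stream does not perturb the others.
#'
#' @param seed Integer global seed.
#' @param name Stream name, e.g. `"sampler"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  h <- .crc32(charToRaw(as.character(name)), 0)
  as.integer((as.double(seed) * 69069 + h) %% 2147483647)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_rgb_image <- function(img) {
  (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)
}

assert_rgb <- function(img) {
  assert_that(is_rgb_image(img), "expected an H x W x 3 RGB image array")
}
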