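// Small 3-conv-block CNN used as the desk-scale patch backbone.
//
// Layout contract with the R side: an image of side s with 3 channels is a
// column of length 3*s*s, flattened as an R array [i, j, c] (row index
// fastest, then column, then channel), i.e. channel-major planes.  All
// convolutions are 3x3, pad 1, stride 1; pooling is 2x2 max, stride 2; the
// head is global average pooling followed by a linear map to 2 logits.
//
// Activation maps are (channels x pixels) matrices with pixel index
// i + s*j.  Their transpose (pixels x channels, column-major) is exactly
// the channel-major plane layout im2col expects, so layer handoffs go
// through an explicit .t().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// im2col for a 3x3/pad-1 convolution over one channel-major image.
// Output: (9*Cin) x (s*s) patch matrix.
void im2col3(const double* img, int s, int cin, mat& K) {
  K.set_size(9 * cin, s * s);
  for (int j = 0; j < s; ++j) {
    for (int i = 0; i < s; ++i) {
      int col = i + s * j;
      double* kcol = K.colptr(col);
      for (int c = 0; c < cin; ++c) {
        const double* ch = img + c * s * s;
        int base = 9 * c;
        int k = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di, ++k) {
            int ii = i + di, jj = j + dj;
            kcol[base + k] =
                (ii < 0 || jj < 0 || ii >= s || jj >= s) ? 0.0 : ch[ii + s * jj];
          }
        }
      }
    }
  }
}

// Transpose of im2col3: scatter-add patch gradients back to a channel-major
// image gradient of cin*s*s doubles.
void col2im3(const mat& dK, int s, int cin, double* dimg) {
  std::fill(dimg, dimg + (size_t)cin * s * s, 0.0);
  for (int j = 0; j < s; ++j) {
    for (int i = 0; i < s; ++i) {
      int col = i + s * j;
      const double* kcol = dK.colptr(col);
      for (int c = 0; c < cin; ++c) {
        double* ch = dimg + c * s * s;
        int base = 9 * c;
        int k = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di, ++k) {
            int ii = i + di, jj = j + dj;
            if (ii >= 0 && jj >= 0 && ii < s && jj < s)
              ch[ii + s * jj] += kcol[base + k];
          }
        }
      }
    }
  }
}

// 2x2/2 max pool of a (channels x s*s) activation map; records argmaxes.
void maxpool2(const mat& A, int s, mat& P, umat& idx) {
  int h = s / 2;
  P.set_size(A.n_rows, h * h);
  idx.set_size(A.n_rows, h * h);
  for (int j = 0; j < h; ++j) {
    for (int i = 0; i < h; ++i) {
      int pc = i + h * j;
      int c00 = 2 * i + s * 2 * j, c10 = c00 + 1, c01 = c00 + s, c11 = c01 + 1;
      for (uword r = 0; r < A.n_rows; ++r) {
        double v = A(r, c00); uword w = c00;
        if (A(r, c10) > v) { v = A(r, c10); w = c10; }
        if (A(r, c01) > v) { v = A(r, c01); w = c01; }
        if (A(r, c11) > v) { v = A(r, c11); w = c11; }
        P(r, pc) = v; idx(r, pc) = w;
      }
    }
  }
}

void maxpool2_back(const mat& dP, const umat& idx, int s, mat& dA) {
  dA.zeros(dP.n_rows, s * s);
  for (uword c = 0; c < dP.n_cols; ++c)
    for (uword r = 0; r < dP.n_rows; ++r)
      dA(r, idx(r, c)) += dP(r, c);
}

struct Cache {
  mat K1, K2, K3;
  mat A1, A2, A3;   // post-ReLU conv activations (channels x pixels)
  mat P1t, P2t;     // pooled maps, transposed to pixels x channels
  umat I1, I2;
  vec g;            // global-average-pooled features
};

vec forward_one(const double* img, int s,
                const mat& W1, const vec& b1, const mat& W2, const vec& b2,
                const mat& W3, const vec& b3, const mat& W4, const vec& b4,
                Cache& C) {
  int s2 = s / 2, s4 = s / 4;
  mat P;
  im2col3(img, s, 3, C.K1);
  C.A1 = W1 * C.K1;
  C.A1.each_col() += b1;
  C.A1.transform([](double v) { return v > 0 ? v : 0; });
  maxpool2(C.A1, s, P, C.I1);
  C.P1t = P.t();
  im2col3(C.P1t.memptr(), s2, (int)W1.n_rows, C.K2);
  C.A2 = W2 * C.K2;
  C.A2.each_col() += b2;
  C.A2.transform([](double v) { return v > 0 ? v : 0; });
  maxpool2(C.A2, s2, P, C.I2);
  C.P2t = P.t();
  im2col3(C.P2t.memptr(), s4, (int)W2.n_rows, C.K3);
  C.A3 = W3 * C.K3;
  C.A3.each_col() += b3;
  C.A3.transform([](double v) { return v > 0 ? v : 0; });
  C.g = mean(C.A3, 1);
  return W4 * C.g + b4;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward(Rcpp::List W, const arma::mat& X, int side) {
  mat W1 = W["W1"]; vec b1 = W["b1"]; mat W2 = W["W2"]; vec b2 = W["b2"];
  mat W3 = W["W3"]; vec b3 = W["b3"]; mat W4 = W["W4"]; vec b4 = W["b4"];
  if (X.n_rows != (uword)(3 * side * side))
    Rcpp::stop("input row count does not match 3*side^2");
  Cache C;
  mat P(2, X.n_cols);
  for (uword n = 0; n < X.n_cols; ++n) {
    vec logit = forward_one(X.colptr(n), side, W1, b1, W2, b2, W3, b3, W4, b4, C);
    logit -= logit.max();
    vec e = exp(logit);
    P.col(n) = e / accu(e);
  }
  return P;
}

// Mean cross-entropy loss and parameter gradients over a batch.
// y: 0/1 class index per column of X (1 = positive class).
// sample_w: optional per-example weights (length 0 = unweighted).
// [[Rcpp::export(name = ".cnn_loss_grad")]]
Rcpp::List cnn_loss_grad(Rcpp::List W, const arma::mat& X,
                         const arma::ivec& y, int side,
                         const arma::vec& sample_w) {
  mat W1 = W["W1"]; vec b1 = W["b1"]; mat W2 = W["W2"]; vec b2 = W["b2"];
  mat W3 = W["W3"]; vec b3 = W["b3"]; mat W4 = W["W4"]; vec b4 = W["b4"];
  int s = side, s2 = s / 2, s4 = s / 4;
  uword n = X.n_cols;
  if (y.n_elem != n) Rcpp::stop("label length mismatch");
  bool weighted = sample_w.n_elem == n;

  mat dW1(size(W1), fill::zeros), dW2(size(W2), fill::zeros);
  mat dW3(size(W3), fill::zeros), dW4(size(W4), fill::zeros);
  vec db1(b1.n_elem, fill::zeros), db2(b2.n_elem, fill::zeros);
  vec db3(b3.n_elem, fill::zeros), db4(b4.n_elem, fill::zeros);
  double loss = 0.0, wsum = 0.0;

  Cache C;
  mat dA3, dA2, dA1, dK, dP;
  vec dimg2((uword)W1.n_rows * s2 * s2), dimg3((uword)W2.n_rows * s4 * s4);

  for (uword i = 0; i < n; ++i) {
    double wi = weighted ? sample_w(i) : 1.0;
    wsum += wi;
    vec logits = forward_one(X.colptr(i), s, W1, b1, W2, b2, W3, b3, W4, b4, C);
    vec p = logits - logits.max();
    p = exp(p);
    p /= accu(p);
    int yi = y(i);
    loss += -wi * std::log(std::max(p(yi), 1e-300));
    vec dlog = p;
    dlog(yi) -= 1.0;
    dlog *= wi;

    dW4 += dlog * C.g.t();
    db4 += dlog;
    vec dg = W4.t() * dlog;

    dA3 = repmat(dg / (double)(s4 * s4), 1, s4 * s4);
    dA3.elem(find(C.A3 <= 0)).zeros();
    dW3 += dA3 * C.K3.t();
    db3 += sum(dA3, 1);
    dK = W3.t() * dA3;
    col2im3(dK, s4, (int)W2.n_rows, dimg3.memptr());
    // channel-major image gradient -> (pixels x channels) -> pool layout
    dP = mat(dimg3.memptr(), s4 * s4, W2.n_rows, false).t();

    maxpool2_back(dP, C.I2, s2, dA2);
    dA2.elem(find(C.A2 <= 0)).zeros();
    dW2 += dA2 * C.K2.t();
    db2 += sum(dA2, 1);
    dK = W2.t() * dA2;
    col2im3(dK, s2, (int)W1.n_rows, dimg2.memptr());
    dP = mat(dimg2.memptr(), s2 * s2, W1.n_rows, false).t();

    maxpool2_back(dP, C.I1, s, dA1);
    dA1.elem(find(C.A1 <= 0)).zeros();
    dW1 += dA1 * C.K1.t();
    db1 += sum(dA1, 1);
  }

  double inv = 1.0 / std::max(wsum, 1e-12);
  loss *= inv;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W1") = dW1 * inv, Rcpp::Named("b1") = db1 * inv,
          Rcpp::Named("W2") = dW2 * inv, Rcpp::Named("b2") = db2 * inv,
          Rcpp::Named("W3") = dW3 * inv, Rcpp::Named("b3") = db3 * inv,
          Rcpp::Named("W4") = dW4 * inv, Rcpp::Named("b4") = db4 * inv));
}
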