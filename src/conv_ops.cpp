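// Low-level convolution primitives for the network engine.
//
// Layout conventions (match R's column-major arrays):
//   feature batch: numeric array dim (H, W, C, N)
//   conv weights:  flattened to a (k*k*C_in) x C_out matrix, row index
//                  r = di + k*dj + k*k*c  (di = kernel row, dj = kernel col)
//   im2col column index p = ho + Hout*wo, so the GEMM output (P x C_out)
//   shares memory layout with an (Hout, Wout, C_out) array slice.
//
// Transposed convolution is expressed in R through these same primitives
// (forward = conv_bwd_data, backward-data = conv_fwd, backward-weight =
// conv_bwd_weight with the roles of input and upstream gradient swapped).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Hout, int Wout,
                   arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + dj;
          double* col = cols.colptr(0) + r; // row r, advance by K per column
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Hout; ++ho)
              cols(r, ho + (size_t)Hout * wo) = 0.0;
            continue;
          }
          const double* xw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + di;
            cols(r, ho + (size_t)Hout * wo) =
                (hi >= 0 && hi < H) ? xw[hi] : 0.0;
          }
          (void)col;
        }
      }
    }
  }
}

// scatter-add of column matrix back onto an image (adjoint of im2col)
static void col2im_add(const arma::mat& cols, int H, int W, int C,
                       int k, int stride, int pad, int Hout, int Wout,
                       double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + dj;
          if (wi < 0 || wi >= W) continue;
          double* xw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + di;
            if (hi >= 0 && hi < H)
              xw[hi] += cols(r, ho + (size_t)Hout * wo);
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wk, NumericVector b,
                           int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = k * k * C;
  if (Wk.nrow() != K) stop("weight rows do not match k*k*C_in");
  const int Cout = Wk.ncol();
  const int Hout = out_size(H, k, stride, pad);
  const int Wout = out_size(W, k, stride, pad);
  if (Hout < 1 || Wout < 1) stop("input too small for kernel/stride/padding");
  const size_t P = (size_t)Hout * Wout;

  arma::mat Wm(Wk.begin(), K, Cout, false);
  arma::mat cols(K, P);
  NumericVector out(P * Cout * N);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Hout, Wout, cols);
    arma::mat o(out.begin() + P * Cout * n, P, Cout, false, true);
    o = cols.t() * Wm;
    for (int co = 0; co < Cout; ++co) o.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector dy, NumericMatrix Wk,
                  int k, int stride, int pad, bool need_dx) {
  IntegerVector dxdim = dims4(x), dydim = dims4(dy);
  const int H = dxdim[0], W = dxdim[1], C = dxdim[2], N = dxdim[3];
  const int Hout = dydim[0], Wout = dydim[1], Cout = dydim[2];
  if (dydim[3] != N) stop("batch size mismatch between x and dy");
  if (out_size(H, k, stride, pad) != Hout ||
      out_size(W, k, stride, pad) != Wout)
    stop("dy spatial size inconsistent with x and conv geometry");
  const int K = k * k * C;
  if (Wk.nrow() != K || Wk.ncol() != Cout) stop("weight shape mismatch");
  const size_t P = (size_t)Hout * Wout;

  arma::mat Wm(Wk.begin(), K, Cout, false);
  arma::mat cols(K, P);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  for (int n = 0; n < N; ++n) {
    const arma::mat dym(const_cast<double*>(dy.begin()) + P * Cout * n,
                        P, Cout, false);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Hout, Wout, cols);
    dW += cols * dym;
    db += arma::sum(dym, 0).t();
    if (need_dx) {
      arma::mat dcols = Wm * dym.t();
      col2im_add(dcols, H, W, C, k, stride, pad, Hout, Wout,
                 dx.begin() + (size_t)H * W * C * n);
    }
  }

  List res = List::create(_["dW"] = wrap(dW), _["db"] = wrap(db));
  if (need_dx) res["dx"] = dx;
  return res;
}

// backward-data alone; also serves as the transposed-convolution forward
// (Hin/Win give the size of the reconstructed input plane).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericMatrix Wk,
                                int k, int stride, int pad,
                                int Hin, int Win) {
  IntegerVector d = dims4(dy);
  const int Hout = d[0], Wout = d[1], Cout = d[2], N = d[3];
  const int K = Wk.nrow();
  if (K % (k * k) != 0) stop("weight rows not a multiple of k*k");
  const int C = K / (k * k);
  if (Wk.ncol() != Cout) stop("weight columns do not match dy channels");
  if (out_size(Hin, k, stride, pad) != Hout ||
      out_size(Win, k, stride, pad) != Wout)
    stop("requested input size inconsistent with conv geometry");
  const size_t P = (size_t)Hout * Wout;

  arma::mat Wm(Wk.begin(), K, Cout, false);
  NumericVector dx((size_t)Hin * Win * C * N);
  dx.attr("dim") = IntegerVector::create(Hin, Win, C, N);

  for (int n = 0; n < N; ++n) {
    const arma::mat dym(const_cast<double*>(dy.begin()) + P * Cout * n,
                        P, Cout, false);
    arma::mat dcols = Wm * dym.t();
    col2im_add(dcols, Hin, Win, C, k, stride, pad, Hout, Wout,
               dx.begin() + (size_t)Hin * Win * C * n);
  }
  return dx;
}
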