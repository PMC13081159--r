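// Low-level kernels for the CPU training engine: 2-D convolution via
// im2col + GEMM (forward, input-gradient, weight-gradient) and binary
// connected-component labelling.
//
// Array layout follows R's column-major convention throughout:
//   feature maps  (H, W, C, N)   — height fastest
//   conv weights  (kh, kw, Cin/groups, Cout)
//
// The patch matrix is stored transposed, (N*P) x K with P = Ho*Wo and
// K = kh*kw*Cin_g, so that both the fill loops and the GEMMs run down
// contiguous columns; samples are batched into one GEMM per group.
// Pointwise (1x1, stride 1) convolutions skip im2col entirely and GEMM
// directly on channel-plane views.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill rows [n*P, (n+1)*P) of colsT from sample slab x (H x W x C0)
static void im2col_t(const double* x, int H, int W, int C0,
                     int kh, int kw, int pad, int stride,
                     int Ho, int Wo, arma::mat& colsT, size_t row0) {
  const size_t P = (size_t)Ho * Wo;
  for (int ci = 0; ci < C0; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        double* dst = colsT.colptr(r) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          double* dcol = dst + (size_t)Ho * jo;
          if (j < 0 || j >= W) {
            std::fill(dcol, dcol + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * j;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            dcol[io] = (i < 0 || i >= H) ? 0.0 : xcol[i];
          }
        }
      }
    }
  }
}

static void col2im_add_t(const arma::mat& dcolsT, size_t row0,
                         int H, int W, int C0,
                         int kh, int kw, int pad, int stride,
                         int Ho, int Wo, double* dx) {
  for (int ci = 0; ci < C0; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        const double* src = dcolsT.colptr(r) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          double* xcol = xc + (size_t)H * j;
          const double* scol = src + (size_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride + ki - pad;
            if (i >= 0 && i < H) xcol[i] += scol[io];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int pad, int stride,
                             int groups) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin_g = wdim[2], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout_g = Cout / groups;
  const int K = kh * kw * Cin_g;
  const size_t P = (size_t)Ho * Wo;
  const bool pointwise = (kh == 1 && kw == 1 && pad == 0 && stride == 1);

  NumericVector out((size_t)P * Cout * N);
  const arma::mat Wall(const_cast<double*>(w.begin()), K, Cout, false, true);
  const bool has_bias = bias.size() == Cout;

  if (pointwise) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(x.begin()) +
                          ((size_t)n * Cin + g * Cin_g) * P,
                          P, Cin_g, false, true);
        arma::mat Y(out.begin() + ((size_t)n * Cout + g * Cout_g) * P,
                    P, Cout_g, false, true);
        Y = X * Wall.cols(g * Cout_g, (g + 1) * Cout_g - 1);
      }
    }
  } else {
    arma::mat colsT((size_t)N * P, K);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        im2col_t(x.begin() + ((size_t)n * Cin + g * Cin_g) * H * W,
                 H, W, Cin_g, kh, kw, pad, stride, Ho, Wo, colsT, n * P);
      }
      const arma::mat Y =
        colsT * Wall.cols(g * Cout_g, (g + 1) * Cout_g - 1);
      for (int n = 0; n < N; ++n) {
        for (int co = 0; co < Cout_g; ++co) {
          std::copy(Y.colptr(co) + (size_t)n * P,
                    Y.colptr(co) + (size_t)(n + 1) * P,
                    out.begin() +
                      ((size_t)n * Cout + g * Cout_g + co) * P);
        }
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n) {
      for (int co = 0; co < Cout; ++co) {
        double* o = out.begin() + ((size_t)n * Cout + co) * P;
        const double bv = bias[co];
        for (size_t p = 0; p < P; ++p) o[p] += bv;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy, int pad, int stride,
                    int groups, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin_g = wdim[2], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout_g = Cout / groups;
  const int K = kh * kw * Cin_g;
  const size_t P = (size_t)Ho * Wo;
  const bool pointwise = (kh == 1 && kw == 1 && pad == 0 && stride == 1);

  NumericVector dx((size_t)H * W * Cin * N);
  NumericVector dw(w.size());
  NumericVector db(has_bias ? Cout : 0);
  const arma::mat Wall(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWall(dw.begin(), K, Cout, false, true);

  if (pointwise) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(x.begin()) +
                          ((size_t)n * Cin + g * Cin_g) * P,
                          P, Cin_g, false, true);
        const arma::mat dY(const_cast<double*>(dy.begin()) +
                           ((size_t)n * Cout + g * Cout_g) * P,
                           P, Cout_g, false, true);
        arma::mat dX(dx.begin() + ((size_t)n * Cin + g * Cin_g) * P,
                     P, Cin_g, false, true);
        dWall.cols(g * Cout_g, (g + 1) * Cout_g - 1) += X.t() * dY;
        dX += dY * Wall.cols(g * Cout_g, (g + 1) * Cout_g - 1).t();
      }
    }
  } else {
    arma::mat colsT((size_t)N * P, K);
    arma::mat dYg((size_t)N * P, Cout_g);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        im2col_t(x.begin() + ((size_t)n * Cin + g * Cin_g) * H * W,
                 H, W, Cin_g, kh, kw, pad, stride, Ho, Wo, colsT, n * P);
        for (int co = 0; co < Cout_g; ++co) {
          const double* s = dy.begin() +
            ((size_t)n * Cout + g * Cout_g + co) * P;
          std::copy(s, s + P, dYg.colptr(co) + (size_t)n * P);
        }
      }
      dWall.cols(g * Cout_g, (g + 1) * Cout_g - 1) += colsT.t() * dYg;
      const arma::mat dcolsT =
        dYg * Wall.cols(g * Cout_g, (g + 1) * Cout_g - 1).t();
      for (int n = 0; n < N; ++n) {
        col2im_add_t(dcolsT, n * P, H, W, Cin_g, kh, kw, pad, stride,
                     Ho, Wo,
                     dx.begin() + ((size_t)n * Cin + g * Cin_g) * H * W);
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n) {
      for (int co = 0; co < Cout; ++co) {
        const double* o = dy.begin() + ((size_t)n * Cout + co) * P;
        double s = 0.0;
        for (size_t p = 0; p < P; ++p) s += o[p];
        db[co] += s;
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Binary connected components, 8- or 4-connectivity, iterative flood fill.
// mask: H x W in {0,1}; returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, int H, int W,
                                   bool eight) {
  IntegerVector lab((size_t)H * W, 0);
  std::vector<size_t> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = eight ? 8 : 4;
  for (size_t s = 0; s < (size_t)H * W; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = cur % H, j = cur / H;
      for (int t = 0; t < nn; ++t) {
        const int ii = i + di8[t], jj = j + dj8[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        const size_t q = ii + (size_t)H * jj;
        if (mask[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(H, W);
  return lab;
}
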