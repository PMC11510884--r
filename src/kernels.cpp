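// Dense numeric kernels for the network: 2-D convolution (im2col + BLAS gemm),
// max pooling and spatial pyramid pooling, each with its adjoint for backprop.
// Tensor layout throughout: column-major R arrays (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix for one image: rows = kh*kw*Cin, cols = Ho*Wo.
template <typename T, typename MatT>
static void im2col(const T* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, MatT& K) {
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)c * H * W;
    for (int dkw = 0; dkw < kw; ++dkw) {
      for (int dkh = 0; dkh < kh; ++dkh) {
        int r = dkh + kh * (dkw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dkw;
          T* Kcol = K.memptr() + (size_t)r + (size_t)K.n_rows * (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) Kcol[(size_t)ho * K.n_rows] = 0.0;
          } else {
            const T* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + dkh;
              Kcol[(size_t)ho * K.n_rows] =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back into the image gradient.
template <typename T, typename MatT>
static void col2im(const MatT& K, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, T* dx) {
  for (int c = 0; c < C; ++c) {
    T* xc = dx + (size_t)c * H * W;
    for (int dkw = 0; dkw < kw; ++dkw) {
      for (int dkh = 0; dkh < kh; ++dkh) {
        int r = dkh + kh * (dkw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dkw;
          if (wi < 0 || wi >= W) continue;
          const T* Kcol = K.memptr() + (size_t)r + (size_t)K.n_rows * (size_t)Ho * wo;
          T* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dkh;
            if (hi >= 0 && hi < H) xcol[hi] += Kcol[(size_t)ho * K.n_rows];
          }
        }
      }
    }
  }
}

static arma::fvec to_float(const NumericVector& v) {
  arma::fvec out(v.size());
  const double* p = v.begin();
  float* q = out.memptr();
  for (R_xlen_t i = 0; i < v.size(); ++i) q[i] = (float)p[i];
  return out;
}

// Convolution in single precision (sgemm); act = 1 fuses a ReLU into the output.
// [[Rcpp::export]]
NumericVector cn_conv2d_forward(NumericVector x, NumericVector w,
                                NumericVector bias, int stride, int pad,
                                int act = 0) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  arma::fvec xf = to_float(x), wf = to_float(w);
  arma::fmat Wm(wf.memptr(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::fmat K(one_by_one ? 0 : (size_t)kh * kw * Cin,
               one_by_one ? 0 : (size_t)Ho * Wo);
  arma::fmat Yn((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    if (one_by_one) {
      arma::fmat Xn(xf.memptr() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
      Yn = Xn * Wm;
    } else {
      im2col(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
      Yn = K.t() * Wm;
    }
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float* col = Yn.colptr(co);
      float b = (float)bias[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
        float v = col[i] + b;
        if (act == 1 && v < 0) v = 0;
        yp[(size_t)co * Ho * Wo + i] = v;
      }
    }
  }
  return y;
}

// Backward pass. When act = 1, `y` must be the forward (post-ReLU) output and
// dy is masked by it. Single precision internally; gradients returned as double.
// [[Rcpp::export]]
List cn_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                        int stride, int pad, bool need_dx,
                        int act = 0, Nullable<NumericVector> y = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  arma::fvec xf = to_float(x), wf = to_float(w), dyf = to_float(dy);
  if (act == 1) {
    if (y.isNull()) stop("conv2d backward: ReLU output required");
    NumericVector yy(y);
    const double* yp = yy.begin();
    float* dp = dyf.memptr();
    for (R_xlen_t i = 0; i < dy.size(); ++i) if (yp[i] <= 0) dp[i] = 0;
  }
  arma::fmat Wm(wf.memptr(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::fvec dxf;
  if (need_dx) dxf.zeros((size_t)H * W * C * N);
  arma::fmat dWm((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::fmat K(one_by_one ? 0 : (size_t)kh * kw * Cin,
               one_by_one ? 0 : (size_t)Ho * Wo);
  arma::fmat dK(arma::size(K));
  for (int n = 0; n < N; ++n) {
    arma::fmat Dn(dyf.memptr() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    if (one_by_one) {
      arma::fmat Xn(xf.memptr() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
      dWm += Xn.t() * Dn;
      if (need_dx) {
        arma::fmat dXn(dxf.memptr() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
        dXn = Dn * Wm.t();
      }
    } else {
      im2col(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
      dWm += K * Dn;
      if (need_dx) {
        dK = Wm * Dn.t();
        col2im(dK, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dxf.memptr() + (size_t)n * H * W * C);
      }
    }
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(Dn.col(co));
  }
  NumericVector dw((R_xlen_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  NumericVector dx(need_dx ? (R_xlen_t)H * W * C * N : 0);
  if (need_dx) {
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    std::copy(dxf.begin(), dxf.end(), dx.begin());
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Fused stem: conv (stride) + ReLU + max pool, all in single precision. The
// large pre-pool activation stays internal; backward only needs the pooled
// output and the argmax indices (positions with pooled value <= 0 were
// clipped by the ReLU and get zero gradient anyway).
// [[Rcpp::export]]
List cn_stempool_forward(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad, int pkh, int pkw, int pstride,
                         int ppad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("stem: input has %d channels but weights expect %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int Hp = out_size(Ho, pkh, pstride, ppad), Wp = out_size(Wo, pkw, pstride, ppad);
  if (Hp < 1 || Wp < 1) stop("stem: pooled output would be empty");

  arma::fvec xf = to_float(x), wf = to_float(w);
  arma::fmat Wm(wf.memptr(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Hp * Wp * Cout * N);
  y.attr("dim") = IntegerVector::create(Hp, Wp, Cout, N);
  IntegerVector idx(y.size());  // 0-based index into the pre-pool (Ho,Wo,Cout,N) tensor
  arma::fmat K((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  arma::fmat Yn((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
    Yn = K.t() * Wm;
    for (int co = 0; co < Cout; ++co) {
      float* col = Yn.colptr(co);
      float b = (float)bias[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
        float v = col[i] + b;
        col[i] = v < 0 ? 0.0f : v;
      }
      // max pool this channel
      size_t obase = ((size_t)n * Cout + co) * (size_t)Hp * Wp;
      size_t pbase = ((size_t)n * Cout + co) * (size_t)Ho * Wo;
      for (int wp = 0; wp < Wp; ++wp) {
        for (int hp = 0; hp < Hp; ++hp) {
          float best = -HUGE_VALF; int besti = -1;
          for (int dw2 = 0; dw2 < pkw; ++dw2) {
            int wi = wp * pstride - ppad + dw2;
            if (wi < 0 || wi >= Wo) continue;
            for (int dh2 = 0; dh2 < pkh; ++dh2) {
              int hi = hp * pstride - ppad + dh2;
              if (hi < 0 || hi >= Ho) continue;
              float v = col[(size_t)wi * Ho + hi];
              if (v > best) { best = v; besti = (int)((size_t)wi * Ho + hi); }
            }
          }
          size_t o = obase + (size_t)wp * Hp + hp;
          y[o] = besti < 0 ? 0.0 : best;
          idx[o] = besti < 0 ? -1 : (int)(pbase + besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
List cn_stempool_backward(NumericVector x, NumericVector w, NumericVector dpool,
                          NumericVector pooled, IntegerVector idx,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  arma::fvec xf = to_float(x);
  arma::fvec dyf; dyf.zeros((size_t)Ho * Wo * Cout * N);
  // scatter pooled gradients; ReLU mask: clipped positions have pooled value 0
  for (R_xlen_t i = 0; i < dpool.size(); ++i)
    if (idx[i] >= 0 && pooled[i] > 0) dyf[idx[i]] += (float)dpool[i];
  arma::fmat dWm((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  arma::fmat K((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::fmat Dn(dyf.memptr() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
    dWm += K * Dn;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(Dn.col(co));
  }
  NumericVector dw((R_xlen_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cn_maxpool_forward(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("maxpool: output would be empty");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x of each max
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int besti = -1;
          for (int dkw = 0; dkw < kw; ++dkw) {
            int wi = wo * stride - pad + dkw;
            if (wi < 0 || wi >= W) continue;
            for (int dkh = 0; dkh < kh; ++dkh) {
              int hi = ho * stride - pad + dkh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[(size_t)wi * H + hi];
              if (v > best) { best = v; besti = (int)((size_t)wi * H + hi); }
            }
          }
          if (besti < 0) best = 0.0;  // window fully in padding
          o = ((size_t)n * C + c) * (size_t)Ho * Wo + (size_t)wo * Ho + ho;
          y[o] = best;
          idx[o] = besti < 0 ? -1 : (int)(base + besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cn_maxpool_backward(NumericVector dy, IntegerVector idx,
                                  IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (idx[i] >= 0) dx[idx[i]] += dy[i];
  return dx;
}

// Spatial pyramid pooling: for each level l the map is split into an l x l grid
// (cell boundaries floor(i*H/l)) and max-pooled per cell and channel. Tokens are
// emitted level-major, row-major within a level, as a ((N * n_tokens) x C) matrix
// whose row for item n, token t is n * n_tokens + t (0-based).
// [[Rcpp::export]]
List cn_spp_forward(NumericVector x, IntegerVector levels) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int ntok = 0;
  for (int li = 0; li < levels.size(); ++li) {
    if (H < levels[li] || W < levels[li])
      stop("spp: map %dx%d smaller than pyramid level %d", H, W, levels[li]);
    ntok += levels[li] * levels[li];
  }
  NumericMatrix tok((size_t)N * ntok, C);
  IntegerMatrix idx((size_t)N * ntok, C);
  for (int n = 0; n < N; ++n) {
    int t = 0;
    for (int li = 0; li < levels.size(); ++li) {
      int l = levels[li];
      for (int gr = 0; gr < l; ++gr) {        // row-major within a level
        int h0 = (int)((long long)gr * H / l), h1 = (int)((long long)(gr + 1) * H / l);
        for (int gc = 0; gc < l; ++gc) {
          int w0 = (int)((long long)gc * W / l), w1 = (int)((long long)(gc + 1) * W / l);
          int row = n * ntok + t;
          for (int c = 0; c < C; ++c) {
            const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
            double best = -HUGE_VAL; size_t besti = 0;
            for (int wi = w0; wi < w1; ++wi)
              for (int hi = h0; hi < h1; ++hi) {
                double v = xc[(size_t)wi * H + hi];
                if (v > best) { best = v; besti = (size_t)wi * H + hi; }
              }
            tok(row, c) = best;
            idx(row, c) = (int)(((size_t)n * C + c) * H * W + besti);
          }
          ++t;
        }
      }
    }
  }
  return List::create(_["tokens"] = tok, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cn_spp_backward(NumericMatrix dtok, IntegerMatrix idx,
                              IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (int j = 0; j < dtok.ncol(); ++j)
    for (int i = 0; i < dtok.nrow(); ++i)
      dx[idx(i, j)] += dtok(i, j);
  return dx;
}

// In-place ReLU on a fresh tensor (internal: callers own the buffer).
// [[Rcpp::export]]
NumericVector cn_relu_inplace(NumericVector x) {
  double* p = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) if (p[i] < 0) p[i] = 0;
  return x;
}

// In-place ReLU adjoint: zero dy wherever the forward output was clipped.
// [[Rcpp::export]]
NumericVector cn_relu_backward(NumericVector dy, NumericVector y) {
  double* d = dy.begin();
  const double* p = y.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) if (p[i] <= 0) d[i] = 0;
  return dy;
}

// Channel-wise concatenation of equally shaped (H, W, C, N) arrays.
// [[Rcpp::export]]
NumericVector cn_concat_channels(List xs) {
  int nb = xs.size();
  NumericVector x0 = xs[0];
  IntegerVector d = x0.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((R_xlen_t)H * W * C * nb * N);
  y.attr("dim") = IntegerVector::create(H, W, C * nb, N);
  size_t chunk = (size_t)H * W * C;
  for (int b = 0; b < nb; ++b) {
    NumericVector xb = xs[b];
    for (int n = 0; n < N; ++n)
      std::copy(xb.begin() + (size_t)n * chunk, xb.begin() + (size_t)(n + 1) * chunk,
                y.begin() + ((size_t)n * nb + b) * chunk);
  }
  return y;
}

// Split the gradient of a channel concatenation back into its nb parts.
// [[Rcpp::export]]
List cn_split_channels(NumericVector dy, int nb) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], Call = d[2], N = d[3];
  int C = Call / nb;
  List out(nb);
  size_t chunk = (size_t)H * W * C;
  for (int b = 0; b < nb; ++b) {
    NumericVector part((R_xlen_t)H * W * C * N);
    part.attr("dim") = IntegerVector::create(H, W, C, N);
    for (int n = 0; n < N; ++n)
      std::copy(dy.begin() + ((size_t)n * nb + b) * chunk,
                dy.begin() + ((size_t)n * nb + b + 1) * chunk,
                part.begin() + (size_t)n * chunk);
    out[b] = part;
  }
  return out;
}

// Multi-head self-attention over per-item token blocks. x is ((N*n_tok) x d),
// item i occupying rows i*n_tok .. (i+1)*n_tok-1 (0-based). Double precision:
// these matrices are small and the cost is dominated by the projections.
// [[Rcpp::export]]
List cn_mha_forward(const arma::mat& x, const arma::mat& wq, const arma::mat& wk,
                    const arma::mat& wv, const arma::mat& wo,
                    const arma::vec& bq, const arma::vec& bk,
                    const arma::vec& bv, const arma::vec& bo,
                    int n_tok, int n_heads) {
  int d = x.n_cols;
  int dh = d / n_heads;
  int n_items = x.n_rows / n_tok;
  arma::mat q = x * wq; q.each_row() += bq.t();
  arma::mat k = x * wk; k.each_row() += bk.t();
  arma::mat v = x * wv; v.each_row() += bv.t();
  arma::mat o(x.n_rows, d);
  arma::cube attn(n_tok, n_tok, (size_t)n_heads * n_items);
  double scale = 1.0 / std::sqrt((double)dh);
  for (int i = 0; i < n_items; ++i) {
    size_t r0 = (size_t)i * n_tok, r1 = r0 + n_tok - 1;
    for (int h = 0; h < n_heads; ++h) {
      size_t c0 = (size_t)h * dh, c1 = c0 + dh - 1;
      arma::mat s = q.submat(r0, c0, r1, c1) * k.submat(r0, c0, r1, c1).t() * scale;
      s.each_col() -= arma::max(s, 1);
      s = arma::exp(s);
      s.each_col() /= arma::sum(s, 1);
      attn.slice((size_t)i * n_heads + h) = s;
      o.submat(r0, c0, r1, c1) = s * v.submat(r0, c0, r1, c1);
    }
  }
  arma::mat y = o * wo; y.each_row() += bo.t();
  return List::create(_["y"] = y, _["q"] = q, _["k"] = k, _["v"] = v,
                      _["o"] = o, _["attn"] = attn);
}

// [[Rcpp::export]]
List cn_mha_backward(const arma::mat& x, const arma::mat& wq, const arma::mat& wk,
                     const arma::mat& wv, const arma::mat& wo,
                     const arma::mat& q, const arma::mat& k, const arma::mat& v,
                     const arma::mat& o, const arma::cube& attn,
                     const arma::mat& dy, int n_tok, int n_heads) {
  int d = x.n_cols;
  int dh = d / n_heads;
  int n_items = x.n_rows / n_tok;
  arma::mat dwo = o.t() * dy;
  arma::vec dbo = arma::sum(dy, 0).t();
  arma::mat do_ = dy * wo.t();
  arma::mat dq(arma::size(q), arma::fill::none), dk(arma::size(k), arma::fill::none),
            dv(arma::size(v), arma::fill::none);
  double scale = 1.0 / std::sqrt((double)dh);
  for (int i = 0; i < n_items; ++i) {
    size_t r0 = (size_t)i * n_tok, r1 = r0 + n_tok - 1;
    for (int h = 0; h < n_heads; ++h) {
      size_t c0 = (size_t)h * dh, c1 = c0 + dh - 1;
      const arma::mat& a = attn.slice((size_t)i * n_heads + h);
      arma::mat doh = do_.submat(r0, c0, r1, c1);
      arma::mat da = doh * v.submat(r0, c0, r1, c1).t();
      dv.submat(r0, c0, r1, c1) = a.t() * doh;
      arma::mat ds = a % (da.each_col() - arma::sum(a % da, 1));
      ds *= scale;
      dq.submat(r0, c0, r1, c1) = ds * k.submat(r0, c0, r1, c1);
      dk.submat(r0, c0, r1, c1) = ds.t() * q.submat(r0, c0, r1, c1);
    }
  }
  return List::create(
    _["dx"] = dq * wq.t() + dk * wk.t() + dv * wv.t(),
    _["dwq"] = x.t() * dq, _["dwk"] = x.t() * dk, _["dwv"] = x.t() * dv,
    _["dwo"] = dwo,
    _["dbq"] = arma::sum(dq, 0).t(), _["dbk"] = arma::sum(dk, 0).t(),
    _["dbv"] = arma::sum(dv, 0).t(), _["dbo"] = dbo);
}
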