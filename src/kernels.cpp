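// Dense numerical kernels for progseg.
//
// Array layout conventions (match the R side):
//   images / feature maps: numeric array dim c(D, H, W, C), column-major,
//     so voxel (d,h,w) of channel c sits at d + D*(h + H*(w + W*c)).
//   conv weights: dim c(K, K, K, Cin, Cout); flattened this is exactly the
//     (K^3*Cin) x Cout matrix used by the im2col GEMM.
//   displacement fields: dim c(D, H, W, 3), displacements in voxel units,
//     pull (backward-warp) convention, component order (d, h, w).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the im2col matrix M (N x K^3*Cin), N = D*H*W, zero padding `pad`.
// Column c*K^3 + k holds channel c shifted by kernel offset k.
static arma::mat build_im2col(const double* x, int D, int H, int W, int C,
                              int K, int pad) {
  const int N = D * H * W;
  const int K3 = K * K * K;
  arma::mat M((size_t)N, (size_t)K3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * N;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        for (int kd = 0; kd < K; ++kd) {
          const int k = kd + K * (kh + K * kw);
          double* col = M.colptr((size_t)c * K3 + k);
          const int dd = kd - pad, dh = kh - pad, dw = kw - pad;
          const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
          if (d1 <= d0) continue;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dh;
              if (sh < 0 || sh >= H) continue;
              const double* src = xc + (size_t)(d0 + dd) +
                                  (size_t)D * (sh + (size_t)H * sw);
              double* dst = col + (size_t)d0 + (size_t)D * (h + (size_t)H * w);
              std::memcpy(dst, src, sizeof(double) * (size_t)(d1 - d0));
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add the im2col layout back onto the input grid (adjoint of
// build_im2col).
static void col2im_add(const arma::mat& Gcol, double* gx, int D, int H, int W,
                       int C, int K, int pad) {
  const int N = D * H * W;
  const int K3 = K * K * K;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * N;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        for (int kd = 0; kd < K; ++kd) {
          const int k = kd + K * (kh + K * kw);
          const double* col = Gcol.colptr((size_t)c * K3 + k);
          const int dd = kd - pad, dh = kh - pad, dw = kw - pad;
          const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
          if (d1 <= d0) continue;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dh;
              if (sh < 0 || sh >= H) continue;
              double* dst = xc + (size_t)(d0 + dd) +
                            (size_t)D * (sh + (size_t)H * sw);
              const double* src = col + (size_t)d0 +
                                  (size_t)D * (h + (size_t)H * w);
              for (int d = 0; d < d1 - d0; ++d) dst[d] += src[d];
            }
          }
        }
      }
    }
  }
}

// Resolution-preserving 3D convolution ("same" padding).
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector b,
                         int D, int H, int W, int Cin, int Cout, int K,
                         int pad) {
  const int N = D * H * W;
  const int K3 = K * K * K;
  arma::mat M = build_im2col(x.begin(), D, H, W, Cin, K, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K3 * Cin, Cout, false,
               true);
  arma::mat Y = M * Wm;
  for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return out;
}

// Gradients of cpp_conv3d w.r.t. input, weights and bias.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy, int D,
                    int H, int W, int Cin, int Cout, int K, int pad,
                    bool need_gx) {
  const int N = D * H * W;
  const int K3 = K * K * K;
  arma::mat Gy(const_cast<double*>(gy.begin()), (size_t)N, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K3 * Cin, Cout, false,
               true);
  arma::mat M = build_im2col(x.begin(), D, H, W, Cin, K, pad);
  arma::mat Gw = M.t() * Gy;
  NumericVector gw(Gw.begin(), Gw.end());
  gw.attr("dim") = IntegerVector::create(K, K, K, Cin, Cout);
  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(Gy.col(c));
  NumericVector gx;
  if (need_gx) {
    arma::mat Gcol = Gy * Wm.t();
    gx = NumericVector((size_t)N * Cin);
    col2im_add(Gcol, gx.begin(), D, H, W, Cin, K, pad);
    gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Build the (Cin x 8*Cout) matrix view of a kernel-2 transposed-conv weight
// stored as dim c(2,2,2,Cin,Cout): Wm(ci, co*8 + k) = w[k + 8*(ci + Cin*co)].
static arma::mat convT_weight_mat(const double* w, int Cin, int Cout) {
  arma::mat Wm(Cin, (size_t)8 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int k = 0; k < 8; ++k)
        Wm(ci, (size_t)co * 8 + k) = w[k + 8 * ((size_t)ci + (size_t)Cin * co)];
  return Wm;
}

// Transposed 3D convolution, kernel 2, stride 2 (x2 upsampling). Each output
// voxel receives exactly one contribution, so scatter is an assignment.
// [[Rcpp::export]]
NumericVector cpp_convT3d(NumericVector x, NumericVector w, NumericVector b,
                          int D, int H, int W, int Cin, int Cout) {
  const int N = D * H * W;
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  arma::mat X(const_cast<double*>(x.begin()), (size_t)N, Cin, false, true);
  arma::mat Wm = convT_weight_mat(w.begin(), Cin, Cout);
  arma::mat Y8 = X * Wm;  // N x 8*Cout
  NumericVector out((size_t)D2 * H2 * W2 * Cout);
  double* o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int k = 0; k < 8; ++k) {
      const int kd = k & 1, kh = (k >> 1) & 1, kw = (k >> 2) & 1;
      const double* src = Y8.colptr((size_t)co * 8 + k);
      for (int wv = 0; wv < W; ++wv)
        for (int h = 0; h < H; ++h)
          for (int d = 0; d < D; ++d) {
            const size_t oi = (size_t)(2 * d + kd) +
                              (size_t)D2 * ((2 * h + kh) +
                              (size_t)H2 * ((2 * wv + kw) + (size_t)W2 * co));
            o[oi] = src[d + (size_t)D * (h + (size_t)H * wv)] + b[co];
          }
    }
  }
  out.attr("dim") = IntegerVector::create(D2, H2, W2, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_convT3d_bwd(NumericVector x, NumericVector w, NumericVector gy, int D,
                     int H, int W, int Cin, int Cout) {
  const int N = D * H * W;
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  arma::mat G8((size_t)N, (size_t)8 * Cout);
  const double* g = gy.begin();
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int k = 0; k < 8; ++k) {
      const int kd = k & 1, kh = (k >> 1) & 1, kw = (k >> 2) & 1;
      double* dst = G8.colptr((size_t)co * 8 + k);
      for (int wv = 0; wv < W; ++wv)
        for (int h = 0; h < H; ++h)
          for (int d = 0; d < D; ++d) {
            const size_t oi = (size_t)(2 * d + kd) +
                              (size_t)D2 * ((2 * h + kh) +
                              (size_t)H2 * ((2 * wv + kw) + (size_t)W2 * co));
            const double v = g[oi];
            dst[d + (size_t)D * (h + (size_t)H * wv)] = v;
            s += v;
          }
    }
    gb[co] = s;
  }
  arma::mat X(const_cast<double*>(x.begin()), (size_t)N, Cin, false, true);
  arma::mat Wm = convT_weight_mat(w.begin(), Cin, Cout);
  arma::mat Gx = G8 * Wm.t();
  arma::mat Gwm = X.t() * G8;  // Cin x 8*Cout
  NumericVector gx(Gx.begin(), Gx.end());
  gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  NumericVector gw((size_t)8 * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int k = 0; k < 8; ++k)
        gw[k + 8 * ((size_t)ci + (size_t)Cin * co)] =
            Gwm(ci, (size_t)co * 8 + k);
  gw.attr("dim") = IntegerVector::create(2, 2, 2, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; returns pooled values and 1-based argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, int D, int H, int W, int C) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Do * Ho * Wo * C);
  IntegerVector idx((size_t)Do * Ho * Wo * C);
  const double* xp = x.begin();
  size_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int wv = 0; wv < Wo; ++wv)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d, ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                const size_t xi = (size_t)(2 * d + kd) +
                                  (size_t)D * ((2 * h + kh) +
                                  (size_t)H * ((2 * wv + kw) + (size_t)W * c));
                if (xp[xi] > best) { best = xp[xi]; besti = xi; }
              }
          y[oi] = best;
          idx[oi] = (int)(besti + 1);
        }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx,
                                int nx) {
  NumericVector gx(nx);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Backward (pull) warp with trilinear interpolation and edge clamping.
// out(v) = img(v + dvf(v)), coordinates clamped to the grid.
// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector img, NumericVector dvf, int D,
                                 int H, int W) {
  const size_t N = (size_t)D * H * W;
  NumericVector out(N);
  const double* im = img.begin();
  const double* dv = dvf.begin();
  size_t i = 0;
  for (int wv = 0; wv < W; ++wv)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++i) {
        const double sd = clampd(d + dv[i], 0.0, D - 1.0);
        const double sh = clampd(h + dv[i + N], 0.0, H - 1.0);
        const double sw = clampd(wv + dv[i + 2 * N], 0.0, W - 1.0);
        const int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh),
                  w0 = (int)std::floor(sw);
        const int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1),
                  w1 = std::min(w0 + 1, W - 1);
        const double fd = sd - d0, fh = sh - h0, fw = sw - w0;
        double acc = 0.0;
        const int ds[2] = {d0, d1}, hs[2] = {h0, h1}, ws[2] = {w0, w1};
        const double wd[2] = {1.0 - fd, fd}, wh[2] = {1.0 - fh, fh},
                     ww[2] = {1.0 - fw, fw};
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int cc = 0; cc < 2; ++cc) {
              const double wt = wd[a] * wh[b] * ww[cc];
              if (wt == 0.0) continue;
              acc += wt * im[(size_t)ds[a] +
                             (size_t)D * (hs[b] + (size_t)H * ws[cc])];
            }
        out[i] = acc;
      }
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}

// Backward warp with nearest-neighbour sampling (labels stay labels).
// [[Rcpp::export]]
NumericVector cpp_warp_nn(NumericVector img, NumericVector dvf, int D, int H,
                          int W) {
  const size_t N = (size_t)D * H * W;
  NumericVector out(N);
  const double* im = img.begin();
  const double* dv = dvf.begin();
  size_t i = 0;
  for (int wv = 0; wv < W; ++wv)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++i) {
        const int sd = (int)clampd(std::round(d + dv[i]), 0.0, D - 1.0);
        const int sh = (int)clampd(std::round(h + dv[i + N]), 0.0, H - 1.0);
        const int sw = (int)clampd(std::round(wv + dv[i + 2 * N]), 0.0,
                                   W - 1.0);
        out[i] = im[(size_t)sd + (size_t)D * (sh + (size_t)H * sw)];
      }
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}

// Boundary voxels: foreground with at least one 6-neighbour background, or
// touching the volume edge.
static std::vector<std::array<int, 3>> boundary_voxels(const double* m, int D,
                                                       int H, int W) {
  std::vector<std::array<int, 3>> out;
  for (int wv = 0; wv < W; ++wv)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        if (m[(size_t)d + (size_t)D * (h + (size_t)H * wv)] == 0.0) continue;
        bool bd = d == 0 || d == D - 1 || h == 0 || h == H - 1 || wv == 0 ||
                  wv == W - 1;
        if (!bd) {
          const int off[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                                 {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
          for (int k = 0; k < 6 && !bd; ++k) {
            const size_t ni = (size_t)(d + off[k][0]) +
                              (size_t)D * ((h + off[k][1]) +
                              (size_t)H * (wv + off[k][2]));
            if (m[ni] == 0.0) bd = true;
          }
        }
        if (bd) out.push_back({d, h, wv});
      }
  return out;
}

// Directed boundary-to-boundary distances (mm) in both directions.
// [[Rcpp::export]]
List cpp_surface_dists(NumericVector a, NumericVector b, int D, int H, int W,
                       NumericVector spacing) {
  std::vector<std::array<int, 3>> pa = boundary_voxels(a.begin(), D, H, W);
  std::vector<std::array<int, 3>> pb = boundary_voxels(b.begin(), D, H, W);
  const double sd = spacing[0], sh = spacing[1], sw = spacing[2];
  auto directed = [&](const std::vector<std::array<int, 3>>& from,
                      const std::vector<std::array<int, 3>>& to) {
    NumericVector out(from.size());
    for (size_t i = 0; i < from.size(); ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (size_t j = 0; j < to.size(); ++j) {
        const double dd = (from[i][0] - to[j][0]) * sd;
        const double dh = (from[i][1] - to[j][1]) * sh;
        const double dw = (from[i][2] - to[j][2]) * sw;
        const double v = dd * dd + dh * dh + dw * dw;
        if (v < best) best = v;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  };
  return List::create(_["ab"] = directed(pa, pb), _["ba"] = directed(pb, pa));
}

// Connected components of a binary mask under 6-connectivity (flood fill).
// [[Rcpp::export]]
int cpp_count_components(NumericVector m, int D, int H, int W) {
  std::vector<char> seen((size_t)D * H * W, 0);
  const double* mp = m.begin();
  int count = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < (size_t)D * H * W; ++start) {
    if (mp[start] == 0.0 || seen[start]) continue;
    ++count;
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      const size_t i = stack.back();
      stack.pop_back();
      const int d = (int)(i % D), h = (int)((i / D) % H),
                wv = (int)(i / ((size_t)D * H));
      const int off[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                             {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int k = 0; k < 6; ++k) {
        const int nd = d + off[k][0], nh = h + off[k][1], nw = wv + off[k][2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
          continue;
        const size_t ni = (size_t)nd + (size_t)D * (nh + (size_t)H * nw);
        if (mp[ni] != 0.0 && !seen[ni]) {
          seen[ni] = 1;
          stack.push_back(ni);
        }
      }
    }
  }
  return count;
}
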