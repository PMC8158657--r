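#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are stored column-major as (H, W, L) or (H, W, L, C) arrays,
// matching R's array layout. All kernels are single-threaded so that
// results are bit-reproducible.

static inline int idx3(int i, int j, int k, int H, int W) {
  return i + H * (j + W * k);
}

// 3D convolution, kernel (k,k,k,Cin,Cout), zero padding `pad`, stride `stride`.
// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], Cin = xd[3];
  const int K = wd[0], Cout = wd[4];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int Lo = (L + 2 * pad - K) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Lo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Lo, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  const int xch = H * W * L, ych = Ho * Wo * Lo, wch = K * K * K;

  for (int co = 0; co < Cout; ++co) {
    double *yc = py + static_cast<R_xlen_t>(co) * ych;
    for (int n = 0; n < ych; ++n) yc[n] = pb[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + static_cast<R_xlen_t>(ci) * xch;
      const double *wc = pw + static_cast<R_xlen_t>(wch) * (ci + Cin * co);
      for (int kk = 0; kk < K; ++kk) {
        for (int kj = 0; kj < K; ++kj) {
          for (int ki = 0; ki < K; ++ki) {
            const double wv = wc[ki + K * (kj + K * kk)];
            if (wv == 0.0) continue;
            for (int zo = 0; zo < Lo; ++zo) {
              const int zi = zo * stride + kk - pad;
              if (zi < 0 || zi >= L) continue;
              for (int jo = 0; jo < Wo; ++jo) {
                const int ji = jo * stride + kj - pad;
                if (ji < 0 || ji >= W) continue;
                const double *xrow = xc + H * (ji + W * zi);
                double *yrow = yc + Ho * (jo + Wo * zo);
                for (int io = 0; io < Ho; ++io) {
                  const int ii = io * stride + ki - pad;
                  if (ii < 0 || ii >= H) continue;
                  yrow[io] += wv * xrow[ii];
                }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Gradients of conv3_fwd w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv3_bwd(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], Cin = xd[3];
  const int K = wd[0], Cout = wd[4];
  const int Ho = yd[0], Wo = yd[1], Lo = yd[2];

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const int xch = H * W * L, ych = Ho * Wo * Lo, wch = K * K * K;

  for (int co = 0; co < Cout; ++co) {
    const double *gc = pg + static_cast<R_xlen_t>(co) * ych;
    double s = 0.0;
    for (int n = 0; n < ych; ++n) s += gc[n];
    pgb[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + static_cast<R_xlen_t>(ci) * xch;
      double *gxc = pgx + static_cast<R_xlen_t>(ci) * xch;
      const double *wc = pw + static_cast<R_xlen_t>(wch) * (ci + Cin * co);
      double *gwc = pgw + static_cast<R_xlen_t>(wch) * (ci + Cin * co);
      for (int kk = 0; kk < K; ++kk) {
        for (int kj = 0; kj < K; ++kj) {
          for (int ki = 0; ki < K; ++ki) {
            const double wv = wc[ki + K * (kj + K * kk)];
            double acc = 0.0;
            for (int zo = 0; zo < Lo; ++zo) {
              const int zi = zo * stride + kk - pad;
              if (zi < 0 || zi >= L) continue;
              for (int jo = 0; jo < Wo; ++jo) {
                const int ji = jo * stride + kj - pad;
                if (ji < 0 || ji >= W) continue;
                const double *xrow = xc + H * (ji + W * zi);
                double *gxrow = gxc + H * (ji + W * zi);
                const double *grow = gc + Ho * (jo + Wo * zo);
                for (int io = 0; io < Ho; ++io) {
                  const int ii = io * stride + ki - pad;
                  if (ii < 0 || ii >= H) continue;
                  acc += grow[io] * xrow[ii];
                  gxrow[ii] += grow[io] * wv;
                }
              }
            }
            gwc[ki + K * (kj + K * kk)] = acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct LinMap {
  std::vector<int> lo;
  std::vector<double> wlo; // weight on lo; 1 - wlo on lo + 1 (clamped)
  std::vector<int> hi;
};

// align_corners = FALSE convention: source coord = (i + 0.5) * in/out - 0.5.
static LinMap make_map(int out_n, int in_n) {
  LinMap m;
  m.lo.resize(out_n);
  m.hi.resize(out_n);
  m.wlo.resize(out_n);
  const double scale = static_cast<double>(in_n) / out_n;
  for (int i = 0; i < out_n; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in_n - 1) s = in_n - 1;
    int lo = static_cast<int>(std::floor(s));
    int hi = lo + 1 < in_n ? lo + 1 : in_n - 1;
    m.lo[i] = lo;
    m.hi[i] = hi;
    m.wlo[i] = 1.0 - (s - lo);
  }
  return m;
}

// Trilinear resize of an (H,W,L,C) array to (oh,ow,ol,C).
// [[Rcpp::export]]
NumericVector resize3(NumericVector x, int oh, int ow, int ol) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], C = xd[3];
  LinMap mi = make_map(oh, H), mj = make_map(ow, W), mk = make_map(ol, L);
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * ol * C);
  y.attr("dim") = IntegerVector::create(oh, ow, ol, C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + static_cast<R_xlen_t>(c) * H * W * L;
    double *yc = py + static_cast<R_xlen_t>(c) * oh * ow * ol;
    for (int k = 0; k < ol; ++k) {
      const int k0 = mk.lo[k], k1 = mk.hi[k];
      const double wk = mk.wlo[k];
      for (int j = 0; j < ow; ++j) {
        const int j0 = mj.lo[j], j1 = mj.hi[j];
        const double wj = mj.wlo[j];
        for (int i = 0; i < oh; ++i) {
          const int i0 = mi.lo[i], i1 = mi.hi[i];
          const double wi = mi.wlo[i];
          const double v =
            wk * (wj * (wi * xc[idx3(i0, j0, k0, H, W)] +
                        (1 - wi) * xc[idx3(i1, j0, k0, H, W)]) +
                  (1 - wj) * (wi * xc[idx3(i0, j1, k0, H, W)] +
                              (1 - wi) * xc[idx3(i1, j1, k0, H, W)])) +
            (1 - wk) * (wj * (wi * xc[idx3(i0, j0, k1, H, W)] +
                              (1 - wi) * xc[idx3(i1, j0, k1, H, W)]) +
                        (1 - wj) * (wi * xc[idx3(i0, j1, k1, H, W)] +
                                    (1 - wi) * xc[idx3(i1, j1, k1, H, W)]));
          yc[idx3(i, j, k, oh, ow)] = v;
        }
      }
    }
  }
  return y;
}

// Adjoint of resize3: scatter output-gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector resize3_bwd(NumericVector gy, int ih, int iw, int il) {
  IntegerVector yd = gy.attr("dim");
  const int oh = yd[0], ow = yd[1], ol = yd[2], C = yd[3];
  LinMap mi = make_map(oh, ih), mj = make_map(ow, iw), mk = make_map(ol, il);
  NumericVector gx(static_cast<R_xlen_t>(ih) * iw * il * C);
  gx.attr("dim") = IntegerVector::create(ih, iw, il, C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = pg + static_cast<R_xlen_t>(c) * oh * ow * ol;
    double *xc = px + static_cast<R_xlen_t>(c) * ih * iw * il;
    for (int k = 0; k < ol; ++k) {
      const int k0 = mk.lo[k], k1 = mk.hi[k];
      const double wk = mk.wlo[k];
      for (int j = 0; j < ow; ++j) {
        const int j0 = mj.lo[j], j1 = mj.hi[j];
        const double wj = mj.wlo[j];
        for (int i = 0; i < oh; ++i) {
          const int i0 = mi.lo[i], i1 = mi.hi[i];
          const double wi = mi.wlo[i];
          const double g = gc[idx3(i, j, k, oh, ow)];
          xc[idx3(i0, j0, k0, ih, iw)] += g * wk * wj * wi;
          xc[idx3(i1, j0, k0, ih, iw)] += g * wk * wj * (1 - wi);
          xc[idx3(i0, j1, k0, ih, iw)] += g * wk * (1 - wj) * wi;
          xc[idx3(i1, j1, k0, ih, iw)] += g * wk * (1 - wj) * (1 - wi);
          xc[idx3(i0, j0, k1, ih, iw)] += g * (1 - wk) * wj * wi;
          xc[idx3(i1, j0, k1, ih, iw)] += g * (1 - wk) * wj * (1 - wi);
          xc[idx3(i0, j1, k1, ih, iw)] += g * (1 - wk) * (1 - wj) * wi;
          xc[idx3(i1, j1, k1, ih, iw)] += g * (1 - wk) * (1 - wj) * (1 - wi);
        }
      }
    }
  }
  return gx;
}

// Box mean over a cubic window of odd size k, borders clamped (mean over the
// in-bounds part of the window). Separable implementation, per channel.
// [[Rcpp::export]]
NumericVector boxmean3(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], C = xd[3];
  const int r = k / 2;
  NumericVector out(clone(x));
  out.attr("dim") = xd;
  const int n = H * W * L;
  std::vector<double> buf(std::max(std::max(H, W), L));
  std::vector<double> cs(std::max(std::max(H, W), L) + 1);

  for (int c = 0; c < C; ++c) {
    double *v = out.begin() + static_cast<R_xlen_t>(c) * n;
    // pass along H
    for (int z = 0; z < L; ++z)
      for (int j = 0; j < W; ++j) {
        double *p = v + H * (j + W * z);
        cs[0] = 0;
        for (int i = 0; i < H; ++i) cs[i + 1] = cs[i] + p[i];
        for (int i = 0; i < H; ++i) {
          int a = std::max(0, i - r), b = std::min(H - 1, i + r);
          buf[i] = (cs[b + 1] - cs[a]) / (b - a + 1);
        }
        for (int i = 0; i < H; ++i) p[i] = buf[i];
      }
    // pass along W
    for (int z = 0; z < L; ++z)
      for (int i = 0; i < H; ++i) {
        cs[0] = 0;
        for (int j = 0; j < W; ++j) cs[j + 1] = cs[j] + v[idx3(i, j, z, H, W)];
        for (int j = 0; j < W; ++j) {
          int a = std::max(0, j - r), b = std::min(W - 1, j + r);
          buf[j] = (cs[b + 1] - cs[a]) / (b - a + 1);
        }
        for (int j = 0; j < W; ++j) v[idx3(i, j, z, H, W)] = buf[j];
      }
    // pass along L
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        cs[0] = 0;
        for (int z = 0; z < L; ++z) cs[z + 1] = cs[z] + v[idx3(i, j, z, H, W)];
        for (int z = 0; z < L; ++z) {
          int a = std::max(0, z - r), b = std::min(L - 1, z + r);
          buf[z] = (cs[b + 1] - cs[a]) / (b - a + 1);
        }
        for (int z = 0; z < L; ++z) v[idx3(i, j, z, H, W)] = buf[z];
      }
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing `s`: f is sampled at coordinates 0, s, 2s, ...
static void dt1(std::vector<double> &f, int n, double s) {
  std::vector<int> vtx(n);
  std::vector<double> zz(n + 1), d(n);
  int k = 0;
  vtx[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sweep;
    while (true) {
      double vs = vtx[k] * s;
      sweep = ((f[q] + qs * qs) - (f[vtx[k]] + vs * vs)) / (2 * qs - 2 * vs);
      if (sweep <= zz[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zz[k] = sweep;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (zz[k + 1] < qs) ++k;
    double vs = vtx[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[vtx[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance transform of a binary mask (H,W,L): distance from
// every voxel to the nearest foreground voxel, in physical units given the
// per-axis spacing. Background of an empty mask maps to Inf.
// [[Rcpp::export]]
NumericVector edt3(NumericVector mask, NumericVector spacing) {
  IntegerVector xd = mask.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2];
  // Large finite sentinel instead of Inf so the lower-envelope recursion in
  // dt1 never produces NaN when comparing two background-only parabolas.
  const double BIG = 1e20;
  NumericVector out(static_cast<R_xlen_t>(H) * W * L);
  out.attr("dim") = IntegerVector::create(H, W, L);
  double *v = out.begin();
  const double *m = mask.begin();
  for (int n = 0; n < H * W * L; ++n) v[n] = m[n] > 0.5 ? 0.0 : BIG;

  std::vector<double> f(std::max(std::max(H, W), L));
  // along H
  for (int z = 0; z < L; ++z)
    for (int j = 0; j < W; ++j) {
      double *p = v + H * (j + W * z);
      for (int i = 0; i < H; ++i) f[i] = p[i];
      dt1(f, H, spacing[0]);
      for (int i = 0; i < H; ++i) p[i] = f[i];
    }
  // along W
  for (int z = 0; z < L; ++z)
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) f[j] = v[idx3(i, j, z, H, W)];
      dt1(f, W, spacing[1]);
      for (int j = 0; j < W; ++j) v[idx3(i, j, z, H, W)] = f[j];
    }
  // along L
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      for (int z = 0; z < L; ++z) f[z] = v[idx3(i, j, z, H, W)];
      dt1(f, L, spacing[2]);
      for (int z = 0; z < L; ++z) v[idx3(i, j, z, H, W)] = f[z];
    }
  for (int n = 0; n < H * W * L; ++n)
    v[n] = v[n] >= 1e19 ? R_PosInf : std::sqrt(v[n]);
  return out;
}
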