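// Dense 3D network primitives used by the residual denoisers.
// Tensor layout: column-major R arrays with dim = (X, Y, Z, C, B).
// Convolutions use replicate (clamp-to-edge) padding so spatial shape is
// preserved; the backward pass accumulates into the clamped source voxels,
// which is the exact adjoint of that padding.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector input, IntegerVector idim,
                             NumericVector w, int k, int ci, int co,
                             NumericVector bias) {
  const int X = idim[0], Y = idim[1], Z = idim[2], B = idim[4];
  const int r = k / 2;
  const R_xlen_t sp = (R_xlen_t)X * Y * Z;
  NumericVector out((R_xlen_t)sp * co * B);
  const double* in = input.begin();
  const double* W = w.begin();
  double* O = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* inb = in + (R_xlen_t)b * sp * ci;
    double* ob = O + (R_xlen_t)b * sp * co;
    for (int oc = 0; oc < co; ++oc) {
      double* oc_p = ob + (R_xlen_t)oc * sp;
      for (R_xlen_t i = 0; i < sp; ++i) oc_p[i] = bias[oc];
      for (int icc = 0; icc < ci; ++icc) {
        const double* ic_p = inb + (R_xlen_t)icc * sp;
        const double* wk = W + (R_xlen_t)k * k * k * (icc + (R_xlen_t)ci * oc);
        for (int kz = 0; kz < k; ++kz)
          for (int ky = 0; ky < k; ++ky)
            for (int kx = 0; kx < k; ++kx) {
              double wv = wk[kx + k * (ky + k * kz)];
              if (wv == 0.0) continue;
              int dzo = kz - r, dyo = ky - r, dxo = kx - r;
              for (int z = 0; z < Z; ++z) {
                int sz = clampi(z + dzo, 0, Z - 1);
                for (int y = 0; y < Y; ++y) {
                  int sy = clampi(y + dyo, 0, Y - 1);
                  const double* row = ic_p + (R_xlen_t)X * (sy + (R_xlen_t)Y * sz);
                  double* orow = oc_p + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
                  for (int x = 0; x < X; ++x)
                    orow[x] += wv * row[clampi(x + dxo, 0, X - 1)];
                }
              }
            }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector input, IntegerVector idim,
                    NumericVector w, int k, int ci, int co,
                    NumericVector gout) {
  const int X = idim[0], Y = idim[1], Z = idim[2], B = idim[4];
  const int r = k / 2;
  const R_xlen_t sp = (R_xlen_t)X * Y * Z;
  NumericVector gin((R_xlen_t)sp * ci * B);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double* in = input.begin();
  const double* W = w.begin();
  const double* GO = gout.begin();
  double* GI = gin.begin();
  double* GW = gw.begin();
  for (int b = 0; b < B; ++b) {
    const double* inb = in + (R_xlen_t)b * sp * ci;
    const double* gob = GO + (R_xlen_t)b * sp * co;
    double* gib = GI + (R_xlen_t)b * sp * ci;
    for (int oc = 0; oc < co; ++oc) {
      const double* go_p = gob + (R_xlen_t)oc * sp;
      double s = 0.0;
      for (R_xlen_t i = 0; i < sp; ++i) s += go_p[i];
      gb[oc] += s;
      for (int icc = 0; icc < ci; ++icc) {
        const double* ic_p = inb + (R_xlen_t)icc * sp;
        double* gi_p = gib + (R_xlen_t)icc * sp;
        const double* wk = W + (R_xlen_t)k * k * k * (icc + (R_xlen_t)ci * oc);
        double* gwk = GW + (R_xlen_t)k * k * k * (icc + (R_xlen_t)ci * oc);
        for (int kz = 0; kz < k; ++kz)
          for (int ky = 0; ky < k; ++ky)
            for (int kx = 0; kx < k; ++kx) {
              double wv = wk[kx + k * (ky + k * kz)];
              double acc = 0.0;
              int dzo = kz - r, dyo = ky - r, dxo = kx - r;
              for (int z = 0; z < Z; ++z) {
                int sz = clampi(z + dzo, 0, Z - 1);
                for (int y = 0; y < Y; ++y) {
                  int sy = clampi(y + dyo, 0, Y - 1);
                  const double* row = ic_p + (R_xlen_t)X * (sy + (R_xlen_t)Y * sz);
                  double* grow = gi_p + (R_xlen_t)X * (sy + (R_xlen_t)Y * sz);
                  const double* gorow = go_p + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
                  for (int x = 0; x < X; ++x) {
                    int sx = clampi(x + dxo, 0, X - 1);
                    acc += gorow[x] * row[sx];
                    grow[sx] += gorow[x] * wv;
                  }
                }
              }
              gwk[kx + k * (ky + k * kz)] += acc;
            }
      }
    }
  }
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 average pooling, stride 2 (spatial dims must be even)
// [[Rcpp::export(name = ".avgpool2_fwd_cpp")]]
NumericVector avgpool2_fwd_cpp(NumericVector input, IntegerVector idim) {
  const int X = idim[0], Y = idim[1], Z = idim[2], C = idim[3], B = idim[4];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((R_xlen_t)Xo * Yo * Zo * C * B);
  const double* in = input.begin();
  double* O = out.begin();
  const R_xlen_t spi = (R_xlen_t)X * Y * Z, spo = (R_xlen_t)Xo * Yo * Zo;
  for (int cb = 0; cb < C * B; ++cb) {
    const double* ic = in + (R_xlen_t)cb * spi;
    double* oc = O + (R_xlen_t)cb * spo;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int x = 0; x < Xo; ++x) {
          double s = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                s += ic[(2 * x + dx) + (R_xlen_t)X * ((2 * y + dy) + (R_xlen_t)Y * (2 * z + dz))];
          oc[x + (R_xlen_t)Xo * (y + (R_xlen_t)Yo * z)] = s * 0.125;
        }
  }
  return out;
}

// [[Rcpp::export(name = ".avgpool2_bwd_cpp")]]
NumericVector avgpool2_bwd_cpp(NumericVector gout, IntegerVector idim) {
  const int X = idim[0], Y = idim[1], Z = idim[2], C = idim[3], B = idim[4];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector gin((R_xlen_t)X * Y * Z * C * B);
  const double* GO = gout.begin();
  double* GI = gin.begin();
  const R_xlen_t spi = (R_xlen_t)X * Y * Z, spo = (R_xlen_t)Xo * Yo * Zo;
  for (int cb = 0; cb < C * B; ++cb) {
    double* ic = GI + (R_xlen_t)cb * spi;
    const double* oc = GO + (R_xlen_t)cb * spo;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int x = 0; x < Xo; ++x) {
          double gv = oc[x + (R_xlen_t)Xo * (y + (R_xlen_t)Yo * z)] * 0.125;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                ic[(2 * x + dx) + (R_xlen_t)X * ((2 * y + dy) + (R_xlen_t)Y * (2 * z + dz))] = gv;
        }
  }
  return gin;
}

// transposed convolution, kernel 2, stride 2 (exact 2x upsampling)
// weight layout: (2,2,2, Ci, Co)
// [[Rcpp::export(name = ".tconv2_fwd_cpp")]]
NumericVector tconv2_fwd_cpp(NumericVector input, IntegerVector idim,
                             NumericVector w, int ci, int co,
                             NumericVector bias) {
  const int X = idim[0], Y = idim[1], Z = idim[2], B = idim[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const R_xlen_t spi = (R_xlen_t)X * Y * Z, spo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out(spo * co * B);
  const double* in = input.begin();
  const double* W = w.begin();
  double* O = out.begin();
  for (int b = 0; b < B; ++b)
    for (int oc = 0; oc < co; ++oc) {
      double* op = O + spo * (oc + (R_xlen_t)co * b);
      for (R_xlen_t i = 0; i < spo; ++i) op[i] = bias[oc];
      for (int icc = 0; icc < ci; ++icc) {
        const double* ip = in + spi * (icc + (R_xlen_t)ci * b);
        const double* wk = W + 8 * ((R_xlen_t)icc + (R_xlen_t)ci * oc);
        for (int z = 0; z < Z; ++z)
          for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
              double v = ip[x + (R_xlen_t)X * (y + (R_xlen_t)Y * z)];
              if (v == 0.0) continue;
              for (int dz = 0; dz < 2; ++dz)
                for (int dy = 0; dy < 2; ++dy)
                  for (int dx = 0; dx < 2; ++dx)
                    op[(2 * x + dx) + (R_xlen_t)Xo * ((2 * y + dy) + (R_xlen_t)Yo * (2 * z + dz))] +=
                      v * wk[dx + 2 * (dy + 2 * dz)];
            }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".tconv2_bwd_cpp")]]
List tconv2_bwd_cpp(NumericVector input, IntegerVector idim,
                    NumericVector w, int ci, int co, NumericVector gout) {
  const int X = idim[0], Y = idim[1], Z = idim[2], B = idim[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const R_xlen_t spi = (R_xlen_t)X * Y * Z, spo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector gin(spi * ci * B);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double* in = input.begin();
  const double* W = w.begin();
  const double* GO = gout.begin();
  double* GI = gin.begin();
  double* GW = gw.begin();
  for (int b = 0; b < B; ++b)
    for (int oc = 0; oc < co; ++oc) {
      const double* gop = GO + spo * (oc + (R_xlen_t)co * b);
      double s = 0.0;
      for (R_xlen_t i = 0; i < spo; ++i) s += gop[i];
      gb[oc] += s;
      for (int icc = 0; icc < ci; ++icc) {
        const double* ip = in + spi * (icc + (R_xlen_t)ci * b);
        double* gip = GI + spi * (icc + (R_xlen_t)ci * b);
        const double* wk = W + 8 * ((R_xlen_t)icc + (R_xlen_t)ci * oc);
        double* gwk = GW + 8 * ((R_xlen_t)icc + (R_xlen_t)ci * oc);
        for (int z = 0; z < Z; ++z)
          for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
              R_xlen_t ii = x + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
              double v = ip[ii];
              double acc = 0.0;
              for (int dz = 0; dz < 2; ++dz)
                for (int dy = 0; dy < 2; ++dy)
                  for (int dx = 0; dx < 2; ++dx) {
                    double go = gop[(2 * x + dx) + (R_xlen_t)Xo * ((2 * y + dy) + (R_xlen_t)Yo * (2 * z + dz))];
                    acc += go * wk[dx + 2 * (dy + 2 * dz)];
                    gwk[dx + 2 * (dy + 2 * dz)] += go * v;
                  }
              gip[ii] += acc; // accumulate across output channels
            }
      }
    }
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// separable Gaussian blur with mirror (reflect) padding, used by 3D SSIM
// [[Rcpp::export(name = ".gauss_blur3d_cpp")]]
NumericVector gauss_blur3d_cpp(NumericVector input, IntegerVector idim,
                               NumericVector kernel) {
  const int X = idim[0], Y = idim[1], Z = idim[2];
  const int kr = (kernel.size() - 1) / 2;
  const double* K = kernel.begin();
  NumericVector tmp1(clone(input));
  NumericVector tmp2(input.size());
  // reflect index into [0, n)
  auto refl = [](int i, int n) {
    if (n == 1) return 0;
    int p = 2 * (n - 1);
    i = ((i % p) + p) % p;
    return i < n ? i : p - i;
  };
  // axis 0
  {
    const double* in = tmp1.begin(); double* out = tmp2.begin();
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const double* row = in + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
        double* orow = out + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
        for (int x = 0; x < X; ++x) {
          double s = 0.0;
          for (int j = -kr; j <= kr; ++j) s += K[j + kr] * row[refl(x + j, X)];
          orow[x] = s;
        }
      }
  }
  // axis 1
  {
    const double* in = tmp2.begin(); double* out = tmp1.begin();
    for (int z = 0; z < Z; ++z)
      for (int x = 0; x < X; ++x) {
        for (int y = 0; y < Y; ++y) {
          double s = 0.0;
          for (int j = -kr; j <= kr; ++j)
            s += K[j + kr] * in[x + (R_xlen_t)X * (refl(y + j, Y) + (R_xlen_t)Y * z)];
          out[x + (R_xlen_t)X * (y + (R_xlen_t)Y * z)] = s;
        }
      }
  }
  // axis 2
  {
    const double* in = tmp1.begin(); double* out = tmp2.begin();
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x)
        for (int z = 0; z < Z; ++z) {
          double s = 0.0;
          for (int j = -kr; j <= kr; ++j)
            s += K[j + kr] * in[x + (R_xlen_t)X * (y + (R_xlen_t)Y * refl(z + j, Z))];
          out[x + (R_xlen_t)X * (y + (R_xlen_t)Y * z)] = s;
        }
  }
  return tmp2;
}
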