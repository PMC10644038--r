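#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// exp(-e) for e in [0, 14] via a dense lookup table with linear
// interpolation (~1e-5 absolute accuracy; deterministic)
static const int LUTN = 7168;  // 512 entries per unit
static const float LUTSCALE = LUTN / 14.0f;
static std::vector<float> expLut;

static inline void initExpLut() {
  if ((int)expLut.size() == LUTN + 2) return;
  expLut.assign(LUTN + 2, 0.0f);
  for (int i = 0; i <= LUTN + 1; ++i)
    expLut[i] = (float)std::exp(-(double)i / LUTSCALE);
}

static inline float expNeg(float e) {
  const float t = e * LUTSCALE;
  const int i = (int)t;
  const float f = t - (float)i;
  return expLut[i] + f * (expLut[i + 1] - expLut[i]);
}

// Two-class fully connected CRF solved by mean-field iteration.
//
// Pairwise potentials follow the canonical bilateral parameterisation:
//   appearance kernel  w_app * exp(-|p_i-p_j|^2 / (2 sd_s^2) - |c_i-c_j|^2 / (2 sd_c^2))
//   smoothness kernel  w_sm  * exp(-|p_i-p_j|^2 / (2 sd_g^2))
// with a Potts label-compatibility (penalty 1 for differing labels).
//
// The appearance kernel is evaluated exactly over all pixel pairs (O(N^2)),
// which is intended for working resolutions up to ~128 px; the smoothness
// kernel uses a truncated window of radius 3*sd_g with precomputed offsets.
//
// rgb is an N x 3 matrix in [0,1]; colours are scaled by 255 so that sd_c is
// expressed on the conventional 8-bit scale. q1 holds the foreground
// probability; unary potentials are -log of the clamped heat map.

// [[Rcpp::export]]
NumericVector crf_meanfield_cpp(NumericMatrix rgb, NumericVector heat,
                                int height, int width,
                                double w_app, double sd_s, double sd_c,
                                double w_sm, double sd_g,
                                int iterations, double unary_clamp) {
  const int n = height * width;
  if (rgb.nrow() != n || heat.size() != n)
    stop("image/heat dimensions do not match height*width");

  std::vector<float> r(n), g(n), b(n), px(n), py(n);
  std::vector<double> u1(n), u0(n), q1(n);
  // column-major over (row, col): index = row + col*height
  for (int c = 0, idx = 0; c < width; ++c)
    for (int rw = 0; rw < height; ++rw, ++idx) {
      r[idx] = (float)(rgb(idx, 0) * 255.0);
      g[idx] = (float)(rgb(idx, 1) * 255.0);
      b[idx] = (float)(rgb(idx, 2) * 255.0);
      px[idx] = (float)c;
      py[idx] = (float)rw;
      double h = heat[idx];
      if (h < unary_clamp) h = unary_clamp;
      if (h > 1.0 - unary_clamp) h = 1.0 - unary_clamp;
      u1[idx] = -std::log(h);
      u0[idx] = -std::log(1.0 - h);
      q1[idx] = h;
    }

  const float inv2ss = (float)(1.0 / (2.0 * sd_s * sd_s));
  const float inv2sc = (float)(1.0 / (2.0 * sd_c * sd_c));
  initExpLut();

  // precomputed smoothness window
  const int rad = (int)std::ceil(3.0 * sd_g);
  std::vector<double> gw((2 * rad + 1) * (2 * rad + 1));
  for (int dy = -rad; dy <= rad; ++dy)
    for (int dx = -rad; dx <= rad; ++dx)
      gw[(dy + rad) * (2 * rad + 1) + (dx + rad)] =
        std::exp(-(double)(dx * dx + dy * dy) / (2.0 * sd_g * sd_g));

  std::vector<double> s1(n), ks(n), m1s(n), k0s(n);

  for (int it = 0; it < iterations; ++it) {
    // appearance kernel: S1_i = sum_j k_ij q1_j, K_i = sum_j k_ij (j != i)
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(ks.begin(), ks.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const float ri = r[i], gi = g[i], bi = b[i], xi = px[i], yi = py[i];
      const double qi = q1[i];
      double acc_s = 0.0, acc_k = 0.0;
      for (int j = i + 1; j < n; ++j) {
        const float dx = xi - px[j], dy = yi - py[j];
        const float dr = ri - r[j], dg = gi - g[j], db = bi - b[j];
        const float e = (dx * dx + dy * dy) * inv2ss +
                        (dr * dr + dg * dg + db * db) * inv2sc;
        if (e > 13.9f) continue;  // exp(-14) ~ 8e-7: negligible
        const double k = (double)expNeg(e);
        acc_s += k * q1[j];
        acc_k += k;
        s1[j] += k * qi;
        ks[j] += k;
      }
      s1[i] += acc_s;
      ks[i] += acc_k;
    }
    // smoothness kernel over truncated window
    for (int c = 0; c < width; ++c) {
      for (int rw = 0; rw < height; ++rw) {
        const int i = rw + c * height;
        double acc_s = 0.0, acc_k = 0.0;
        for (int dy = -rad; dy <= rad; ++dy) {
          const int rr = rw + dy;
          if (rr < 0 || rr >= height) continue;
          for (int dx = -rad; dx <= rad; ++dx) {
            const int cc = c + dx;
            if (cc < 0 || cc >= width || (dx == 0 && dy == 0)) continue;
            const double k = gw[(dy + rad) * (2 * rad + 1) + (dx + rad)];
            const int j = rr + cc * height;
            acc_s += k * q1[j];
            acc_k += k;
          }
        }
        m1s[i] = acc_s;
        k0s[i] = acc_k;
      }
    }
    // mean-field update (Potts: energy for label l picks up messages of the
    // other label)
    for (int i = 0; i < n; ++i) {
      const double m1a = s1[i], m0a = ks[i] - s1[i];
      const double m1g = m1s[i], m0g = k0s[i] - m1s[i];
      const double e1 = u1[i] + w_app * m0a + w_sm * m0g;
      const double e0 = u0[i] + w_app * m1a + w_sm * m1g;
      // q1 = exp(-e1) / (exp(-e1) + exp(-e0)), stabilised
      const double z = e0 - e1;
      q1[i] = 1.0 / (1.0 + std::exp(-z));
    }
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = q1[i];
  return out;
}
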