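#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxelwise 3D fiber orientation by weighted vector summation.
//
// For every voxel above the intensity threshold whose cubic window fits
// entirely inside the volume, the window is max-intensity projected onto the
// xy, xz and yz planes. In each projection, candidate directions d = 1..180
// degrees through the window center are scored by
//   w(d) = L(d) * max(0, 1 - CV(d)),
// where L(d) is the length of the contiguous above-threshold run through the
// center along d and CV(d) the coefficient of variation of intensity over
// that run. The per-projection angle is the doubled-angle weighted mean
//   0.5 * atan2(sum w sin 2d, sum w cos 2d),
// which is the axial-data analogue of a weighted vector sum. The xy angle is
// theta; the xz and yz angles (beta, gamma) combine into the polar angle phi
// through tan^2(phi) = 1/tan^2(beta) + 1/tan^2(gamma).
//
// Volume layout: numeric array dim (nz, ny, nx), linear index
// z + nz*(y + ny*x). x is the stretch axis; angles are measured from the
// first axis of each projection plane (x for xy/xz, y for yz) toward the
// second (y, z, z respectively).

namespace {

struct Chords {
  // per direction: interleaved (a, b) integer offsets of the sample path,
  // ordered from one chord end to the other; center sample index.
  std::vector<std::vector<int>> offs;
  std::vector<int> center_at;
};

// Precompute nearest-neighbour sample offsets along each 1-degree direction
// through the center of a (2h+1)^2 window, stepping by 0.5 px.
Chords make_chords(int h) {
  Chords ch;
  ch.offs.resize(180);
  ch.center_at.resize(180);
  for (int d = 1; d <= 180; ++d) {
    double rad = d * M_PI / 180.0;
    double ca = std::cos(rad), sa = std::sin(rad);
    std::vector<std::pair<int, int>> pts;
    for (double t = -2.0 * h; t <= 2.0 * h + 1e-9; t += 1.0) {
      double s = t * 0.5;
      int a = (int)std::lround(s * ca);
      int b = (int)std::lround(s * sa);
      if (std::abs(a) > h || std::abs(b) > h) continue;
      if (!pts.empty() && pts.back().first == a && pts.back().second == b)
        continue;
      pts.push_back(std::make_pair(a, b));
    }
    std::vector<int> v;
    int cidx = 0;
    for (size_t i = 0; i < pts.size(); ++i) {
      if (pts[i].first == 0 && pts[i].second == 0) cidx = (int)(v.size() / 2);
      v.push_back(pts[i].first);
      v.push_back(pts[i].second);
    }
    ch.offs[d - 1] = v;
    ch.center_at[d - 1] = cidx;
  }
  return ch;
}

// Weighted doubled-angle vector sum over one 2D projection (size w x w,
// indexed [a + h + (b + h) * w] with a = first axis, b = second axis).
// Returns angle in degrees [0, 180) or -1 if all weights vanish.
double projection_angle(const std::vector<double>& img, int h, int w,
                        double thr, const Chords& ch) {
  double C = 0.0, S = 0.0, wtot = 0.0;
  for (int d = 1; d <= 180; ++d) {
    const std::vector<int>& off = ch.offs[d - 1];
    int n = (int)(off.size() / 2);
    int c = ch.center_at[d - 1];
    // intensity along the chord
    // contiguous above-threshold run through the center
    double cint = img[(off[2 * c] + h) + (off[2 * c + 1] + h) * w];
    if (cint < thr) continue;
    int lo = c, hi = c;
    while (lo > 0) {
      double v = img[(off[2 * (lo - 1)] + h) + (off[2 * (lo - 1) + 1] + h) * w];
      if (v < thr) break;
      --lo;
    }
    while (hi < n - 1) {
      double v = img[(off[2 * (hi + 1)] + h) + (off[2 * (hi + 1) + 1] + h) * w];
      if (v < thr) break;
      ++hi;
    }
    int run = hi - lo + 1;
    double sum = 0.0, sum2 = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double v = img[(off[2 * k] + h) + (off[2 * k + 1] + h) * w];
      sum += v;
      sum2 += v * v;
    }
    double mean = sum / run;
    double cv = 0.0;
    if (run > 1 && mean > 0) {
      double var = (sum2 - sum * sum / run) / (run - 1);
      if (var > 0) cv = std::sqrt(var) / mean;
    }
    double da = off[2 * hi] - off[2 * lo], db = off[2 * hi + 1] - off[2 * lo + 1];
    double L = std::sqrt(da * da + db * db) + 1.0;  // chord length in px
    double wt = L * std::max(0.0, 1.0 - cv);
    if (wt <= 0) continue;
    double d2 = 2.0 * d * M_PI / 180.0;
    C += wt * std::cos(d2);
    S += wt * std::sin(d2);
    wtot += wt;
  }
  if (wtot <= 0) return -1.0;
  double ang = 0.5 * std::atan2(S, C) * 180.0 / M_PI;
  if (ang < 0) ang += 180.0;
  if (ang >= 180.0) ang -= 180.0;
  return ang;
}

}  // namespace

// [[Rcpp::export(name = ".orientation_core")]]
List orientation_core(NumericVector vol, IntegerVector dims, double threshold,
                      int window) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int h = window / 2, w = window;
  Chords ch = make_chords(h);
  NumericVector theta(vol.size(), NA_REAL);
  NumericVector phi(vol.size(), NA_REAL);
  LogicalVector valid(vol.size(), false);
  std::vector<double> pxy(w * w), pxz(w * w), pyz(w * w);
  const double* v = REAL(vol);
  for (int x = h; x < nx - h; ++x) {
    for (int y = h; y < ny - h; ++y) {
      for (int z = h; z < nz - h; ++z) {
        R_xlen_t idx = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (v[idx] < threshold) continue;
        // max-intensity projections of the window
        std::fill(pxy.begin(), pxy.end(), 0.0);
        std::fill(pxz.begin(), pxz.end(), 0.0);
        std::fill(pyz.begin(), pyz.end(), 0.0);
        for (int dx = -h; dx <= h; ++dx) {
          for (int dy = -h; dy <= h; ++dy) {
            R_xlen_t base = (R_xlen_t)nz * ((y + dy) + (R_xlen_t)ny * (x + dx));
            for (int dz = -h; dz <= h; ++dz) {
              double val = v[(z + dz) + base];
              // xy: axes (x, y); xz: (x, z); yz: (y, z)
              double& a1 = pxy[(dx + h) + (dy + h) * w];
              if (val > a1) a1 = val;
              double& a2 = pxz[(dx + h) + (dz + h) * w];
              if (val > a2) a2 = val;
              double& a3 = pyz[(dy + h) + (dz + h) * w];
              if (val > a3) a3 = val;
            }
          }
        }
        double th = projection_angle(pxy, h, w, threshold, ch);
        double be = projection_angle(pxz, h, w, threshold, ch);
        double ga = projection_angle(pyz, h, w, threshold, ch);
        if (th < 0 || be < 0 || ga < 0) continue;  // degenerate window
        // polar angle magnitude from the two out-of-plane projections
        double tb = std::tan(be * M_PI / 180.0);
        double tg = std::tan(ga * M_PI / 180.0);
        double ph;
        const double eps = 1e-12;
        if (std::abs(tb) < eps || std::abs(tg) < eps) {
          ph = 90.0;
        } else {
          double t2 = 1.0 / (tb * tb) + 1.0 / (tg * tg);
          ph = std::atan(std::sqrt(t2)) * 180.0 / M_PI;
        }
        // tilt sign: take the axial representative with uy >= 0
        // (theta in (0,180)); gamma tells the z-slope along +y, beta the
        // z-slope along +x, whose sign flips with cos(theta). phi > 90
        // encodes a downward tilt so that opposite tilts cancel in the
        // z-component of the directional mean.
        if (ph < 90.0 - 1e-9) {
          double sth = std::sin(th * M_PI / 180.0);
          double uzsign;
          if (sth > 0.17) {  // theta more than ~10 deg away from the x axis
            uzsign = (ga > 90.0) ? -1.0 : 1.0;
          } else {
            double sbeta = (be < 90.0) ? 1.0 : -1.0;
            uzsign = (std::cos(th * M_PI / 180.0) >= 0.0) ? sbeta : -sbeta;
          }
          if (uzsign < 0) ph = 180.0 - ph;
        }
        theta[idx] = th;
        phi[idx] = ph;
        valid[idx] = true;
      }
    }
  }
  return List::create(_["theta"] = theta, _["phi"] = phi, _["valid"] = valid);
}
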