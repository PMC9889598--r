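// Strip-integral system matrix for a parallel-beam 2D PET geometry.
//
// Detector strip i at angle theta covers perpendicular offsets
// s in [s_i - bw/2, s_i + bw/2].  The matrix entry for pixel j is the
// intersection area of the strip with the (square) pixel divided by the
// strip width, i.e. the strip-averaged intersection length in mm.
//
// The area of a square pixel below the line x cos(t) + y sin(t) = s is
// the CDF of the pixel's (trapezoidal) projection profile, which gives a
// closed form for each strip/pixel pair.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// CDF at offset t (relative to pixel centre projection) of the trapezoid
// profile with half-base hw, half-top c and plateau height h.
static inline double trap_cdf(double t, double hw, double c, double h) {
  double total = h * (hw + c);
  if (t <= -hw) return 0.0;
  if (t >= hw) return total;
  double ramp = hw - c; // width of each sloped side
  if (t < -c) {
    double u = t + hw;
    return 0.5 * h * u * u / ramp;
  }
  if (t <= c) {
    return 0.5 * h * ramp + h * (t + c);
  }
  double u = hw - t;
  return total - 0.5 * h * u * u / ramp;
}

// [[Rcpp::export]]
List cpp_strip_sysmat(int H, int W, double pixel_mm, int n_bins, int n_angles,
                      double bin_width_mm) {
  std::vector<int> ri, ci;
  std::vector<double> val;
  ri.reserve((size_t)H * W * n_angles / 4);
  ci.reserve((size_t)H * W * n_angles / 4);
  val.reserve((size_t)H * W * n_angles / 4);

  const double bw = bin_width_mm;
  const double s0 = -0.5 * (n_bins - 1) * bw; // centre of first bin

  for (int a = 0; a < n_angles; ++a) {
    double th = M_PI * a / n_angles;
    double ct = std::cos(th), st = std::sin(th);
    double act = std::fabs(ct), ast = std::fabs(st);
    double hw = 0.5 * pixel_mm * (act + ast);
    double c = 0.5 * pixel_mm * std::fabs(act - ast);
    double mx = std::max(act, ast);
    double h = pixel_mm / mx; // plateau height; area = pixel_mm^2
    bool degenerate = (hw - c) < 1e-12 * pixel_mm;

    for (int row = 0; row < H; ++row) {
      double y = (row - 0.5 * (H - 1)) * pixel_mm;
      for (int col = 0; col < W; ++col) {
        double x = (col - 0.5 * (W - 1)) * pixel_mm;
        double tc = x * ct + y * st; // projected pixel centre
        // bins whose strip [s - bw/2, s + bw/2] can overlap the profile
        int i0 = (int)std::floor((tc - hw - s0) / bw + 0.5 - 0.5);
        int i1 = (int)std::ceil((tc + hw - s0) / bw - 0.5 + 0.5);
        if (i0 < 0) i0 = 0;
        if (i1 > n_bins - 1) i1 = n_bins - 1;
        for (int i = i0; i <= i1; ++i) {
          double s = s0 + i * bw;
          double t1 = s - 0.5 * bw - tc;
          double t2 = s + 0.5 * bw - tc;
          double area;
          if (degenerate) {
            // axis-aligned case: rectangular profile of width 2*hw
            double lo = std::max(t1, -hw), hi = std::min(t2, hw);
            area = (hi > lo) ? (hi - lo) * h : 0.0;
          } else {
            area = trap_cdf(t2, hw, c, h) - trap_cdf(t1, hw, c, h);
          }
          if (area > 1e-12) {
            ri.push_back(a * n_bins + i + 1); // 1-based row = bin + nb*angle
            ci.push_back(col * H + row + 1);  // 1-based, column-major (H x W)
            val.push_back(area / bw);
          }
        }
      }
    }
  }
  return List::create(Named("i") = wrap(ri), Named("j") = wrap(ci),
                      Named("x") = wrap(val));
}
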