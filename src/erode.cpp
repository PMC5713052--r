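#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale erosion with an arbitrary (possibly non-flat) structuring
// element: out(x) = min over SE support of img(x + u) - b(u).
//
// img:   numeric matrix
// du,dv: integer offsets of the SE support (relative to the origin)
// bh:    SE height at each offset (0 for flat SEs)
// reflect: reflect-pad the borders if true, otherwise ignore offsets that
//          fall outside the image (border pixels use the clipped support)
//
// The offset-outer / pixel-inner loop keeps the inner loop contiguous in
// memory so it vectorises; with the default 50-pixel ball on a 100x100
// band this is the hot path of the enhancement chain.
// [[Rcpp::export(name = ".erode_cpp")]]
NumericMatrix erode_cpp(NumericMatrix img, IntegerVector du, IntegerVector dv,
                        NumericVector bh, bool reflect) {
  const int nr = img.nrow(), nc = img.ncol(), K = du.size();
  int rmax = 0, cmax = 0;
  for (int k = 0; k < K; ++k) {
    if (std::abs(du[k]) > rmax) rmax = std::abs(du[k]);
    if (std::abs(dv[k]) > cmax) cmax = std::abs(dv[k]);
  }
  if (rmax >= nr || cmax >= nc)
    stop("structuring element is larger than the image");

  const int pr = nr + 2 * rmax, pc = nc + 2 * cmax;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> pad((size_t)pr * pc);
  // reflect (mirror without repeating the edge) or +inf padding
  for (int j = 0; j < pc; ++j) {
    int sj = j - cmax;
    bool outj = (sj < 0 || sj >= nc);
    if (outj) sj = (sj < 0) ? -sj : 2 * nc - 2 - sj;
    for (int i = 0; i < pr; ++i) {
      int si = i - rmax;
      bool outi = (si < 0 || si >= nr);
      if (outi) si = (si < 0) ? -si : 2 * nr - 2 - si;
      pad[(size_t)j * pr + i] =
          (!reflect && (outi || outj)) ? inf : img(si, sj);
    }
  }

  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), inf);
  double *o = REAL(out);
  for (int k = 0; k < K; ++k) {
    const double b = bh[k];
    const int roff = du[k] + rmax, coff = dv[k] + cmax;
    for (int j = 0; j < nc; ++j) {
      const double *src = &pad[(size_t)(j + coff) * pr + roff];
      double *dst = o + (size_t)j * nr;
      for (int i = 0; i < nr; ++i)
        dst[i] = std::min(dst[i], src[i] - b);
    }
  }
  return out;
}

// ---- fast exact erosion by a ball SE -------------------------------------
//
// out(i,j) = min over u^2+v^2 <= r^2 of img(i+u, j+v) - h*sqrt(1-(u^2+v^2)/r^2)
//
// Decomposed per column offset v into 1-D min-plus convolutions along the
// rows with the concave profile b_v(u); a concave profile makes the
// windowed matrix Monge, so the per-output argmin is monotone and each line
// solves in O(n log n) by divide-and-conquer instead of O(n * window).

namespace {
struct Line1D {
  const double *f;   // padded line
  const double *b;   // profile, index u + w
  int w;             // half-window
  double *out;
  // outputs indexed 0..n-1; center of output i is padded index i + pad0
  int pad0;
  void solve(int lo, int hi, int jl, int jh) {
    if (lo > hi) return;
    const int mid = (lo + hi) / 2, c = mid + pad0;
    int j0 = std::max(jl, c - w), j1 = std::min(jh, c + w);
    double best = std::numeric_limits<double>::infinity();
    int jb = j0;
    for (int j = j0; j <= j1; ++j) {
      const double v = f[j] - b[j - c + w];
      if (v < best) { best = v; jb = j; }
    }
    out[mid] = best;
    solve(lo, mid - 1, jl, jb);
    solve(mid + 1, hi, jb, jh);
  }
};
}  // namespace

// [[Rcpp::export(name = ".erode_ball_cpp")]]
NumericMatrix erode_ball_cpp(NumericMatrix img, int r, double h,
                             bool reflect) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r >= nr || r >= nc)
    stop("structuring element is larger than the image");
  const double inf = std::numeric_limits<double>::infinity();
  const int pr = nr + 2 * r, pc = nc + 2 * r;
  std::vector<double> pad((size_t)pr * pc);
  for (int j = 0; j < pc; ++j) {
    int sj = j - r;
    bool outj = (sj < 0 || sj >= nc);
    if (outj) sj = (sj < 0) ? -sj : 2 * nc - 2 - sj;
    for (int i = 0; i < pr; ++i) {
      int si = i - r;
      bool outi = (si < 0 || si >= nr);
      if (outi) si = (si < 0) ? -si : 2 * nr - 2 - si;
      pad[(size_t)j * pr + i] = (!reflect && (outi || outj)) ? inf : img(si, sj);
    }
  }
  // stage A: T_v(i, j) over interior rows i, all padded columns j
  std::vector<double> T((size_t)(r + 1) * nr * pc);
  std::vector<double> prof(2 * r + 1);
  for (int v = 0; v <= r; ++v) {
    const int w = (int)std::floor(std::sqrt((double)r * r - (double)v * v));
    for (int u = -w; u <= w; ++u)
      prof[u + w] = h * std::sqrt(std::max(
          1.0 - ((double)u * u + (double)v * v) / ((double)r * r), 0.0));
    double *Tv = &T[(size_t)v * nr * pc];
    for (int j = 0; j < pc; ++j) {
      Line1D ln;
      ln.f = &pad[(size_t)j * pr];
      ln.b = prof.data();
      ln.w = w;
      ln.out = Tv + (size_t)j * nr;
      ln.pad0 = r;
      ln.solve(0, nr - 1, r - w, pr - 1 - (r - w));
    }
  }
  // stage B: out(i,j) = min over v of T_|v|(i, j + v) (padded column j+r+v)
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), inf);
  double *o = REAL(out);
  for (int v = -r; v <= r; ++v) {
    const double *Tv = &T[(size_t)std::abs(v) * nr * pc];
    for (int j = 0; j < nc; ++j) {
      const double *src = Tv + (size_t)(j + r + v) * nr;
      double *dst = o + (size_t)j * nr;
      for (int i = 0; i < nr; ++i)
        dst[i] = std::min(dst[i], src[i]);
    }
  }
  return out;
}
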