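#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Reflect an out-of-range index into [0, n-1] (edge-mirror without repeating
// the border pixel twice in a row beyond one reflection; radii are small
// relative to image extent, enforced on the R side).
static inline int reflect(int i, int n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

//' Median filter with a disk footprint and reflective edge handling.
//'
//' @param img numeric matrix (rows = y, cols = x)
//' @param radius disk radius in pixels (>= 1); the footprint is all offsets
//'   (dy, dx) with dy^2 + dx^2 <= radius^2, centre included
//' @return matrix of the same shape holding the local medians
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix disk_median_cpp(NumericMatrix img, int radius) {
  const int ny = img.nrow(), nx = img.ncol();
  if (radius < 1) stop("radius must be >= 1");
  if (radius >= ny || radius >= nx)
    stop("median radius exceeds image half-extent");

  // Precompute disk offsets once.
  std::vector<int> offy, offx;
  const double r2 = static_cast<double>(radius) * radius;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= r2) { offy.push_back(dy); offx.push_back(dx); }
  const size_t k = offy.size();

  NumericMatrix out(ny, nx);
  std::vector<double> buf(k);
  const size_t mid = k / 2;  // k is odd for a centred disk
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (size_t j = 0; j < k; ++j)
        buf[j] = img(reflect(y + offy[j], ny), reflect(x + offx[j], nx));
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (k % 2 == 0) {
        // even count cannot occur for a centred disk, but keep it correct
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      out(y, x) = med;
    }
  }
  return out;
}

//' Label 8-connected foreground components.
//'
//' @param mask logical matrix; TRUE marks foreground
//' @return integer matrix, 0 for background, components labelled 1..N in
//'   column-major discovery order
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components8_cpp(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(y, x));
      lab(y, x) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dy == 0 && dx == 0) continue;
            int yy = p.first + dy, xx = p.second + dx;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (mask(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              stack.push_back(std::make_pair(yy, xx));
            }
          }
        }
      }
    }
  }
  return lab;
}
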