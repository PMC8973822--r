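#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <deque>

using namespace Rcpp;

// Circular-neighbourhood median filter. Offsets satisfy dx^2 + dy^2 <= r^2;
// neighbourhoods are truncated at the image border (no padding), matching
// the radius-defined kernel of the ImageJ-style "Median radius" filter.
// [[Rcpp::export]]
NumericMatrix median_filter_disc_cpp(const NumericMatrix& img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  if (nr == 0 || nc == 0) stop("empty image");
  if (radius < 0) stop("radius must be >= 0");
  const int r = (int)std::floor(radius);
  std::vector<int> dx, dy;
  for (int i = -r; i <= r; ++i)
    for (int j = -r; j <= r; ++j)
      if ((double)(i * i + j * j) <= radius * radius) { dx.push_back(i); dy.push_back(j); }
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(dx.size());
  for (int col = 0; col < nc; ++col) {
    for (int row = 0; row < nr; ++row) {
      buf.clear();
      for (size_t k = 0; k < dx.size(); ++k) {
        const int rr = row + dx[k], cc = col + dy[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) buf.push_back(img(rr, cc));
      }
      const size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        // median of an even count: mean of the two central order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        med = (med + lo) / 2.0;
      }
      out(row, col) = med;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask by raster-scan BFS.
// Labels are assigned 1, 2, ... in raster order (column-major here, but the
// caller relabels by top-left pixel in row-raster order afterwards).
// [[Rcpp::export]]
IntegerMatrix label_components8_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int col = 0; col < nc; ++col) {
    for (int row = 0; row < nr; ++row) {
      if (!mask(row, col) || lab(row, col) != 0) continue;
      ++next;
      lab(row, col) = next;
      q.clear();
      q.push_back(std::make_pair(row, col));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second;
        q.pop_front();
        for (int i = -1; i <= 1; ++i) {
          for (int j = -1; j <= 1; ++j) {
            if (i == 0 && j == 0) continue;
            const int rr = cr + i, c2 = cc + j;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              q.push_back(std::make_pair(rr, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}
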