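// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// raster/anti-raster + FIFO algorithm, 8-connectivity). The building block
// for the h-minima / extended-regional-minima transform used in
// immunopositive cell extraction.

#include <Rcpp.h>
#include <queue>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export(name = ".reconstructDilationCpp")]]
NumericMatrix reconstructDilationCpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical shape");
  NumericMatrix J(nr, nc);
  for (int i = 0; i < nr * nc; ++i)
    J[i] = std::min(marker[i], mask[i]);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // scans run column-major (R memory order): visited pixels are those in
  // earlier columns plus the one above in the current column
  const int drp[4] = {-1, 0, 1, -1};
  const int dcp[4] = {-1, -1, -1, 0};
  // anti-raster: the mirrored set
  const int drm[4] = {1, 0, -1, 1};
  const int dcm[4] = {1, 1, 1, 0};

  // raster scan
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc)
          v = std::max(v, J(rr, cc));
      }
      J(r, c) = std::min(v, mask(r, c));
    }

  // anti-raster scan, queueing pixels that can still propagate
  std::queue<std::pair<int, int> > fifo;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc)
          v = std::max(v, J(rr, cc));
      }
      J(r, c) = std::min(v, mask(r, c));
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(std::make_pair(r, c));
          break;
        }
      }
    }

  // propagation
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        fifo.push(std::make_pair(rr, cc));
      }
    }
  }
  return J;
}
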