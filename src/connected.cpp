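#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary 3D lattice (column-major voxel
// order) under 6-, 18- or 26-neighbourhood connectivity. Background = 0;
// components are numbered in first-touch scan order (relabelled in R).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector incl, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (incl.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets admitted by the connectivity
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!incl[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < nn; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (incl[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
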