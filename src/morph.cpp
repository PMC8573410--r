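// Connected-component labeling on 3D binary grids (6/18/26 connectivity).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

void neighbor_offsets(int connectivity, std::vector<std::array<int, 3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

}  // namespace

// Label components in scan order; label ids start at 1 in order of the
// smallest linear voxel index contained in each component.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dim, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, offs);

  IntegerVector lab(n, 0);
  std::vector<long> queue;
  int next = 0;
  for (long seed = 0; seed < n; ++seed) {
    if (mask[seed] == 0 || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    queue.clear();
    queue.push_back(seed);
    while (!queue.empty()) {
      const long v = queue.back();
      queue.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((long)nx * ny));
      for (const auto& o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const long w = (long)xx + (long)nx * yy + (long)nx * ny * zz;
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          queue.push_back(w);
        }
      }
    }
  }
  return lab;
}
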