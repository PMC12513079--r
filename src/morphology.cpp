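// 3D binary morphology and connected-component labelling used by the
// breast-region heuristic and the lesion-matching evaluation.
#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected components with 26-connectivity; returns labels 1..K, 0 = bg.
// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(IntegerVector vox, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector labels(vox.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int z0 = 0; z0 < nz; ++z0) for (int y0 = 0; y0 < ny; ++y0)
    for (int x0 = 0; x0 < nx; ++x0) {
      int i0 = idx3(x0, y0, z0, nx, ny);
      if (vox[i0] == 0 || labels[i0] != 0) continue;
      ++next;
      labels[i0] = next;
      stack.clear();
      stack.push_back(i0);
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                zz >= nz) continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (vox[j] != 0 && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
      }
    }
  labels.attr("n_components") = next;
  return labels;
}

static std::vector<std::array<int, 3>> ball_offsets(double r) {
  std::vector<std::array<int, 3>> off;
  int ri = (int)std::floor(r);
  for (int dz = -ri; dz <= ri; ++dz) for (int dy = -ri; dy <= ri; ++dy)
    for (int dx = -ri; dx <= ri; ++dx)
      if (dx * dx + dy * dy + dz * dz <= r * r)
        off.push_back({dx, dy, dz});
  return off;
}

static IntegerVector morph(IntegerVector vox, IntegerVector dims, double r,
                           bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto off = ball_offsets(r);
  IntegerVector out(vox.size());
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i = idx3(x, y, z, nx, ny);
      bool acc = !dilate;  // erode: AND over ball; dilate: OR over ball
      for (auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        bool v;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          v = false;  // outside treated as background
        else
          v = vox[idx3(xx, yy, zz, nx, ny)] != 0;
        if (dilate) { if (v) { acc = true; break; } }
        else if (!v) { acc = false; break; }
      }
      out[i] = acc ? 1 : 0;
    }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".bin_dilate")]]
IntegerVector bin_dilate(IntegerVector vox, IntegerVector dims, double r) {
  return morph(vox, dims, r, true);
}

// [[Rcpp::export(name = ".bin_erode")]]
IntegerVector bin_erode(IntegerVector vox, IntegerVector dims, double r) {
  return morph(vox, dims, r, false);
}
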