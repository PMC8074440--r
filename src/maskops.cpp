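// Mask utilities: 3D connected components and boundary point-set distances.
// Label volumes are integer arrays dim (rows, cols, slices), column-major.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Keep only the largest connected component of `label`; returns a logical
// array marking retained voxels. connectivity = 26 (3D) or 8 (in-plane only).
// Tie-break between equal-sized components: the component discovered first
// when scanning voxels in ascending (slice, row, col) order, i.e. the one
// whose minimum (slice, row, col) index is lexicographically smallest.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(IntegerVector labels, int label,
                                    int connectivity) {
  IntegerVector d = labels.attr("dim");
  if (d.size() != 3) stop("expected a 3D (row, col, slice) array");
  int nr = d[0], nc = d[1], ns = d[2];
  LogicalVector keep((size_t)nr * nc * ns);
  keep.attr("dim") = d;
  std::vector<int> comp((size_t)nr * nc * ns, 0);
  int ncomp = 0;
  std::vector<size_t> best_voxels, cur;
  int ds_max = (connectivity == 8) ? 0 : 1;
  std::vector<size_t> stack;
  for (int s = 0; s < ns; ++s)
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        size_t i = (size_t)r + nr * ((size_t)c + (size_t)nc * s);
        if (labels[i] != label || comp[i]) continue;
        ++ncomp;
        cur.clear();
        stack.clear();
        stack.push_back(i);
        comp[i] = ncomp;
        while (!stack.empty()) {
          size_t v = stack.back(); stack.pop_back();
          cur.push_back(v);
          int vs = (int)(v / ((size_t)nr * nc));
          int rem = (int)(v % ((size_t)nr * nc));
          int vc = rem / nr, vr = rem % nr;
          for (int dz = -ds_max; dz <= ds_max; ++dz)
            for (int dc = -1; dc <= 1; ++dc)
              for (int dr = -1; dr <= 1; ++dr) {
                if (!dr && !dc && !dz) continue;
                int r2 = vr + dr, c2 = vc + dc, s2 = vs + dz;
                if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc ||
                    s2 < 0 || s2 >= ns) continue;
                size_t j = (size_t)r2 + nr * ((size_t)c2 + (size_t)nc * s2);
                if (labels[j] == label && !comp[j]) {
                  comp[j] = ncomp;
                  stack.push_back(j);
                }
              }
        }
        if (cur.size() > best_voxels.size()) best_voxels = cur;
      }
  for (size_t v : best_voxels) keep[v] = true;
  return keep;
}

// Directed distances from each point of A to its nearest point of B
// (points are rows of n x 3 matrices in physical mm coordinates).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
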