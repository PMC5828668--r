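#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-components labeling of a logical matrix.
// Components are numbered 1..n in raster order (column-major, as R stores
// matrices) of each component's first pixel, so labeling is deterministic.
static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);

  // neighbour offsets already visited in column-major raster order
  // (up, left, and for 8-connectivity the two upper/lower-left diagonals)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      int neigh[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c) - 1;
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1) - 1;
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1) - 1;
        if (r < nr - 1 && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1) - 1;
      }
      if (nn == 0) {
        parent.push_back((int) parent.size());
        lab(r, c) = (int) parent.size();
      } else {
        best = find_root(parent, neigh[0]);
        for (int k = 1; k < nn; ++k) {
          int root = find_root(parent, neigh[k]);
          if (root < best) { parent[best] = root; best = root; }
          else if (root > best) parent[root] = best;
        }
        lab(r, c) = best + 1;
      }
    }
  }

  // relabel roots 1..n in raster order of first occurrence
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int root = find_root(parent, lab(r, c) - 1);
      if (newlab[root] == 0) newlab[root] = ++next;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
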