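#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find labelling of a binary mask, 4-connectivity.
// Returns an integer matrix of component labels (0 = background),
// labels are 1..k in raster scan order of first appearance.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // background sentinel

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0) ? lab(i - 1, j) : 0;
      int left = (j > 0) ? lab(i, j - 1) : 0;
      if (up == 0 && left == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(i, j) = nl;
      } else if (up != 0 && left == 0) {
        lab(i, j) = up;
      } else if (up == 0) {
        lab(i, j) = left;
      } else {
        int ru = find_root(parent, up), rl = find_root(parent, left);
        int r = ru < rl ? ru : rl;
        parent[ru] = r; parent[rl] = r;
        lab(i, j) = r;
      }
    }
  }

  // compress and relabel consecutively in scan order
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
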