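#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a logical matrix.
// connectivity is 4 or 8; labels are assigned in raster (row-major on the
// R column-major matrix traversed column-by-column) order and compacted to
// 1..n_components so results are deterministic.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  // scan column-major (R storage order); neighbors already visited are
  // those with smaller column, or same column and smaller row
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously-seen neighbors: (i-1, j); (i-1, j-1), (i, j-1), (i+1, j-1)
      int di[4] = {-1, -1, 0, 1};
      int dj[4] = {0, -1, -1, -1};
      // for 4-connectivity only (i-1,j) and (i,j-1)
      for (int k = 0; k < 4; ++k) {
        if (connectivity == 4 && !(k == 0 || k == 2)) continue;
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = best;
      }
    }
  }

  // resolve + compact labels
  std::vector<int> remap(next, 0);
  int n_comp = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (remap[r] == 0) remap[r] = ++n_comp;
      lab(i, j) = remap[r];
    }
  }
  lab.attr("n_components") = n_comp;
  return lab;
}

// Per-label summaries: area, centroid, bounding box, edge contact.
// [[Rcpp::export]]
List cc_stats_cpp(IntegerMatrix lab, int n_comp) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerVector area(n_comp, 0);
  NumericVector crow(n_comp, 0.0), ccol(n_comp, 0.0);
  IntegerVector r0(n_comp, nr), c0(n_comp, nc), r1(n_comp, -1), c1(n_comp, -1);
  LogicalVector edge(n_comp, false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int k = l - 1;
      area[k] += 1;
      crow[k] += i;
      ccol[k] += j;
      if (i < r0[k]) r0[k] = i;
      if (j < c0[k]) c0[k] = j;
      if (i > r1[k]) r1[k] = i;
      if (j > c1[k]) c1[k] = j;
      if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) edge[k] = true;
    }
  }
  for (int k = 0; k < n_comp; ++k) {
    crow[k] /= area[k];
    ccol[k] /= area[k];
  }
  return List::create(_["area_px"] = area, _["centroid_row"] = crow,
                      _["centroid_col"] = ccol, _["row0"] = r0, _["col0"] = c0,
                      _["row1"] = r1, _["col1"] = c1,
                      _["touches_edge"] = edge);
}
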