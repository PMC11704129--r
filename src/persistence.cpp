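#include <Rcpp.h>
using namespace Rcpp;

// Disjoint-set forest with path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Elder-rule merge sequence over a node/edge filtration.
//
// Nodes carry a scalar value; edges are processed in the order given (the
// caller sorts them by filtration value with a deterministic tie-break).
// Each component tracks its extreme node: the maximum-value node when
// `maximize` is true, the minimum-value node otherwise.  When two distinct
// components merge, the one whose extreme is less extreme dies and one row
// (extreme value, merge value, extreme node index) is emitted.  Ties on the
// extreme value are broken toward the lower node index, which keeps the
// output deterministic.
//
// [[Rcpp::export]]
NumericMatrix uf_merge_pairs(NumericVector node_val, IntegerVector edge_i,
                             IntegerVector edge_j, NumericVector edge_w,
                             bool maximize) {
  const int n = node_val.size();
  const int m = edge_i.size();
  std::vector<int> parent(n), ext_node(n);
  for (int k = 0; k < n; ++k) {
    parent[k] = k;
    ext_node[k] = k;
  }
  std::vector<double> ext_val(node_val.begin(), node_val.end());

  std::vector<double> out_ext, out_merge;
  std::vector<int> out_node;
  out_ext.reserve(m / 4 + 8);
  out_merge.reserve(m / 4 + 8);
  out_node.reserve(m / 4 + 8);

  for (int k = 0; k < m; ++k) {
    int a = uf_find(parent, edge_i[k] - 1);
    int b = uf_find(parent, edge_j[k] - 1);
    if (a == b) continue;
    bool a_wins;
    if (ext_val[a] != ext_val[b]) {
      a_wins = maximize ? (ext_val[a] > ext_val[b]) : (ext_val[a] < ext_val[b]);
    } else {
      a_wins = ext_node[a] < ext_node[b];
    }
    int live = a_wins ? a : b;
    int dead = a_wins ? b : a;
    out_ext.push_back(ext_val[dead]);
    out_merge.push_back(edge_w[k]);
    out_node.push_back(ext_node[dead] + 1);
    parent[dead] = live;
  }

  NumericMatrix res(out_ext.size(), 3);
  for (size_t r = 0; r < out_ext.size(); ++r) {
    res(r, 0) = out_ext[r];
    res(r, 1) = out_merge[r];
    res(r, 2) = out_node[r];
  }
  colnames(res) = CharacterVector::create("extreme", "merge", "node");
  return res;
}

// Connected-component labelling of a binary mask (column-major H x W).
// connectivity is 4 or 8.  Labels are positive integers assigned in
// raster (column-major) order of each component's first pixel.
//
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int n = H * W;
  std::vector<int> parent(n);
  for (int k = 0; k < n; ++k) parent[k] = k;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int id = j * H + i;
      if (i > 0 && mask(i - 1, j)) parent[uf_find(parent, id)] = uf_find(parent, id - 1);
      if (j > 0 && mask(i, j - 1)) parent[uf_find(parent, id)] = uf_find(parent, id - H);
      if (connectivity == 8) {
        if (i > 0 && j > 0 && mask(i - 1, j - 1))
          parent[uf_find(parent, id)] = uf_find(parent, id - H - 1);
        if (i + 1 < H && j > 0 && mask(i + 1, j - 1))
          parent[uf_find(parent, id)] = uf_find(parent, id - H + 1);
      }
    }
  }

  IntegerMatrix lab(H, W);
  std::vector<int> rename(n, 0);
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) { lab(i, j) = 0; continue; }
      int r = uf_find(parent, j * H + i);
      if (rename[r] == 0) rename[r] = ++next;
      lab(i, j) = rename[r];
    }
  }
  return lab;
}
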