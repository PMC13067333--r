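#include <Rcpp.h>
using namespace Rcpp;

// Union-find connected-component labelling of signed suprathreshold cells on
// a (node, frequency, time) lattice. Nodes carry an arbitrary symmetric
// adjacency (channel neighbours or voxel 26-connectivity); frequency and time
// axes are chains that can be toggled. Cells link only when they share the
// same sign. Layout: idx = node + nnode*(f + nf*t), 0-based internally.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// [[Rcpp::export]]
IntegerVector label_clusters_cpp(IntegerVector sign, int nnode, int nf, int nt,
                                 List neighbors, bool freq_adj, bool time_adj) {
  int ncell = nnode * nf * nt;
  if (sign.size() != ncell) stop("sign length mismatch");
  std::vector<int> parent(ncell);
  for (int i = 0; i < ncell; ++i) parent[i] = i;

  // pre-extract neighbour lists (1-based from R)
  std::vector<std::vector<int>> nb(nnode);
  for (int v = 0; v < nnode; ++v) {
    IntegerVector x = neighbors[v];
    nb[v].assign(x.begin(), x.end());
  }

  for (int t = 0; t < nt; ++t) {
    for (int f = 0; f < nf; ++f) {
      int base = nnode * (f + nf * t);
      for (int v = 0; v < nnode; ++v) {
        int i = v + base;
        int s = sign[i];
        if (s == 0) continue;
        for (size_t k = 0; k < nb[v].size(); ++k) {
          int w = nb[v][k] - 1;
          if (w < v) continue; // each pair once
          int j = w + base;
          if (sign[j] == s) uf_union(parent, i, j);
        }
        if (freq_adj && f + 1 < nf) {
          int j = v + nnode * ((f + 1) + nf * t);
          if (sign[j] == s) uf_union(parent, i, j);
        }
        if (time_adj && t + 1 < nt) {
          int j = v + nnode * (f + nf * (t + 1));
          if (sign[j] == s) uf_union(parent, i, j);
        }
      }
    }
  }

  IntegerVector lab(ncell, 0);
  std::vector<int> remap(ncell, 0);
  int next = 0;
  for (int i = 0; i < ncell; ++i) {
    if (sign[i] == 0) continue;
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}
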