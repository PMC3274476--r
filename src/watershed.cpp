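#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Marker-based (seeded) watershed on a 3D intensity array by priority flood:
// regions grow from seeds in order of decreasing intensity, 6-connectivity.
// Each region stops at voxels below its own absolute intensity floor, which
// keeps segmentation robust to the illumination-axis attenuation gradient.

namespace {
struct Node {
  double v; int idx; int label;
  bool operator<(const Node& o) const { return v < o.v; }  // max-heap
};
}

// [[Rcpp::export]]
IntegerVector seeded_watershed3(NumericVector vol, IntegerVector dims,
                                IntegerVector seed_idx,   // 1-based linear
                                IntegerVector seed_label,
                                NumericVector floor_of_label) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  size_t sx = (size_t)ny, sz = (size_t)ny * nx, n = sz * (size_t)nz;
  const double* p = &vol[0];
  IntegerVector labels(n, 0);
  std::priority_queue<Node> q;

  for (int s = 0; s < seed_idx.size(); ++s) {
    int i = seed_idx[s] - 1;
    q.push({p[i], i, seed_label[s]});
  }

  const int noff = 6;
  while (!q.empty()) {
    Node nd = q.top(); q.pop();
    if (labels[nd.idx] != 0) continue;
    labels[nd.idx] = nd.label;
    int z = nd.idx / (int)sz, rem = nd.idx % (int)sz;
    int x = rem / ny, y = rem % ny;
    int cand[noff][3] = {{y-1,x,z},{y+1,x,z},{y,x-1,z},{y,x+1,z},{y,x,z-1},{y,x,z+1}};
    double fl = floor_of_label[nd.label - 1];
    for (int c = 0; c < noff; ++c) {
      int yy = cand[c][0], xx = cand[c][1], zz = cand[c][2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      size_t j = yy + xx * sx + zz * sz;
      if (labels[j] != 0) continue;
      if (p[j] < fl) continue;
      q.push({p[j], (int)j, nd.label});
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
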