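#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fruchterman-Reingold style pairwise repulsion, exact O(n^2).
// Force magnitude k^2 / d along the separating direction.
// [[Rcpp::export]]
NumericMatrix repulsion_exact(NumericMatrix pos, double k) {
  int n = pos.nrow();
  NumericMatrix f(n, 2);
  double k2 = k * k;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-12) {
        // coincident nodes: deterministic index-based nudge
        dx = 1e-3 * ((i + j) % 7 + 1);
        dy = 1e-3 * ((i - j) % 5 + 1);
        d2 = dx * dx + dy * dy;
      }
      double m = k2 / d2;  // (k^2/d) * (1/d) for the unit vector
      f(i, 0) += dx * m;
      f(i, 1) += dy * m;
      f(j, 0) -= dx * m;
      f(j, 1) -= dy * m;
    }
  }
  return f;
}

// Grid-approximated repulsion for large graphs: nodes repel the centroids
// of occupied grid cells (count-weighted), with exact pairwise forces
// inside the node's own cell. Cell size should be a few ideal edge lengths.
// [[Rcpp::export]]
NumericMatrix repulsion_grid(NumericMatrix pos, double k, double cell) {
  int n = pos.nrow();
  NumericMatrix f(n, 2);
  double k2 = k * k;
  double minx = R_PosInf, miny = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (pos(i, 0) < minx) minx = pos(i, 0);
    if (pos(i, 1) < miny) miny = pos(i, 1);
  }
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor((pos(i, 0) - minx) / cell);
    long long iy = (long long)std::floor((pos(i, 1) - miny) / cell);
    key[i] = ix * 1000003LL + iy;
    cells[key[i]].push_back(i);
  }
  // centroids
  std::vector<long long> ckey;
  std::vector<double> cx, cy, cn;
  ckey.reserve(cells.size());
  for (std::unordered_map<long long, std::vector<int> >::iterator it = cells.begin();
       it != cells.end(); ++it) {
    double sx = 0, sy = 0;
    for (size_t j = 0; j < it->second.size(); ++j) {
      sx += pos(it->second[j], 0);
      sy += pos(it->second[j], 1);
    }
    ckey.push_back(it->first);
    cx.push_back(sx / it->second.size());
    cy.push_back(sy / it->second.size());
    cn.push_back((double)it->second.size());
  }
  int nc = ckey.size();
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < nc; ++c) {
      if (ckey[c] == key[i]) continue;
      double dx = pos(i, 0) - cx[c];
      double dy = pos(i, 1) - cy[c];
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-12) continue;
      double m = cn[c] * k2 / d2;
      f(i, 0) += dx * m;
      f(i, 1) += dy * m;
    }
  }
  // exact within own cell
  for (std::unordered_map<long long, std::vector<int> >::iterator it = cells.begin();
       it != cells.end(); ++it) {
    std::vector<int>& v = it->second;
    for (size_t a = 0; a < v.size(); ++a) {
      for (size_t b = a + 1; b < v.size(); ++b) {
        int i = v[a], j = v[b];
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double d2 = dx * dx + dy * dy;
        if (d2 < 1e-12) {
          dx = 1e-3 * ((i + j) % 7 + 1);
          dy = 1e-3 * ((i - j) % 5 + 1);
          d2 = dx * dx + dy * dy;
        }
        double m = k2 / d2;
        f(i, 0) += dx * m;
        f(i, 1) += dy * m;
        f(j, 0) -= dx * m;
        f(j, 1) -= dy * m;
      }
    }
  }
  return f;
}

// Spring attraction along edges: magnitude d^2 / k toward the neighbour.
// edges is a 2-column 0-based integer matrix.
// [[Rcpp::export]]
NumericMatrix attraction_edges(NumericMatrix pos, IntegerMatrix edges, double k) {
  int n = pos.nrow();
  NumericMatrix f(n, 2);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-12) continue;
    double m = d / k;  // (d^2/k) / d
    f(i, 0) -= dx * m;
    f(i, 1) -= dy * m;
    f(j, 0) += dx * m;
    f(j, 1) += dy * m;
  }
  return f;
}

// Exact constraint projection on one coordinate. Nodes are grouped into
// alignment super-nodes (super_members: list of 0-based node index
// vectors; singletons for nodes that only appear in relative constraints).
// Each super-node takes the mean coordinate of its members (the alignment
// snap), then relative constraints — edges (first, second) between
// super-nodes, requiring second >= first + gap — are enforced in one
// forward pass over `topo`, a topological order of the super-node DAG.
// Finally the constrained nodes are shifted back so their mean
// displacement is zero (no drift), and the new values are written into
// pos. The constraint residual after this pass is exactly zero up to
// floating point.
// [[Rcpp::export]]
void project_exact(NumericMatrix pos, int coord,
                   List super_members, IntegerVector topo,
                   IntegerVector edge_first, IntegerVector edge_second,
                   double gap) {
  int ns = super_members.size();
  if (ns == 0) return;
  std::vector<double> value(ns, 0.0);
  for (int s = 0; s < ns; ++s) {
    IntegerVector mem = super_members[s];
    double acc = 0;
    for (int j = 0; j < mem.size(); ++j) acc += pos(mem[j], coord);
    value[s] = acc / mem.size();
  }
  // incoming edges per super-node
  std::vector<std::vector<int> > in(ns);
  for (int e = 0; e < edge_first.size(); ++e) {
    in[edge_second[e]].push_back(edge_first[e]);
  }
  for (int t = 0; t < topo.size(); ++t) {
    int s = topo[t];
    for (size_t j = 0; j < in[s].size(); ++j) {
      double lb = value[in[s][j]] + gap;
      if (value[s] < lb) value[s] = lb;
    }
  }
  // recentre: zero mean displacement over constrained nodes
  double shift = 0;
  int cnt = 0;
  for (int s = 0; s < ns; ++s) {
    IntegerVector mem = super_members[s];
    for (int j = 0; j < mem.size(); ++j) {
      shift += value[s] - pos(mem[j], coord);
      ++cnt;
    }
  }
  shift /= cnt;
  for (int s = 0; s < ns; ++s) {
    IntegerVector mem = super_members[s];
    for (int j = 0; j < mem.size(); ++j) {
      pos(mem[j], coord) = value[s] - shift;
    }
  }
}
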