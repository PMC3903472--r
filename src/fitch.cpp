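// Parsimony kernels: bit-packed Fitch (Wagner) scoring of binary-character
// matrices on unrooted binary trees, stepwise-addition tree construction and
// NNI hill-climbing. Trees are edge lists over node ids 1..(2n-2): leaves
// 1..n index rows of the character matrix, internal nodes n+1.. upward.
// Scoring uses flat reusable buffers so tight search loops do not allocate.
#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// packed leaf states: one pair of bitsets (state 0 / state 1) per taxon
struct Packed {
  int ntaxa, nw;
  std::vector<uint64_t> s0, s1, valid;
  explicit Packed(const IntegerMatrix& X) {
    ntaxa = X.nrow();
    const int k = X.ncol();
    nw = (k + 63) / 64;
    s0.assign((size_t)ntaxa * nw, 0);
    s1.assign((size_t)ntaxa * nw, 0);
    valid.assign(nw, 0);
    for (int j = 0; j < k; ++j) valid[j >> 6] |= (uint64_t(1) << (j & 63));
    for (int i = 0; i < ntaxa; ++i)
      for (int j = 0; j < k; ++j) {
        if (X(i, j) == 1) s1[(size_t)i * nw + (j >> 6)] |= (uint64_t(1) << (j & 63));
        else s0[(size_t)i * nw + (j >> 6)] |= (uint64_t(1) << (j & 63));
      }
  }
};

// reusable scratch for adjacency + traversal + node state sets
struct Work {
  std::vector<int> deg, off, nbr, stack, post, parent;
  std::vector<uint64_t> n0, n1;
};

// Fitch downpass length of the tree given by edges (ea[i], eb[i]); exact
// for unrooted binary trees rooted at any internal node (sequential
// set-fold; the root trifurcation is an arbitrary resolution).
static int fitch_edges(const std::vector<int>& ea, const std::vector<int>& eb,
                       int ne, const Packed& p, Work& w) {
  int nn = 0;
  for (int i = 0; i < ne; ++i) {
    if (ea[i] > nn) nn = ea[i];
    if (eb[i] > nn) nn = eb[i];
  }
  const int nw = p.nw;
  w.deg.assign(nn + 1, 0);
  for (int i = 0; i < ne; ++i) { ++w.deg[ea[i]]; ++w.deg[eb[i]]; }
  w.off.assign(nn + 2, 0);
  for (int v = 1; v <= nn; ++v) w.off[v + 1] = w.off[v] + w.deg[v];
  w.nbr.resize(2 * ne);
  {
    std::vector<int>& cur = w.deg;  // reuse as fill cursor
    for (int v = 1; v <= nn; ++v) cur[v] = w.off[v];
    for (int i = 0; i < ne; ++i) {
      w.nbr[cur[ea[i]]++] = eb[i];
      w.nbr[cur[eb[i]]++] = ea[i];
    }
  }
  int root = -1;
  for (int v = nn; v >= 1; --v)
    if (v > p.ntaxa && w.off[v + 1] > w.off[v]) { root = v; break; }
  if (root < 0) root = ea[0];
  w.parent.assign(nn + 1, 0);
  w.stack.clear();
  w.post.clear();
  w.stack.push_back(root);
  w.parent[root] = -1;
  while (!w.stack.empty()) {
    int v = w.stack.back();
    w.stack.pop_back();
    w.post.push_back(v);
    for (int q = w.off[v]; q < w.off[v + 1]; ++q) {
      int u = w.nbr[q];
      if (u != w.parent[v]) { w.parent[u] = v; w.stack.push_back(u); }
    }
  }
  w.n0.assign((size_t)(nn + 1) * nw, 0);
  w.n1.assign((size_t)(nn + 1) * nw, 0);
  int steps = 0;
  for (int idx = (int)w.post.size() - 1; idx >= 0; --idx) {
    int v = w.post[idx];
    uint64_t* v0 = &w.n0[(size_t)v * nw];
    uint64_t* v1 = &w.n1[(size_t)v * nw];
    if (v <= p.ntaxa) {
      const uint64_t* l0 = &p.s0[(size_t)(v - 1) * nw];
      const uint64_t* l1 = &p.s1[(size_t)(v - 1) * nw];
      for (int j = 0; j < nw; ++j) { v0[j] = l0[j]; v1[j] = l1[j]; }
      continue;
    }
    bool first = true;
    for (int q = w.off[v]; q < w.off[v + 1]; ++q) {
      int u = w.nbr[q];
      if (u == w.parent[v]) continue;
      const uint64_t* u0 = &w.n0[(size_t)u * nw];
      const uint64_t* u1 = &w.n1[(size_t)u * nw];
      if (first) {
        for (int j = 0; j < nw; ++j) { v0[j] = u0[j]; v1[j] = u1[j]; }
        first = false;
        continue;
      }
      for (int j = 0; j < nw; ++j) {
        uint64_t i0 = v0[j] & u0[j], i1 = v1[j] & u1[j];
        uint64_t empty = ~(i0 | i1);
        steps += popcount64(empty & p.valid[j]);
        v0[j] = i0 | (empty & (v0[j] | u0[j]));
        v1[j] = i1 | (empty & (v1[j] | u1[j]));
      }
    }
  }
  return steps;
}

// [[Rcpp::export(name = ".fitch_len_cpp")]]
int fitch_len_cpp(IntegerMatrix edge, int ntaxa, IntegerMatrix X) {
  Packed p(X);
  Work w;
  const int ne = edge.nrow();
  std::vector<int> ea(ne), eb(ne);
  for (int i = 0; i < ne; ++i) { ea[i] = edge(i, 0); eb[i] = edge(i, 1); }
  return fitch_edges(ea, eb, ne, p, w);
}

// Attachment cost of an extra all-zero leaf (taxon ntaxa+1 of X) on every
// edge of the tree: returns the full-tree length for each candidate edge,
// in the input edge order. Used to root at the aberration-free ancestor.
// [[Rcpp::export(name = ".attach_costs_cpp")]]
IntegerVector attach_costs_cpp(IntegerMatrix edge, int ntaxa,
                               IntegerMatrix X) {
  Packed p(X);  // X has ntaxa+1 rows; last row is the ancestor
  Work w;
  const int ne = edge.nrow();
  std::vector<int> ea(ne + 2), eb(ne + 2);
  int mx = 0;
  for (int i = 0; i < ne; ++i) {
    ea[i] = edge(i, 0);
    eb[i] = edge(i, 1);
    if (ea[i] > mx) mx = ea[i];
    if (eb[i] > mx) mx = eb[i];
  }
  const int anc = ntaxa + 1, wnode = mx + 1;
  IntegerVector out(ne);
  for (int e = 0; e < ne; ++e) {
    int v = eb[e];
    eb[e] = wnode;
    ea[ne] = wnode; eb[ne] = v;
    ea[ne + 1] = wnode; eb[ne + 1] = anc;
    out[e] = fitch_edges(ea, eb, ne + 2, p, w);
    eb[e] = v;
  }
  return out;
}

// Stepwise addition: taxa added in `ord` (1-based taxon ids), each at the
// edge minimising the Fitch length of the grown tree; ties -> first edge.
// [[Rcpp::export(name = ".stepwise_addition_cpp")]]
List stepwise_addition_cpp(IntegerMatrix X, IntegerVector ord) {
  const int n = X.nrow();
  if (n < 3 || ord.size() != n) stop("need >= 3 taxa and a full addition order");
  Packed p(X);
  Work w;
  std::vector<int> ea, eb;
  int next_internal = n + 1;
  ea.push_back(next_internal); eb.push_back(ord[0]);
  ea.push_back(next_internal); eb.push_back(ord[1]);
  ea.push_back(next_internal); eb.push_back(ord[2]);
  ++next_internal;
  for (int k = 3; k < n; ++k) {
    int leaf = ord[k];
    int best_edge = -1, best_len = INT_MAX;
    int ne = (int)ea.size();
    ea.resize(ne + 2); eb.resize(ne + 2);
    for (int e = 0; e < ne; ++e) {
      int v = eb[e];
      eb[e] = next_internal;
      ea[ne] = next_internal; eb[ne] = v;
      ea[ne + 1] = next_internal; eb[ne + 1] = leaf;
      int len = fitch_edges(ea, eb, ne + 2, p, w);
      if (len < best_len) { best_len = len; best_edge = e; }
      eb[e] = v;
    }
    int v = eb[best_edge];
    eb[best_edge] = next_internal;
    ea[ne] = next_internal; eb[ne] = v;
    ea[ne + 1] = next_internal; eb[ne + 1] = leaf;
    ++next_internal;
  }
  int len = fitch_edges(ea, eb, (int)ea.size(), p, w);
  IntegerMatrix em((int)ea.size(), 2);
  for (size_t i = 0; i < ea.size(); ++i) { em(i, 0) = ea[i]; em(i, 1) = eb[i]; }
  return List::create(_["edge"] = em, _["length"] = len);
}

// One best-improvement NNI pass repeated until no move improves the length
// (or max_sweeps reached). Returns the improved tree, its length and the
// number of rearrangements examined.
// [[Rcpp::export(name = ".nni_search_cpp")]]
List nni_search_cpp(IntegerMatrix edge, int ntaxa, IntegerMatrix X,
                    int max_sweeps) {
  Packed p(X);
  Work w;
  const int ne = edge.nrow();
  std::vector<int> ea(ne), eb(ne);
  for (int i = 0; i < ne; ++i) { ea[i] = edge(i, 0); eb[i] = edge(i, 1); }
  int cur = fitch_edges(ea, eb, ne, p, w);
  double examined = 0;
  std::vector<int> eu, ev;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int best_len = cur, bf = -1, bg = -1, bu = -1, bv = -1;
    for (int e = 0; e < ne; ++e) {
      int u = ea[e], v = eb[e];
      if (u <= ntaxa || v <= ntaxa) continue;  // internal edges only
      eu.clear(); ev.clear();
      for (int f = 0; f < ne; ++f) {
        if (f == e) continue;
        if (ea[f] == u || eb[f] == u) eu.push_back(f);
        if (ea[f] == v || eb[f] == v) ev.push_back(f);
      }
      for (size_t j = 0; j < ev.size(); ++j) {
        int f = eu[0], g = ev[j];
        int* fu = (ea[f] == u) ? &eb[f] : &ea[f];
        int* gv = (ea[g] == v) ? &eb[g] : &ea[g];
        std::swap(*fu, *gv);
        examined += 1;
        int len = fitch_edges(ea, eb, ne, p, w);
        if (len < best_len) { best_len = len; bf = f; bg = g; bu = u; bv = v; }
        std::swap(*fu, *gv);
      }
    }
    if (bf < 0) break;
    int* fu = (ea[bf] == bu) ? &eb[bf] : &ea[bf];
    int* gv = (ea[bg] == bv) ? &eb[bg] : &ea[bg];
    std::swap(*fu, *gv);
    cur = best_len;
  }
  IntegerMatrix em(ne, 2);
  for (int i = 0; i < ne; ++i) { em(i, 0) = ea[i]; em(i, 1) = eb[i]; }
  return List::create(_["edge"] = em, _["length"] = cur,
                      _["examined"] = examined);
}
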