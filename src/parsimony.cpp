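// Maximum-parsimony engine: Fitch small parsimony over bitmask-encoded
// characters, stepwise random-addition tree building, and
// close-neighbor-interchange (CNI) hill climbing bounded by a number of
// successive nearest-neighbor-interchange (NNI) moves.
//
// Trees are rooted binary, stored as parent/child index arrays.  Tips are
// nodes 0 .. nTip-1, internal nodes nTip .. 2*nTip-2; the Fitch score is
// invariant to root placement, so the rooted score equals the unrooted
// parsimony score of the same topology.  Characters are unordered
// multistate with unit cost (standard protein parsimony); bootstrap column
// resampling is passed in as integer column weights.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  int nTip;
  int root;
  std::vector<int> par, ch1, ch2;  // -1 when absent
  std::vector<int> active;         // internal node in use?

  explicit Tree(int n) : nTip(n), root(-1),
      par(2 * n - 1, -1), ch1(2 * n - 1, -1), ch2(2 * n - 1, -1),
      active(2 * n - 1, 0) {}

  void replace_child(int p, int oldc, int newc) {
    if (ch1[p] == oldc) ch1[p] = newc; else ch2[p] = newc;
  }
  int sibling(int v) const {
    int p = par[v];
    return ch1[p] == v ? ch2[p] : ch1[p];
  }
};

struct Scorer {
  int nTip, nCol;
  const int* w;
  std::vector<int> buf;        // (2n-1) x nCol node state sets
  std::vector<int> postorder;  // scratch
  std::vector<int> stack;      // scratch

  Scorer(const IntegerMatrix& states, const IntegerVector& weights)
      : nTip(states.nrow()), nCol(states.ncol()), w(&weights[0]),
        buf((2 * states.nrow() - 1) * (size_t)states.ncol()),
        postorder(), stack() {
    postorder.reserve(2 * nTip - 1);
    stack.reserve(2 * nTip - 1);
    // tip rows never change: fill once
    for (int v = 0; v < nTip; ++v)
      for (int c = 0; c < nCol; ++c)
        buf[(size_t)v * nCol + c] = states(v, c);
  }

  // full Fitch score of a rooted binary tree; stops early (returning a
  // value >= bound) once the partial score reaches `bound`
  long score(const Tree& t, long bound = -1) {
    postorder.clear();
    stack.clear();
    stack.push_back(t.root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v >= nTip) {
        postorder.push_back(v);
        stack.push_back(t.ch1[v]);
        stack.push_back(t.ch2[v]);
      }
    }
    long sc = 0;
    for (int k = (int)postorder.size() - 1; k >= 0; --k) {
      int v = postorder[k];
      const int* a = &buf[(size_t)t.ch1[v] * nCol];
      const int* b = &buf[(size_t)t.ch2[v] * nCol];
      int* out = &buf[(size_t)v * nCol];
      for (int c = 0; c < nCol; ++c) {
        int x = a[c] & b[c];
        if (x) out[c] = x;
        else { out[c] = a[c] | b[c]; sc += w[c]; }
      }
      if (bound >= 0 && sc >= bound) return sc;
    }
    return sc;
  }
};

// ---- stepwise addition ----------------------------------------------------

// insert tip x above node c using spare internal node w
void insert_at(Tree& t, int c, int x, int w) {
  int p = t.par[c];
  t.par[w] = p;
  if (p >= 0) t.replace_child(p, c, w); else t.root = w;
  t.ch1[w] = c; t.ch2[w] = x;
  t.par[c] = w; t.par[x] = w;
  t.active[w] = 1;
}

void remove_at(Tree& t, int c, int x, int w) {
  int p = t.par[w];
  t.par[c] = p;
  if (p >= 0) t.replace_child(p, w, c); else t.root = c;
  t.par[x] = -1; t.par[w] = -1;
  t.ch1[w] = t.ch2[w] = -1;
  t.active[w] = 0;
}

// candidate attachment points: every node except the root
void candidates(const Tree& t, std::vector<int>& out) {
  out.clear();
  for (int v = 0; v < 2 * t.nTip - 1; ++v) {
    if (v == t.root) continue;
    if (v < t.nTip) {
      if (t.par[v] >= 0) out.push_back(v);
    } else if (t.active[v]) {
      out.push_back(v);
    }
  }
}

Tree stepwise_addition(Scorer& sc, const std::vector<int>& order) {
  int n = sc.nTip;
  Tree t(n);
  int root = n;  // first internal node
  t.root = root;
  t.active[root] = 1;
  t.ch1[root] = order[0]; t.ch2[root] = order[1];
  t.par[order[0]] = root; t.par[order[1]] = root;
  int next_internal = n + 1;
  std::vector<int> cand;
  for (size_t k = 2; k < order.size(); ++k) {
    int x = order[k];
    int w = next_internal++;
    candidates(t, cand);
    long best = -1; int best_c = -1;
    for (int c : cand) {
      insert_at(t, c, x, w);
      long s = sc.score(t, best);
      remove_at(t, c, x, w);
      if (best < 0 || s < best) { best = s; best_c = c; }
    }
    insert_at(t, best_c, x, w);
  }
  return t;
}

// ---- NNI / CNI ------------------------------------------------------------

// swap subtrees rooted at a and b (neither ancestor of the other)
void swap_subtrees(Tree& t, int a, int b) {
  int pa = t.par[a], pb = t.par[b];
  t.replace_child(pa, a, b);
  t.replace_child(pb, b, a);
  t.par[a] = pb; t.par[b] = pa;
}

// all NNI moves of the unrooted topology, as subtree swap pairs
void nni_moves(const Tree& t, std::vector<std::pair<int, int> >& out) {
  out.clear();
  int n2 = 2 * t.nTip - 1;
  for (int v = t.nTip; v < n2; ++v) {
    if (!t.active[v] || v == t.root) continue;
    if (t.par[v] != t.root) {
      int s = t.sibling(v);
      out.push_back(std::make_pair(t.ch1[v], s));
      out.push_back(std::make_pair(t.ch2[v], s));
    }
  }
  // root edge: both children internal -> one unrooted internal edge
  int a = t.ch1[t.root], b = t.ch2[t.root];
  if (a >= t.nTip && b >= t.nTip) {
    out.push_back(std::make_pair(t.ch1[a], t.ch1[b]));
    out.push_back(std::make_pair(t.ch1[a], t.ch2[b]));
  }
}

// hill climb; level 1 = best single NNI, level >= 2 also explores pairs of
// successive NNI moves once no single move improves
long cni(Scorer& sc, Tree& t, int level, long cur) {
  std::vector<std::pair<int, int> > mv, mv2;
  for (;;) {
    nni_moves(t, mv);
    long best = cur;
    int best_i = -1;
    for (size_t i = 0; i < mv.size(); ++i) {
      swap_subtrees(t, mv[i].first, mv[i].second);
      long s = sc.score(t, best);
      swap_subtrees(t, mv[i].first, mv[i].second);
      if (s < best) { best = s; best_i = (int)i; }
    }
    if (best_i >= 0) {
      swap_subtrees(t, mv[best_i].first, mv[best_i].second);
      cur = best;
      continue;
    }
    if (level < 2) return cur;
    // two-move neighborhood
    long best2 = cur;
    std::pair<int, int> m1b, m2b;
    bool found = false;
    for (size_t i = 0; i < mv.size(); ++i) {
      swap_subtrees(t, mv[i].first, mv[i].second);
      nni_moves(t, mv2);
      for (size_t j = 0; j < mv2.size(); ++j) {
        swap_subtrees(t, mv2[j].first, mv2[j].second);
        long s = sc.score(t, best2);
        swap_subtrees(t, mv2[j].first, mv2[j].second);
        if (s < best2) {
          best2 = s; m1b = mv[i]; m2b = mv2[j]; found = true;
        }
      }
      swap_subtrees(t, mv[i].first, mv[i].second);
    }
    if (!found) return cur;
    swap_subtrees(t, m1b.first, m1b.second);
    swap_subtrees(t, m2b.first, m2b.second);
    cur = best2;
  }
}

// ---- conversion -----------------------------------------------------------

// ape-style edge matrix: tips 1..n, root n+1, internals preorder-numbered
IntegerMatrix tree_to_edge(const Tree& t) {
  int n = t.nTip;
  std::vector<int> newnum(2 * n - 1, -1);
  int next = n + 1;
  std::vector<std::pair<int, int> > edges;
  std::vector<int> stack;
  newnum[t.root] = next++;
  stack.push_back(t.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int kids[2] = { t.ch1[v], t.ch2[v] };
    for (int k = 0; k < 2; ++k) {
      int c = kids[k];
      if (c < 0) continue;
      if (c < n) newnum[c] = c + 1;
      else newnum[c] = next++;
      edges.push_back(std::make_pair(newnum[v], newnum[c]));
      if (c >= n) stack.push_back(c);
    }
  }
  IntegerMatrix em((int)edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    em(i, 0) = edges[i].first;
    em(i, 1) = edges[i].second;
  }
  return em;
}

Tree edge_to_tree(const IntegerMatrix& edge, int nTip) {
  Tree t(nTip);
  int root1 = -1;
  std::vector<int> seen_child(2 * nTip, 0);
  for (int i = 0; i < edge.nrow(); ++i) seen_child[edge(i, 1)] = 1;
  for (int i = 0; i < edge.nrow(); ++i) {
    if (!seen_child[edge(i, 0)]) { root1 = edge(i, 0); break; }
  }
  t.root = root1 - 1;
  for (int i = 0; i < edge.nrow(); ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    t.par[c] = p;
    if (t.ch1[p] < 0) t.ch1[p] = c;
    else if (t.ch2[p] < 0) t.ch2[p] = c;
    else stop("tree is not binary");
    if (p >= nTip) t.active[p] = 1;
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
double cpp_fitch_edge(IntegerMatrix edge, int nTip, IntegerMatrix states,
                      IntegerVector weights) {
  // generalized left-fold Fitch over an edge matrix in postorder
  // (children rows before parent rows); handles multifurcations by
  // sequential pairwise folding
  int nNode = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    nNode = std::max(nNode, std::max(edge(i, 0), edge(i, 1)));
  int nCol = states.ncol();
  std::vector<int> acc((size_t)nNode * nCol, 0);
  std::vector<int> filled(nNode, 0);
  long sc = 0;
  for (int i = 0; i < states.nrow(); ++i) {
    for (int c = 0; c < nCol; ++c) acc[(size_t)i * nCol + c] = states(i, c);
    filled[i] = 1;
  }
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    if (!filled[ch]) stop("edge matrix is not in postorder");
    int* a = &acc[(size_t)p * nCol];
    const int* b = &acc[(size_t)ch * nCol];
    if (!filled[p]) {
      for (int c = 0; c < nCol; ++c) a[c] = b[c];
      filled[p] = 1;
    } else {
      for (int c = 0; c < nCol; ++c) {
        int x = a[c] & b[c];
        if (x) a[c] = x;
        else { a[c] = a[c] | b[c]; sc += weights[c]; }
      }
    }
  }
  return (double)sc;
}

// [[Rcpp::export]]
List cpp_random_addition(IntegerMatrix states, IntegerVector weights,
                         IntegerVector order) {
  Scorer sc(states, weights);
  std::vector<int> ord(order.size());
  for (int i = 0; i < order.size(); ++i) ord[i] = order[i] - 1;
  Tree t = stepwise_addition(sc, ord);
  long s = sc.score(t);
  return List::create(_["edge"] = tree_to_edge(t), _["score"] = (double)s);
}

// [[Rcpp::export]]
List cpp_cni(IntegerMatrix states, IntegerVector weights, IntegerMatrix edge,
             int nTip, int level) {
  Scorer sc(states, weights);
  Tree t = edge_to_tree(edge, nTip);
  long s0 = sc.score(t);
  long s = cni(sc, t, level, s0);
  return List::create(_["edge"] = tree_to_edge(t), _["score"] = (double)s);
}

// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix states, IntegerVector weights,
                   IntegerMatrix orders, int level) {
  Scorer sc(states, weights);
  long best = -1;
  Tree best_tree(states.nrow());
  for (int r = 0; r < orders.nrow(); ++r) {
    std::vector<int> ord(orders.ncol());
    for (int i = 0; i < orders.ncol(); ++i) ord[i] = orders(r, i) - 1;
    Tree t = stepwise_addition(sc, ord);
    long s = sc.score(t);
    s = cni(sc, t, level, s);
    if (best < 0 || s < best) { best = s; best_tree = t; }
  }
  return List::create(_["edge"] = tree_to_edge(best_tree),
                      _["score"] = (double)best);
}
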