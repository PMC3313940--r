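#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Dinucleotide-preserving shuffle (Altschul-Erikson construction).
//
// The sequence is viewed as an Eulerian walk on the graph whose vertices are
// the distinct letters and whose edges are the observed adjacent pairs.  A
// random "last exit" edge is drawn for every vertex except the terminal one
// and the draw is accepted only when the last-exit edges form an arborescence
// into the terminal vertex; the remaining out-edges are then permuted
// uniformly and the walk is replayed.  This samples uniformly over sequences
// with exactly the same multiset of overlapping dinucleotides (hence the same
// length, mononucleotide counts, first and last letter).
//
// Draws come from R's RNG so set.seed() on the R side gives reproducibility.

static inline int runif_int(int n) {
  // uniform on 0..n-1, guarding the (measure-zero) unif_rand() == 1.0 edge
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// [[Rcpp::export]]
std::string dinuc_shuffle_cpp(std::string s) {
  const int n = (int)s.size();
  if (n < 3) return s;  // 0 or 1 dinucleotides: arrangement is unique

  int code[256];
  std::fill(code, code + 256, -1);
  std::vector<char> letters;
  std::vector<int> seq(n);
  for (int i = 0; i < n; ++i) {
    unsigned char c = (unsigned char)s[i];
    if (code[c] < 0) {
      code[c] = (int)letters.size();
      letters.push_back(s[i]);
    }
    seq[i] = code[c];
  }
  const int V = (int)letters.size();
  if (V == 1) return s;

  std::vector<std::vector<int> > adj(V);
  for (int i = 0; i + 1 < n; ++i) adj[seq[i]].push_back(seq[i + 1]);
  const int first = seq[0], last = seq[n - 1];

  // rejection-sample the last-exit edges
  std::vector<int> lastEdge(V, -1);
  for (int attempt = 0;; ++attempt) {
    if (attempt > 1000000)
      stop("dinucleotide shuffle: no valid edge arrangement found");
    for (int v = 0; v < V; ++v) {
      lastEdge[v] = (v == last || adj[v].empty())
                        ? -1
                        : runif_int((int)adj[v].size());
    }
    bool ok = true;
    for (int v = 0; v < V && ok; ++v) {
      if (v == last || adj[v].empty()) continue;
      int cur = v, steps = 0;
      while (cur != last && steps <= V) {
        if (lastEdge[cur] < 0) break;  // dead end that is not 'last'
        cur = adj[cur][lastEdge[cur]];
        ++steps;
      }
      if (cur != last) ok = false;
    }
    if (ok) break;
  }

  // permute the non-last out-edges of every vertex (all edges for 'last')
  for (int v = 0; v < V; ++v) {
    std::vector<int>& a = adj[v];
    if (a.empty()) continue;
    int m = (int)a.size();
    if (lastEdge[v] >= 0) {
      std::swap(a[lastEdge[v]], a[m - 1]);
      --m;
    }
    for (int i = m - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(a[i], a[j]);
    }
  }

  // replay the walk
  std::string out(n, ' ');
  out[0] = letters[first];
  std::vector<int> ptr(V, 0);
  int cur = first;
  for (int i = 1; i < n; ++i) {
    int nxt = adj[cur][ptr[cur]++];
    out[i] = letters[nxt];
    cur = nxt;
  }
  return out;
}

// [[Rcpp::export]]
std::vector<std::string> dinuc_shuffle_set_cpp(std::vector<std::string> xs) {
  for (size_t i = 0; i < xs.size(); ++i) xs[i] = dinuc_shuffle_cpp(xs[i]);
  return xs;
}
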