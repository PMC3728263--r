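#include <Rcpp.h>
using namespace Rcpp;

// Base pairing weight: GC=3, AU=2, GU=1, otherwise unpairable (-1).
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return -1;
}

// Stacking-aware Nussinov fold. Maximizes total pair weight plus a +1 bonus
// for every stacked pair (i,j) whose inner neighbour (i+1,j-1) is also paired,
// over nested structures with hairpin loops >= 3 nt. Deterministic traceback.
// Sequence must be uppercase DNA alphabet (U already mapped to T).
// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq) {
  const int n = (int) seq.size();
  const int MINLOOP = 3;
  IntegerVector ptable(n, 0);
  if (n < MINLOOP + 2) {
    return List::create(_["score"] = 0, _["pairs"] = ptable);
  }
  // P(i,j): best score with (i,j) paired; F(i,j): unconstrained best.
  // P is stored column-major (indexed [j][i]) so the bifurcation scan over
  // k in F touches contiguous memory.
  std::vector<std::vector<int>> P(n, std::vector<int>(n, -1000000));
  std::vector<std::vector<int>> F(n, std::vector<int>(n, 0));
#define PM(i, j) P[(j)][(i)]
  for (int span = MINLOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int w = pair_weight(seq[i], seq[j]);
      if (w > 0) {
        int interior = (j - i >= 2) ? F[i + 1][j - 1] : 0;
        int best = interior;
        if (j - i - 2 > MINLOOP && PM(i + 1, j - 1) > -1000000)
          best = std::max(best, PM(i + 1, j - 1) + 1);
        PM(i, j) = w + best;
      }
      int f = F[i][j - 1];  // j unpaired
      const int *pcol = P[j].data();
      for (int k = i; k <= j - MINLOOP - 1; ++k) {
        if (pcol[k] <= -1000000) continue;
        int cand = (k > i ? F[i][k - 1] : 0) + pcol[k];
        if (cand > f) f = cand;
      }
      F[i][j] = f;
    }
  }
  // Traceback; ties prefer pairing with the 5'-most k, and stacked inner pairs.
  std::vector<std::pair<int, int>> st;          // (i, j, mode) intervals
  std::vector<int> mode;                        // 0 = F interval, 1 = P pair
  st.push_back(std::make_pair(0, n - 1));
  mode.push_back(0);
  while (!st.empty()) {
    int i = st.back().first, j = st.back().second;
    int m = mode.back();
    st.pop_back(); mode.pop_back();
    if (i >= j) continue;
    if (m == 1) {
      // (i,j) paired
      ptable[i] = j + 1; ptable[j] = i + 1;
      int w = pair_weight(seq[i], seq[j]);
      int target = PM(i, j) - w;
      if (j - i - 2 > MINLOOP && PM(i + 1, j - 1) > -1000000 &&
          PM(i + 1, j - 1) + 1 == target) {
        st.push_back(std::make_pair(i + 1, j - 1)); mode.push_back(1);
      } else if (j - i >= 2) {
        st.push_back(std::make_pair(i + 1, j - 1)); mode.push_back(0);
      }
      continue;
    }
    // F interval: prefer the 5'-most paired decomposition on ties
    bool done = false;
    for (int k = i; k <= j - MINLOOP - 1 && !done; ++k) {
      if (PM(k, j) <= -1000000) continue;
      int cand = (k > i ? F[i][k - 1] : 0) + PM(k, j);
      if (cand == F[i][j]) {
        if (k > i) { st.push_back(std::make_pair(i, k - 1)); mode.push_back(0); }
        st.push_back(std::make_pair(k, j)); mode.push_back(1);
        done = true;
      }
    }
    if (!done) {
      st.push_back(std::make_pair(i, j - 1)); mode.push_back(0);
    }
  }
  return List::create(_["score"] = F[0][n - 1], _["pairs"] = ptable);
}

// Altschul-Erickson dinucleotide shuffle: returns a sequence with exactly the
// same mononucleotide and dinucleotide counts. Uses R's RNG.
// [[Rcpp::export]]
std::string dinuc_shuffle_cpp(std::string seq) {
  const int n = (int) seq.size();
  if (n < 3) return seq;
  // map characters to vertex ids
  std::map<char, int> vid;
  std::vector<char> vchar;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (vid.find(c) == vid.end()) { vid[c] = (int) vchar.size(); vchar.push_back(c); }
    s[i] = vid[c];
  }
  const int V = (int) vchar.size();
  if (V == 1) return seq;
  // edge multiset: out-edges per vertex
  std::vector<std::vector<int>> out(V);
  for (int i = 0; i + 1 < n; ++i) out[s[i]].push_back(s[i + 1]);
  const int last = s[n - 1];
  // pick last out-edge per vertex (except 'last') so chosen edges reach 'last'
  std::vector<int> lastEdge(V, -1);
  for (int tries = 0; tries < 10000; ++tries) {
    for (int v = 0; v < V; ++v) {
      lastEdge[v] = -1;
      if (v == last || out[v].empty()) continue;
      int k = (int) std::floor(unif_rand() * out[v].size());
      if (k >= (int) out[v].size()) k = (int) out[v].size() - 1;
      lastEdge[v] = out[v][k];
    }
    // check: from every vertex with out-edges, following lastEdge reaches 'last'
    bool ok = true;
    for (int v = 0; v < V && ok; ++v) {
      if (v == last || out[v].empty()) continue;
      int u = v, steps = 0;
      while (u != last && steps <= V) {
        if (u != last && out[u].empty()) break;
        u = lastEdge[u];
        if (u < 0) break;
        ++steps;
      }
      if (u != last) ok = false;
    }
    if (ok) break;
    if (tries == 9999) return seq;  // give up: degenerate graph, keep input
  }
  // build per-vertex edge orderings: random permutation of non-last edges,
  // then the chosen last edge appended
  std::vector<std::vector<int>> order(V);
  for (int v = 0; v < V; ++v) {
    std::vector<int> pool = out[v];
    if (lastEdge[v] >= 0) {
      // remove one instance of lastEdge[v]
      for (size_t k = 0; k < pool.size(); ++k) {
        if (pool[k] == lastEdge[v]) { pool.erase(pool.begin() + k); break; }
      }
    }
    // Fisher-Yates
    for (int k = (int) pool.size() - 1; k > 0; --k) {
      int r = (int) std::floor(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(pool[k], pool[r]);
    }
    if (lastEdge[v] >= 0) pool.push_back(lastEdge[v]);
    order[v] = pool;
  }
  // walk
  std::string res;
  res.reserve(n);
  std::vector<size_t> ptr(V, 0);
  int v = s[0];
  res.push_back(vchar[v]);
  for (int i = 0; i + 1 < n; ++i) {
    int u = order[v][ptr[v]++];
    res.push_back(vchar[u]);
    v = u;
  }
  return res;
}
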