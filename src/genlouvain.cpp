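// Generalized Louvain optimization of categorical multislice modularity.
//
// Quality (unnormalized):
//   sum_s sum_c [ 2 * E_in(c, s) - gamma * K(c, s)^2 / (2 m_s) ]
//     + omega * sum_i sum_c cnt(c, i) * (cnt(c, i) - 1)
// where E_in(c, s) = intra-slice edges of slice s inside community c,
// K(c, s) = summed slice-s degree of community c, m_s = edge count of slice
// s, and cnt(c, i) = number of slices in which node i belongs to community c
// (categorical all-to-all inter-slice coupling of the same node).
//
// Optimization follows the Louvain scheme: greedy single-vertex moves in
// randomized order over the (node, slice) vertex set, then aggregation of
// communities into a dense quality matrix and greedy moves on that, repeated
// until no gain. Deterministic given the seed.

#include <Rcpp.h>
#include <random>
#include <vector>

static void fisherYates(std::vector<int>& v, std::mt19937& rng) {
  for (size_t i = v.size(); i > 1; --i) {
    size_t j = rng() % i;
    std::swap(v[i - 1], v[j]);
  }
}
using namespace Rcpp;

namespace {

struct MultisliceProblem {
  int n, S;
  std::vector<std::vector<int>> adj;   // vertex -> intra-slice neighbours
  std::vector<double> k;               // intra-slice degree per vertex
  std::vector<double> twom;            // 2 m_s per slice
  double gamma, omega;

  int vid(int node, int slice) const { return slice * n + node; }
  int nodeOf(int v) const { return v % n; }
  int sliceOf(int v) const { return v / n; }
};

// Greedy local-move phase on the vertex level. comm is modified in place.
// Returns total gain achieved (in unnormalized quality units).
double movePhase(const MultisliceProblem& P, std::vector<int>& comm,
                 std::mt19937& rng) {
  const int V = P.n * P.S;
  // community bookkeeping: K(c, s) and cnt(c, i), dense over the initial
  // label space (labels are always < V)
  std::vector<double> Kcs((size_t)V * P.S, 0.0);
  // cnt(c, i): community x node counts, dense (V * n can be large: 8704*256
  // = 2.2e6 ints) -> acceptable.
  std::vector<int> cnt((size_t)V * P.n, 0);

  for (int v = 0; v < V; ++v) {
    int c = comm[v];
    Kcs[(size_t)c * P.S + P.sliceOf(v)] += P.k[v];
    cnt[(size_t)c * P.n + P.nodeOf(v)] += 1;
  }

  std::vector<int> order(V);
  for (int v = 0; v < V; ++v) order[v] = v;

  std::vector<double> linkW(V, 0.0);
  std::vector<int> touched;
  touched.reserve(256);

  double totalGain = 0.0;
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps < 64) {
    improved = false;
    ++sweeps;
    fisherYates(order, rng);
    for (int idx = 0; idx < V; ++idx) {
      int v = order[idx];
      int s = P.sliceOf(v), node = P.nodeOf(v);
      int cOld = comm[v];
      // candidate communities: intra-slice neighbours + same-node vertices
      touched.clear();
      for (int w : P.adj[v]) {
        int c = comm[w];
        if (linkW[c] == 0.0 && c != cOld) touched.push_back(c);
        linkW[c] += 1.0;  // binary graphs
      }
      std::vector<int> cands = touched;
      for (int s2 = 0; s2 < P.S; ++s2) {
        if (s2 == s) continue;
        int c = comm[P.vid(node, s2)];
        if (c != cOld) {
          bool seen = false;
          for (int cc : cands) if (cc == c) { seen = true; break; }
          if (!seen) cands.push_back(c);
        }
      }
      // gain of placing v in community c (relative, ordered-pair units):
      //   2*links(v,c) - 2*gamma*k_v*K(c,s)/(2 m_s) + 2*omega*cnt(c,node)
      double kv = P.k[v];
      double KOld = Kcs[(size_t)cOld * P.S + s] - kv;
      int cntOld = cnt[(size_t)cOld * P.n + node] - 1;
      double qStay = 2.0 * linkW[cOld]
        - 2.0 * P.gamma * kv * KOld / P.twom[s]
        + 2.0 * P.omega * cntOld;
      double bestGain = 0.0;
      int bestC = cOld;
      for (int c : cands) {
        double q = 2.0 * linkW[c]
          - 2.0 * P.gamma * kv * Kcs[(size_t)c * P.S + s] / P.twom[s]
          + 2.0 * P.omega * cnt[(size_t)c * P.n + node];
        double gain = q - qStay;
        if (gain > bestGain + 1e-12) { bestGain = gain; bestC = c; }
      }
      // reset scratch
      for (int w : P.adj[v]) linkW[comm[w]] = 0.0;
      if (bestC != cOld) {
        Kcs[(size_t)cOld * P.S + s] -= kv;
        cnt[(size_t)cOld * P.n + node] -= 1;
        Kcs[(size_t)bestC * P.S + s] += kv;
        cnt[(size_t)bestC * P.n + node] += 1;
        comm[v] = bestC;
        totalGain += bestGain;
        improved = true;
      }
    }
  }
  return totalGain;
}

// Renumber communities consecutively; returns number of communities.
int renumber(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t v = 0; v < comm.size(); ++v) {
    if (map[comm[v]] < 0) map[comm[v]] = next++;
    comm[v] = map[comm[v]];
  }
  return next;
}

// Greedy Louvain on a dense symmetric quality matrix (aggregated level).
// labels get the final community of each supernode. Returns gain.
double denseMovePhase(const std::vector<std::vector<double>>& B,
                      std::vector<int>& labels, std::mt19937& rng) {
  int C = (int)B.size();
  for (int i = 0; i < C; ++i) labels[i] = i;
  std::vector<int> order(C);
  for (int i = 0; i < C; ++i) order[i] = i;
  double totalGain = 0.0;
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps < 64) {
    improved = false;
    ++sweeps;
    fisherYates(order, rng);
    for (int oi = 0; oi < C; ++oi) {
      int u = order[oi];
      int cu = labels[u];
      std::vector<double> w(C, 0.0);
      for (int v = 0; v < C; ++v)
        if (v != u) w[labels[v]] += B[u][v];
      double qStay = 2.0 * w[cu];
      double bestGain = 0.0;
      int bestC = cu;
      for (int c = 0; c < C; ++c) {
        if (c == cu) continue;
        double gain = 2.0 * w[c] - qStay;
        if (gain > bestGain + 1e-12) { bestGain = gain; bestC = c; }
      }
      if (bestC != cu) { labels[u] = bestC; totalGain += bestGain; improved = true; }
    }
  }
  return totalGain;
}

} // namespace

// [[Rcpp::export]]
IntegerVector multisliceLouvainCpp(IntegerMatrix edges, int nNodes, int nSlices,
                                   double gamma, double omega, int seed) {
  MultisliceProblem P;
  P.n = nNodes; P.S = nSlices; P.gamma = gamma; P.omega = omega;
  const int V = nNodes * nSlices;
  P.adj.assign(V, {});
  P.k.assign(V, 0.0);
  P.twom.assign(nSlices, 0.0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int s = edges(e, 0) - 1, i = edges(e, 1) - 1, j = edges(e, 2) - 1;
    if (s < 0 || s >= nSlices || i < 0 || j < 0 || i >= nNodes || j >= nNodes)
      stop("edge table indices out of range");
    int u = P.vid(i, s), v = P.vid(j, s);
    P.adj[u].push_back(v);
    P.adj[v].push_back(u);
    P.k[u] += 1.0; P.k[v] += 1.0;
    P.twom[s] += 2.0;
  }
  for (int s = 0; s < nSlices; ++s)
    if (P.twom[s] <= 0) stop("slice %d has no edges", s + 1);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> comm(V);
  for (int v = 0; v < V; ++v) comm[v] = v;

  movePhase(P, comm, rng);
  int C = renumber(comm);

  // aggregation rounds
  for (int round = 0; round < 32; ++round) {
    // build aggregated quality matrix
    std::vector<std::vector<double>> B(C, std::vector<double>(C, 0.0));
    // intra-slice edges
    for (int v = 0; v < V; ++v) {
      for (int w : P.adj[v]) {      // each undirected edge appears twice
        B[comm[v]][comm[w]] += 0.5; // so add half per direction -> 1 per edge
      }
    }
    // make symmetric ordered-pair convention: B now holds edge counts with
    // B[c][d] = edges between c and d (d != c) and B[c][c] = edges inside c.
    // null model per slice
    std::vector<std::vector<double>> Ks(nSlices, std::vector<double>(C, 0.0));
    for (int v = 0; v < V; ++v) Ks[P.sliceOf(v)][comm[v]] += P.k[v];
    for (int s = 0; s < nSlices; ++s)
      for (int c = 0; c < C; ++c)
        for (int d = 0; d < C; ++d)
          B[c][d] -= 0.5 * gamma * Ks[s][c] * Ks[s][d] / P.twom[s];
    // coupling: cnt per community per node
    std::vector<std::vector<int>> cnt(C, std::vector<int>(nNodes, 0));
    for (int v = 0; v < V; ++v) cnt[comm[v]][P.nodeOf(v)] += 1;
    for (int c = 0; c < C; ++c)
      for (int d = 0; d < C; ++d) {
        double coup = 0.0;
        for (int i = 0; i < nNodes; ++i) {
          coup += (c == d)
            ? 0.5 * (double)cnt[c][i] * (cnt[c][i] - 1)
            : 0.5 * (double)cnt[c][i] * cnt[d][i];
        }
        B[c][d] += omega * coup;
      }

    std::vector<int> labels(C);
    double gain = denseMovePhase(B, labels, rng);
    if (gain <= 1e-9) break;
    for (int v = 0; v < V; ++v) comm[v] = labels[comm[v]];
    C = renumber(comm);
    // vertex-level refinement after each aggregation
    movePhase(P, comm, rng);
    C = renumber(comm);
  }

  IntegerVector out(V);
  for (int v = 0; v < V; ++v) out[v] = comm[v] + 1;
  return out;
}

// [[Rcpp::export]]
double multisliceQualityCpp(IntegerMatrix edges, IntegerVector membership,
                            int nNodes, int nSlices, double gamma,
                            double omega) {
  const int V = nNodes * nSlices;
  if (membership.size() != V) stop("membership must have nNodes * nSlices entries");
  std::vector<double> k(V, 0.0);
  std::vector<double> twom(nSlices, 0.0);
  double edgeTerm = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    int s = edges(e, 0) - 1, i = edges(e, 1) - 1, j = edges(e, 2) - 1;
    int u = s * nNodes + i, v = s * nNodes + j;
    k[u] += 1.0; k[v] += 1.0;
    twom[s] += 2.0;
    if (membership[u] == membership[v]) edgeTerm += 2.0;
  }
  int C = 0;
  for (int v = 0; v < V; ++v) C = std::max(C, (int)membership[v]);
  std::vector<std::vector<double>> Ks(nSlices, std::vector<double>(C, 0.0));
  for (int v = 0; v < V; ++v)
    Ks[v / nNodes][membership[v] - 1] += k[v];
  double nullTerm = 0.0;
  for (int s = 0; s < nSlices; ++s) {
    if (twom[s] <= 0) continue;
    for (int c = 0; c < C; ++c)
      nullTerm += gamma * Ks[s][c] * Ks[s][c] / twom[s];
  }
  double coupTerm = 0.0;
  for (int i = 0; i < nNodes; ++i) {
    std::vector<int> cnt(C, 0);
    for (int s = 0; s < nSlices; ++s)
      cnt[membership[s * nNodes + i] - 1] += 1;
    for (int c = 0; c < C; ++c)
      coupTerm += (double)cnt[c] * (cnt[c] - 1);
  }
  return edgeTerm - nullTerm + omega * coupTerm;
}
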