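#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Adjacency is passed in CSR form: offsets has length n+1, targets holds the
// 0-based neighbour indices of node i in targets[offsets[i] .. offsets[i+1]-1].
// Parallel edges are collapsed before CSR construction: one hop per edge
// regardless of multiplicity.

// [[Rcpp::export]]
IntegerVector cpp_bfs_dist(IntegerVector offsets, IntegerVector targets,
                           int n, int src) {
  IntegerVector dist(n, -1);
  std::queue<int> q;
  dist[src] = 0;
  q.push(src);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int j = offsets[v]; j < offsets[v + 1]; ++j) {
      int w = targets[j];
      if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        q.push(w);
      }
    }
  }
  return dist;
}

// Sum of finite shortest-path lengths from each node to the nodes it reaches
// (self excluded), plus the count reached and the harmonic sum; one BFS per
// source.
// [[Rcpp::export]]
List cpp_distance_sums(IntegerVector offsets, IntegerVector targets, int n) {
  NumericVector sums(n), harm(n);
  IntegerVector reached(n);
  std::vector<int> dist(n);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0; q[tail++] = s;
    double sm = 0.0, hm = 0.0; int cnt = 0;
    while (head < tail) {
      int v = q[head++];
      for (int j = offsets[v]; j < offsets[v + 1]; ++j) {
        int w = targets[j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          sm += dist[w];
          hm += 1.0 / dist[w];
          ++cnt;
          q[tail++] = w;
        }
      }
    }
    sums[s] = sm; harm[s] = hm; reached[s] = cnt;
  }
  return List::create(_["sum"] = sums, _["harmonic"] = harm,
                      _["reached"] = reached);
}

// Brandes (2001) accumulation for unweighted directed betweenness over
// ordered pairs a != b != i; geodesics counted on the simple digraph.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerVector offsets, IntegerVector targets,
                              int n) {
  NumericVector bc(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> stack_(n);
  std::vector<int> q(n);
  // predecessor lists stored compactly per BFS
  std::vector< std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    int head = 0, tail = 0, sp = 0;
    dist[s] = 0; sigma[s] = 1.0; q[tail++] = s;
    while (head < tail) {
      int v = q[head++];
      stack_[sp++] = v;
      for (int j = offsets[v]; j < offsets[v + 1]; ++j) {
        int w = targets[j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    while (sp > 0) {
      int w = stack_[--sp];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}

// Geodesic length and number of distinct shortest paths from a to b.
// Returns c(length, count); length = -1 and count = 0 when unreachable.
// [[Rcpp::export]]
NumericVector cpp_count_paths(IntegerVector offsets, IntegerVector targets,
                              int n, int a, int b) {
  std::vector<int> dist(n, -1);
  std::vector<double> sigma(n, 0.0);
  std::vector<int> q(n);
  int head = 0, tail = 0;
  dist[a] = 0; sigma[a] = 1.0; q[tail++] = a;
  while (head < tail) {
    int v = q[head++];
    if (dist[b] >= 0 && dist[v] >= dist[b]) break;  // b's layer done
    for (int j = offsets[v]; j < offsets[v + 1]; ++j) {
      int w = targets[j];
      if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        q[tail++] = w;
      }
      if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
    }
  }
  NumericVector out(2);
  out[0] = dist[b];
  out[1] = dist[b] < 0 ? 0.0 : sigma[b];
  return out;
}
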