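#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spatiotemporal grid: node id = ch + n_ch * t. Neighbors are the channel's
// adjacency partners at the same time point plus the same channel at t +/- 1.

static void flood(int start, const std::vector<char>& supra,
                  std::vector<int>& labels, int lab, int n_ch, int n_t,
                  const std::vector<std::vector<int>>& adj,
                  std::vector<int>& stack, std::vector<int>& members) {
  stack.clear();
  members.clear();
  stack.push_back(start);
  labels[start] = lab;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    members.push_back(v);
    int ch = v % n_ch, t = v / n_ch;
    if (t > 0) {
      int u = v - n_ch;
      if (supra[u] && labels[u] < 0) { labels[u] = lab; stack.push_back(u); }
    }
    if (t < n_t - 1) {
      int u = v + n_ch;
      if (supra[u] && labels[u] < 0) { labels[u] = lab; stack.push_back(u); }
    }
    for (int nb : adj[ch]) {
      int u = nb + n_ch * t;
      if (supra[u] && labels[u] < 0) { labels[u] = lab; stack.push_back(u); }
    }
  }
}

static std::vector<std::vector<int>> adj_from_list(List adjacency, int n_ch) {
  std::vector<std::vector<int>> adj(n_ch);
  for (int i = 0; i < n_ch; ++i) {
    IntegerVector v = adjacency[i];
    adj[i].assign(v.begin(), v.end());
  }
  return adj;
}

// [[Rcpp::export]]
NumericMatrix tfce_cpp(NumericMatrix map, List adjacency, double E, double H,
                       double dh) {
  int n_ch = map.nrow(), n_t = map.ncol(), n = n_ch * n_t;
  if (dh <= 0) stop("dh must be > 0");
  NumericMatrix out(n_ch, n_t);
  std::vector<std::vector<int>> adj = adj_from_list(adjacency, n_ch);
  std::vector<char> supra(n);
  std::vector<int> labels(n), stack, members;

  for (int sign = 0; sign < 2; ++sign) {
    double mx = 0.0;
    std::vector<double> vals(n);
    for (int i = 0; i < n; ++i) {
      double v = map[i];
      vals[i] = sign == 0 ? v : -v;
      if (vals[i] > mx) mx = vals[i];
    }
    if (mx <= 0) continue;
    int n_steps = (int)std::floor(mx / dh + 1e-12);
    for (int k = 1; k <= n_steps; ++k) {
      double h = k * dh;
      for (int i = 0; i < n; ++i) supra[i] = vals[i] >= h - 1e-12 * dh;
      std::fill(labels.begin(), labels.end(), -1);
      double inc_base = std::pow(h, H) * dh;
      int lab = 0;
      for (int i = 0; i < n; ++i) {
        if (!supra[i] || labels[i] >= 0) continue;
        flood(i, supra, labels, lab++, n_ch, n_t, adj, stack, members);
        double inc = std::pow((double)members.size(), E) * inc_base;
        for (int v : members) out[v] += (sign == 0 ? inc : -inc);
      }
    }
  }
  return out;
}

// Label the connected components of a logical mask (same connectivity).
// Returns an integer matrix: 0 outside the mask, 1..K component labels.
// [[Rcpp::export]]
IntegerMatrix components_cpp(LogicalMatrix mask, List adjacency) {
  int n_ch = mask.nrow(), n_t = mask.ncol(), n = n_ch * n_t;
  std::vector<std::vector<int>> adj = adj_from_list(adjacency, n_ch);
  std::vector<char> supra(n);
  for (int i = 0; i < n; ++i) supra[i] = mask[i] != 0;
  std::vector<int> labels(n, -1), stack, members;
  int lab = 0;
  for (int i = 0; i < n; ++i) {
    if (!supra[i] || labels[i] >= 0) continue;
    flood(i, supra, labels, lab++, n_ch, n_t, adj, stack, members);
  }
  IntegerMatrix out(n_ch, n_t);
  for (int i = 0; i < n; ++i) out[i] = supra[i] ? labels[i] + 1 : 0;
  return out;
}
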