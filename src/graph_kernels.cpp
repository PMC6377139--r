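#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Edge lists arrive 1-based (R convention) and are converted here once.
static std::vector<std::vector<int>> build_adj(int n, const IntegerVector& ei,
                                               const IntegerVector& ej) {
    std::vector<std::vector<int>> adj(n);
    int m = ei.size();
    for (int e = 0; e < m; ++e) {
        int u = ei[e] - 1, v = ej[e] - 1;
        if (u < 0 || v < 0 || u >= n || v >= n)
            stop("edge endpoint out of range");
        if (u == v) stop("self-loop in edge list");
        adj[u].push_back(v);
        adj[v].push_back(u);
    }
    return adj;
}

// Local clustering coefficient: C_i = 2 t_i / (k_i (k_i - 1)), 0 when k_i < 2.
// [[Rcpp::export]]
NumericVector cpp_local_clustering(int n, IntegerVector ei, IntegerVector ej) {
    std::vector<std::vector<int>> adj = build_adj(n, ei, ej);
    // dense neighbour lookup; ROI graphs are small (n <= a few hundred)
    std::vector<std::vector<char>> dense(n, std::vector<char>(n, 0));
    for (int u = 0; u < n; ++u)
        for (int v : adj[u]) dense[u][v] = 1;
    NumericVector cc(n);
    for (int u = 0; u < n; ++u) {
        int k = (int)adj[u].size();
        if (k < 2) { cc[u] = 0.0; continue; }
        long t = 0;
        for (int a = 0; a < k; ++a)
            for (int b = a + 1; b < k; ++b)
                if (dense[adj[u][a]][adj[u][b]]) ++t;
        cc[u] = 2.0 * (double)t / ((double)k * (k - 1));
    }
    return cc;
}

// Characteristic path length by repeated BFS.
// policy 0: mean distance over reachable pairs only.
// policy 1: harmonic, 1 / global efficiency (unreachable pairs contribute 0).
// Returns NA when the graph has no edges (no finite pair distances).
// [[Rcpp::export]]
double cpp_path_length(int n, IntegerVector ei, IntegerVector ej, int policy) {
    if (ei.size() == 0) return NA_REAL;
    std::vector<std::vector<int>> adj = build_adj(n, ei, ej);
    double sum_d = 0.0, sum_inv = 0.0;
    long n_reach = 0;
    std::vector<int> dist(n), queue(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        int head = 0, tail = 0;
        queue[tail++] = s;
        while (head < tail) {
            int u = queue[head++];
            for (int v : adj[u]) {
                if (dist[v] < 0) {
                    dist[v] = dist[u] + 1;
                    queue[tail++] = v;
                }
            }
        }
        for (int v = 0; v < n; ++v) {
            if (v == s) continue;
            if (dist[v] > 0) {
                sum_d += dist[v];
                sum_inv += 1.0 / dist[v];
                ++n_reach;
            }
        }
    }
    if (policy == 0) {
        if (n_reach == 0) return NA_REAL;
        return sum_d / (double)n_reach;
    }
    double eff = sum_inv / ((double)n * (n - 1));  // all ordered pairs
    if (eff <= 0.0) return NA_REAL;
    return 1.0 / eff;
}

// Brandes betweenness centrality, unweighted, undirected, raw fractional
// counts over unordered pairs (accumulate over all sources, halve at the end).
// [[Rcpp::export]]
NumericVector cpp_betweenness(int n, IntegerVector ei, IntegerVector ej) {
    std::vector<std::vector<int>> adj = build_adj(n, ei, ej);
    NumericVector bc(n);
    std::vector<int> dist(n), stack_(n), queue(n);
    std::vector<double> sigma(n), delta(n);
    std::vector<std::vector<int>> pred(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        std::fill(sigma.begin(), sigma.end(), 0.0);
        std::fill(delta.begin(), delta.end(), 0.0);
        for (int v = 0; v < n; ++v) pred[v].clear();
        dist[s] = 0; sigma[s] = 1.0;
        int head = 0, tail = 0, top = 0;
        queue[tail++] = s;
        while (head < tail) {
            int u = queue[head++];
            stack_[top++] = u;
            for (int v : adj[u]) {
                if (dist[v] < 0) {
                    dist[v] = dist[u] + 1;
                    queue[tail++] = v;
                }
                if (dist[v] == dist[u] + 1) {
                    sigma[v] += sigma[u];
                    pred[v].push_back(u);
                }
            }
        }
        while (top > 0) {
            int w = stack_[--top];
            for (int u : pred[w])
                delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
            if (w != s) bc[w] += delta[w];
        }
    }
    for (int v = 0; v < n; ++v) bc[v] *= 0.5;
    return bc;
}

// Relative largest-connected-component trajectory under sequential node
// removal.  `order` is a permutation of 1..n (removal order).  Entry k
// (1-based) of the result is LCC(after removing the first k-1 nodes) / n:
// the curve starts at the intact graph and ends with a single surviving node.
// Computed backwards with union-find: nodes are re-activated in reverse
// removal order and components merged incrementally.
// [[Rcpp::export]]
NumericVector cpp_lcc_trajectory(int n, IntegerVector ei, IntegerVector ej,
                                 IntegerVector order) {
    if ((int)order.size() != n) stop("removal order must list every node");
    std::vector<std::vector<int>> adj = build_adj(n, ei, ej);
    std::vector<int> parent(n), csize(n, 0);
    std::vector<char> active(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
    NumericVector out(n);
    int best = 0;
    // find with path halving
    auto find = [&](int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
    };
    for (int k = n - 1; k >= 0; --k) {
        int v = order[k] - 1;
        if (v < 0 || v >= n || active[v]) stop("order is not a permutation");
        active[v] = 1;
        csize[v] = 1;
        if (best < 1) best = 1;
        for (int u : adj[v]) {
            if (!active[u]) continue;
            int rv = find(v), ru = find(u);
            if (rv != ru) {
                if (csize[rv] < csize[ru]) std::swap(rv, ru);
                parent[ru] = rv;
                csize[rv] += csize[ru];
                if (csize[rv] > best) best = csize[rv];
            }
        }
        out[k] = (double)best / (double)n;
    }
    return out;
}

// Degree-preserving rewiring by double edge swaps.  Draws `nswaps` candidate
// swaps; candidates creating self-loops or duplicate edges are rejected.
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_double_edge_swap(int n, IntegerVector ei, IntegerVector ej,
                                   int nswaps) {
    int m = ei.size();
    std::vector<int> a(m), b(m);
    std::unordered_set<int64_t> present;
    present.reserve((size_t)m * 2);
    auto key = [&](int u, int v) {
        if (u > v) std::swap(u, v);
        return (int64_t)u * (int64_t)n + (int64_t)v;
    };
    for (int e = 0; e < m; ++e) {
        a[e] = ei[e] - 1;
        b[e] = ej[e] - 1;
        present.insert(key(a[e], b[e]));
    }
    if (m >= 2) {
        for (int s = 0; s < nswaps; ++s) {
            int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
            int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
            if (e1 == e2) continue;
            int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
            if (unif_rand() < 0.5) std::swap(x, y);
            // proposed: (u,x) and (v,y)
            if (u == x || v == y) continue;
            if (present.count(key(u, x)) || present.count(key(v, y))) continue;
            present.erase(key(u, v));
            present.erase(key(x, y));
            present.insert(key(u, x));
            present.insert(key(v, y));
            a[e1] = u; b[e1] = x;
            a[e2] = v; b[e2] = y;
        }
    }
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
        out(e, 0) = std::min(a[e], b[e]) + 1;
        out(e, 1) = std::max(a[e], b[e]) + 1;
    }
    return out;
}
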