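#include <Rcpp.h>
using namespace Rcpp;

// Union-find over the subgraph induced by `member` vertices.
// edges: m x 2 integer matrix, 1-based vertex indices.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_member_components")]]
IntegerVector cpp_member_components(IntegerMatrix edges, LogicalVector member) {
  int n = member.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (member[a] && member[b]) {
      int ra = uf_find(parent, a), rb = uf_find(parent, b);
      if (ra != rb) parent[ra] = rb;
    }
  }
  // component id per member vertex (dense 1..k), 0 for non-members
  IntegerVector comp(n, 0);
  std::vector<int> relabel(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (!member[i]) continue;
    int r = uf_find(parent, i);
    if (relabel[r] == 0) relabel[r] = ++k;
    comp[i] = relabel[r];
  }
  comp.attr("n_components") = k;
  return comp;
}

// Number of like-type components of `target`-spin vertices for many
// permuted labelings at once; labels: n x p matrix of +1/-1.
// [[Rcpp::export(name = ".cpp_component_counts")]]
IntegerVector cpp_component_counts(IntegerMatrix edges, IntegerMatrix labels,
                                   int target) {
  int n = labels.nrow(), p = labels.ncol(), m = edges.nrow();
  IntegerVector out(p);
  std::vector<int> parent(n);
  for (int s = 0; s < p; ++s) {
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int e = 0; e < m; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      if (labels(a, s) == target && labels(b, s) == target) {
        int ra = uf_find(parent, a), rb = uf_find(parent, b);
        if (ra != rb) parent[ra] = rb;
      }
    }
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (labels(i, s) == target && uf_find(parent, i) == i) ++k;
    out[s] = k;
  }
  return out;
}

// Gibbs sampler for the autologistic model with spins in {-1,+1}:
// Pr(z_i = +1 | rest) = plogis(2*alpha + 2*beta*S_i), S_i = sum of
// neighboring spins. Adjacency in CSR form (1-based values). Uses R's RNG
// so reproducibility follows set.seed().
// [[Rcpp::export(name = ".cpp_gibbs_autologistic")]]
IntegerVector cpp_gibbs_autologistic(IntegerVector adj_ptr, IntegerVector adj_idx,
                                     IntegerVector z0, double alpha, double beta,
                                     int n_sweeps) {
  int n = z0.size();
  std::vector<int> z(z0.begin(), z0.end());
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  RNGScope scope;
  for (int s = 0; s < n_sweeps; ++s) {
    // random scan order (Fisher-Yates with R's RNG)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      int S = 0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k)
        S += z[adj_idx[k - 1] - 1];
      double eta = 2.0 * alpha + 2.0 * beta * (double)S;
      double p = 1.0 / (1.0 + std::exp(-eta));
      z[i] = (unif_rand() < p) ? 1 : -1;
    }
  }
  return IntegerVector(z.begin(), z.end());
}

// Newton-Raphson for 2-parameter logistic regression y ~ 1 + s,
// y in {0,1}. Returns c(intercept, slope, converged). Fast path for
// permutation envelopes; agrees with stats::glm by test.
// [[Rcpp::export(name = ".cpp_logit2_newton")]]
NumericVector cpp_logit2_newton(NumericVector s, IntegerVector y,
                                double tol, int max_iter, double bound) {
  int n = s.size();
  double b0 = 0.0, b1 = 0.0;
  bool ok = false;
  for (int it = 0; it < max_iter; ++it) {
    double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
    for (int i = 0; i < n; ++i) {
      double eta = b0 + b1 * s[i];
      double p = 1.0 / (1.0 + std::exp(-eta));
      double r = y[i] - p, w = p * (1.0 - p);
      g0 += r;          g1 += r * s[i];
      h00 += w;         h01 += w * s[i];  h11 += w * s[i] * s[i];
    }
    double det = h00 * h11 - h01 * h01;
    if (det <= 1e-12 * (h00 * h11 + 1e-300)) break;  // singular: separation
    double d0 = (h11 * g0 - h01 * g1) / det;
    double d1 = (h00 * g1 - h01 * g0) / det;
    b0 += d0; b1 += d1;
    if (std::fabs(b0) > bound || std::fabs(b1) > bound) break;
    if (std::sqrt(g0 * g0 + g1 * g1) < tol) { ok = true; break; }
  }
  if (b0 >  bound) b0 =  bound;
  if (b0 < -bound) b0 = -bound;
  if (b1 >  bound) b1 =  bound;
  if (b1 < -bound) b1 = -bound;
  return NumericVector::create(b0, b1, ok ? 1.0 : 0.0);
}

// Unlike-neighbor-pair counts for many labelings at once.
// [[Rcpp::export(name = ".cpp_unlike_counts")]]
IntegerVector cpp_unlike_counts(IntegerMatrix edges, IntegerMatrix labels) {
  int m = edges.nrow(), p = labels.ncol();
  IntegerVector out(p);
  for (int s = 0; s < p; ++s) {
    int u = 0;
    for (int e = 0; e < m; ++e)
      if (labels(edges(e, 0) - 1, s) != labels(edges(e, 1) - 1, s)) ++u;
    out[s] = u;
  }
  return out;
}
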