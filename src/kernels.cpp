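#include <Rcpp.h>
using namespace Rcpp;

// ---- union-find helpers -----------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &rank_, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) rank_[a]++;
}

// Partition occupied sites into dispersal clusters.
//
// For every unordered pair (i, j) of occupied sites an independent dispersal
// event X ~ Weibull(shape = 2, scale = psi) is compared against the pairwise
// least-cost distance; an edge exists iff X >= cost. The comparison is drawn
// as one uniform against the Weibull tail P(X >= c) = exp(-(c/psi)^2), which
// is the same event in distribution. Pairs whose success probability falls
// below p_min are treated as absent without consuming random numbers.
//
// cost: full least-cost matrix over suitable sites; idx: 0-based positions of
// the occupied sites within that matrix. Returns 1-based cluster membership.
// [[Rcpp::export]]
IntegerVector cluster_partition_cpp(NumericMatrix cost, IntegerVector idx,
                                    double psi, double p_min) {
  const int m = idx.size();
  IntegerVector member(m);
  std::vector<int> parent(m), rank_(m, 0);
  for (int i = 0; i < m; ++i) parent[i] = i;

  const double inv_psi2 = 1.0 / (psi * psi);
  const double cost_max = psi * std::sqrt(-std::log(p_min));
  for (int j = 1; j < m; ++j) {        // column-major order over i < j
    const int cj = idx[j];
    for (int i = 0; i < j; ++i) {
      // an edge inside an existing component never changes the partition,
      // so its draw can be skipped without affecting the distribution
      if (uf_find(parent, i) == uf_find(parent, j)) continue;
      const double c = cost(idx[i], cj);
      if (!R_finite(c) || c > cost_max) continue;  // success prob below p_min
      double p = std::exp(-c * c * inv_psi2);
      if (unif_rand() <= p) uf_union(parent, rank_, i, j);
    }
  }

  std::map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < m; ++i) {
    int root = uf_find(parent, i);
    auto it = relabel.find(root);
    if (it == relabel.end()) {
      relabel[root] = ++next;
      member[i] = next;
    } else {
      member[i] = it->second;
    }
  }
  return member;
}

// For each target site, the minimal least-cost distance from any occupied
// site, together with the (0-based) position of the occupied site achieving
// it. Ties are broken in favour of the occupied site with the largest
// abundance. Returns list(cost =, source =) with source 1-based into occ_idx.
// [[Rcpp::export]]
List colonization_minima_cpp(NumericMatrix cost, IntegerVector occ_idx,
                             IntegerVector targ_idx, NumericVector occ_n) {
  const int no = occ_idx.size(), nt = targ_idx.size();
  NumericVector cmin(nt);
  IntegerVector src(nt);
  for (int t = 0; t < nt; ++t) {
    const int ct = targ_idx[t];
    double best = R_PosInf, best_n = -1.0;
    int best_i = -1;
    for (int i = 0; i < no; ++i) {
      const double c = cost(occ_idx[i], ct);
      if (c < best - 1e-12 || (std::abs(c - best) <= 1e-12 && occ_n[i] > best_n)) {
        best = c;
        best_i = i;
        best_n = occ_n[i];
      }
    }
    cmin[t] = best;
    src[t] = best_i + 1;
  }
  return List::create(_["cost"] = cmin, _["source"] = src);
}

// Closed-form Lotka-Volterra diffuse-competition equilibrium with sequential
// competitive exclusion: candidate abundances are solved jointly; while any
// candidate is negative, the single most negative one is excluded (set to 0)
// and the remaining community re-solved. Requires alpha_ff > alpha_fh.
// [[Rcpp::export]]
NumericVector lv_equilibrium_cpp(NumericVector r, NumericVector alpha_fh,
                                 double alpha_ff) {
  const int k = r.size();
  NumericVector n(k, 0.0);
  if (k == 0) return n;
  std::vector<bool> active(k, true);
  std::vector<double> inv_d(k);
  for (int i = 0; i < k; ++i) inv_d[i] = 1.0 / (alpha_ff - alpha_fh[i]);

  for (;;) {
    double num = 0.0, den = 1.0;
    for (int i = 0; i < k; ++i) {
      if (!active[i]) continue;
      num += r[i] * inv_d[i];
      den += alpha_fh[i] * inv_d[i];
    }
    const double ntot = num / den;
    int worst = -1;
    for (int i = 0; i < k; ++i) {
      if (!active[i]) { n[i] = 0.0; continue; }
      n[i] = (r[i] - alpha_fh[i] * ntot) * inv_d[i];
      if (n[i] >= 0.0) continue;
      // most negative candidate; ties resolved on trait values, not position,
      // so the result is invariant under reordering of the community
      if (worst < 0 || n[i] < n[worst] ||
          (n[i] == n[worst] && (alpha_fh[i] > alpha_fh[worst] ||
                                (alpha_fh[i] == alpha_fh[worst] && r[i] < r[worst])))) {
        worst = i;
      }
    }
    if (worst < 0) break;
    active[worst] = false;
  }
  for (int i = 0; i < k; ++i) if (n[i] < 0.0) n[i] = 0.0;
  return n;
}

// Batched equilibrium: populations sorted by site; `first` holds the 0-based
// start of each site segment, with an extra terminal entry = total length.
// [[Rcpp::export]]
NumericVector lv_equilibrium_groups_cpp(NumericVector r, NumericVector alpha_fh,
                                        IntegerVector first, double alpha_ff) {
  const int nseg = first.size() - 1;
  NumericVector out(r.size());
  for (int s = 0; s < nseg; ++s) {
    const int a = first[s], b = first[s + 1];
    NumericVector rs(r.begin() + a, r.begin() + b);
    NumericVector as(alpha_fh.begin() + a, alpha_fh.begin() + b);
    NumericVector ns = lv_equilibrium_cpp(rs, as, alpha_ff);
    for (int i = a; i < b; ++i) out[i] = ns[i - a];
  }
  return out;
}
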