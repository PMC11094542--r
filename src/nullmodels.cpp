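#include <Rcpp.h>
using namespace Rcpp;

// Mean nearest-taxon distance between two communities on a shared taxon index.
// fa, fb index the rows/cols of d; perm (optional) relabels taxa on d, which is
// how the taxa-shuffle null is applied without copying the distance matrix.
static double bmntd_core(const std::vector<int>& ia, const std::vector<double>& wa,
                         const std::vector<int>& ib, const std::vector<double>& wb,
                         const NumericMatrix& d, const int* perm, bool weighted) {
  const int na = ia.size(), nb = ib.size();
  double sa = 0.0, sb = 0.0;
  for (int u = 0; u < na; ++u) {
    const int i = perm ? perm[ia[u]] : ia[u];
    double mn = R_PosInf;
    for (int v = 0; v < nb; ++v) {
      const int j = perm ? perm[ib[v]] : ib[v];
      const double dv = d(i, j);
      if (dv < mn) mn = dv;
    }
    sa += weighted ? wa[u] * mn : mn;
  }
  for (int v = 0; v < nb; ++v) {
    const int j = perm ? perm[ib[v]] : ib[v];
    double mn = R_PosInf;
    for (int u = 0; u < na; ++u) {
      const int i = perm ? perm[ia[u]] : ia[u];
      const double dv = d(i, j);
      if (dv < mn) mn = dv;
    }
    sb += weighted ? wb[v] * mn : mn;
  }
  if (weighted) return 0.5 * (sa + sb);
  // incidence mode pools taxa from both communities (picante convention)
  return (sa + sb) / double(na + nb);
}

static void presence(const NumericVector& f, std::vector<int>& idx,
                     std::vector<double>& w, bool weighted) {
  double tot = 0.0;
  for (int i = 0; i < f.size(); ++i)
    if (f[i] > 0) { idx.push_back(i); tot += f[i]; }
  if (weighted)
    for (size_t u = 0; u < idx.size(); ++u) w.push_back(f[idx[u]] / tot);
}

// [[Rcpp::export]]
double cpp_bmntd(NumericVector fa, NumericVector fb, NumericMatrix d,
                 bool weighted = true) {
  std::vector<int> ia, ib; std::vector<double> wa, wb;
  presence(fa, ia, wa, weighted);
  presence(fb, ib, wb, weighted);
  if (ia.empty() || ib.empty()) stop("empty community");
  return bmntd_core(ia, wa, ib, wb, d, nullptr, weighted);
}

// Null betaMNTD values under taxa-label shuffles of the distance matrix.
// perms: k x n_null matrix of 0-based permutations of 0..k-1.
// [[Rcpp::export]]
NumericVector cpp_bmntd_nulls(NumericVector fa, NumericVector fb, NumericMatrix d,
                              IntegerMatrix perms, bool weighted = true) {
  std::vector<int> ia, ib; std::vector<double> wa, wb;
  presence(fa, ia, wa, weighted);
  presence(fb, ib, wb, weighted);
  if (ia.empty() || ib.empty()) stop("empty community");
  const int n_null = perms.ncol();
  NumericVector out(n_null);
  for (int r = 0; r < n_null; ++r) {
    const int* perm = &perms(0, r);
    out[r] = bmntd_core(ia, wa, ib, wb, d, perm, weighted);
  }
  return out;
}

// Weighted sampling without replacement (sequential, matching the semantics of
// R's sample(..., prob=)); returns 0-based indices. Uses R's RNG.
static void sample_wor(int k, int size, const double* w, std::vector<int>& out) {
  std::vector<double> wk(w, w + k);
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  double tot = 0.0;
  for (int i = 0; i < k; ++i) tot += wk[i];
  out.clear();
  int m = k;
  for (int s = 0; s < size; ++s) {
    double u = unif_rand() * tot, acc = 0.0;
    int pick = m - 1;
    for (int i = 0; i < m; ++i) {
      acc += wk[i];
      if (u <= acc) { pick = i; break; }
    }
    out.push_back(idx[pick]);
    tot -= wk[pick];
    wk[pick] = wk[m - 1]; idx[pick] = idx[m - 1];
    --m;
  }
}

// Raup-Crick null Bray-Curtis draws for one sample pair.
// occ: per-taxon occupancy weights over the pool; meta: metacommunity relative
// abundances; (na, sa) and (nb, sb) are each sample's total reads and richness.
// Each null community gets sa (sb) taxa by occupancy, one individual each, and
// the remaining reads multinomially by metacommunity abundance.
// [[Rcpp::export]]
NumericVector cpp_rc_nulls(int na, int sa, int nb, int sb,
                           NumericVector occ, NumericVector meta, int n_null) {
  const int k = occ.size();
  if (k != meta.size()) stop("occ/meta length mismatch");
  RNGScope scope;
  NumericVector out(n_null);
  std::vector<int> ta, tb;
  std::vector<double> ca(k), cb(k), prob;
  std::vector<int> draw;
  for (int r = 0; r < n_null; ++r) {
    std::fill(ca.begin(), ca.end(), 0.0);
    std::fill(cb.begin(), cb.end(), 0.0);
    sample_wor(k, sa, occ.begin(), ta);
    sample_wor(k, sb, occ.begin(), tb);
    // one individual per drawn taxon, remainder by metacommunity weights
    for (int i : ta) ca[i] = 1.0;
    for (int i : tb) cb[i] = 1.0;
    if (na > sa) {
      prob.assign(sa, 0.0);
      double tot = 0.0;
      for (int u = 0; u < sa; ++u) { prob[u] = meta[ta[u]]; tot += prob[u]; }
      for (int u = 0; u < sa; ++u) prob[u] = (tot > 0) ? prob[u] / tot : 1.0 / sa;
      draw.assign(sa, 0);
      ::rmultinom(na - sa, prob.data(), sa, draw.data());
      for (int u = 0; u < sa; ++u) ca[ta[u]] += draw[u];
    }
    if (nb > sb) {
      prob.assign(sb, 0.0);
      double tot = 0.0;
      for (int u = 0; u < sb; ++u) { prob[u] = meta[tb[u]]; tot += prob[u]; }
      for (int u = 0; u < sb; ++u) prob[u] = (tot > 0) ? prob[u] / tot : 1.0 / sb;
      draw.assign(sb, 0);
      ::rmultinom(nb - sb, prob.data(), sb, draw.data());
      for (int u = 0; u < sb; ++u) cb[tb[u]] += draw[u];
    }
    double smin = 0.0;
    for (int i = 0; i < k; ++i) smin += std::min(ca[i], cb[i]);
    out[r] = 1.0 - 2.0 * smin / (double(na) + double(nb));
  }
  return out;
}
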