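// Compiled cores for the phylogenetic and taxonomic turnover null models.
// All randomness goes through R's RNG (RNGScope) so results are fully
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// betaMNTD for a set of sample pairs under a taxon->tip relabeling `perm`
// (0-based; identity gives the observed value).
//   bmntd(k,m) = 0.5 * [ sum_{i in k} f_ik min_{j in m} d(i,j)
//              + sum_{j in m} f_jm min_{i in k} d(i,j) ]
// comm_idx[s]: 0-based taxon indices present in sample s
// comm_w[s]:   matching relative-abundance weights (sum to 1)
static void bmntd_pairs(const NumericMatrix& D,
                        const std::vector<std::vector<int> >& idx,
                        const std::vector<std::vector<double> >& w,
                        const IntegerMatrix& pairs,
                        const std::vector<int>& perm,
                        double* out) {
  const int n_pairs = pairs.nrow();
  for (int p = 0; p < n_pairs; ++p) {
    const std::vector<int>& ik = idx[pairs(p, 0)];
    const std::vector<int>& im = idx[pairs(p, 1)];
    const std::vector<double>& wk = w[pairs(p, 0)];
    const std::vector<double>& wm = w[pairs(p, 1)];
    double s1 = 0.0;
    for (size_t a = 0; a < ik.size(); ++a) {
      const int ti = perm[ik[a]];
      double mn = R_PosInf;
      for (size_t b = 0; b < im.size(); ++b) {
        const double d = D(ti, perm[im[b]]);
        if (d < mn) mn = d;
      }
      s1 += wk[a] * mn;
    }
    double s2 = 0.0;
    for (size_t b = 0; b < im.size(); ++b) {
      const int tj = perm[im[b]];
      double mn = R_PosInf;
      for (size_t a = 0; a < ik.size(); ++a) {
        const double d = D(perm[ik[a]], tj);
        if (d < mn) mn = d;
      }
      s2 += wm[b] * mn;
    }
    out[p] = 0.5 * (s1 + s2);
  }
}

static void unpack_comms(const List& comm_idx, const List& comm_w,
                         std::vector<std::vector<int> >& idx,
                         std::vector<std::vector<double> >& w) {
  const int n = comm_idx.size();
  idx.resize(n);
  w.resize(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector iv = comm_idx[s];
    NumericVector wv = comm_w[s];
    idx[s].assign(iv.begin(), iv.end());
    w[s].assign(wv.begin(), wv.end());
  }
}

// [[Rcpp::export]]
NumericVector cpp_beta_mntd(NumericMatrix D, List comm_idx, List comm_w,
                            IntegerMatrix pairs) {
  std::vector<std::vector<int> > idx;
  std::vector<std::vector<double> > w;
  unpack_comms(comm_idx, comm_w, idx, w);
  std::vector<int> ident(D.nrow());
  for (int i = 0; i < D.nrow(); ++i) ident[i] = i;
  NumericVector out(pairs.nrow());
  bmntd_pairs(D, idx, w, pairs, ident, REAL(out));
  return out;
}

// Null model: shuffle the taxon <-> tip mapping across the whole tree per
// replicate (one shared permutation per replicate across all pairs), and
// standardize: bNTI = (obs - mean_null) / sd_null.
// [[Rcpp::export]]
List cpp_beta_nti(NumericMatrix D, List comm_idx, List comm_w,
                  IntegerMatrix pairs, int n_null) {
  RNGScope scope;
  std::vector<std::vector<int> > idx;
  std::vector<std::vector<double> > w;
  unpack_comms(comm_idx, comm_w, idx, w);
  const int n_taxa = D.nrow();
  const int n_pairs = pairs.nrow();

  std::vector<int> ident(n_taxa);
  for (int i = 0; i < n_taxa; ++i) ident[i] = i;
  NumericVector obs(n_pairs);
  bmntd_pairs(D, idx, w, pairs, ident, REAL(obs));

  std::vector<double> sum(n_pairs, 0.0), sumsq(n_pairs, 0.0);
  std::vector<double> buf(n_pairs);
  std::vector<int> perm(n_taxa);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n_taxa; ++i) perm[i] = i;
    // Fisher-Yates with R's RNG
    for (int i = n_taxa - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    bmntd_pairs(D, idx, w, pairs, perm, buf.data());
    for (int p = 0; p < n_pairs; ++p) {
      sum[p] += buf[p];
      sumsq[p] += buf[p] * buf[p];
    }
  }
  NumericVector null_mean(n_pairs), null_sd(n_pairs), bnti(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    const double m = sum[p] / n_null;
    double v = (sumsq[p] - n_null * m * m) / (n_null - 1);
    if (v < 0) v = 0;
    const double s = std::sqrt(v);
    null_mean[p] = m;
    null_sd[p] = s;
    if (s > 0) {
      bnti[p] = (obs[p] - m) / s;
    } else {
      // degenerate null (e.g. star phylogeny): no deviation possible
      bnti[p] = (std::abs(obs[p] - m) < 1e-12) ? 0.0 : NA_REAL;
    }
  }
  return List::create(_["obs"] = obs, _["null_mean"] = null_mean,
                      _["null_sd"] = null_sd, _["bnti"] = bnti);
}

// Bray-Curtis between two sparse communities with sorted index vectors.
static double bc_sparse(const std::vector<int>& ia, const std::vector<int>& ca,
                        const std::vector<int>& ib, const std::vector<int>& cb) {
  double shared = 0.0, tot_a = 0.0, tot_b = 0.0;
  size_t a = 0, b = 0;
  for (size_t i = 0; i < ca.size(); ++i) tot_a += ca[i];
  for (size_t i = 0; i < cb.size(); ++i) tot_b += cb[i];
  while (a < ia.size() && b < ib.size()) {
    if (ia[a] == ib[b]) {
      shared += std::min(ca[a], cb[b]);
      ++a; ++b;
    } else if (ia[a] < ib[b]) {
      ++a;
    } else {
      ++b;
    }
  }
  return 1.0 - 2.0 * shared / (tot_a + tot_b);
}

// Reassemble one community under the Raup-Crick null: draw `richness`
// species weighted by metacommunity occupancy (without replacement,
// exponential-key method), seed each with one read, distribute the
// remaining reads multinomially with metacommunity relative-abundance
// weights restricted to the drawn species.
static void reassemble(int richness, int total_reads,
                       const std::vector<double>& occ_w,
                       const std::vector<double>& abund_w,
                       std::vector<int>& out_idx, std::vector<int>& out_cnt,
                       std::vector<std::pair<double, int> >& keys,
                       std::vector<double>& probs, std::vector<int>& draws) {
  const int n_sp = (int)occ_w.size();
  keys.clear();
  for (int i = 0; i < n_sp; ++i) {
    if (occ_w[i] > 0) {
      keys.push_back(std::make_pair(exp_rand() / occ_w[i], i));
    }
  }
  if (richness > (int)keys.size()) richness = (int)keys.size();
  std::nth_element(keys.begin(), keys.begin() + richness - 1, keys.end());
  out_idx.resize(richness);
  for (int i = 0; i < richness; ++i) out_idx[i] = keys[i].second;
  std::sort(out_idx.begin(), out_idx.end());

  out_cnt.assign(richness, 1);
  const int rest = total_reads - richness;
  if (rest > 0) {
    probs.resize(richness);
    double tot = 0.0;
    for (int i = 0; i < richness; ++i) {
      probs[i] = abund_w[out_idx[i]];
      tot += probs[i];
    }
    if (tot <= 0) {
      for (int i = 0; i < richness; ++i) probs[i] = 1.0;
      tot = richness;
    }
    for (int i = 0; i < richness; ++i) probs[i] /= tot;
    draws.resize(richness);
    ::rmultinom(rest, probs.data(), richness, draws.data());
    for (int i = 0; i < richness; ++i) out_cnt[i] += draws[i];
  }
}

// counts: samples x species (non-negative). pairs: 0-based sample index
// pairs. Returns rescaled RC in [-1, 1]:
//   RC = 2 * ( (#null < obs) + 0.5 * #ties ) / n_null - 1
// Null sample reassemblies are shared across pairs within a replicate.
// [[Rcpp::export]]
NumericVector cpp_rc_bray(NumericMatrix counts, IntegerMatrix pairs,
                          int n_null) {
  RNGScope scope;
  const int n_samp = counts.nrow();
  const int n_sp = counts.ncol();
  const int n_pairs = pairs.nrow();

  // metacommunity weights
  std::vector<double> occ_w(n_sp, 0.0), abund_w(n_sp, 0.0);
  for (int j = 0; j < n_sp; ++j) {
    double occ = 0.0, ab = 0.0;
    for (int i = 0; i < n_samp; ++i) {
      if (counts(i, j) > 0) occ += 1.0;
      ab += counts(i, j);
    }
    occ_w[j] = occ;
    abund_w[j] = ab;
  }

  // which samples participate in pairs
  std::vector<bool> used(n_samp, false);
  for (int p = 0; p < n_pairs; ++p) {
    used[pairs(p, 0)] = true;
    used[pairs(p, 1)] = true;
  }

  // observed sparse communities, richness, totals
  std::vector<std::vector<int> > obs_idx(n_samp), obs_cnt(n_samp);
  std::vector<int> richness(n_samp, 0), totals(n_samp, 0);
  for (int i = 0; i < n_samp; ++i) {
    if (!used[i]) continue;
    for (int j = 0; j < n_sp; ++j) {
      const int c = (int)counts(i, j);
      if (c > 0) {
        obs_idx[i].push_back(j);
        obs_cnt[i].push_back(c);
        richness[i] += 1;
        totals[i] += c;
      }
    }
    if (totals[i] == 0) stop("pair includes an empty sample (row %d)", i + 1);
  }

  NumericVector obs_bc(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    const int a = pairs(p, 0), b = pairs(p, 1);
    obs_bc[p] = bc_sparse(obs_idx[a], obs_cnt[a], obs_idx[b], obs_cnt[b]);
  }

  std::vector<double> n_less(n_pairs, 0.0), n_ties(n_pairs, 0.0);
  std::vector<std::vector<int> > null_idx(n_samp), null_cnt(n_samp);
  std::vector<std::pair<double, int> > keys;
  std::vector<double> probs;
  std::vector<int> draws;

  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n_samp; ++i) {
      if (!used[i]) continue;
      reassemble(richness[i], totals[i], occ_w, abund_w,
                 null_idx[i], null_cnt[i], keys, probs, draws);
    }
    for (int p = 0; p < n_pairs; ++p) {
      const int a = pairs(p, 0), b = pairs(p, 1);
      const double bc = bc_sparse(null_idx[a], null_cnt[a],
                                  null_idx[b], null_cnt[b]);
      if (bc < obs_bc[p] - 1e-12) {
        n_less[p] += 1.0;
      } else if (bc <= obs_bc[p] + 1e-12) {
        n_ties[p] += 1.0;
      }
    }
  }

  NumericVector rc(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    rc[p] = 2.0 * ((n_less[p] + 0.5 * n_ties[p]) / n_null) - 1.0;
  }
  return rc;
}
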