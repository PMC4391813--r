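#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured (discrete-deme) Kingman coalescent.
//
// Time is measured in mutational units (1/mu generations), so with
// theta = 4*Ne*mu (diploid nuclear) or 2*Nf*mu (haploid maternal) the
// pairwise coalescence rate inside a deme is 2/theta, the per-lineage
// mutation rate is 1, and the backward migration rate of a lineage in
// deme d toward source deme s is M[s,d] = m/mu (immigration into d).
//
// M is oriented row -> column = forward direction of gene flow.

struct Genealogy {
  std::vector<int> parent;     // 2n-1 entries, root = -1
  std::vector<double> blen;    // branch length to parent, mutational units
  std::vector<int> tip_deme;   // 0-based deme of each tip
  bool capped;                 // TRUE if the height cap was hit
};

static Genealogy sim_genealogy(const IntegerVector &n_per_deme,
                               const NumericVector &theta,
                               const NumericMatrix &M,
                               double max_height) {
  const int nd = n_per_deme.size();
  int n = 0;
  for (int i = 0; i < nd; ++i) n += n_per_deme[i];
  Genealogy g;
  g.parent.assign(2 * n - 1, -1);
  g.blen.assign(2 * n - 1, 0.0);
  g.tip_deme.assign(n, 0);
  g.capped = false;

  // active lineages kept in per-deme pools (O(1) pick and move)
  std::vector< std::vector<int> > pool(nd);
  std::vector<double> node_time(2 * n - 1, 0.0);
  {
    int id = 0;
    for (int d = 0; d < nd; ++d)
      for (int j = 0; j < n_per_deme[d]; ++j) {
        g.tip_deme[id] = d;
        pool[d].push_back(id);
        ++id;
      }
  }
  std::vector<double> th(theta.begin(), theta.end());
  // backward emigration rate per lineage in deme d: sum_s M(s, d)
  std::vector<double> mig_out(nd, 0.0);
  for (int d = 0; d < nd; ++d)
    for (int s = 0; s < nd; ++s)
      if (s != d) mig_out[d] += M(s, d);

  double t = 0.0;
  int next_node = n;
  int alive = n;
  // after this many migration events the demes are thoroughly mixed and
  // the process is indistinguishable from panmixia; stop paying for
  // individual migration events (high-M draws from a [0,100] prior)
  long mig_events = 0;
  const long MIG_CAP = 20000;

  while (alive > 1) {
    double coal_tot = 0.0, mig_tot = 0.0;
    std::vector<double> coal_rate(nd);
    for (int d = 0; d < nd; ++d) {
      double kd = (double)pool[d].size();
      coal_rate[d] = th[d] > 0 ? kd * (kd - 1) / th[d] : 0.0;
      coal_tot += coal_rate[d];
      mig_tot += kd * mig_out[d];
    }
    double total = coal_tot + mig_tot;
    bool force = false;
    if (total <= 0.0) {
      force = true;
    } else {
      double dt = R::exp_rand() / total;
      if (t + dt > max_height) force = true; else t += dt;
    }
    if (force) {
      // height cap: join every remaining lineage at max_height
      g.capped = true;
      t = max_height;
      std::vector<int> rest;
      for (int d = 0; d < nd; ++d)
        rest.insert(rest.end(), pool[d].begin(), pool[d].end());
      while (rest.size() > 1) {
        int i = (int)(R::unif_rand() * rest.size());
        int j = (int)(R::unif_rand() * (rest.size() - 1));
        if (j >= i) ++j;
        int u = rest[i], v = rest[j];
        int w = next_node++;
        g.parent[u] = w; g.blen[u] = t - node_time[u];
        g.parent[v] = w; g.blen[v] = t - node_time[v];
        node_time[w] = t;
        if (i > j) std::swap(i, j);
        rest[i] = w;
        rest[j] = rest.back(); rest.pop_back();
      }
      break;
    }
    double u = R::unif_rand() * total;
    if (u >= coal_tot) {
      // migration: deme weighted by k[d]*mig_out[d], lineage uniform,
      // source deme by M(s, d)
      double r = u - coal_tot;
      int d = 0;
      for (; d < nd; ++d) {
        double w = (double)pool[d].size() * mig_out[d];
        if (r < w) break; r -= w;
      }
      if (d == nd) d = nd - 1;
      int idx = (int)(R::unif_rand() * pool[d].size());
      double r2 = R::unif_rand() * mig_out[d];
      int s = 0;
      for (; s < nd; ++s) { if (s == d) continue; if (r2 < M(s, d)) break; r2 -= M(s, d); }
      if (s == nd || s == d) { s = (d + 1) % nd; }
      int node = pool[d][idx];
      pool[d][idx] = pool[d].back(); pool[d].pop_back();
      pool[s].push_back(node);
      if (++mig_events >= MIG_CAP) {
        // strong-migration limit: pool every lineage into deme 0 with the
        // harmonic-mean effective size, and stop migrating
        double inv = 0.0;
        for (int dd = 0; dd < nd; ++dd) inv += 1.0 / th[dd];
        th[0] = (double)nd * nd / inv;
        for (int dd = 1; dd < nd; ++dd) {
          pool[0].insert(pool[0].end(), pool[dd].begin(), pool[dd].end());
          pool[dd].clear();
        }
        for (int dd = 0; dd < nd; ++dd) mig_out[dd] = 0.0;
      }
    } else {
      // coalescence of a uniform pair within deme d
      int d;
      double r = u;
      for (d = 0; d < nd; ++d) { if (r < coal_rate[d]) break; r -= coal_rate[d]; }
      if (d == nd) d = nd - 1;
      int kd = (int)pool[d].size();
      int p1 = (int)(R::unif_rand() * kd);
      int p2 = (int)(R::unif_rand() * (kd - 1));
      if (p2 >= p1) ++p2;
      int uu = pool[d][p1], vv = pool[d][p2];
      int w = next_node++;
      g.parent[uu] = w; g.blen[uu] = t - node_time[uu];
      g.parent[vv] = w; g.blen[vv] = t - node_time[vv];
      node_time[w] = t;
      if (p1 > p2) std::swap(p1, p2);
      pool[d][p1] = w;
      pool[d][p2] = pool[d].back(); pool[d].pop_back();
      --alive;
    }
  }
  return g;
}

//' @noRd
// [[Rcpp::export]]
List cpp_genealogy(IntegerVector n_per_deme, NumericVector theta,
                   NumericMatrix M, double max_height) {
  Genealogy g = sim_genealogy(n_per_deme, theta, M, max_height);
  return List::create(_["parent"]   = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["blen"]     = NumericVector(g.blen.begin(), g.blen.end()),
                      _["tip_deme"] = IntegerVector(g.tip_deme.begin(), g.tip_deme.end()),
                      _["capped"]   = g.capped);
}

// net repeat-count change over nmut mutations under SMM (model 0) or
// TPM (model 1: prob p_single of a +/-1 step, otherwise a geometric
// multi-step jump with mean magnitude geom_mean >= 1)
static int mutate_steps(int nmut, int model, double p_single, double geom_mean) {
  if (nmut == 0) return 0;
  int nsingle = nmut, net = 0;
  if (model == 1) {
    nsingle = (int)R::rbinom((double)nmut, p_single);
    int nmulti = nmut - nsingle;
    double p = 1.0 / std::max(1.0, geom_mean);  // magnitude = 1 + Geom(p), mean 1/p
    for (int i = 0; i < nmulti; ++i) {
      int mag = 1 + (int)R::rgeom(p);
      net += (R::unif_rand() < 0.5) ? mag : -mag;
    }
  }
  // singles: net contribution 2*Binom(nsingle, 1/2) - nsingle
  int up = (int)R::rbinom((double)nsingle, 0.5);
  net += 2 * up - nsingle;
  return net;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_microsat_sim(IntegerVector n_per_deme, NumericVector theta,
                               NumericMatrix M, int n_loci,
                               int model, double p_single, double geom_mean,
                               double max_height) {
  int n = 0;
  for (int i = 0; i < n_per_deme.size(); ++i) n += n_per_deme[i];
  IntegerMatrix out(n, n_loci);
  std::vector<int> state(2 * n - 1);
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = sim_genealogy(n_per_deme, theta, M, max_height);
    int nn = 2 * n - 1;
    state[nn - 1] = 0;  // root (highest index: internal nodes created in time order)
    for (int v = nn - 2; v >= 0; --v) {
      int nmut = (int)R::rpois(g.blen[v]);
      state[v] = state[g.parent[v]] + mutate_steps(nmut, model, p_single, geom_mean);
    }
    for (int i = 0; i < n; ++i) out(i, l) = state[i];
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_drift_freqs(NumericMatrix freqs, int two_ne, int t) {
  // multinomial Wright-Fisher resampling of allele frequencies,
  // one column per locus, for t generations
  int K = freqs.nrow(), L = freqs.ncol();
  NumericMatrix out(clone(freqs));
  std::vector<double> p(K);
  std::vector<int> cnt(K);
  for (int g = 0; g < t; ++g) {
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int a = 0; a < K; ++a) { p[a] = out(a, l); s += p[a]; }
      if (s <= 0) continue;
      for (int a = 0; a < K; ++a) p[a] /= s;
      rmultinom(two_ne, p.data(), K, cnt.data());
      for (int a = 0; a < K; ++a) out(a, l) = (double)cnt[a] / two_ne;
    }
  }
  return out;
}
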