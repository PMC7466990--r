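#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulation of mean branch lengths per sample
// configuration for two demes with epoch-switching migration.
//
// Time runs backward from the present in (continuous) generations.
//   epoch 0: [0, t2)    migration rates m2_* (the recent epoch)
//   epoch 1: [t2, t1)   migration rates m1_*
//   epoch 2: [t1, inf)  single ancestral deme of diploid size anc_n
//
// Migration convention (matches the forward-time rate definition where
// M_XY is the fraction of deme Y replaced by migrants from X each
// generation): a lineage currently in Y jumps backward to X at rate M_XY.
// Deme 0 = wild, deme 1 = domestic, so a wild lineage moves at rate m_dw
// and a domestic lineage at rate m_wd.
//
// Coalescence within a deme of diploid size N occurs at rate
// k(k-1)/2 * 1/(2N) for k resident lineages.
//
// Each lineage carries the number of sampled chromosomes it subtends in
// (wild, domestic). When a lineage is removed by coalescence, its lifetime
// is added to L[i][j]; a mutation on that stretch of branch would appear in
// exactly i wild and j domestic sampled copies. The returned matrix is the
// per-replicate mean of L over n_reps independent genealogies, in
// generations; multiplying by the per-site mutation rate gives the expected
// unfolded joint SFS per site (infinite-sites, small-mu approximation).
//
// Uses R's RNG so results are reproducible via set.seed() on the R side.

namespace {

struct Lineage {
  int i;       // wild sample descendants
  int j;       // domestic sample descendants
  double birth;
};

inline int pick(int k) {
  // uniform integer in [0, k)
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

} // namespace

// [[Rcpp::export(name = ".coal_branch_config")]]
NumericMatrix coal_branch_config(int n_wild, int n_dom,
                                 double anc_n, double t1, double t2,
                                 double size_wild, double size_dom,
                                 double m1_wd, double m1_dw,
                                 double m2_wd, double m2_dw,
                                 int n_reps) {
  if (n_wild < 1 || n_dom < 1) stop("need at least one sampled chromosome per deme");
  if (n_reps < 1) stop("n_reps must be >= 1");
  if (anc_n <= 0 || size_wild <= 0 || size_dom <= 0) stop("population sizes must be positive");
  if (t1 < 0 || t2 < 0 || t2 > t1) stop("need 0 <= t2 <= t1");

  const int n_tot = n_wild + n_dom;
  NumericMatrix acc(n_wild + 1, n_dom + 1);

  std::vector<Lineage> lin;
  lin.reserve(2 * n_tot);
  std::vector<int> deme_idx[2]; // lineage ids resident in each deme
  deme_idx[0].reserve(2 * n_tot);
  deme_idx[1].reserve(2 * n_tot);

  for (int rep = 0; rep < n_reps; ++rep) {
    lin.clear();
    deme_idx[0].clear();
    deme_idx[1].clear();

    if (t1 > 0.0) {
      for (int s = 0; s < n_wild; ++s) {
        deme_idx[0].push_back((int)lin.size());
        lin.push_back({1, 0, 0.0});
      }
      for (int s = 0; s < n_dom; ++s) {
        deme_idx[1].push_back((int)lin.size());
        lin.push_back({0, 1, 0.0});
      }
    } else {
      // degenerate split time: panmictic ancestral deme from the start
      for (int s = 0; s < n_wild; ++s) {
        deme_idx[0].push_back((int)lin.size());
        lin.push_back({1, 0, 0.0});
      }
      for (int s = 0; s < n_dom; ++s) {
        deme_idx[0].push_back((int)lin.size());
        lin.push_back({0, 1, 0.0});
      }
    }

    double t = 0.0;
    int k_alive = n_tot;

    while (k_alive > 1) {
      const int kw = (int)deme_idx[0].size();
      const int kd = (int)deme_idx[1].size();
      int epoch;
      if (t >= t1) epoch = 2;
      else if (t >= t2) epoch = 1;
      else epoch = 0;

      double r_cw = 0, r_cd = 0, r_mw = 0, r_md = 0, boundary = R_PosInf;
      if (epoch == 2) {
        r_cw = (double)kw * (kw - 1) / 2.0 / (2.0 * anc_n);
      } else {
        const double mw = (epoch == 0) ? m2_dw : m1_dw; // wild lineage -> dom
        const double md = (epoch == 0) ? m2_wd : m1_wd; // dom lineage -> wild
        r_cw = (double)kw * (kw - 1) / 2.0 / (2.0 * size_wild);
        r_cd = (double)kd * (kd - 1) / 2.0 / (2.0 * size_dom);
        r_mw = kw * mw;
        r_md = kd * md;
        boundary = (epoch == 0) ? t2 : t1;
      }
      const double tot = r_cw + r_cd + r_mw + r_md;

      if (tot <= 0.0) {
        // nothing can happen in this epoch; jump to its end
        t = boundary;
        if (t >= t1) { // merge demes into the ancestor
          for (int id : deme_idx[1]) deme_idx[0].push_back(id);
          deme_idx[1].clear();
        }
        continue;
      }

      const double dt = exp_rand() / tot;
      if (t + dt >= boundary) {
        t = boundary;
        if (t >= t1) {
          for (int id : deme_idx[1]) deme_idx[0].push_back(id);
          deme_idx[1].clear();
        }
        continue;
      }
      t += dt;

      double u = unif_rand() * tot;
      if (u < r_cw || (epoch == 2)) {
        // coalescence in deme 0 (or the merged ancestral deme)
        std::vector<int> &v = deme_idx[0];
        int a = pick((int)v.size());
        int b = pick((int)v.size() - 1);
        if (b >= a) ++b;
        const int ia = v[a], ib = v[b];
        acc(lin[ia].i, lin[ia].j) += t - lin[ia].birth;
        acc(lin[ib].i, lin[ib].j) += t - lin[ib].birth;
        Lineage parent = {lin[ia].i + lin[ib].i, lin[ia].j + lin[ib].j, t};
        // remove the two children (larger index first), then add parent
        if (a < b) std::swap(a, b);
        v[a] = v.back(); v.pop_back();
        v[b] = v.back(); v.pop_back();
        v.push_back((int)lin.size());
        lin.push_back(parent);
        --k_alive;
      } else if (u < r_cw + r_cd) {
        std::vector<int> &v = deme_idx[1];
        int a = pick((int)v.size());
        int b = pick((int)v.size() - 1);
        if (b >= a) ++b;
        const int ia = v[a], ib = v[b];
        acc(lin[ia].i, lin[ia].j) += t - lin[ia].birth;
        acc(lin[ib].i, lin[ib].j) += t - lin[ib].birth;
        Lineage parent = {lin[ia].i + lin[ib].i, lin[ia].j + lin[ib].j, t};
        if (a < b) std::swap(a, b);
        v[a] = v.back(); v.pop_back();
        v[b] = v.back(); v.pop_back();
        v.push_back((int)lin.size());
        lin.push_back(parent);
        --k_alive;
      } else if (u < r_cw + r_cd + r_mw) {
        // a wild-resident lineage traces back to the domestic deme
        std::vector<int> &v = deme_idx[0];
        int a = pick((int)v.size());
        const int id = v[a];
        v[a] = v.back(); v.pop_back();
        deme_idx[1].push_back(id);
      } else {
        std::vector<int> &v = deme_idx[1];
        int a = pick((int)v.size());
        const int id = v[a];
        v[a] = v.back(); v.pop_back();
        deme_idx[0].push_back(id);
      }
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // the root lineage is never closed; its config is the full sample and is
  // excluded by construction (a mutation above the MRCA is invisible)
  for (int i = 0; i <= n_wild; ++i)
    for (int j = 0; j <= n_dom; ++j)
      acc(i, j) /= n_reps;
  acc(0, 0) = 0.0;
  acc(n_wild, n_dom) = 0.0;
  return acc;
}
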