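// Two-population multispecies-coalescent engine: coalescent gene-tree
// density, JC69 pruning likelihood, Metropolis-within-Gibbs sampler for
// (tau, theta_A, theta_B, theta_root), and reversible-jump split-vs-merge
// model choice.  Node convention: tips 0..n-1 (age 0), internals n..2n-2.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Tree {
  int n;                 // tips
  int nn;                // 2n - 1
  int root;
  std::vector<int> c1, c2, par;  // -1 for none
  std::vector<double> age;
  std::vector<int> mask;         // bit 1 = pop A, bit 2 = pop B below node
  std::vector<int> post;         // postorder (internal nodes only)

  void build_postorder() {
    post.clear();
    std::vector<int> stack, seen(nn, 0);
    stack.push_back(root);
    std::vector<int> out;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      out.push_back(v);
      if (c1[v] >= 0) { stack.push_back(c1[v]); stack.push_back(c2[v]); }
    }
    for (int i = (int)out.size() - 1; i >= 0; --i)
      if (c1[out[i]] >= 0) post.push_back(out[i]);
  }
  void update_masks(const std::vector<int>& tipmask) {
    for (int i = 0; i < n; ++i) mask[i] = tipmask[i];
    for (size_t k = 0; k < post.size(); ++k) {
      int v = post[k];
      mask[v] = mask[c1[v]] | mask[c2[v]];
    }
  }
  // recompute masks on the path from node up to the root
  void update_masks_up(int v) {
    while (v >= 0) {
      if (c1[v] >= 0) mask[v] = mask[c1[v]] | mask[c2[v]];
      v = par[v];
    }
  }
  bool is_ancestor(int a, int b) const {  // a ancestor of b?
    int v = b;
    while (v >= 0) { if (v == a) return true; v = par[v]; }
    return false;
  }
  double min_mixed_age() const {
    double m = R_PosInf;
    for (int v = n; v < nn; ++v)
      if (mask[v] == 3 && age[v] < m) m = age[v];
    return m;
  }
};

static Tree tree_from_r(const IntegerMatrix& children,
                        const NumericVector& age, int ntips,
                        const IntegerVector& tipcode) {
  Tree T;
  T.n = ntips; T.nn = 2 * ntips - 1;
  T.c1.assign(T.nn, -1); T.c2.assign(T.nn, -1);
  T.par.assign(T.nn, -1);
  T.age.assign(age.begin(), age.end());
  T.mask.assign(T.nn, 0);
  for (int v = ntips; v < T.nn; ++v) {
    T.c1[v] = children(v, 0) - 1;
    T.c2[v] = children(v, 1) - 1;
    T.par[T.c1[v]] = v;
    T.par[T.c2[v]] = v;
  }
  T.root = -1;
  for (int v = ntips; v < T.nn; ++v) if (T.par[v] < 0) T.root = v;
  T.build_postorder();
  std::vector<int> tm(ntips);
  for (int i = 0; i < ntips; ++i) tm[i] = tipcode[i] == 0 ? 1 : 2;
  T.update_masks(tm);
  return T;
}

// ---------------------------------------------------------------- coalescent

// Log-density of the genealogy under the two-population MSC.  tau = 0 with
// a single theta_root gives the merged (one-population) model.  Returns
// false on a tau-constraint violation (viol = offending node, 0-based).
static bool coal_stats(const Tree& T, double tau,
                       int cc[3], double SS[3], int* viol) {
  cc[0] = cc[1] = cc[2] = 0;
  SS[0] = SS[1] = SS[2] = 0.0;
  if (viol) *viol = -1;
  std::vector<double> evA, evB, evR;
  int nA = 0, nB = 0;
  for (int i = 0; i < T.n; ++i) (T.mask[i] == 1 ? nA : nB)++;
  for (int v = T.n; v < T.nn; ++v) {
    if (T.age[v] < tau) {
      if (T.mask[v] == 3) { if (viol) *viol = v; return false; }
      (T.mask[v] == 1 ? evA : evB).push_back(T.age[v]);
    } else evR.push_back(T.age[v]);
  }
  std::sort(evA.begin(), evA.end());
  std::sort(evB.begin(), evB.end());
  std::sort(evR.begin(), evR.end());
  // within-population phases on [0, tau)
  double t; int k;
  t = 0.0; k = nA;
  for (size_t i = 0; i < evA.size(); ++i) {
    SS[0] += (double)k * (k - 1) * (evA[i] - t); t = evA[i]; --k; ++cc[0];
  }
  if (k > 1 && R_FINITE(tau)) SS[0] += (double)k * (k - 1) * (tau - t);
  t = 0.0; k = nB;
  for (size_t i = 0; i < evB.size(); ++i) {
    SS[1] += (double)k * (k - 1) * (evB[i] - t); t = evB[i]; --k; ++cc[1];
  }
  if (k > 1 && R_FINITE(tau)) SS[1] += (double)k * (k - 1) * (tau - t);
  // ancestral (root) phase from tau
  t = tau; k = (nA - cc[0]) + (nB - cc[1]);
  for (size_t i = 0; i < evR.size(); ++i) {
    SS[2] += (double)k * (k - 1) * (evR[i] - t); t = evR[i]; --k; ++cc[2];
  }
  return true;
}

static double coal_ld(const Tree& T, double tau, double thA, double thB,
                      double thR, int* viol = 0) {
  int cc[3]; double SS[3];
  if (!coal_stats(T, tau, cc, SS, viol)) return R_NegInf;
  double th[3] = { thA, thB, thR };
  double ld = 0.0;
  for (int p = 0; p < 3; ++p) {
    if (cc[p] == 0 && SS[p] == 0.0) continue;
    if (!(th[p] > 0)) return R_NegInf;
    ld += cc[p] * std::log(2.0 / th[p]) - SS[p] / th[p];
  }
  return ld;
}

// ------------------------------------------------------------------- JC69

// Felsenstein pruning over compressed site patterns; tip states are IUPAC
// bitmasks (A=1, C=2, G=4, T=8; N/gap = 15).
struct Lik {
  int npat;
  std::vector<double> w;
  std::vector<double> tipL;  // n * npat * 4
  std::vector<double> buf;   // nn * 4 scratch (per pattern)

  void init(const IntegerMatrix& states, const NumericVector& weights,
            int n, int nn) {
    npat = states.ncol();
    w.assign(weights.begin(), weights.end());
    tipL.assign((size_t)n * npat * 4, 0.0);
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < npat; ++s) {
        int m = states(i, s);
        for (int x = 0; x < 4; ++x)
          tipL[((size_t)i * npat + s) * 4 + x] = (m >> x) & 1 ? 1.0 : 0.0;
      }
    buf.assign((size_t)nn * 4, 0.0);
  }

  double loglik(const Tree& T) {
    std::vector<double> e4(T.nn, 0.0);
    for (int v = 0; v < T.nn; ++v)
      if (T.par[v] >= 0)
        e4[v] = std::exp(-4.0 * (T.age[T.par[v]] - T.age[v]) / 3.0);
    double ll = 0.0;
    for (int s = 0; s < npat; ++s) {
      double scale = 0.0;
      for (size_t k = 0; k < T.post.size(); ++k) {
        int v = T.post[k];
        double* L = &buf[(size_t)v * 4];
        for (int x = 0; x < 4; ++x) L[x] = 1.0;
        int ch[2] = { T.c1[v], T.c2[v] };
        for (int q = 0; q < 2; ++q) {
          int c = ch[q];
          const double* Lc = c < T.n ? &tipL[((size_t)c * npat + s) * 4]
                                     : &buf[(size_t)c * 4];
          double S = Lc[0] + Lc[1] + Lc[2] + Lc[3];
          double base = 0.25 * (1.0 - e4[c]) * S;
          for (int x = 0; x < 4; ++x) L[x] *= base + e4[c] * Lc[x];
        }
        double m = std::max(std::max(L[0], L[1]), std::max(L[2], L[3]));
        if (m < 1e-100) {
          if (m <= 0.0) return R_NegInf;
          for (int x = 0; x < 4; ++x) L[x] /= m;
          scale += std::log(m);
        }
      }
      const double* Lr = &buf[(size_t)T.root * 4];
      double site = 0.25 * (Lr[0] + Lr[1] + Lr[2] + Lr[3]);
      if (site <= 0.0) return R_NegInf;
      ll += w[s] * (std::log(site) + scale);
    }
    return ll;
  }
};

// --------------------------------------------------------------- utilities

static double ig_logpdf(double x, double a, double b) {
  if (!(x > 0)) return R_NegInf;
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(x) - b / x;
}
static double ig_draw(double a, double b) {
  return 1.0 / R::rgamma(a, 1.0 / b);  // rgamma(shape, scale); rate = b
}
static double ig_cdf(double q, double a, double b) {
  if (!(q > 0)) return 0.0;
  return R::pgamma(1.0 / q, a, 1.0 / b, 0, 0);  // upper tail of Gamma(a, rate b)
}
static double ig_quantile(double p, double a, double b) {
  return 1.0 / R::qgamma(p, a, 1.0 / b, 0, 0);
}
static int unif_int(int k) {
  int v = (int)(R::unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// [[Rcpp::export]]
List coal_logdensity_cpp(IntegerMatrix children, NumericVector age,
                         int ntips, IntegerVector tipcode, double tau,
                         double theta_a, double theta_b, double theta_root) {
  Tree T = tree_from_r(children, age, ntips, tipcode);
  int viol = -1;
  double ld = coal_ld(T, tau, theta_a, theta_b, theta_root, &viol);
  return List::create(_["logdensity"] = ld, _["violating_node"] = viol + 1);
}

// [[Rcpp::export]]
List coal_suffstats_cpp(IntegerMatrix children, NumericVector age,
                        int ntips, IntegerVector tipcode, double tau) {
  Tree T = tree_from_r(children, age, ntips, tipcode);
  int cc[3]; double SS[3]; int viol = -1;
  bool ok = coal_stats(T, tau, cc, SS, &viol);
  return List::create(_["ok"] = ok,
                      _["events"] = IntegerVector::create(cc[0], cc[1], cc[2]),
                      _["S"] = NumericVector::create(SS[0], SS[1], SS[2]),
                      _["violating_node"] = viol + 1);
}

// [[Rcpp::export]]
double jc69_loglik_cpp(IntegerMatrix children, NumericVector age, int ntips,
                       IntegerMatrix states, NumericVector weights) {
  IntegerVector tipcode(ntips);  // populations irrelevant to the likelihood
  Tree T = tree_from_r(children, age, ntips, tipcode);
  Lik L;
  L.init(states, weights, T.n, T.nn);
  return L.loglik(T);
}

// ---------------------------------------------------------------- sampler

struct Priors { double a_th, b_th, a_tau, b_tau; };

struct Sampler {
  Tree T;
  Lik lik;
  Priors pr;
  bool prior_only, fix_tree, merged;
  double tau, th[3];          // merged model uses th[2] only
  double cur_ll, cur_coal;
  // tuned step sizes
  double s_root, s_tau, s_scale;
  double acc[3], att[3];      // root-age, tau, scale
  double acc_age, att_age, acc_top, att_top;

  double log_prior_params() const {
    double lp = 0.0;
    if (merged) {
      lp += ig_logpdf(th[2], pr.a_th, pr.b_th);
    } else {
      for (int p = 0; p < 3; ++p) lp += ig_logpdf(th[p], pr.a_th, pr.b_th);
      lp += ig_logpdf(tau, pr.a_tau, pr.b_tau);
    }
    return lp;
  }
  double coal_now() {
    return merged ? coal_ld(T, 0.0, 1.0, 1.0, th[2])
                  : coal_ld(T, tau, th[0], th[1], th[2]);
  }
  double ll_now() { return prior_only ? 0.0 : lik.loglik(T); }

  void refresh() { cur_coal = coal_now(); cur_ll = ll_now(); }

  void move_age(int v) {
    double lo = std::max(T.age[T.c1[v]], T.age[T.c2[v]]);
    if (!merged && T.mask[v] == 3 && tau > lo) lo = tau;
    double old = T.age[v], lhr = 0.0, prop;
    if (T.par[v] < 0) {
      double x = old - lo;
      prop = lo + x * std::exp(s_root * (R::unif_rand() - 0.5));
      lhr = std::log((prop - lo) / x);
      att[0] += 1;
    } else {
      double hi = T.age[T.par[v]];
      if (hi <= lo) return;
      prop = lo + R::unif_rand() * (hi - lo);
    }
    att_age += 1;
    T.age[v] = prop;
    double nc = coal_now();
    double nl = ll_now();
    double lr = (nc + nl) - (cur_coal + cur_ll) + lhr;
    if (std::log(R::unif_rand()) < lr) {
      cur_coal = nc; cur_ll = nl; acc_age += 1;
      if (T.par[v] < 0) acc[0] += 1;
    } else T.age[v] = old;
  }

  void move_narrow() {
    att_top += 1;
    // internal non-root node p with internal parent
    std::vector<int> cand;
    for (int v = T.n; v < T.nn; ++v) if (v != T.root && T.par[v] >= 0)
      cand.push_back(v);
    if (cand.empty()) return;
    int p = cand[unif_int((int)cand.size())];
    int g = T.par[p];
    int u = T.c1[g] == p ? T.c2[g] : T.c1[g];
    if (!(T.age[u] < T.age[p])) return;
    bool first = R::unif_rand() < 0.5;
    int c = first ? T.c1[p] : T.c2[p];
    // swap u and c
    if (first) T.c1[p] = u; else T.c2[p] = u;
    if (T.c1[g] == u) T.c1[g] = c; else T.c2[g] = c;
    T.par[u] = p; T.par[c] = g;
    T.build_postorder();
    T.mask[p] = T.mask[T.c1[p]] | T.mask[T.c2[p]];
    double nc = coal_now(), nl = ll_now();
    if (std::log(R::unif_rand()) < (nc + nl) - (cur_coal + cur_ll)) {
      cur_coal = nc; cur_ll = nl; acc_top += 1;
    } else {
      if (first) T.c1[p] = c; else T.c2[p] = c;
      if (T.c1[g] == c) T.c1[g] = u; else T.c2[g] = u;
      T.par[u] = g; T.par[c] = p;
      T.build_postorder();
      T.mask[p] = T.mask[T.c1[p]] | T.mask[T.c2[p]];
    }
  }

  void swap_children(int i, int j) {
    int pi = T.par[i], pj = T.par[j];
    if (T.c1[pi] == i) T.c1[pi] = j; else T.c2[pi] = j;
    if (T.c1[pj] == j) T.c1[pj] = i; else T.c2[pj] = i;
    T.par[i] = pj; T.par[j] = pi;
    T.build_postorder();
    T.update_masks_up(pi);
    T.update_masks_up(pj);
  }

  void move_swap() {
    att_top += 1;
    int i = unif_int(T.nn), j = unif_int(T.nn);
    if (i == T.root || j == T.root || i == j) return;
    if (T.par[i] == T.par[j]) return;
    if (T.is_ancestor(i, j) || T.is_ancestor(j, i)) return;
    if (!(T.age[T.par[i]] > T.age[j] && T.age[T.par[j]] > T.age[i])) return;
    swap_children(i, j);
    double nc = coal_now(), nl = ll_now();
    if (std::log(R::unif_rand()) < (nc + nl) - (cur_coal + cur_ll)) {
      cur_coal = nc; cur_ll = nl; acc_top += 1;
    } else swap_children(j, i);  // exact inverse
  }

  void move_tau() {
    att[1] += 1;
    double old = tau;
    tau = old * std::exp(s_tau * (R::unif_rand() - 0.5));
    double nc = coal_now();
    double lr = nc - cur_coal + ig_logpdf(tau, pr.a_tau, pr.b_tau)
              - ig_logpdf(old, pr.a_tau, pr.b_tau) + std::log(tau / old);
    if (std::log(R::unif_rand()) < lr) { cur_coal = nc; acc[1] += 1; }
    else tau = old;
  }

  void gibbs_theta() {
    int cc[3]; double SS[3];
    coal_stats(T, merged ? 0.0 : tau, cc, SS, 0);
    if (merged) {
      th[2] = ig_draw(pr.a_th + cc[2], pr.b_th + SS[2]);
    } else {
      for (int p = 0; p < 3; ++p)
        th[p] = ig_draw(pr.a_th + cc[p], pr.b_th + SS[p]);
    }
    cur_coal = coal_now();
  }

  void move_scale() {
    att[2] += 1;
    double f = std::exp(s_scale * (R::unif_rand() - 0.5));
    int d = (T.n - 1) + (merged ? 1 : 4);
    std::vector<double> oldage = T.age;
    double oldtau = tau, oldth[3] = { th[0], th[1], th[2] };
    double oldlp = log_prior_params();
    for (int v = T.n; v < T.nn; ++v) T.age[v] *= f;
    if (!merged) { tau *= f; th[0] *= f; th[1] *= f; }
    th[2] *= f;
    double nc = coal_now(), nl = ll_now();
    double lr = (nc + nl + log_prior_params())
              - (cur_coal + cur_ll + oldlp) + d * std::log(f);
    if (std::log(R::unif_rand()) < lr) {
      cur_coal = nc; cur_ll = nl; acc[2] += 1;
    } else {
      T.age = oldage; tau = oldtau;
      th[0] = oldth[0]; th[1] = oldth[1]; th[2] = oldth[2];
    }
  }

  void tune() {
    double* steps[3] = { &s_root, &s_tau, &s_scale };
    for (int k = 0; k < 3; ++k) {
      if (att[k] < 20) continue;
      double r = acc[k] / att[k];
      if (r < 0.2) *steps[k] *= 0.7;
      else if (r > 0.4) *steps[k] *= 1.3;
      if (*steps[k] < 1e-3) *steps[k] = 1e-3;
      if (*steps[k] > 10.0) *steps[k] = 10.0;
      acc[k] = att[k] = 0;
    }
  }

  void sweep() {
    if (!fix_tree) {
      for (int v = T.n; v < T.nn; ++v) move_age(v);
      for (int r = 0; r < 2; ++r) move_narrow();
      for (int r = 0; r < 2; ++r) move_swap();
    }
    if (!merged) move_tau();
    gibbs_theta();
    if (!fix_tree) move_scale();
  }
};

static Sampler make_sampler(const IntegerMatrix& children,
                            const NumericVector& age, int ntips,
                            const IntegerVector& tipcode,
                            const IntegerMatrix& states,
                            const NumericVector& weights,
                            NumericVector prior, double tau0,
                            NumericVector theta0, bool prior_only,
                            bool fix_tree, bool merged) {
  Sampler S;
  S.T = tree_from_r(children, age, ntips, tipcode);
  S.lik.init(states, weights, S.T.n, S.T.nn);
  S.pr.a_th = prior[0]; S.pr.b_th = prior[1];
  S.pr.a_tau = prior[2]; S.pr.b_tau = prior[3];
  S.prior_only = prior_only; S.fix_tree = fix_tree; S.merged = merged;
  S.tau = tau0;
  S.th[0] = theta0[0]; S.th[1] = theta0[1]; S.th[2] = theta0[2];
  S.s_root = 0.5; S.s_tau = 0.5; S.s_scale = 0.3;
  S.acc[0] = S.acc[1] = S.acc[2] = 0;
  S.att[0] = S.att[1] = S.att[2] = 0;
  S.acc_age = S.att_age = S.acc_top = S.att_top = 0;
  S.refresh();
  return S;
}

// [[Rcpp::export]]
List run_a00_cpp(IntegerMatrix children, NumericVector age, int ntips,
                 IntegerVector tipcode, IntegerMatrix states,
                 NumericVector weights, NumericVector prior, double tau0,
                 NumericVector theta0, int nsample, int burnin, int thin,
                 bool prior_only, bool fix_tree, bool merged) {
  Sampler S = make_sampler(children, age, ntips, tipcode, states, weights,
                           prior, tau0, theta0, prior_only, fix_tree, merged);
  if (!R_FINITE(S.cur_coal))
    stop("initial gene tree incompatible with the model parameters");
  NumericMatrix trace(nsample, 5);
  colnames(trace) = CharacterVector::create("tau", "theta_a", "theta_b",
                                            "theta_root", "loglik");
  for (int it = 0; it < burnin; ++it) {
    S.sweep();
    if (it % 50 == 49) S.tune();
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int s = 0; s < nsample; ++s) {
    for (int t = 0; t < thin; ++t) S.sweep();
    trace(s, 0) = S.merged ? NA_REAL : S.tau;
    trace(s, 1) = S.merged ? NA_REAL : S.th[0];
    trace(s, 2) = S.merged ? NA_REAL : S.th[1];
    trace(s, 3) = S.th[2];
    trace(s, 4) = S.cur_ll;
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  double age_rate = S.att_age > 0 ? S.acc_age / S.att_age : NA_REAL;
  double top_rate = S.att_top > 0 ? S.acc_top / S.att_top : NA_REAL;
  return List::create(_["trace"] = trace,
                      _["acceptance"] = NumericVector::create(
                          _["age"] = age_rate, _["topology"] = top_rate),
                      _["steps"] = NumericVector::create(
                          _["root"] = S.s_root, _["tau"] = S.s_tau,
                          _["scale"] = S.s_scale));
}

// [[Rcpp::export]]
List run_rj_cpp(IntegerMatrix children, NumericVector age, int ntips,
                IntegerVector tipcode, IntegerMatrix states,
                NumericVector weights, NumericVector prior, double tau0,
                NumericVector theta0, int nsample, int burnin, int thin,
                bool prior_only, double log_prior_split_odds,
                bool init_split) {
  Sampler S = make_sampler(children, age, ntips, tipcode, states, weights,
                           prior, tau0, theta0, prior_only, false, false);
  if (!init_split) {
    S.merged = true;
    S.refresh();
  }
  if (!R_FINITE(S.cur_coal))
    stop("initial gene tree incompatible with the model parameters");
  int acc_jump = 0, att_jump = 0;

  // log of the analytic theta-integrated gene-tree density for one
  // population: integral of IG-prior(theta) * coalescent factor
  auto log_Z = [&](int c, double Ssum) {
    double a = S.pr.a_th, b = S.pr.b_th;
    return c * std::log(2.0) + a * std::log(b) - R::lgammafn(a)
         + R::lgammafn(a + c) - (a + c) * std::log(b + Ssum);
  };

  // Trans-model move between merged (one theta) and split (tau + three
  // theta).  tau is proposed from its prior truncated at the youngest
  // node joining the two populations; all theta are proposed from their
  // conditional inverse-gamma posteriors given the genealogy, so the
  // theta factors cancel analytically and the acceptance ratio involves
  // only the theta-integrated coalescent densities.
  auto try_jump = [&]() {
    ++att_jump;
    double tm = S.T.min_mixed_age();
    double F = ig_cdf(tm, S.pr.a_tau, S.pr.b_tau);
    if (!(F > 0)) return;
    int cc[3]; double SS[3];
    if (!S.merged) {
      double lZ_split = 0.0;
      coal_stats(S.T, S.tau, cc, SS, 0);
      for (int p = 0; p < 3; ++p) lZ_split += log_Z(cc[p], SS[p]);
      coal_stats(S.T, 0.0, cc, SS, 0);
      double lZ_merge = log_Z(cc[2], SS[2]);
      double lr = -log_prior_split_odds + lZ_merge - lZ_split - std::log(F);
      if (std::log(R::unif_rand()) < lr) {
        S.merged = true;
        S.th[2] = ig_draw(S.pr.a_th + cc[2], S.pr.b_th + SS[2]);
        S.cur_coal = coal_ld(S.T, 0.0, 1.0, 1.0, S.th[2]);
        ++acc_jump;
      }
    } else {
      double u = R::unif_rand() * F;
      double tau_new = ig_quantile(u, S.pr.a_tau, S.pr.b_tau);
      if (!(tau_new > 0) || tau_new > tm) return;
      coal_stats(S.T, 0.0, cc, SS, 0);
      double lZ_merge = log_Z(cc[2], SS[2]);
      if (!coal_stats(S.T, tau_new, cc, SS, 0)) return;
      double lZ_split = 0.0;
      for (int p = 0; p < 3; ++p) lZ_split += log_Z(cc[p], SS[p]);
      double lr = log_prior_split_odds + lZ_split - lZ_merge + std::log(F);
      if (std::log(R::unif_rand()) < lr) {
        S.merged = false; S.tau = tau_new;
        for (int p = 0; p < 3; ++p)
          S.th[p] = ig_draw(S.pr.a_th + cc[p], S.pr.b_th + SS[p]);
        S.cur_coal = coal_ld(S.T, tau_new, S.th[0], S.th[1], S.th[2]);
        ++acc_jump;
      }
    }
  };

  NumericMatrix trace(nsample, 6);
  colnames(trace) = CharacterVector::create("split", "tau", "theta_a",
                                            "theta_b", "theta_root",
                                            "loglik");
  for (int it = 0; it < burnin; ++it) {
    S.sweep(); try_jump();
    if (it % 50 == 49) S.tune();
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int s = 0; s < nsample; ++s) {
    for (int t = 0; t < thin; ++t) { S.sweep(); try_jump(); }
    trace(s, 0) = S.merged ? 0.0 : 1.0;
    trace(s, 1) = S.merged ? NA_REAL : S.tau;
    trace(s, 2) = S.merged ? NA_REAL : S.th[0];
    trace(s, 3) = S.merged ? NA_REAL : S.th[1];
    trace(s, 4) = S.th[2];
    trace(s, 5) = S.cur_ll;
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trace"] = trace,
                      _["jump_rate"] = att_jump > 0 ?
                          (double)acc_jump / att_jump : NA_REAL);
}
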