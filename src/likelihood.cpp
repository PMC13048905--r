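// Felsenstein pruning engines.
//
// Two code paths:
//  * Poisson-exchangeability models (profile mixtures and per-site
//    frequency / PMSF models).  With all exchangeabilities equal the
//    normalized rate matrix gives the closed form
//        P(t) = e I + (1 - e) 1 pi^T,   e = exp(-t / beta),
//        beta = 1 - sum_a pi_a^2,
//    so a pruning step costs O(states) per site and the likelihood is,
//    for a single branch, LINEAR in e per mixture class.  That linearity
//    drives the fast per-branch optimizer below.
//  * Dense path: caller supplies per-class, per-edge transition matrices
//    (from an eigendecomposition in R); used for LG / GTR-type models.
//
// Conventions shared with the R side:
//  * states: integer matrix n_tip x n_pattern, 0-based state codes,
//    -1 = gap/missing (all-ones conditional vector).
//  * edge: ape postorder edge matrix (parent, child), 1-based node ids,
//    tips 1..n_tip, every child's subtree listed before its own edge.
//  * root = parent of the last postorder edge.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SCALE_FLOOR = 1e-280;

// ---------------------------------------------------------------------------
// Poisson closed-form sweeps
// ---------------------------------------------------------------------------

// Downward (postorder) sweep for one rate class.
// pis: s x (1 or n_pat); per-pattern profiles when percol is true.
// Fills D (n_node x n_pat x s), dscale (n_node x n_pat),
// Y (n_edge x n_pat x s) = M(t_e) D[child_e]  (shares dscale[child]).
static void pois_down(const IntegerMatrix& states, const IntegerMatrix& edge,
                      const NumericVector& blen, const NumericMatrix& pis,
                      bool percol, const NumericVector& invbeta, double rate,
                      std::vector<double>& D, std::vector<double>& dscale,
                      std::vector<double>& Y) {
  const int s = pis.nrow(), n_tip = states.nrow(), n_pat = states.ncol();
  const int n_edge = edge.nrow();
  int n_node = 0;
  for (int i = 0; i < n_edge; ++i)
    n_node = std::max(n_node, std::max(edge(i, 0), edge(i, 1)));
  D.resize((size_t)n_node * n_pat * s);
  dscale.resize((size_t)n_node * n_pat);
  Y.resize((size_t)n_edge * n_pat * s);
  std::vector<char> touched(n_node, 0);

  // tip partials (all entries written: buffers are reused across calls)
  for (int tip = 0; tip < n_tip; ++tip) {
    double* Dt = &D[(size_t)tip * n_pat * s];
    for (int p = 0; p < n_pat; ++p) {
      int st = states(tip, p);
      for (int a = 0; a < s; ++a)
        Dt[(size_t)p * s + a] = (st < 0 || a == st) ? 1.0 : 0.0;
      dscale[(size_t)tip * n_pat + p] = 0.0;
    }
    touched[tip] = 1;
  }

  for (int i = 0; i < n_edge; ++i) {
    int par = edge(i, 0) - 1, chi = edge(i, 1) - 1;
    double t = blen[i] * rate;
    const double* Dc = &D[(size_t)chi * n_pat * s];
    double* Yi = &Y[(size_t)i * n_pat * s];
    double* Dp = &D[(size_t)par * n_pat * s];
    if (!touched[par]) {
      for (int p = 0; p < n_pat; ++p) {
        for (int a = 0; a < s; ++a) Dp[(size_t)p * s + a] = 1.0;
        dscale[(size_t)par * n_pat + p] = 0.0;
      }
      touched[par] = 1;
    }
    for (int p = 0; p < n_pat; ++p) {
      const double* pi = percol ? &pis(0, p) : &pis(0, 0);
      double e = std::exp(-t * (percol ? invbeta[p] : invbeta[0]));
      const double* x = Dc + (size_t)p * s;
      double* y = Yi + (size_t)p * s;
      double pidot = 0.0;
      for (int a = 0; a < s; ++a) pidot += pi[a] * x[a];
      double q = (1.0 - e) * pidot;
      double* dp = Dp + (size_t)p * s;
      double mx = 0.0;
      for (int a = 0; a < s; ++a) {
        double v = e * x[a] + q;
        y[a] = v;
        v *= dp[a];
        dp[a] = v;
        if (v > mx) mx = v;
      }
      dscale[(size_t)par * n_pat + p] += dscale[(size_t)chi * n_pat + p];
      if (mx < SCALE_FLOOR && mx > 0.0) {
        for (int a = 0; a < s; ++a) dp[a] /= mx;
        dscale[(size_t)par * n_pat + p] += std::log(mx);
      }
    }
  }
}

// Upward sweep producing, for every edge, the linear branch profile
//   lik_pat(t) = ( e * A + (1 - e) * C ) * exp(S)
// A = sum_a pi_a G_a D_a ; C = (pi . D)(pi . G); S carries all scalers.
static void pois_up_profiles(const IntegerMatrix& edge, const NumericVector& blen,
                             const NumericMatrix& pis, bool percol,
                             const NumericVector& invbeta, double rate, int n_pat,
                             const std::vector<double>& D,
                             const std::vector<double>& dscale,
                             const std::vector<double>& Y,
                             std::vector<double>& A, std::vector<double>& C,
                             std::vector<double>& S) {
  const int s = pis.nrow(), n_edge = edge.nrow();
  int n_node = 0;
  for (int i = 0; i < n_edge; ++i)
    n_node = std::max(n_node, std::max(edge(i, 0), edge(i, 1)));
  int root = edge(n_edge - 1, 0) - 1;

  std::vector<double> U((size_t)n_node * n_pat * s);
  std::vector<double> uscale((size_t)n_node * n_pat, 0.0);
  {
    double* Ur = &U[(size_t)root * n_pat * s];
    for (size_t j = 0; j < (size_t)n_pat * s; ++j) Ur[j] = 1.0;
  }
  // children-of lists (postorder edge index per child)
  std::vector<std::vector<int> > kids(n_node);
  for (int i = 0; i < n_edge; ++i) kids[edge(i, 0) - 1].push_back(i);

  A.resize((size_t)n_edge * n_pat);
  C.resize((size_t)n_edge * n_pat);
  S.resize((size_t)n_edge * n_pat);
  std::vector<double> G((size_t)n_pat * s);

  // preorder = reverse postorder
  for (int i = n_edge - 1; i >= 0; --i) {
    int par = edge(i, 0) - 1, chi = edge(i, 1) - 1;
    double t = blen[i] * rate;
    const std::vector<int>& sib = kids[par];
    const double* Up = &U[(size_t)par * n_pat * s];
    for (int p = 0; p < n_pat; ++p) {
      const double* pi = percol ? &pis(0, p) : &pis(0, 0);
      double* g = &G[(size_t)p * s];
      const double* up = Up + (size_t)p * s;
      double sc = uscale[(size_t)par * n_pat + p];
      for (int a = 0; a < s; ++a) g[a] = up[a];
      for (size_t k = 0; k < sib.size(); ++k) {
        int ei = sib[k];
        if (ei == i) continue;
        const double* y = &Y[(size_t)ei * n_pat * s + (size_t)p * s];
        for (int a = 0; a < s; ++a) g[a] *= y[a];
        sc += dscale[(size_t)(edge(ei, 1) - 1) * n_pat + p];
      }
      double mx = 0.0;
      for (int a = 0; a < s; ++a)
        if (g[a] > mx) mx = g[a];
      if (mx < SCALE_FLOOR && mx > 0.0) {
        for (int a = 0; a < s; ++a) g[a] /= mx;
        sc += std::log(mx);
      }
      // branch profile for edge i
      const double* d = &D[(size_t)chi * n_pat * s + (size_t)p * s];
      double agd = 0.0, pid = 0.0, pig = 0.0;
      for (int a = 0; a < s; ++a) {
        agd += pi[a] * g[a] * d[a];
        pid += pi[a] * d[a];
        pig += pi[a] * g[a];
      }
      A[(size_t)i * n_pat + p] = agd;
      C[(size_t)i * n_pat + p] = pid * pig;
      S[(size_t)i * n_pat + p] = sc + dscale[(size_t)chi * n_pat + p];
      // U[child] = M(t)^T G
      double e = std::exp(-t * (percol ? invbeta[p] : invbeta[0]));
      double gsum = 0.0;
      for (int a = 0; a < s; ++a) gsum += g[a];
      double* uc = &U[(size_t)chi * n_pat * s + (size_t)p * s];
      for (int a = 0; a < s; ++a) uc[a] = e * g[a] + (1.0 - e) * pi[a] * gsum;
      uscale[(size_t)chi * n_pat + p] = sc;
    }
  }
}

// Root likelihood (log) for one class from the downward sweep.
static void pois_root_loglik(const IntegerMatrix& edge, const NumericMatrix& pis,
                             bool percol, int n_pat, const std::vector<double>& D,
                             const std::vector<double>& dscale, double* out) {
  const int s = pis.nrow(), n_edge = edge.nrow();
  int root = edge(n_edge - 1, 0) - 1;
  const double* Dr = &D[(size_t)root * n_pat * s];
  for (int p = 0; p < n_pat; ++p) {
    const double* pi = percol ? &pis(0, p) : &pis(0, 0);
    double lik = 0.0;
    for (int a = 0; a < s; ++a) lik += pi[a] * Dr[(size_t)p * s + a];
    out[p] = std::log(lik) + dscale[(size_t)root * n_pat + p];
  }
}

static NumericVector betas_of(const NumericMatrix& pis) {
  int s = pis.nrow(), K = pis.ncol();
  NumericVector ib(K);
  for (int k = 0; k < K; ++k) {
    double ss = 0.0;
    for (int a = 0; a < s; ++a) ss += pis(a, k) * pis(a, k);
    ib[k] = 1.0 / (1.0 - ss);
  }
  return ib;
}

// Per-pattern log-likelihood matrix under a Poisson profile mixture.
// Returns n_pat x K matrix of log L_{ik} = log mean_g L_i(pi_k, r_g);
// total per-pattern loglik = logsumexp_k(log w_k + logL_ik).
// [[Rcpp::export]]
NumericMatrix cpp_mix_classlog(IntegerMatrix states, IntegerMatrix edge,
                               NumericVector blen, NumericMatrix profiles,
                               NumericVector rates) {
  const int n_pat = states.ncol(), K = profiles.ncol(), G = rates.size();
  NumericVector invbeta = betas_of(profiles);
  NumericMatrix out(n_pat, K);
  std::vector<double> D, dscale, Y, tmp(n_pat);
  for (int k = 0; k < K; ++k) {
    NumericMatrix pik = profiles(Range(0, profiles.nrow() - 1), Range(k, k));
    NumericVector ib(1);
    ib[0] = invbeta[k];
    std::vector<double> acc(n_pat, R_NegInf);
    for (int g = 0; g < G; ++g) {
      pois_down(states, edge, blen, pik, false, ib, rates[g], D, dscale, Y);
      pois_root_loglik(edge, pik, false, n_pat, D, dscale, &tmp[0]);
      for (int p = 0; p < n_pat; ++p) {
        double a = acc[p], b = tmp[p];
        acc[p] = (a > b) ? a + std::log1p(std::exp(b - a))
                         : b + std::log1p(std::exp(a - b));
      }
    }
    double lg = std::log((double)G);
    for (int p = 0; p < n_pat; ++p) out(p, k) = acc[p] - lg;
  }
  return out;
}

// Per-pattern log-likelihood under per-site (per-pattern) frequencies.
// pis: s x n_pat. Returns vector of per-pattern logliks (mean over gamma).
// [[Rcpp::export]]
NumericVector cpp_pmsf_loglik(IntegerMatrix states, IntegerMatrix edge,
                              NumericVector blen, NumericMatrix pis,
                              NumericVector rates) {
  const int n_pat = states.ncol(), G = rates.size();
  NumericVector invbeta = betas_of(pis);
  std::vector<double> D, dscale, Y, tmp(n_pat), acc(n_pat, R_NegInf);
  for (int g = 0; g < G; ++g) {
    pois_down(states, edge, blen, pis, true, invbeta, rates[g], D, dscale, Y);
    pois_root_loglik(edge, pis, true, n_pat, D, dscale, &tmp[0]);
    for (int p = 0; p < n_pat; ++p) {
      double a = acc[p], b = tmp[p];
      acc[p] = (a > b) ? a + std::log1p(std::exp(b - a))
                       : b + std::log1p(std::exp(a - b));
    }
  }
  NumericVector out(n_pat);
  double lg = std::log((double)G);
  for (int p = 0; p < n_pat; ++p) out[p] = acc[p] - lg;
  return out;
}

// ---------------------------------------------------------------------------
// Fast branch-length optimization (Poisson path)
// ---------------------------------------------------------------------------

// Classes are (profile k, gamma category g) pairs (mixture mode, percol=false,
// weight w_k / G) or gamma categories alone (PMSF mode, percol=true, weight
// 1/G).  For each edge the cached profile gives
//   lnL(t) = sum_pat w_pat log( sum_c q_c [ e_c A + (1 - e_c) C ] ) + const
// with e_c = exp(-t * rate_c * invbeta_c).  One round caches profiles for all
// edges at the incoming lengths and optimizes each length on its own profile
// (a Jacobi-style update); the true joint lnL is recomputed after each round
// and the round is rejected (lengths reverted) if it failed to improve.

struct EdgeCache {
  // per edge: folded coefficients fa,fc (n_class x n_pat) and per-pattern
  // log offset m (n_pat), so lik_pat(t) = exp(m) * sum_c (e_c fa + (1-e_c) fc)
  std::vector<float> fa, fc;
  std::vector<double> m;
};

static double edge_obj(const EdgeCache& ec, const std::vector<double>& wpat,
                       const std::vector<double>& crate, int n_class, int n_pat,
                       double t) {
  std::vector<double> ev(n_class);
  for (int c = 0; c < n_class; ++c) ev[c] = std::exp(-t * crate[c]);
  double tot = 0.0;
  for (int p = 0; p < n_pat; ++p) {
    double lik = 0.0;
    const float* fa = &ec.fa[(size_t)p * n_class];
    const float* fc = &ec.fc[(size_t)p * n_class];
    for (int c = 0; c < n_class; ++c)
      lik += ev[c] * (double)fa[c] + (1.0 - ev[c]) * (double)fc[c];
    if (lik <= 0.0) lik = 1e-300;
    tot += wpat[p] * (std::log(lik) + ec.m[p]);
  }
  return tot;
}

// golden-section maximization of edge_obj over log t in [log lo, log hi]
static double edge_golden(const EdgeCache& ec, const std::vector<double>& wpat,
                          const std::vector<double>& crate, int n_class,
                          int n_pat, double lo, double hi, int iters) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = edge_obj(ec, wpat, crate, n_class, n_pat, std::exp(x1));
  double f2 = edge_obj(ec, wpat, crate, n_class, n_pat, std::exp(x2));
  for (int it = 0; it < iters; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = edge_obj(ec, wpat, crate, n_class, n_pat, std::exp(x2));
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = edge_obj(ec, wpat, crate, n_class, n_pat, std::exp(x1));
    }
  }
  return std::exp(0.5 * (a + b));
}

// Shared optimizer core. In mixture mode pis is s x K and logw has length
// K*G (flattened class weights, log scale); in PMSF mode pis is s x n_pat,
// classes are the G gamma categories with weight 1/G.
static List optimize_core(IntegerMatrix states, NumericVector wpat,
                          IntegerMatrix edge, NumericVector blen,
                          NumericMatrix pis, bool pmsf, NumericVector wk,
                          NumericVector rates, int max_rounds, double tol,
                          double tmin, double tmax) {
  const int n_pat = states.ncol(), n_edge = edge.nrow(), G = rates.size();
  const int K = pmsf ? 1 : pis.ncol();
  const int n_class = K * G;
  NumericVector invbeta = betas_of(pis);  // per profile (mix) / per pattern (pmsf)
  std::vector<double> wp(wpat.begin(), wpat.end());
  NumericVector bl = clone(blen);

  // class bookkeeping (mixture mode): class c = k * G + g
  std::vector<double> logw(n_class), cr_rate(n_class);
  for (int k = 0; k < K; ++k)
    for (int g = 0; g < G; ++g) {
      int c = k * G + g;
      logw[c] = (pmsf ? 0.0 : std::log(wk[k])) - std::log((double)G);
      cr_rate[c] = rates[g] * (pmsf ? 1.0 : invbeta[k]);
    }

  std::vector<double> D, dscale, Y, A, C, S;
  // per-edge caches of raw A, C, S per class (float: final lnL is
  // recomputed in double before a round is accepted)
  std::vector<std::vector<float> > Ae(n_edge), Ce(n_edge), Se(n_edge);
  for (int i = 0; i < n_edge; ++i) {
    Ae[i].assign((size_t)n_pat * n_class, 0.f);
    Ce[i].assign((size_t)n_pat * n_class, 0.f);
    Se[i].assign((size_t)n_pat * n_class, 0.f);
  }
  std::vector<double> rootlog(n_pat);

  // full joint lnL at lengths b (also refreshes nothing)
  NumericMatrix pis_all = pis;
  std::vector<double> classacc((size_t)n_pat * n_class);
  int s_states = pis.nrow();
  std::vector<double> lnl_trace;

  // helper lambdas are avoided for portability; inline loops instead.
  double cur = R_NegInf;
  {
    // initial lnL
    std::vector<double> tmp(n_pat);
    std::vector<double> persite(n_pat, R_NegInf);
    for (int k = 0; k < K; ++k) {
      NumericMatrix pik =
          pmsf ? pis : NumericMatrix(pis(Range(0, s_states - 1), Range(k, k)));
      NumericVector ib(pmsf ? invbeta.size() : 1);
      if (pmsf)
        ib = invbeta;
      else
        ib[0] = invbeta[k];
      for (int g = 0; g < G; ++g) {
        pois_down(states, edge, bl, pik, pmsf, ib, rates[g], D, dscale, Y);
        pois_root_loglik(edge, pik, pmsf, n_pat, D, dscale, &tmp[0]);
        for (int p = 0; p < n_pat; ++p) {
          double a = persite[p], b2 = tmp[p] + logw[k * G + g];
          persite[p] = (a > b2) ? a + std::log1p(std::exp(b2 - a))
                                : b2 + std::log1p(std::exp(a - b2));
        }
      }
    }
    cur = 0.0;
    for (int p = 0; p < n_pat; ++p) cur += wp[p] * persite[p];
  }
  lnl_trace.push_back(cur);

  EdgeCache ec;
  for (int round = 0; round < max_rounds; ++round) {
    // cache branch profiles for every edge, class by class
    for (int k = 0; k < K; ++k) {
      NumericMatrix pik =
          pmsf ? pis : NumericMatrix(pis(Range(0, s_states - 1), Range(k, k)));
      NumericVector ib(pmsf ? invbeta.size() : 1);
      if (pmsf)
        ib = invbeta;
      else
        ib[0] = invbeta[k];
      for (int g = 0; g < G; ++g) {
        int c = k * G + g;
        pois_down(states, edge, bl, pik, pmsf, ib, rates[g], D, dscale, Y);
        pois_up_profiles(edge, bl, pik, pmsf, ib, rates[g], n_pat, D, dscale, Y,
                         A, C, S);
        for (int i = 0; i < n_edge; ++i)
          for (int p = 0; p < n_pat; ++p) {
            Ae[i][(size_t)p * n_class + c] = (float)A[(size_t)i * n_pat + p];
            Ce[i][(size_t)p * n_class + c] = (float)C[(size_t)i * n_pat + p];
            Se[i][(size_t)p * n_class + c] =
                (float)(S[(size_t)i * n_pat + p] + logw[c]);
          }
      }
    }
    NumericVector newbl = clone(bl);
    ec.fa.assign((size_t)n_pat * n_class, 0.f);
    ec.fc.assign((size_t)n_pat * n_class, 0.f);
    ec.m.assign(n_pat, 0.0);
    for (int i = 0; i < n_edge; ++i) {
      std::vector<double> crate(cr_rate);
      for (int p = 0; p < n_pat; ++p) {
        double mx = R_NegInf;
        const float* se = &Se[i][(size_t)p * n_class];
        for (int c = 0; c < n_class; ++c)
          if ((double)se[c] > mx) mx = (double)se[c];
        ec.m[p] = mx;
        for (int c = 0; c < n_class; ++c) {
          double f = std::exp((double)se[c] - mx);
          ec.fa[(size_t)p * n_class + c] =
              (float)(f * (double)Ae[i][(size_t)p * n_class + c]);
          ec.fc[(size_t)p * n_class + c] =
              (float)(f * (double)Ce[i][(size_t)p * n_class + c]);
        }
      }
      double newt;
      if (!pmsf) {
        newt = edge_golden(ec, wp, crate, n_class, n_pat, tmin, tmax, 28);
      } else {
        // exact golden for per-pattern invbeta
        const double gr = 0.6180339887498949;
        double a = std::log(tmin), b = std::log(tmax);
        double xs[2];
        double fs[2];
        xs[0] = b - gr * (b - a);
        xs[1] = a + gr * (b - a);
        for (int j = 0; j < 2; ++j) {
          double t = std::exp(xs[j]);
          double tot = 0.0;
          for (int p = 0; p < n_pat; ++p) {
            double lik = 0.0;
            for (int c = 0; c < n_class; ++c) {
              double e = std::exp(-t * cr_rate[c] * invbeta[p]);
              lik += e * (double)ec.fa[(size_t)p * n_class + c] +
                     (1.0 - e) * (double)ec.fc[(size_t)p * n_class + c];
            }
            if (lik <= 0.0) lik = 1e-300;
            tot += wp[p] * (std::log(lik) + ec.m[p]);
          }
          fs[j] = tot;
        }
        for (int it = 0; it < 28; ++it) {
          int drop = (fs[0] < fs[1]) ? 0 : 1;
          if (drop == 0) {
            a = xs[0];
            xs[0] = xs[1];
            fs[0] = fs[1];
            xs[1] = a + gr * (b - a);
          } else {
            b = xs[1];
            xs[1] = xs[0];
            fs[1] = fs[0];
            xs[0] = b - gr * (b - a);
          }
          int j = (drop == 0) ? 1 : 0;
          double t = std::exp(xs[j]);
          double tot = 0.0;
          for (int p = 0; p < n_pat; ++p) {
            double lik = 0.0;
            for (int c = 0; c < n_class; ++c) {
              double e = std::exp(-t * cr_rate[c] * invbeta[p]);
              lik += e * (double)ec.fa[(size_t)p * n_class + c] +
                     (1.0 - e) * (double)ec.fc[(size_t)p * n_class + c];
            }
            if (lik <= 0.0) lik = 1e-300;
            tot += wp[p] * (std::log(lik) + ec.m[p]);
          }
          fs[j] = tot;
        }
        newt = std::exp(0.5 * (a + b));
      }
      newbl[i] = newt;
    }
    // evaluate joint lnL at proposed lengths; damp on failure
    double prop = R_NegInf;
    NumericVector trial = clone(newbl);
    bool accepted = false;
    for (int attempt = 0; attempt < 4; ++attempt) {
      std::vector<double> tmp(n_pat), persite(n_pat, R_NegInf);
      for (int k = 0; k < K; ++k) {
        NumericMatrix pik =
            pmsf ? pis : NumericMatrix(pis(Range(0, s_states - 1), Range(k, k)));
        NumericVector ib(pmsf ? invbeta.size() : 1);
        if (pmsf)
          ib = invbeta;
        else
          ib[0] = invbeta[k];
        for (int g = 0; g < G; ++g) {
          pois_down(states, edge, trial, pik, pmsf, ib, rates[g], D, dscale, Y);
          pois_root_loglik(edge, pik, pmsf, n_pat, D, dscale, &tmp[0]);
          for (int p = 0; p < n_pat; ++p) {
            double a = persite[p], b2 = tmp[p] + logw[k * G + g];
            persite[p] = (a > b2) ? a + std::log1p(std::exp(b2 - a))
                                  : b2 + std::log1p(std::exp(a - b2));
          }
        }
      }
      prop = 0.0;
      for (int p = 0; p < n_pat; ++p) prop += wp[p] * persite[p];
      if (prop >= cur - 1e-9) {
        accepted = true;
        break;
      }
      for (int i = 0; i < n_edge; ++i)
        trial[i] = std::sqrt(trial[i] * bl[i]);  // geometric damping
    }
    if (!accepted) break;  // keep previous lengths; lnL trace stays monotone
    double gain = prop - cur;
    bl = trial;
    cur = prop;
    lnl_trace.push_back(cur);
    if (gain < tol) break;
  }
  return List::create(_["blen"] = bl, _["lnl"] = cur,
                      _["trace"] = NumericVector(lnl_trace.begin(), lnl_trace.end()));
}

// [[Rcpp::export]]
List cpp_optimize_blens_mix(IntegerMatrix states, NumericVector wpat,
                            IntegerMatrix edge, NumericVector blen,
                            NumericMatrix profiles, NumericVector wk,
                            NumericVector rates, int max_rounds, double tol,
                            double tmin, double tmax) {
  return optimize_core(states, wpat, edge, blen, profiles, false, wk, rates,
                       max_rounds, tol, tmin, tmax);
}

// [[Rcpp::export]]
List cpp_optimize_blens_pmsf(IntegerMatrix states, NumericVector wpat,
                             IntegerMatrix edge, NumericVector blen,
                             NumericMatrix pis, NumericVector rates,
                             int max_rounds, double tol, double tmin,
                             double tmax) {
  NumericVector wk(1, 1.0);
  return optimize_core(states, wpat, edge, blen, pis, true, wk, rates,
                       max_rounds, tol, tmin, tmax);
}

// ---------------------------------------------------------------------------
// Dense path: caller-supplied transition matrices
// ---------------------------------------------------------------------------

// Plist: list over classes; each element a list over edges of s x s
// transition matrices (rows = parent state).  rootf: s x n_class.
// Returns n_pat x n_class per-pattern log-likelihoods.
// [[Rcpp::export]]
NumericMatrix cpp_dense_loglik(IntegerMatrix states, IntegerMatrix edge,
                               List Plist, NumericMatrix rootf) {
  const int n_tip = states.nrow(), n_pat = states.ncol();
  const int n_edge = edge.nrow(), n_class = Plist.size();
  const int s = rootf.nrow();
  int n_node = 0;
  for (int i = 0; i < n_edge; ++i)
    n_node = std::max(n_node, std::max(edge(i, 0), edge(i, 1)));
  int root = edge(n_edge - 1, 0) - 1;
  NumericMatrix out(n_pat, n_class);
  std::vector<double> D((size_t)n_node * n_pat * s);
  std::vector<double> dscale((size_t)n_node * n_pat);
  std::vector<char> touched(n_node);

  for (int c = 0; c < n_class; ++c) {
    List Pc = Plist[c];
    std::fill(D.begin(), D.end(), 0.0);
    std::fill(dscale.begin(), dscale.end(), 0.0);
    std::fill(touched.begin(), touched.end(), 0);
    for (int tip = 0; tip < n_tip; ++tip) {
      double* Dt = &D[(size_t)tip * n_pat * s];
      for (int p = 0; p < n_pat; ++p) {
        int st = states(tip, p);
        if (st < 0)
          for (int a = 0; a < s; ++a) Dt[(size_t)p * s + a] = 1.0;
        else
          Dt[(size_t)p * s + st] = 1.0;
      }
      touched[tip] = 1;
    }
    for (int i = 0; i < n_edge; ++i) {
      int par = edge(i, 0) - 1, chi = edge(i, 1) - 1;
      NumericMatrix P = Pc[i];
      double* Dp = &D[(size_t)par * n_pat * s];
      const double* Dc = &D[(size_t)chi * n_pat * s];
      if (!touched[par]) {
        for (size_t j = 0; j < (size_t)n_pat * s; ++j) Dp[j] = 1.0;
        touched[par] = 1;
      }
      for (int p = 0; p < n_pat; ++p) {
        const double* x = Dc + (size_t)p * s;
        double* dp = Dp + (size_t)p * s;
        double mx = 0.0;
        for (int a = 0; a < s; ++a) {
          double v = 0.0;
          for (int b = 0; b < s; ++b) v += P(a, b) * x[b];
          if (v < 0.0) v = 0.0;  // eigendecomposition round-off
          v *= dp[a];
          dp[a] = v;
          if (v > mx) mx = v;
        }
        dscale[(size_t)par * n_pat + p] += dscale[(size_t)chi * n_pat + p];
        if (mx < SCALE_FLOOR && mx > 0.0) {
          for (int a = 0; a < s; ++a) dp[a] /= mx;
          dscale[(size_t)par * n_pat + p] += std::log(mx);
        }
      }
    }
    const double* Dr = &D[(size_t)root * n_pat * s];
    for (int p = 0; p < n_pat; ++p) {
      double lik = 0.0;
      for (int a = 0; a < s; ++a) lik += rootf(a, c) * Dr[(size_t)p * s + a];
      if (lik <= 0.0) lik = 1e-300;
      out(p, c) = std::log(lik) + dscale[(size_t)root * n_pat + p];
    }
  }
  return out;
}
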