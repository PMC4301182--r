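// Maximum likelihood for the nested random-effects model
//   y_ijk = mu + g_i + s_ij + e_ijk,
//   g ~ N(0, s2g), s ~ N(0, s2s), e ~ N(0, s2e),
// computed from per-species sufficient statistics (replicate mean,
// within-species SS, replicate count), with mu profiled out by GLS and a
// Sherman-Morrison inversion of each genus block. Also hosts the
// genus-bootstrap replicate loop of the randomization test, which needs
// on the order of a million of these fits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

struct NestedData {
  std::vector<double> ybar, ss;  // per species
  std::vector<int> nrep, genus;  // genus id is 0-based, contiguous
  int G;
  double vtot;                   // total sample variance of raw data
  // workspace reused across likelihood evaluations
  mutable std::vector<double> wS, wA, wB, wlogd;
  mutable std::vector<int> wm;
};

// negative log-likelihood, mu profiled; variances on natural scale.
// With reml=true the single-mean REML correction
//   logL_R = logL_P - 0.5 log(1' Sigma^-1 1) + 0.5 log(2 pi)
// is applied.
static double nested_nll(const NestedData &d, double s2g, double s2s,
                         double s2e, bool reml = false) {
  const int S = (int)d.ybar.size();
  const int G = d.G;
  d.wS.assign(G, 0.0);
  d.wA.assign(G, 0.0);
  d.wB.assign(G, 0.0);
  d.wlogd.assign(G, 0.0);
  d.wm.assign(G, 0);
  std::vector<double> &Ssum = d.wS, &Asum = d.wA, &Bsum = d.wB,
      &logdsum = d.wlogd;
  std::vector<int> &m = d.wm;
  double nll = 0.0;
  for (int j = 0; j < S; ++j) {
    const int n = d.nrep[j];
    if (n > 1)
      nll += 0.5 * ((n - 1) * (LOG2PI + std::log(s2e)) + d.ss[j] / s2e);
    nll += 0.5 * std::log((double)n);
    const double dj = s2s + s2e / n;
    const int g = d.genus[j];
    const double inv = 1.0 / dj;
    Ssum[g] += inv;
    Asum[g] += d.ybar[j] * inv;
    Bsum[g] += d.ybar[j] * d.ybar[j] * inv;
    logdsum[g] += std::log(dj);
    m[g] += 1;
  }
  double num = 0.0, den = 0.0;
  for (int g = 0; g < G; ++g) {
    const double w = 1.0 / (1.0 + s2g * Ssum[g]);
    num += Asum[g] * w;
    den += Ssum[g] * w;
  }
  const double mu = num / den;
  for (int g = 0; g < G; ++g) {
    const double t = 1.0 + s2g * Ssum[g];
    const double rsum = Asum[g] - mu * Ssum[g];           // sum (y-mu)/d
    const double rsq = Bsum[g] - 2.0 * mu * Asum[g] + mu * mu * Ssum[g];
    const double Q = rsq - s2g * rsum * rsum / t;
    nll += 0.5 * (m[g] * LOG2PI + logdsum[g] + std::log(t) + Q);
  }
  if (reml) nll += 0.5 * std::log(den) - 0.5 * LOG2PI;
  return nll;
}

struct NllOnLog {
  const NestedData *d;
  double lo, hi;  // box on log-variance scale
  bool reml = false;
  double operator()(const double *th) const {
    double t[3];
    for (int i = 0; i < 3; ++i) {
      t[i] = th[i];
      if (t[i] < lo) t[i] = lo;
      if (t[i] > hi) t[i] = hi;
    }
    return nested_nll(*d, std::exp(t[0]), std::exp(t[1]), std::exp(t[2]),
                      reml);
  }
};

// plain Nelder-Mead in 3 dimensions with box projection in the objective
static void nelder_mead3(const NllOnLog &f, double *x0, double step,
                         int maxit, double ftol) {
  const int n = 3;
  double simplex[4][3], fv[4];
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j < n; ++j) simplex[i][j] = x0[j];
    if (i > 0) simplex[i][i - 1] += step;
    fv[i] = f(simplex[i]);
  }
  for (int iter = 0; iter < maxit; ++iter) {
    // order
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i <= n; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    nh = (hi == 0) ? 1 : 0;
    for (int i = 0; i <= n; ++i)
      if (i != hi && fv[i] > fv[nh]) nh = i;
    if (std::fabs(fv[hi] - fv[lo]) <
        ftol * (std::fabs(fv[lo]) + std::fabs(fv[hi]) + 1e-30) + 1e-14)
      break;
    double cen[3] = {0, 0, 0};
    for (int i = 0; i <= n; ++i)
      if (i != hi)
        for (int j = 0; j < n; ++j) cen[j] += simplex[i][j] / n;
    double xr[3], xe[3], xc[3];
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - simplex[hi][j]);
    double fr = f(xr);
    if (fr < fv[lo]) {
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - simplex[hi][j]);
      double fe = f(xe);
      if (fe < fr) {
        for (int j = 0; j < n; ++j) simplex[hi][j] = xe[j];
        fv[hi] = fe;
      } else {
        for (int j = 0; j < n; ++j) simplex[hi][j] = xr[j];
        fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      for (int j = 0; j < n; ++j) simplex[hi][j] = xr[j];
      fv[hi] = fr;
    } else {
      for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (simplex[hi][j] - cen[j]);
      double fc = f(xc);
      if (fc < fv[hi]) {
        for (int j = 0; j < n; ++j) simplex[hi][j] = xc[j];
        fv[hi] = fc;
      } else {  // shrink towards best
        for (int i = 0; i <= n; ++i)
          if (i != lo) {
            for (int j = 0; j < n; ++j)
              simplex[i][j] = simplex[lo][j] + 0.5 * (simplex[i][j] - simplex[lo][j]);
            fv[i] = f(simplex[i]);
          }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i <= n; ++i)
    if (fv[i] < fv[lo]) lo = i;
  for (int j = 0; j < n; ++j) x0[j] = simplex[lo][j];
}

// moment-based starting values on the variance scale
static void start_values(const NestedData &d, double *s2) {
  const int S = (int)d.ybar.size();
  const int G = d.G;
  double ss_sum = 0.0;
  int df_e = 0;
  for (int j = 0; j < S; ++j) {
    ss_sum += d.ss[j];
    df_e += d.nrep[j] - 1;
  }
  double s2e = df_e > 0 ? ss_sum / df_e : 0.1 * d.vtot;
  std::vector<double> gsum(G, 0.0);
  std::vector<int> gm(G, 0);
  for (int j = 0; j < S; ++j) {
    gsum[d.genus[j]] += d.ybar[j];
    gm[d.genus[j]] += 1;
  }
  double within = 0.0;
  int df_w = 0;
  for (int j = 0; j < S; ++j) {
    const int g = d.genus[j];
    if (gm[g] > 1) {
      const double r = d.ybar[j] - gsum[g] / gm[g];
      within += r * r;
    }
  }
  for (int g = 0; g < G; ++g)
    if (gm[g] > 1) df_w += gm[g] - 1;
  double nbar = 0.0;
  for (int j = 0; j < S; ++j) nbar += d.nrep[j];
  nbar /= S;
  double s2s = df_w > 0 ? within / df_w - s2e / nbar : 0.2 * d.vtot;
  double gmean = 0.0;
  for (int g = 0; g < G; ++g) gmean += gsum[g] / gm[g];
  gmean /= G;
  double between = 0.0;
  for (int g = 0; g < G; ++g) {
    const double r = gsum[g] / gm[g] - gmean;
    between += r * r;
  }
  double s2g = G > 1 ? between / (G - 1) : 0.2 * d.vtot;
  const double floor0 = 1e-6 * d.vtot + 1e-300;
  s2[0] = std::max(s2g, floor0);
  s2[1] = std::max(s2s, floor0);
  s2[2] = std::max(s2e, floor0);
}

static void fit_nested(const NestedData &d, double *s2out, double *nll_out,
                       bool reml = false, bool fast = false) {
  const double floorv = 1e-12 * d.vtot + 1e-300;
  NllOnLog f;
  f.d = &d;
  f.reml = reml;
  f.lo = std::log(floorv);
  f.hi = std::log(1e6 * d.vtot + 1e-300);
  double s2[3];
  start_values(d, s2);
  double th[3] = {std::log(s2[0]), std::log(s2[1]), std::log(s2[2])};
  if (fast) {  // bootstrap replicates: variance-ratio precision suffices
    nelder_mead3(f, th, 0.8, 200, 1e-9);
    nelder_mead3(f, th, 0.15, 80, 1e-10);
  } else {
    nelder_mead3(f, th, 0.7, 500, 1e-12);
    nelder_mead3(f, th, 0.1, 300, 1e-13);  // restart polish
    nelder_mead3(f, th, 0.02, 200, 1e-14); // sharpen near boundaries
  }
  for (int i = 0; i < 3; ++i) {
    double t = th[i];
    if (t < f.lo) t = f.lo;
    if (t > f.hi) t = f.hi;
    s2out[i] = std::exp(t);
  }
  if (nll_out)
    *nll_out = nested_nll(d, s2out[0], s2out[1], s2out[2], reml);
}

static NestedData make_data(const NumericVector &ybar, const NumericVector &ss,
                            const IntegerVector &nrep,
                            const IntegerVector &genus, int G) {
  NestedData d;
  const int S = ybar.size();
  d.ybar.assign(ybar.begin(), ybar.end());
  d.ss.assign(ss.begin(), ss.end());
  d.nrep.assign(nrep.begin(), nrep.end());
  d.genus.assign(genus.begin(), genus.end());
  d.G = G;
  // total variance of the raw observations from the sufficient stats
  double N = 0.0, tot = 0.0;
  for (int j = 0; j < S; ++j) {
    N += d.nrep[j];
    tot += d.nrep[j] * d.ybar[j];
  }
  const double gm = tot / N;
  double sstot = 0.0;
  for (int j = 0; j < S; ++j)
    sstot += d.ss[j] + d.nrep[j] * (d.ybar[j] - gm) * (d.ybar[j] - gm);
  d.vtot = N > 1 ? sstot / (N - 1) : 1.0;
  if (d.vtot <= 0) d.vtot = 1e-12;
  return d;
}

// [[Rcpp::export]]
List nested_ml_cpp(NumericVector ybar, NumericVector ss, IntegerVector nrep,
                   IntegerVector genus, int G, bool reml = false) {
  NestedData d = make_data(ybar, ss, nrep, genus, G);
  double s2[3], nll;
  fit_nested(d, s2, &nll, reml);
  return List::create(_["sigma2"] = NumericVector::create(s2[0], s2[1], s2[2]),
                      _["logL"] = -nll, _["vtot"] = d.vtot);
}

// [[Rcpp::export]]
double nested_nll_cpp(NumericVector sigma2, NumericVector ybar,
                      NumericVector ss, IntegerVector nrep,
                      IntegerVector genus, int G, bool reml = false) {
  NestedData d = make_data(ybar, ss, nrep, genus, G);
  return nested_nll(d, sigma2[0], sigma2[1], sigma2[2], reml);
}

// Genus bootstrap for the randomization test: draw genera with
// replacement (same drawn list applied to both traits, duplicates
// relabeled as distinct units), refit both nested models, and record
// D = rho_A - rho_B with rho = s2_species / s2_genus. A resample whose
// genus variance hits the boundary gets rho = +Inf (sentinel); if both
// traits are degenerate, D is 0. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export]]
List genus_bootstrap_cpp(NumericVector ybarA, NumericVector ssA,
                         IntegerVector nrepA, IntegerVector genusA,
                         NumericVector ybarB, NumericVector ssB,
                         IntegerVector nrepB, IntegerVector genusB, int G,
                         int n_reps) {
  NestedData A = make_data(ybarA, ssA, nrepA, genusA, G);
  NestedData B = make_data(ybarB, ssB, nrepB, genusB, G);
  // per-genus species index lists
  std::vector<std::vector<int>> gidxA(G), gidxB(G);
  for (size_t j = 0; j < A.genus.size(); ++j) gidxA[A.genus[j]].push_back(j);
  for (size_t j = 0; j < B.genus.size(); ++j) gidxB[B.genus[j]].push_back(j);

  NumericVector D(n_reps);
  int degen = 0;
  NestedData rA, rB;
  rA.G = G; rB.G = G;
  rA.vtot = A.vtot; rB.vtot = B.vtot;
  for (int r = 0; r < n_reps; ++r) {
    rA.ybar.clear(); rA.ss.clear(); rA.nrep.clear(); rA.genus.clear();
    rB.ybar.clear(); rB.ss.clear(); rB.nrep.clear(); rB.genus.clear();
    for (int g = 0; g < G; ++g) {
      int pick = (int)(G * unif_rand());
      if (pick >= G) pick = G - 1;
      for (int j : gidxA[pick]) {
        rA.ybar.push_back(A.ybar[j]);
        rA.ss.push_back(A.ss[j]);
        rA.nrep.push_back(A.nrep[j]);
        rA.genus.push_back(g);
      }
      for (int j : gidxB[pick]) {
        rB.ybar.push_back(B.ybar[j]);
        rB.ss.push_back(B.ss[j]);
        rB.nrep.push_back(B.nrep[j]);
        rB.genus.push_back(g);
      }
    }
    double s2a[3], s2b[3];
    fit_nested(rA, s2a, nullptr, false, true);
    fit_nested(rB, s2b, nullptr, false, true);
    const double flA = 1e-10 * rA.vtot, flB = 1e-10 * rB.vtot;
    const bool degA = s2a[0] <= flA, degB = s2b[0] <= flB;
    double rhoA = degA ? R_PosInf : s2a[1] / s2a[0];
    double rhoB = degB ? R_PosInf : s2b[1] / s2b[0];
    if (degA || degB) ++degen;
    if (degA && degB) D[r] = 0.0;
    else D[r] = rhoA - rhoB;
  }
  return List::create(_["D"] = D, _["n_degenerate"] = degen);
}
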