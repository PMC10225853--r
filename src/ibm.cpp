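// Yearly cycle of the two-stage, female-only gridded population model:
// density-dependent Poisson reproduction, kernel-based natal dispersal
// with neighbour-fallback settlement, and binomial survival/transition.
// Individuals within a stage and cell are exchangeable, so demographic
// events are drawn per cell (distributionally identical to
// per-individual Bernoulli draws).
//
// Randomness is counter-based: every draw takes a dedicated uniform
// from a splitmix64 hash of (seed, process, cell, draw index), realized
// through the matching quantile function (qpois/qbinom) or inverse CDF.
// Consequences: (1) full reproducibility from an explicit seed;
// (2) common-random-number coupling — perturbing a parameter leaves all
// unrelated draws untouched, so simulated likelihoods vary smoothly
// (a fine staircase) in the parameters instead of decorrelating
// chaotically, and raising a survival or fecundity parameter is
// pathwise monotone in the realized counts.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in (0, 1), keyed by (base, process, cell, draw index)
static inline double cru(uint64_t base, uint64_t proc, uint64_t cell,
                         uint64_t idx) {
  uint64_t h = splitmix64(splitmix64(splitmix64(base + proc) + cell + 1)
                          + idx + 1);
  double u = (double)(h >> 11) * (1.0 / 9007199254740992.0);
  if (u < 1e-12) u = 1e-12;
  if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
  return u;
}

static inline uint64_t as_u64(double seed) {
  return (uint64_t)(long long)seed;
}

// antithetic flag: encoded in the seed's top bit region is avoided by
// passing it explicitly; u -> 1-u preserves every marginal draw
// distribution (inverse-CDF) while negatively coupling paired
// replicates, the classical variance-reduction for replicate averages
static inline double maybe_flip(double u, bool anti) {
  return anti ? 1.0 - u : u;
}

// process ids inside one annual step
enum { PROC_REPRO = 1, PROC_EMIG = 2, PROC_TRANSFER = 3, PROC_SJ = 4,
       PROC_SA = 5 };

// Exact inverse-CDF draws. Direct series inversion is used in the
// common small-count regime (cheap and exact); R's quantile functions
// handle the tails and large counts.
static inline int q_pois(double u, double lambda) {
  if (lambda > 60.0) return (int) R::qpois(u, lambda, 1, 0);
  double p = std::exp(-lambda);
  if (p <= 0) return (int) R::qpois(u, lambda, 1, 0);
  double cum = p;
  int k = 0;
  while (u > cum && k < 1000) {
    ++k;
    p *= lambda / k;
    cum += p;
  }
  return k;
}

static inline int q_binom(double u, int n, double pr) {
  if (pr <= 0.0) return 0;
  if (pr >= 1.0) return n;
  if (n > 150) return (int) R::qbinom(u, n, pr, 1, 0);
  double q = 1.0 - pr;
  double t = std::pow(q, n);
  if (t <= 1e-300) return (int) R::qbinom(u, n, pr, 1, 0);
  double cum = t;
  int k = 0;
  double odds = pr / q;
  while (u > cum && k < n) {
    ++k;
    t *= odds * (n - k + 1) / k;
    cum += t;
  }
  return k;
}

// Per-cell expected offspring are capped at LAMBDA_CAP: a pure floating
// point / runtime guard against degenerate parameter proposals whose
// fecundity link saturates (such states produce absurd predicted means
// and are rejected by the likelihood anyway).
static const double LAMBDA_CAP = 1e7;

// [[Rcpp::export]]
IntegerMatrix cpp_reproduce(const IntegerMatrix& A,
                            const NumericMatrix& rho_max,
                            const IntegerMatrix& habitat, double b,
                            double seed, bool anti = false) {
  int nr = A.nrow(), nc = A.ncol();
  uint64_t base = as_u64(seed);
  IntegerMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = A(i, j);
      int h = habitat(i, j);
      if (n <= 0 || h <= 0) continue;
      double rho = rho_max(i, j) * std::exp(-(double)n * b * 100.0 / h);
      double lambda = n * rho;
      if (lambda > LAMBDA_CAP) lambda = LAMBDA_CAP;
      if (lambda > 0) {
        double u = maybe_flip(cru(base, PROC_REPRO,
                                  (uint64_t)(j * nr + i), 0), anti);
        J(i, j) = q_pois(u, lambda);
      }
    }
  }
  return J;
}

// Dispersal of a juvenile cohort. Each juvenile emigrates with
// probability p_e; emigrants draw an exponential distance (mean dbar)
// and uniform direction from the natal cell centre. The destination is
// the cell containing the endpoint: settle if suitable; else settle in
// a uniformly chosen suitable cell among the destination's 8 in-grid
// neighbours; else die. Endpoints beyond the grid are deaths.
// When record = true the drawn distances and angles are returned.
// [[Rcpp::export]]
List cpp_disperse(const IntegerMatrix& J, const IntegerMatrix& habitat,
                  double p_e, double dbar, double cell_km, double seed,
                  bool record = false, bool anti = false) {
  int nr = J.nrow(), nc = J.ncol();
  uint64_t base = as_u64(seed);
  IntegerMatrix settled(nr, nc);
  int deaths = 0;
  std::vector<double> dists, angles;
  int nbr_r[8], nbr_c[8];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = J(i, j);
      if (n <= 0) continue;
      uint64_t cell = (uint64_t)(j * nr + i);
      int emig;
      if (p_e >= 1.0) emig = n;
      else if (p_e <= 0.0) emig = 0;
      else {
        double u = maybe_flip(cru(base, PROC_EMIG, cell, 0), anti);
        emig = q_binom(u, n, p_e);
      }
      settled(i, j) += n - emig;  // non-emigrants stay in the natal cell
      double cx = (j + 0.5) * cell_km;
      double cy = (i + 0.5) * cell_km;
      for (int e = 0; e < emig; ++e) {
        double u1 = maybe_flip(cru(base, PROC_TRANSFER, cell,
                                   (uint64_t)(3 * e)), anti);
        double u2 = cru(base, PROC_TRANSFER, cell, (uint64_t)(3 * e + 1));
        double d = -dbar * std::log1p(-u1);
        double a = TWO_PI * u2;
        if (record) { dists.push_back(d); angles.push_back(a); }
        double x = cx + d * std::cos(a);
        double y = cy + d * std::sin(a);
        int dj = (int) std::floor(x / cell_km);
        int di = (int) std::floor(y / cell_km);
        if (di < 0 || di >= nr || dj < 0 || dj >= nc) { ++deaths; continue; }
        if (habitat(di, dj) > 0) { ++settled(di, dj); continue; }
        int k = 0;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int ri = di + dr, cj = dj + dc;
            if (ri < 0 || ri >= nr || cj < 0 || cj >= nc) continue;
            if (habitat(ri, cj) > 0) { nbr_r[k] = ri; nbr_c[k] = cj; ++k; }
          }
        }
        if (k == 0) { ++deaths; continue; }
        double u3 = cru(base, PROC_TRANSFER, cell, (uint64_t)(3 * e + 2));
        int pick = (int)(u3 * k);
        if (pick >= k) pick = k - 1;
        ++settled(nbr_r[pick], nbr_c[pick]);
      }
    }
  }
  List out = List::create(_["settled"] = settled, _["deaths"] = deaths);
  if (record) {
    out["distances"] = NumericVector(dists.begin(), dists.end());
    out["angles"] = NumericVector(angles.begin(), angles.end());
  }
  return out;
}

// Binomial survival of (post-dispersal) juveniles and adults, then the
// one-year stage transition: next adults = surviving adults + surviving
// juveniles; next juveniles = 0.
// [[Rcpp::export]]
List cpp_survive(const IntegerMatrix& J, const IntegerMatrix& A,
                 const NumericMatrix& sj, const NumericMatrix& sa,
                 const IntegerMatrix& habitat, double seed,
                 bool anti = false) {
  int nr = J.nrow(), nc = J.ncol();
  uint64_t base = as_u64(seed);
  IntegerMatrix Anext(nr, nc), Jsurv(nr, nc), Asurv(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (habitat(i, j) <= 0) continue;
      uint64_t cell = (uint64_t)(j * nr + i);
      int js = 0, as_ = 0;
      if (J(i, j) > 0) {
        double u = maybe_flip(cru(base, PROC_SJ, cell, 0), anti);
        js = q_binom(u, J(i, j), sj(i, j));
      }
      if (A(i, j) > 0) {
        double u = maybe_flip(cru(base, PROC_SA, cell, 0), anti);
        as_ = q_binom(u, A(i, j), sa(i, j));
      }
      Jsurv(i, j) = js;
      Asurv(i, j) = as_;
      Anext(i, j) = js + as_;
    }
  }
  return List::create(_["A"] = Anext, _["J_surv"] = Jsurv,
                      _["A_surv"] = Asurv);
}

// One full simulation year: reproduce -> disperse -> survive/transition.
// A juvenile cohort larger than pop_ceiling saturates the step (adults
// set to pop_ceiling on suitable cells, no dispersal walk), bounding
// the cost of runaway parameter proposals.
// [[Rcpp::export]]
List cpp_step(const IntegerMatrix& A, const NumericMatrix& rho_max,
              const NumericMatrix& sj, const NumericMatrix& sa,
              const IntegerMatrix& habitat, double b, double p_e,
              double dbar, double cell_km, double seed,
              bool detail = false, double pop_ceiling = 1e6,
              bool anti = false) {
  IntegerMatrix J = cpp_reproduce(A, rho_max, habitat, b, seed, anti);
  double totalJ = 0;
  for (int k = 0; k < J.length(); ++k) totalJ += J[k];
  if (totalJ > pop_ceiling) {
    int nr = A.nrow(), nc = A.ncol();
    int cell_sat = (int) std::min(pop_ceiling, 2e9);
    IntegerMatrix Asat(nr, nc);
    for (int k = 0; k < Asat.length(); ++k) {
      Asat[k] = habitat[k] > 0 ? cell_sat : 0;
    }
    List out = List::create(_["A"] = Asat, _["J"] = IntegerMatrix(nr, nc));
    if (detail) {
      out["produced"] = J;
      out["settled"] = J;
      out["dispersal_deaths"] = 0;
      out["J_surv"] = IntegerMatrix(nr, nc);
      out["A_surv"] = IntegerMatrix(nr, nc);
    }
    out["saturated"] = true;
    return out;
  }
  List disp = cpp_disperse(J, habitat, p_e, dbar, cell_km, seed, false,
                           anti);
  IntegerMatrix settled = disp["settled"];
  List surv = cpp_survive(settled, A, sj, sa, habitat, seed, anti);
  List out = List::create(_["A"] = surv["A"],
                          _["J"] = IntegerMatrix(A.nrow(), A.ncol()));
  if (detail) {
    out["produced"] = J;
    out["settled"] = settled;
    out["dispersal_deaths"] = disp["deaths"];
    out["J_surv"] = surv["J_surv"];
    out["A_surv"] = surv["A_surv"];
  }
  return out;
}

// Multi-year trajectory for one replicate; the year-y step uses the
// derived stream splitmix64(rep_seed + y). Rate maps are passed as
// [nr x nc x nyears] arrays with NA allowed on unsuitable cells.
// If the total population exceeds pop_ceiling the trajectory saturates:
// every remaining year reports pop_ceiling in each suitable cell, so a
// runaway parameter proposal costs bounded time and earns a predicted
// mean the observation model duly penalizes.
// [[Rcpp::export]]
IntegerVector cpp_run_years(const IntegerMatrix& A0,
                            const NumericVector& rho_max_arr,
                            const NumericVector& sj_arr,
                            const NumericVector& sa_arr,
                            const IntegerMatrix& habitat, double b,
                            double p_e, double dbar, double cell_km,
                            double rep_seed, double pop_ceiling = 1e6,
                            bool anti = false) {
  IntegerVector dims = rho_max_arr.attr("dim");
  int nr = dims[0], nc = dims[1], ny = dims[2];
  IntegerMatrix A = clone(A0);
  IntegerVector out(nr * nc * ny);
  out.attr("dim") = IntegerVector::create(nr, nc, ny);
  int plane = nr * nc;
  int cell_sat = (int) std::min(pop_ceiling, 2e9);
  uint64_t base = as_u64(rep_seed);
  NumericMatrix rho(nr, nc), sj(nr, nc), sa(nr, nc);
  for (int y = 0; y < ny; ++y) {
    double total = 0;
    for (int k = 0; k < plane; ++k) total += A[k];
    if (total > pop_ceiling) {
      for (int yy = y; yy < ny; ++yy) {
        for (int k = 0; k < plane; ++k) {
          out[yy * plane + k] = habitat[k] > 0 ? cell_sat : 0;
        }
      }
      break;
    }
    for (int k = 0; k < plane; ++k) {
      rho[k] = rho_max_arr[y * plane + k];
      sj[k] = sj_arr[y * plane + k];
      sa[k] = sa_arr[y * plane + k];
    }
    // keep the seed inside the exactly-representable double range
    double step_seed =
      (double)(splitmix64(base + (uint64_t)y) & ((1ULL << 53) - 1));
    List st = cpp_step(A, rho, sj, sa, habitat, b, p_e, dbar, cell_km,
                       step_seed, false, pop_ceiling, anti);
    A = as<IntegerMatrix>(st["A"]);
    for (int k = 0; k < plane; ++k) out[y * plane + k] = A[k];
  }
  return out;
}
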