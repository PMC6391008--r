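// Wiener diffusion first-passage-time machinery for the two-boundary model
// with symmetric start (relative start 0.5) and unit diffusion noise.
#include <Rcpp.h>
using namespace Rcpp;

static const double PI2 = M_PI * M_PI;

// Dimensionless first-passage density at the lower boundary for a = 1,
// drift 0, relative start w, evaluated at scaled time u = t / a^2.
// Series regime (small vs large time) chosen by the standard number-of-terms
// criterion; `eps` is the absolute truncation tolerance on f0.
static double wfpt_f0(double u, double w, double eps) {
  if (u <= 0.0) return 0.0;
  // terms needed for small-time expansion
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  // terms needed for large-time expansion
  double kl;
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (PI2 * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }
  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= K / 2; ++k) {
      double z = w + 2.0 * k;
      f += z * std::exp(-z * z / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * PI2 * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

// Density of hitting the *lower* boundary at decision time t, boundary
// separation a, drift v (positive = towards upper), relative start w.
static double wfpt_density_lower(double t, double a, double v, double w, double eps) {
  if (t <= 0.0) return 0.0;
  double u = t / (a * a);
  double f0 = wfpt_f0(u, w, eps);
  if (f0 < 0.0) f0 = 0.0; // series truncation can dip below zero in far tails
  return std::exp(-v * a * w - v * v * t / 2.0) / (a * a) * f0;
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double a, double v, double w,
                               bool upper, double eps) {
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wfpt_density_lower(t[i], a, vv, ww, eps);
  return out;
}

// Probability of absorption at the upper boundary, start a/2, drift v.
// Closed form: 1 / (1 + exp(-a v)).
// [[Rcpp::export]]
double wfpt_p_upper_cpp(double a, double v) {
  return 1.0 / (1.0 + std::exp(-a * v));
}

// With start at a/2 the decision-time distribution is independent of which
// boundary is attained and of the drift sign. Conditional density:
//   g(t) = 2 cosh(d a / 2) * (pi / a^2) * sum_{k odd} sgn_k k exp(-lambda_k t)
// with d = |v|, lambda_k = d^2/2 + k^2 pi^2 / (2 a^2), sgn_k alternating.
// Survival S(t) integrates term-wise. Both evaluated together for Newton.
static void cond_surv_dens(double t, double a, double d, double eps,
                           double *S, double *g) {
  double A = 2.0 * std::cosh(d * a / 2.0) * M_PI / (a * a);
  double s = 0.0, f = 0.0;
  for (int j = 0; j < 800; ++j) {
    double k = 2.0 * j + 1.0;
    double lam = d * d / 2.0 + k * k * PI2 / (2.0 * a * a);
    double e = std::exp(-lam * t);
    double sgn = (j % 2 == 0) ? 1.0 : -1.0;
    double termS = sgn * k * e / lam;
    s += termS;
    f += sgn * k * e;
    if (j >= 2 && k * e < eps) break;
  }
  *S = A * s;
  *g = A * f;
  if (*S < 0.0) *S = 0.0;
  if (*S > 1.0) *S = 1.0;
  if (*g < 0.0) *g = 0.0;
}

// [[Rcpp::export]]
NumericVector wfpt_cond_survival_cpp(NumericVector t, double a, double v) {
  int n = t.size();
  NumericVector out(n);
  double S, g;
  for (int i = 0; i < n; ++i) {
    if (t[i] <= 0) { out[i] = 1.0; continue; }
    cond_surv_dens(t[i], a, std::fabs(v), 1e-14, &S, &g);
    out[i] = S;
  }
  return out;
}

// Inverse-CDF draw of the decision time given (a, |v|): safeguarded Newton
// on S(t) = U with bisection fallback.
static double sample_cond_time(double a, double d) {
  double U = unif_rand();
  if (U <= 0.0) U = 1e-300;
  double tmin = 1e-5 * a * a; // S(tmin) = 1 to double precision
  double lam1 = d * d / 2.0 + PI2 / (2.0 * a * a);
  double A = 2.0 * std::cosh(d * a / 2.0) * M_PI / (a * a);
  // single-term tail guess
  double t = std::log(A / (lam1 * U)) / lam1;
  if (!std::isfinite(t) || t < tmin) t = tmin * 4.0;
  double lo = tmin, hi = t;
  double S, g;
  // expand upper bracket until S(hi) <= U
  for (int i = 0; i < 200; ++i) {
    cond_surv_dens(hi, a, d, 1e-13, &S, &g);
    if (S <= U) break;
    lo = hi;
    hi *= 2.0;
  }
  t = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    cond_surv_dens(t, a, d, 1e-13, &S, &g);
    double err = S - U;
    if (std::fabs(err) < 1e-12) break;
    if (err > 0.0) lo = t; else hi = t;
    double tn = (g > 0.0) ? t + err / g : t; // S decreasing: step forward if S>U
    if (tn <= lo || tn >= hi || !std::isfinite(tn)) tn = 0.5 * (lo + hi);
    if (hi - lo < 1e-12 * t) break;
    t = tn;
  }
  return t;
}

// One first-passage draw: returns (upper_hit, decision_time).
// v is the drift towards the *upper* boundary.
static void sample_fpt_one(double a, double v, int *upper, double *t) {
  double pu = 1.0 / (1.0 + std::exp(-a * v));
  *upper = (unif_rand() < pu) ? 1 : 0;
  *t = sample_cond_time(a, std::fabs(v));
}

// [[Rcpp::export]]
List wfpt_sample_cpp(int n, double a, double v) {
  IntegerVector upper(n);
  NumericVector t(n);
  int u;
  double tt;
  for (int i = 0; i < n; ++i) {
    sample_fpt_one(a, v, &u, &tt);
    upper[i] = u;
    t[i] = tt;
  }
  return List::create(_["upper"] = upper, _["time"] = t);
}

// Euler-Maruyama simulation of the same diffusion: independent brute-force
// oracle for the analytic density and the inverse-CDF sampler. Uses a fast
// internal xoshiro256++ generator (seeded from R's RNG, so runs are
// reproducible under set.seed) because millions of samples at small dt need
// billions of normal draws.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  double rnorm() { // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};
} // namespace

// [[Rcpp::export]]
List wfpt_sample_euler_cpp(int n, double a, double v, double dt) {
  IntegerVector upper(n);
  NumericVector t(n);
  double sdt = std::sqrt(dt);
  long maxstep = (long)(1e4 / dt); // hard cap at 10^4 seconds
  Xoshiro rng((uint64_t)(unif_rand() * 9.007199254740992e15));
  for (int i = 0; i < n; ++i) {
    double x = a / 2.0;
    long s = 0;
    while (x > 0.0 && x < a && s < maxstep) {
      x += v * dt + sdt * rng.rnorm();
      ++s;
    }
    upper[i] = (x >= a) ? 1 : 0;
    t[i] = s * dt;
  }
  return List::create(_["upper"] = upper, _["time"] = t);
}

// hooks used by the model code
void twostepr_sample_fpt(double a, double v, int *upper, double *t) {
  sample_fpt_one(a, v, upper, t);
}
double twostepr_wfpt_logdens_chosen(double t, double a, double delta,
                                    double eps, double floor_dens) {
  // log density of first passage at the boundary assigned to the chosen
  // option, with drift `delta` towards that boundary (start a/2)
  double dens = (t > 0.0) ? wfpt_density_lower(t, a, -delta, 0.5, eps) : 0.0;
  if (!(dens > floor_dens)) dens = floor_dens;
  return std::log(dens);
}
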