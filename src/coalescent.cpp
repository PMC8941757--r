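#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-exponential demography, time in generations measured backwards.
// Epoch matrix columns: t_start, N_start, g with N(t) = N_start * exp(g * (t - t_start)).
// Coalescent rate for k lineages at time t is choose(k,2) / (2 N(t)).

static int find_epoch(double s, const NumericMatrix& ep) {
  int e = ep.nrow() - 1;
  while (e > 0 && ep(e, 0) > s) --e;
  return e;
}

// Invert the integrated coalescent intensity: returns the time of the next
// coalescence for k lineages starting at time s, given a unit-exponential
// deviate drawn from R's RNG. Carries leftover intensity across epoch
// boundaries; closed form within each epoch.
static double next_coal_time(int k, double s, const NumericMatrix& ep) {
  double E = exp_rand();
  const double pair = 0.5 * (double)k * (double)(k - 1);
  const int ne = ep.nrow();
  int e = find_epoch(s, ep);
  double cur = s;
  for (;;) {
    const double t0 = ep(e, 0), N0 = ep(e, 1), g = ep(e, 2);
    const double b = (e + 1 < ne) ? ep(e + 1, 0) : R_PosInf;
    if (g == 0.0) {
      const double rate = pair / (2.0 * N0);
      const double cap = (b == R_PosInf) ? R_PosInf : rate * (b - cur);
      if (E <= cap) return cur + E / rate;
      E -= cap;
    } else {
      // intensity from cur to t: pair/(2 N0 g) * (exp(-g (cur-t0)) - exp(-g (t-t0)))
      const double A = std::exp(-g * (cur - t0));
      double cap;
      if (b == R_PosInf) {
        cap = (g < 0.0) ? R_PosInf : pair / (2.0 * N0 * g) * A;
      } else {
        cap = pair / (2.0 * N0 * g) * (A - std::exp(-g * (b - t0)));
      }
      if (E <= cap) {
        const double X = A - E * 2.0 * N0 * g / pair;
        return t0 - std::log(X) / g;
      }
      E -= cap;
    }
    if (e + 1 >= ne)
      stop("coalescent intensity diverges: terminal epoch never coalesces");
    ++e;
    cur = ep(e, 0);
  }
}

// [[Rcpp::export(name = ".cppCoalTime")]]
double cpp_coal_time(int k, double t_now, NumericMatrix epochs) {
  if (k < 2) stop("k must be >= 2");
  return next_coal_time(k, t_now, epochs);
}

// One genealogy for n tips; accumulates branch length subtending exactly i
// tips into cls[i-1], i = 1..n-1.
static void genealogy_lengths(int n, const NumericMatrix& ep, double* cls) {
  std::vector<int> size(n, 1);
  int k = n;
  double t = 0.0;
  while (k > 1) {
    const double tn = next_coal_time(k, t, ep);
    const double dt = tn - t;
    for (int i = 0; i < k; ++i) cls[size[i] - 1] += dt;
    int a = (int)(unif_rand() * k);
    if (a >= k) a = k - 1;
    int b = (int)(unif_rand() * (k - 1));
    if (b >= k - 1) b = k - 2;
    if (b >= a) ++b;
    size[a] += size[b];
    size[b] = size[k - 1];
    --k;
    t = tn;
  }
}

// [[Rcpp::export(name = ".cppGenealogyLengths")]]
NumericVector cpp_genealogy_lengths(int n, NumericMatrix epochs) {
  if (n < 2) stop("n must be >= 2");
  NumericVector cls(n - 1);
  genealogy_lengths(n, epochs, REAL(cls));
  return cls;
}

// Mean per-class branch lengths (generations) over `reps` genealogies.
// [[Rcpp::export(name = ".cppMeanLengths")]]
NumericVector cpp_mean_lengths(int n, NumericMatrix epochs, int reps) {
  if (n < 2) stop("n must be >= 2");
  if (reps < 1) stop("reps must be >= 1");
  NumericVector acc(n - 1);
  std::vector<double> cls(n - 1);
  for (int r = 0; r < reps; ++r) {
    std::fill(cls.begin(), cls.end(), 0.0);
    genealogy_lengths(n, epochs, cls.data());
    for (int i = 0; i < n - 1; ++i) acc[i] += cls[i];
  }
  for (int i = 0; i < n - 1; ++i) acc[i] /= (double)reps;
  return acc;
}

// Infinite-sites SFS over unlinked loci: one genealogy per locus, locus
// mutation count Poisson(theta_locus * total length), mutations placed on a
// branch class with probability proportional to its length. Returns counts
// for frequency classes 1..n-1 (monomorphic classes handled by the caller).
// [[Rcpp::export(name = ".cppSimulateSfs")]]
NumericVector cpp_simulate_sfs(int n, NumericMatrix epochs, int num_loci,
                               double theta_locus) {
  if (n < 2) stop("n must be >= 2");
  if (num_loci < 1) stop("num_loci must be >= 1");
  if (theta_locus < 0) stop("mutation input must be non-negative");
  NumericVector out(n - 1);
  std::vector<double> cls(n - 1);
  for (int l = 0; l < num_loci; ++l) {
    std::fill(cls.begin(), cls.end(), 0.0);
    genealogy_lengths(n, epochs, cls.data());
    double total = 0.0;
    for (int i = 0; i < n - 1; ++i) total += cls[i];
    if (theta_locus == 0.0 || total <= 0.0) continue;
    const int S = (int)R::rpois(theta_locus * total);
    for (int m = 0; m < S; ++m) {
      double u = unif_rand() * total, c = 0.0;
      int i = 0;
      for (; i < n - 2; ++i) {
        c += cls[i];
        if (u <= c) break;
      }
      out[i] += 1.0;
    }
  }
  return out;
}
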