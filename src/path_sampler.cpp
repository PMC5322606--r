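// Endpoint-conditioned CTMC path sampling by uniformization.
//
// The chain with rate matrix Q is embedded in a Poisson process of rate
// mu >= max_i |q_ii| with jump matrix R = I + Q/mu (self-jumps allowed).
// Conditional on endpoints (a, b) and elapsed time T, the number of
// auxiliary jumps n has pmf proportional to Pois(n; mu T) * (R^n)[a, b];
// given n, the jump chain is a discrete Markov bridge from a to b and jump
// times are n uniform order statistics on [0, T]. Dwelling times and true
// (state-changing) transition counts follow directly; self-jumps only
// refine the time grid. Uses R's RNG, so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Uniformization {
  int s;
  double muT;
  std::vector<NumericMatrix> Rpow;  // R^0 .. R^nmax
  std::vector<double> w;            // Pois(n; muT) * (R^n)[a,b]
  double w_total;                   // ~ P_ab(T), up to truncation
};

NumericMatrix mat_mult(const NumericMatrix& A, const NumericMatrix& B) {
  int s = A.nrow();
  NumericMatrix C(s, s);
  for (int i = 0; i < s; ++i)
    for (int k = 0; k < s; ++k) {
      double aik = A(i, k);
      if (aik == 0.0) continue;
      for (int j = 0; j < s; ++j) C(i, j) += aik * B(k, j);
    }
  return C;
}

// Truncated jump-count distribution for endpoints (a, b).
Uniformization setup(const NumericMatrix& Rmat, double mu, double T,
                     int a, int b) {
  Uniformization u;
  u.s = Rmat.nrow();
  u.muT = mu * T;
  NumericMatrix id(u.s, u.s);
  for (int i = 0; i < u.s; ++i) id(i, i) = 1.0;
  u.Rpow.push_back(id);
  double pois = std::exp(-u.muT);  // Pois(0)
  double pois_cum = pois;
  u.w.push_back(pois * u.Rpow[0](a, b));
  u.w_total = u.w[0];
  int n = 0;
  const int cap = 100000;
  while ((1.0 - pois_cum) > 1e-14 && n < cap) {
    ++n;
    u.Rpow.push_back(mat_mult(u.Rpow[n - 1], Rmat));
    pois *= u.muT / n;
    pois_cum += pois;
    u.w.push_back(pois * u.Rpow[n](a, b));
    u.w_total += u.w[n];
  }
  return u;
}

int sample_jump_count(const Uniformization& u) {
  double x = unif_rand() * u.w_total;
  double cum = 0.0;
  for (size_t n = 0; n < u.w.size(); ++n) {
    cum += u.w[n];
    if (x <= cum) return static_cast<int>(n);
  }
  return static_cast<int>(u.w.size()) - 1;
}

int sample_categorical(const std::vector<double>& p, double total) {
  double x = unif_rand() * total;
  double cum = 0.0;
  for (size_t j = 0; j + 1 < p.size(); ++j) {
    cum += p[j];
    if (x <= cum) return static_cast<int>(j);
  }
  return static_cast<int>(p.size()) - 1;
}

// One bridge realization: fills the jump-chain states (length n+1) given
// endpoints; states may repeat (virtual jumps).
void sample_bridge(const Uniformization& u, const NumericMatrix& Rmat,
                   int a, int b, int n, std::vector<int>& v) {
  v.resize(n + 1);
  v[0] = a;
  if (n == 0) return;
  v[n] = b;
  std::vector<double> p(u.s);
  for (int t = 1; t < n; ++t) {
    double tot = 0.0;
    for (int j = 0; j < u.s; ++j) {
      p[j] = Rmat(v[t - 1], j) * u.Rpow[n - t](j, b);
      tot += p[j];
    }
    v[t] = sample_categorical(p, tot);
  }
}

}  // namespace

// Bulk sampler: nreps endpoint-conditioned paths on one branch; returns
// realized per-state dwelling times and pairwise transition counts
// (row-major index i * s + j, 0-based) per replicate.
// [[Rcpp::export]]
List ec_sample_bulk_cpp(NumericMatrix Rmat, double mu, double T,
                        int a, int b, int nreps) {
  int s = Rmat.nrow();
  NumericMatrix dwell(nreps, s);
  IntegerMatrix trans(nreps, s * s);
  if (T <= 0.0 || mu <= 0.0) {
    if (a != b) stop("impossible endpoints: a != b with no time or no rate");
    for (int r = 0; r < nreps; ++r) dwell(r, a) = T;
    return List::create(_["dwell"] = dwell, _["trans"] = trans);
  }
  Uniformization u = setup(Rmat, mu, T, a, b);
  if (u.w_total <= 0.0) stop("impossible endpoints: P_ab(T) = 0");
  std::vector<int> v;
  std::vector<double> times;
  for (int r = 0; r < nreps; ++r) {
    int n = sample_jump_count(u);
    sample_bridge(u, Rmat, a, b, n, v);
    times.resize(n + 2);
    times[0] = 0.0;
    for (int t = 1; t <= n; ++t) times[t] = unif_rand() * T;
    times[n + 1] = T;
    std::sort(times.begin() + 1, times.begin() + n + 1);
    for (int t = 0; t <= n; ++t) {
      dwell(r, v[t]) += times[t + 1] - times[t];
      if (t > 0 && v[t] != v[t - 1]) trans(r, v[t - 1] * s + v[t]) += 1;
    }
  }
  return List::create(_["dwell"] = dwell, _["trans"] = trans);
}

// Single path with explicit segments: consecutive equal states collapsed.
// [[Rcpp::export]]
List ec_sample_path_cpp(NumericMatrix Rmat, double mu, double T,
                        int a, int b) {
  if (T <= 0.0 || mu <= 0.0) {
    if (a != b) stop("impossible endpoints: a != b with no time or no rate");
    return List::create(_["state"] = IntegerVector::create(a),
                        _["duration"] = NumericVector::create(T));
  }
  Uniformization u = setup(Rmat, mu, T, a, b);
  if (u.w_total <= 0.0) stop("impossible endpoints: P_ab(T) = 0");
  int n = sample_jump_count(u);
  std::vector<int> v;
  sample_bridge(u, Rmat, a, b, n, v);
  std::vector<double> times(n + 2);
  times[0] = 0.0;
  for (int t = 1; t <= n; ++t) times[t] = unif_rand() * T;
  times[n + 1] = T;
  std::sort(times.begin() + 1, times.begin() + n + 1);
  std::vector<int> states;
  std::vector<double> durations;
  for (int t = 0; t <= n; ++t) {
    double d = times[t + 1] - times[t];
    if (!states.empty() && v[t] == states.back()) {
      durations.back() += d;  // collapse virtual (self-)jumps
    } else {
      states.push_back(v[t]);
      durations.push_back(d);
    }
  }
  return List::create(_["state"] = wrap(states),
                      _["duration"] = wrap(durations));
}
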