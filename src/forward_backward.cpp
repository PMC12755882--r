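#include <Rcpp.h>
using namespace Rcpp;

// Exact forward-backward pass for one trial of the sequential-event
// model. Events are ordered, t_1 < ... < t_N; stage i (0..N) has a
// discretized duration pmf Pt(d, i) for d = 1..T; event i has evidence
// f_i(t) = exp(logf(t, i)). The joint over placements is
//   p(t_1..t_N) prop. to  prod_i Pt(t_i - t_{i-1}, i-1) f_i(t_i)
// with t_0 = 0 and a terminal factor Pt(T - t_N, N).
// Per-stage rescaling keeps the recursion in the linear domain without
// underflow for trials up to ~1e4 samples.
//
// logf: T x N log evidence (-Inf at masked samples)
// Pt:   Tmax x (N+1) duration pmfs (row = duration 1..Tmax, col = stage)
// dmax: per-stage kernel truncation (durations beyond carry ~0 mass)
// [[Rcpp::export]]
List fb_trial(NumericMatrix logf, NumericMatrix Pt, IntegerVector dmax) {
  const int T = logf.nrow();
  const int N = logf.ncol();
  if (Pt.ncol() != N + 1 || Pt.nrow() < T)
    stop("Pt must be Tmax x (N+1) with Tmax >= T");

  // shift evidence per event for numerical safety
  std::vector<double> cmax(N);
  NumericMatrix f(T, N);
  for (int i = 0; i < N; ++i) {
    const double* lf = &logf(0, i);
    double m = R_NegInf;
    for (int t = 0; t < T; ++t) if (lf[t] > m) m = lf[t];
    if (!R_finite(m)) stop("event %d has no admissible sample", i + 1);
    cmax[i] = m;
    double* fi = &f(0, i);
    for (int t = 0; t < T; ++t) {
      double v = lf[t] - m;
      fi[t] = R_finite(v) ? std::exp(v) : 0.0;
    }
  }

  NumericMatrix a(T, N), b(T, N);
  std::vector<double> csum(N);

  // forward
  {
    const double* P0 = &Pt(0, 0);
    const double* f0 = &f(0, 0);
    double* a0 = &a(0, 0);
    double s = 0.0;
    for (int t = 0; t < T; ++t) { a0[t] = P0[t] * f0[t]; s += a0[t]; }
    if (s <= 0) stop("forward pass vanished at event 1");
    csum[0] = s;
    for (int t = 0; t < T; ++t) a0[t] /= s;
  }
  for (int i = 1; i < N; ++i) {
    const int dm = dmax[i] < T ? dmax[i] : T;
    const double* Pi = &Pt(0, i);
    const double* fi = &f(0, i);
    const double* ap = &a(0, i - 1);
    double* ai = &a(0, i);
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      if (fi[t] == 0.0) { ai[t] = 0.0; continue; }
      double acc = 0.0;
      const int lo = t - dm < 0 ? 0 : t - dm; // duration t - tp in 1..dm
      for (int tp = lo; tp < t; ++tp)
        acc += ap[tp] * Pi[t - tp - 1];
      ai[t] = acc * fi[t];
      s += ai[t];
    }
    if (s <= 0) stop("forward pass vanished at event %d", i + 1);
    csum[i] = s;
    for (int t = 0; t < T; ++t) ai[t] /= s;
  }

  // terminal stage: duration T - t (sample index t is 0-based)
  const double* PN = &Pt(0, N);
  double lik = 0.0;
  for (int t = 0; t < T - 1; ++t) lik += a(t, N - 1) * PN[T - t - 2];
  if (lik <= 0) stop("likelihood vanished at the terminal stage");
  double loglik = std::log(lik);
  for (int i = 0; i < N; ++i) loglik += std::log(csum[i]) + cmax[i];

  // backward (scaling irrelevant: gamma renormalized per event)
  {
    double* bN = &b(0, N - 1);
    for (int t = 0; t < T; ++t)
      bN[t] = (T - t - 2 >= 0) ? PN[T - t - 2] : 0.0;
  }
  for (int i = N - 2; i >= 0; --i) {
    const int dm = dmax[i + 1] < T ? dmax[i + 1] : T;
    const double* Pi = &Pt(0, i + 1);
    const double* fn = &f(0, i + 1);
    const double* bn = &b(0, i + 1);
    double* bi = &b(0, i);
    double bmx = 0.0;
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      const int hi = t + dm < T - 1 ? t + dm : T - 1;
      for (int tn = t + 1; tn <= hi; ++tn)
        acc += Pi[tn - t - 1] * fn[tn] * bn[tn];
      bi[t] = acc;
      if (acc > bmx) bmx = acc;
    }
    if (bmx <= 0) stop("backward pass vanished at event %d", i + 1);
    for (int t = 0; t < T; ++t) bi[t] /= bmx;
  }

  NumericMatrix gam(T, N);
  for (int i = 0; i < N; ++i) {
    const double* ai = &a(0, i);
    const double* bi = &b(0, i);
    double* gi = &gam(0, i);
    double z = 0.0;
    for (int t = 0; t < T; ++t) { gi[t] = ai[t] * bi[t]; z += gi[t]; }
    if (z <= 0) stop("posterior vanished at event %d", i + 1);
    for (int t = 0; t < T; ++t) gi[t] /= z;
  }

  return List::create(_["gamma"] = gam, _["loglik"] = loglik);
}
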