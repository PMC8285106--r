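#include <Rcpp.h>
using namespace Rcpp;

// Exact L0-penalized changepoint deconvolution for calcium traces.
//
// Model: within a segment starting at s, the fitted calcium follows
// c_u = h * g^(u-s) (geometric decay with per-frame factor g). The
// objective is 0.5 * sum_t (y_t - c_t)^2 + lam * (#segments - 1).
// Segment cost has the closed form
//   C(s,t) = 0.5 * ( D - A^2 / B ),
//   A = sum_{u=s}^{t} y_u g^(u-s),  B = sum_{k=0}^{t-s} g^(2k),
//   D = sum_{u=s}^{t} y_u^2.
// The DP over last-segment starts is exact; candidates are pruned with the
// PELT condition F[s] + C(s,t) >= F[t+1] (with an extra lam margin for the
// penalty-free first segment, whose future penalty never cancels in the
// comparison). Exactness holds because the segment cost is superadditive
// under concatenation (a single decay profile fitted across a split never
// beats fitting each side separately).

// [[Rcpp::export]]
List l0_dp_cpp(NumericVector y, double gamma, double lam) {
  const int T = y.size();
  if (T == 0) {
    return List::create(_["cost"] = 0.0,
                        _["seg_starts"] = IntegerVector(0),
                        _["fit"] = NumericVector(0),
                        _["seg_h"] = NumericVector(0));
  }
  const double g2 = gamma * gamma;

  std::vector<double> D(T + 1, 0.0);
  for (int t = 0; t < T; ++t) D[t + 1] = D[t] + y[t] * y[t];
  std::vector<double> B(T + 1, 0.0);
  {
    double gp = 1.0;
    for (int len = 1; len <= T; ++len) { B[len] = B[len - 1] + gp; gp *= g2; }
  }

  std::vector<double> F(T + 1, 0.0);       // F[t]: optimal cost of y[0..t-1]
  std::vector<int> last_start(T + 1, 0);   // argmin start of final segment
  std::vector<double> A(T, 0.0), P(T, 0.0);
  std::vector<double> base(T, 0.0);        // F[s] + cost(s, t) per candidate
  std::vector<int> cand; cand.reserve(1024);

  for (int t = 0; t < T; ++t) {
    cand.push_back(t);
    A[t] = 0.0; P[t] = 1.0;
    const double Dt = D[t + 1];
    double best = R_PosInf; int best_s = t;
    for (size_t i = 0; i < cand.size(); ++i) {
      const int s = cand[i];
      const double a = A[s] + y[t] * P[s];
      A[s] = a;
      P[s] *= gamma;
      const double b = F[s] + 0.5 * ((Dt - D[s]) - a * a / B[t - s + 1]);
      base[s] = b;
      const double tot = b + (s > 0 ? lam : 0.0);
      if (tot < best) { best = tot; best_s = s; }
    }
    F[t + 1] = best;
    last_start[t + 1] = best_s;
    // prune candidates that can never win again; only the penalty-free
    // first segment (s = 0) needs the extra lam margin
    size_t w = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      const int s = cand[i];
      const double cut = (s == 0) ? best + lam : best;
      if (base[s] < cut) cand[w++] = s;
    }
    if (w == 0) cand[w++] = best_s;
    cand.resize(w);
  }

  // traceback
  std::vector<int> starts;
  int t = T;
  while (t > 0) {
    const int s = last_start[t];
    starts.push_back(s);
    t = s;
  }
  std::reverse(starts.begin(), starts.end());

  const int K = starts.size();
  NumericVector fit(T), seg_h(K);
  IntegerVector seg_starts(K);
  for (int j = 0; j < K; ++j) {
    const int s = starts[j];
    const int e = (j + 1 < K) ? starts[j + 1] - 1 : T - 1;
    double a = 0.0, p = 1.0;
    const int len = e - s + 1;
    for (int u = s; u <= e; ++u) { a += y[u] * p; p *= gamma; }
    const double h = a / B[len];
    seg_h[j] = h;
    double c = h;
    for (int u = s; u <= e; ++u) { fit[u] = c; c *= gamma; }
    seg_starts[j] = s + 1;  // 1-based
  }

  return List::create(_["cost"] = F[T],
                      _["seg_starts"] = seg_starts,
                      _["fit"] = fit,
                      _["seg_h"] = seg_h);
}

// Non-negative deconvolution (OASIS-style pool adjacent violators, no
// sparsity penalty). Solves min 0.5*||y - c||^2 s.t. c_t >= g*c_{t-1},
// c_1 >= 0; the event train is s_t = c_t - g*c_{t-1} >= 0. Pools carry
// (v, w, l, gl = g^l); the fitted pool value is h = v / w with
// c_u = h * g^(u - pool_start). Merging is triggered whenever the boundary
// event would be negative. A final forward sweep clamps pool values below
// the decayed floor of their predecessor (binds only on predominantly
// negative stretches of noise, where amplitudes are ~0 anyway).

// [[Rcpp::export]]
NumericVector oasis_nnd_cpp(NumericVector y, double gamma) {
  const int T = y.size();
  NumericVector c(T);
  if (T == 0) return c;

  std::vector<double> v; v.reserve(T);
  std::vector<double> w; w.reserve(T);
  std::vector<int> start; start.reserve(T);
  std::vector<int> len; len.reserve(T);
  std::vector<double> gl; gl.reserve(T);

  for (int t = 0; t < T; ++t) {
    v.push_back(y[t]); w.push_back(1.0); start.push_back(t);
    len.push_back(1); gl.push_back(gamma);
    while (v.size() > 1) {
      const size_t q = v.size() - 1, p = q - 1;
      const double hp = v[p] / w[p], hq = v[q] / w[q];
      if (hq >= gl[p] * hp) break;  // boundary event non-negative
      v[p] += gl[p] * v[q];
      w[p] += gl[p] * gl[p] * w[q];
      len[p] += len[q];
      gl[p] *= gl[q];
      v.pop_back(); w.pop_back(); start.pop_back(); len.pop_back(); gl.pop_back();
    }
  }

  double prev_end = 0.0;  // calcium value at the last frame of previous pool
  for (size_t i = 0; i < v.size(); ++i) {
    double h = v[i] / w[i];
    const double floor_h = gamma * prev_end;
    if (h < floor_h) h = floor_h;
    double cu = h;
    for (int u = start[i]; u < start[i] + len[i]; ++u) {
      c[u] = cu;
      prev_end = cu;
      cu *= gamma;
    }
  }
  return c;
}
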