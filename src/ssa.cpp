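#include <Rcpp.h>
using namespace Rcpp;

// State-dependent reaction rates shared by all SSA entry points.
// kind: 1 = native (m is ComS), 2 = synex (m is MecA).
// par layouts match the field order documented in the R parameter builders.
static inline void rates(int kind, const double *p, double n, double m,
                         double &g, double &q, double &r, double &s) {
  // common ComK production: alpha_k + beta_k n^h / (k_k^h + n^h)
  double nh = std::pow(n, p[3]);
  double kh = std::pow(p[2], p[3]);
  g = p[0] + p[1] * nh / (kh + nh);
  if (kind == 1) {
    double u = std::pow(n / p[6], p[7]);
    q = p[4] + p[5] / (1.0 + u);
    double den = 1.0 + n / p[10] + m / p[11];
    r = p[8] / den + p[12];
    s = p[9] / den + p[13];
  } else {
    double np = std::pow(n, p[7]);
    double kp = std::pow(p[6], p[7]);
    q = p[4] + p[5] * np / (kp + np);
    r = p[8] * m + p[9];
    s = p[10];
  }
}

// Direct-method Gillespie run recording every event.
// [[Rcpp::export]]
List ssa_events(int kind, NumericVector par, double n0, double m0,
                double t_end, double max_events) {
  std::vector<double> tv, nv, mv;
  tv.reserve(1024); nv.reserve(1024); mv.reserve(1024);
  double t = 0.0, n = n0, m = m0;
  const double *p = par.begin();
  tv.push_back(t); nv.push_back(n); mv.push_back(m);
  bool absorbed = false, truncated = false;
  double g, q, r, s;
  long long events = 0;
  while (t < t_end) {
    rates(kind, p, n, m, g, q, r, s);
    double a1 = g, a2 = r * n, a3 = q, a4 = s * m;
    double tot = a1 + a2 + a3 + a4;
    if (tot <= 0.0) { absorbed = true; break; }
    double u1 = unif_rand();
    t += -std::log(u1) / tot;
    if (t >= t_end) break;
    double u2 = unif_rand() * tot;
    if (u2 < a1)                 n += 1.0;
    else if (u2 < a1 + a2)       n -= 1.0;
    else if (u2 < a1 + a2 + a3)  m += 1.0;
    else                         m -= 1.0;
    tv.push_back(t); nv.push_back(n); mv.push_back(m);
    if (++events >= (long long)max_events) { truncated = true; break; }
  }
  return List::create(_["times"] = wrap(tv), _["n"] = wrap(nv),
                      _["m"] = wrap(mv), _["absorbed"] = absorbed,
                      _["truncated"] = truncated, _["t_final"] = t);
}

// Time-weighted occupancy histogram over (n, m), without storing the path.
// States beyond (n_max, m_max) are clamped into the outermost bin.
// [[Rcpp::export]]
NumericMatrix ssa_occupancy(int kind, NumericVector par, double n0, double m0,
                            double t_end, double burnin, int n_max, int m_max) {
  NumericMatrix H(n_max + 1, m_max + 1);
  double t = 0.0, n = n0, m = m0;
  const double *p = par.begin();
  double g, q, r, s;
  while (t < t_end) {
    rates(kind, p, n, m, g, q, r, s);
    double a1 = g, a2 = r * n, a3 = q, a4 = s * m;
    double tot = a1 + a2 + a3 + a4;
    double t_next;
    if (tot <= 0.0) t_next = t_end;
    else t_next = t + (-std::log(unif_rand()) / tot);
    double lo = std::max(t, burnin);
    double hi = std::min(t_next, t_end);
    if (hi > lo) {
      int i = (int)std::min(n, (double)n_max);
      int j = (int)std::min(m, (double)m_max);
      H(i, j) += hi - lo;
    }
    if (tot <= 0.0 || t_next >= t_end) break;
    t = t_next;
    double u2 = unif_rand() * tot;
    if (u2 < a1)                 n += 1.0;
    else if (u2 < a1 + a2)       n -= 1.0;
    else if (u2 < a1 + a2 + a3)  m += 1.0;
    else                         m -= 1.0;
  }
  double total = 0.0;
  for (int i = 0; i <= n_max; ++i) for (int j = 0; j <= m_max; ++j) total += H(i, j);
  if (total > 0.0)
    for (int i = 0; i <= n_max; ++i) for (int j = 0; j <= m_max; ++j) H(i, j) /= total;
  return H;
}

// Single path sampled at given times (zero-order hold), without storing events.
// [[Rcpp::export]]
NumericMatrix ssa_sample(int kind, NumericVector par, double n0, double m0,
                         NumericVector times) {
  int L = times.size();
  NumericMatrix out(L, 2);
  double t = 0.0, n = n0, m = m0;
  const double *p = par.begin();
  double g, q, r, s;
  int k = 0;
  double t_end = times[L - 1];
  while (k < L) {
    rates(kind, p, n, m, g, q, r, s);
    double a1 = g, a2 = r * n, a3 = q, a4 = s * m;
    double tot = a1 + a2 + a3 + a4;
    double t_next = (tot <= 0.0) ? (t_end + 1.0)
                                 : t + (-std::log(unif_rand()) / tot);
    while (k < L && times[k] < t_next) { out(k, 0) = n; out(k, 1) = m; ++k; }
    if (tot <= 0.0) break;
    t = t_next;
    double u2 = unif_rand() * tot;
    if (u2 < a1)                 n += 1.0;
    else if (u2 < a1 + a2)       n -= 1.0;
    else if (u2 < a1 + a2 + a3)  m += 1.0;
    else                         m -= 1.0;
  }
  return out;
}
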