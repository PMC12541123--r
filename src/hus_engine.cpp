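#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-arm Q = int_0^T S(t)^l1 * Ubar(t)^l2 dt for one treatment arm.
//
// time/event: follow-up time (months, truncated at horizon) and death flag.
// U: n x K matrix of utility values at the visit grid, already imputed;
//    NA entries are ignored (visits after the subject's departure).
// visits: the K visit times (increasing).
//
// Ubar(t) is the mean over the risk set {i : time_i >= t} of each subject's
// piecewise-linear trajectory through their visit values (constant beyond the
// first/last usable visit). S(t) is the Kaplan-Meier estimate (deaths before
// censorings at tied times). Both are simple on the segments cut by the union
// of departure times and visit times, so the integral is exact per segment:
// S^l1 constant, Ubar linear => closed form for int (a+bt)^l2 dt.
//
// Conventions (documented in the package):
//  - a subject still contributes to Ubar at its own departure time;
//  - past the last departure Ubar is carried forward (group-level LOCF);
//  - wherever S(t) = 0 the integrand is defined as 0.

static inline double traj_eval(const NumericMatrix& U, int i,
                               const NumericVector& visits, double t) {
  // piecewise-linear through the subject's non-NA knots (the imputation step
  // leaves NA exactly at visits after the subject's departure), constant
  // extrapolation outside
  int K = visits.size();
  double prev_t = NA_REAL, prev_v = NA_REAL;
  for (int k = 0; k < K; ++k) {
    double v = U(i, k);
    if (NumericVector::is_na(v)) continue;
    if (visits[k] >= t) {
      if (NumericVector::is_na(prev_t)) return v;        // before first knot
      double dt = visits[k] - prev_t;
      if (dt <= 0) return v;
      return prev_v + (v - prev_v) * (t - prev_t) / dt;  // interior
    }
    prev_t = visits[k];
    prev_v = v;
  }
  return prev_v;  // after last knot (NA only if subject has no usable knot)
}

// [[Rcpp::export(name = ".hus_q_arm_cpp")]]
double hus_q_arm_cpp(NumericVector time, IntegerVector event,
                     NumericMatrix U, NumericVector visits,
                     double horizon, double lambda1, double lambda2) {
  int n = time.size();
  if (n < 1) stop("empty arm");

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });

  // Kaplan-Meier over sorted times
  std::vector<double> jt;  // jump (death) times
  std::vector<double> sv;  // S value after each jump
  {
    double S = 1.0;
    int i = 0, at_risk = n;
    while (i < n) {
      double t0 = time[ord[i]];
      int d = 0, c = 0;
      while (i < n && time[ord[i]] == t0) {
        if (event[ord[i]] == 1) ++d; else ++c;
        ++i;
      }
      if (d > 0) {
        S *= 1.0 - (double)d / at_risk;
        jt.push_back(t0);
        sv.push_back(S);
      }
      at_risk -= d + c;
    }
  }

  // breakpoints: 0, departure times, visit times (<= horizon), horizon
  std::vector<double> bp;
  bp.reserve(n + visits.size() + 2);
  bp.push_back(0.0);
  bp.push_back(horizon);
  for (int i = 0; i < n; ++i)
    if (time[i] > 0 && time[i] <= horizon) bp.push_back(time[i]);
  for (int k = 0; k < visits.size(); ++k)
    if (visits[k] > 0 && visits[k] < horizon) bp.push_back(visits[k]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  int m = (int)bp.size();
  double Q = 0.0;
  int lo = 0;          // first index in ord with time >= current b_right
  size_t jk = 0;       // KM sweep pointer
  double S = 1.0;
  double locf = NA_REAL;  // last risk-set mean (carried past the last departure)

  for (int j = 0; j + 1 < m; ++j) {
    double a = bp[j], b = bp[j + 1];
    // S on (a, b): right-continuous step, advance past jumps <= a
    while (jk < jt.size() && jt[jk] <= a) { S = sv[jk]; ++jk; }
    if (S <= 0.0) break;  // integrand defined as 0 from here on

    while (lo < n && time[ord[lo]] < b) ++lo;
    double va, vb;
    if (lo >= n) {                 // risk set empty: carry Ubar forward
      va = vb = locf;
      if (NumericVector::is_na(va)) stop("risk set empty with no prior mean");
    } else {
      double sa = 0.0, sb = 0.0;
      int cnt = 0;
      for (int r = lo; r < n; ++r) {
        int i = ord[r];
        double e1 = traj_eval(U, i, visits, a);
        double e2 = traj_eval(U, i, visits, b);
        if (NumericVector::is_na(e1) || NumericVector::is_na(e2))
          stop("subject with no usable utility knot (impute first)");
        sa += e1; sb += e2; ++cnt;
      }
      va = sa / cnt; vb = sb / cnt;
    }
    locf = vb;

    double dt = b - a;
    double Sw = std::pow(S, lambda1);
    double seg;
    if (lambda2 == 0.0) {
      seg = dt;
    } else if (std::fabs(vb - va) < 1e-12) {
      seg = std::pow(va, lambda2) * dt;
    } else {
      double slope = (vb - va) / dt;
      seg = (std::pow(vb, lambda2 + 1.0) - std::pow(va, lambda2 + 1.0)) /
            (slope * (lambda2 + 1.0));
    }
    if (std::isnan(seg))
      stop("non-finite segment integral (negative utility with fractional lambda2?)");
    Q += Sw * seg;
  }
  return Q;
}
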