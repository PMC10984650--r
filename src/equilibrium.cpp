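#include <Rcpp.h>
using namespace Rcpp;

// Within-segment cumulative-autocorrelation inflation factor Q^2 for a
// conserved segment with heterozygous cost s and internal map length M
// (Morgans).  The per-generation retention of the association between a
// neutral allele and the segment's fitness background is
// Z = 1 - s - M (selection removes variance at rate s, internal
// recombination dissolves the association at rate M), giving
//   Q^2 = 2 / [ (1 - Z) (2 - (2 - M) Z) ].
// At M = 0 this reduces to 1/s^2, the classic background-selection limit.
// `drift` adds the per-generation dissipation of background associations by
// genetic drift (rate 1/(2N)); the equilibrium solver uses it so that the
// weak-selection limit of the within-segment reduction is neutral.
static double q2_segment_cpp(double s, double M, double drift = 0.0) {
  double Z = 1.0 - s - M - drift;
  if (Z >= 1.0) stop("q2_segment: degenerate Z >= 1 (s = %g, M = %g)", s, M);
  double denom = (1.0 - Z) * (2.0 - (2.0 - M) * Z);
  if (denom <= 0.0) stop("q2_segment: non-positive denominator (s = %g, M = %g)", s, M);
  return 2.0 / denom;
}

// Substitution-rate equation: R = 4 Nf U s / (exp(4 Nf s) - 1), continuous at
// s = 0 with limit U, computed with expm1 and an explicit underflow branch.
static double fixation_rate_cpp(double Nf, double U, double s) {
  if (s <= 0.0) return U;
  double x = 4.0 * Nf * s;
  if (x > 700.0) return 4.0 * Nf * U * s * std::exp(-x); // ~0, never NaN
  if (x < 1e-10) return U * (1.0 - x / 2.0);
  return 4.0 * Nf * U * s / std::expm1(x);
}

// Equilibrium additive fitness variance given the diploid segment mutation
// rate U, the (haploid-scale) substitution rate R and cost s.
// va_form 0: VA = (U - 2R) s  (steady-state balance of mutational input and
//            removal by substitution); 1: VA = (U - R) s (comparison form).
static double va_eq_cpp(double U, double R, double s, int va_form) {
  double v = (va_form == 1) ? (U - R) * s : (U - 2.0 * R) * s;
  return v > 0.0 ? v : 0.0;
}

struct EqSolution { double Nf, R, VA; bool converged; };

// Solve the coupled fitness-effective-size / substitution-rate system for one
// segment: Nf = N exp(-VA Q^2 / 2) with VA and R as above.  The substitution
// rate entering VA uses the haploid segment rate U/2 = mu L, so that R has
// the standard neutral limit mu L and VA -> 0 smoothly as s -> 0.
// Damped fixed-point iteration with a guaranteed bracketed-bisection
// fallback: substituting R(Nf) makes the system one-dimensional, and
// f(Nf) = N exp(-VA(Nf) Q^2/2) is decreasing in Nf, so g(Nf) = Nf - f(Nf)
// is increasing with g(0+) < 0 <= g(N): the root is unique.
static EqSolution solve_one(double N, double U, double s, double M,
                            double tol, int max_iter, int va_form) {
  EqSolution out;
  if (s <= 0.0) { // neutral segment: no fitness variance
    out.Nf = N; out.R = U / 2.0; out.VA = 0.0; out.converged = true;
    return out;
  }
  double Q2 = q2_segment_cpp(s, M, 0.5 / N);
  double Uh = U / 2.0;
  auto fmap = [&](double Nf) {
    double R = fixation_rate_cpp(Nf, Uh, s);
    double VA = va_eq_cpp(U, R, s, va_form);
    double expo = VA * Q2 / 2.0;
    return N * std::exp(-expo);
  };
  // damped fixed point
  double x = N;
  bool ok = false;
  for (int it = 0; it < max_iter; ++it) {
    double xn = 0.5 * x + 0.5 * fmap(x);
    if (std::fabs(xn - x) / N < tol) { x = xn; ok = true; break; }
    x = xn;
  }
  if (!ok) { // bracketed bisection on g(Nf) = Nf - f(Nf), increasing
    double lo = N * 1e-12, hi = N;
    for (int it = 0; it < 2000; ++it) {
      double mid = 0.5 * (lo + hi);
      if (mid - fmap(mid) < 0.0) lo = mid; else hi = mid;
      if ((hi - lo) / N < tol * 0.5) break;
    }
    x = 0.5 * (lo + hi);
  }
  out.Nf = std::min(x, N);
  out.R = fixation_rate_cpp(out.Nf, Uh, s);
  out.VA = va_eq_cpp(U, out.R, s, va_form);
  out.converged = true;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".solve_equilibrium_batch")]]
DataFrame solve_equilibrium_batch(NumericVector N, NumericVector U,
                                  NumericVector s, NumericVector M,
                                  double tol, int max_iter, int va_form) {
  if (N.size() == 0 || U.size() == 0 || s.size() == 0 || M.size() == 0)
    return DataFrame::create(_["Nf"] = NumericVector(0),
                             _["R"] = NumericVector(0),
                             _["VA"] = NumericVector(0));
  R_xlen_t n = std::max(std::max(N.size(), U.size()),
                        std::max(s.size(), M.size()));
  NumericVector Nf(n), R(n), VA(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double Ni = N[i % N.size()], Ui = U[i % U.size()];
    double si = s[i % s.size()], Mi = M[i % M.size()];
    if (Ni < 2.0) stop("solve_equilibrium: N must be >= 2");
    if (Ui < 0.0 || si < 0.0 || Mi < 0.0)
      stop("solve_equilibrium: invalid (U, s, M) = (%g, %g, %g)", Ui, si, Mi);
    EqSolution sol = solve_one(Ni, Ui, si, Mi, tol, max_iter, va_form);
    Nf[i] = sol.Nf; R[i] = sol.R; VA[i] = sol.VA;
  }
  return DataFrame::create(_["Nf"] = Nf, _["R"] = R, _["VA"] = VA);
}

//' @noRd
// [[Rcpp::export(name = ".q2_segment_cpp")]]
NumericVector q2_segment_vec(NumericVector s, NumericVector M) {
  R_xlen_t n = std::max(s.size(), M.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = q2_segment_cpp(s[i % s.size()], M[i % M.size()]);
  return out;
}
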