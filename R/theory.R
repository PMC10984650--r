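#' @useDynLib bgsmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats approx rbinom rnorm runif rpois rgamma lowess setNames
#'   qnorm quantile sd var
#' @importFrom utils read.table write.table head tail
NULL

#' Selection regime of a conserved segment
#'
#' Bundles the quantities the equilibrium theory needs for one putatively
#' conserved segment: the diploid per-generation deleterious mutation rate for
#' the whole segment \eqn{U = 2 \mu L}, the heterozygous selection cost
#' \eqn{s} (homozygotes pay \eqn{2s}; effects are multiplicative across
#' sites), the segment's internal genetic map length \eqn{M} (Morgans), its
#' physical length \eqn{L} (bp) and the per-bp mutation rate \eqn{\mu}.
#'
#' @param s heterozygous selection cost, in \eqn{[0, 1]}.
#' @param L segment length in basepairs (\eqn{\ge 1}).
#' @param mu per-bp per-generation deleterious mutation rate. Exactly one of
#'   `mu` and `U` may be omitted; the other is filled in via `U = 2*mu*L`.
#' @param U diploid per-generation deleterious mutation rate of the segment.
#' @param M internal map length in Morgans (default 0: fully linked segment).
#' @return A `bgs_segment_input` list with fields `U`, `s`, `M`, `L`, `mu`.
#' @export
segment_selection <- function(s, L, mu = NULL, U = NULL, M = 0) {
  if (is.null(U) && is.null(mu))
    stop("supply either `mu` or `U`")
  if (is.null(U)) U <- 2 * mu * L
  if (is.null(mu)) mu <- U / (2 * L)
  stopifnot(U >= 0, s >= 0, s <= 1, M >= 0, L >= 1)
  if (abs(U - 2 * mu * L) > 1e-8 * max(U, 1e-300))
    stop("inconsistent (U, mu, L): U must equal 2*mu*L")
  structure(list(U = U, s = s, M = M, L = L, mu = mu),
            class = "bgs_segment_input")
}

#' Population context for equilibrium solving
#'
#' @param N diploid drift-effective population size (individuals, \eqn{\ge 2}).
#' @param rescale optional multiplicative factor in \eqn{(0, 1]} applied to
#'   `N`, used for local rescaling of segment equilibria by a fitted
#'   reduction map.
#' @return A `bgs_population` list with fields `N` and `rescale`.
#' @export
population_context <- function(N, rescale = 1) {
  stopifnot(N >= 2, rescale > 0, rescale <= 1)
  structure(list(N = N, rescale = rescale), class = "bgs_population")
}

#' Grid axes for selection coefficients and mutation rates
#'
#' Log10-spaced grids over which segment equilibria and reduction maps are
#' tabulated. The default selection grid spans \eqn{10^{-8} \le s \le
#' 10^{-2}}; `strong = TRUE` extends it to \eqn{s = 10^{-1}}. The mutation
#' grid spans \eqn{10^{-11} \le m \le 10^{-7}} per bp per generation.
#'
#' @param s_values strictly increasing selection coefficients.
#' @param m_values strictly increasing per-bp mutation rates.
#' @param strong use the strong-selection default grid (up to \eqn{10^{-1}}).
#' @param n_m number of mutation-rate grid points (default grid only).
#' @return A `bgs_grid` list with fields `s_values`, `m_values`.
#' @export
grid_axes <- function(s_values = NULL, m_values = NULL, strong = FALSE,
                      n_m = 17) {
  if (is.null(s_values))
    s_values <- 10^seq(-8, if (strong) -1 else -2)
  if (is.null(m_values))
    m_values <- 10^seq(-11, -7, length.out = n_m)
  stopifnot(length(s_values) >= 1, length(m_values) >= 1,
            all(diff(s_values) > 0), all(diff(m_values) > 0),
            all(s_values > 0), all(m_values > 0))
  structure(list(s_values = s_values, m_values = m_values),
            class = "bgs_grid")
}

#' Cumulative autocorrelation multiplier Q for a flanking neutral site
#'
#' The perturbations a neutral allele receives from a linked block of fitness
#' variance are autocorrelated across generations with per-generation factor
#' \eqn{(1-r)(1-\kappa)}, where \eqn{r} is the recombination fraction to the
#' block and \eqn{\kappa} the per-generation decay rate of the associated
#' variance. Summing the geometric series gives the closed form
#' \deqn{Q = 1 + \sum_{t \ge 1} [(1-r)(1-\kappa)]^t = 1 / (\kappa + r(1 -
#' \kappa)).}
#'
#' @param kappa per-generation variance decay rate, in \eqn{(0, 1]}.
#' @param r recombination fraction, in \eqn{[0, 0.5]}.
#' @return Q (vectorized), always \eqn{\ge 1}, with equality iff `kappa = 1`.
#' @export
q_flank <- function(kappa, r) {
  stopifnot(all(kappa >= 0), all(kappa <= 1), all(r >= 0), all(r <= 0.5))
  if (any(kappa == 0 & r == 0))
    stop("q_flank: kappa = 0 with r = 0 gives a divergent series")
  1 / (kappa + r * (1 - kappa))
}

#' Within-segment inflation factor Q^2
#'
#' For a neutral site inside a selected segment, the association with the
#' segment's own fitness variance is retained each generation with factor
#' \eqn{Z = 1 - s - M} (selection removes associated variance at rate
#' \eqn{s}; internal recombination of total map length \eqn{M} Morgans
#' dissolves the association), and the cumulative inflation factor is
#' \deqn{Q^2 = 2 / [(1 - Z)(2 - (2 - M) Z)].}
#' At \eqn{M = 0} this reduces to \eqn{1/s^2}, i.e. `q_flank(s, 0)^2`, the
#' classic background-selection limit.
#'
#' [solve_equilibrium()] additionally includes the dissipation of background
#' associations by drift, \eqn{Z = 1 - s - M - 1/(2N)}, which caps the
#' inflation factor near \eqn{(2N)^2} so the within-segment reduction has a
#' proper neutral limit; the term is negligible whenever \eqn{2Ns \gg 1}.
#'
#' @param seg a [segment_selection()] object, or a numeric `s` when `s`/`M`
#'   are given directly.
#' @param s,M selection cost and internal map length (used when `seg` is not
#'   a `bgs_segment_input`).
#' @return Q^2 (vectorized over `s`, `M`).
#' @export
q2_segment <- function(seg = NULL, s = NULL, M = NULL) {
  if (inherits(seg, "bgs_segment_input")) {
    s <- seg$s; M <- seg$M
  } else if (is.null(s)) {
    s <- seg
    if (is.null(M)) M <- 0
  }
  if (is.null(M)) M <- 0
  if (any(s <= 0 & M <= 0))
    stop("q2_segment: degenerate Z >= 1 for (s = 0, M = 0)")
  .q2_segment_cpp(as.numeric(s), as.numeric(M))
}

#' Deleterious substitution rate given a fitness-effective size
#'
#' The substitution-rate equation \eqn{R = 4 N_f U s / (e^{4 N_f s} - 1)},
#' continuous at \eqn{s = 0} via the limit \eqn{R \to U}, strictly decreasing
#' in \eqn{s}, evaluated with `expm1` and an underflow branch so the strong
#' selection regime returns 0 rather than NaN.
#'
#' @param Nf fitness-effective population size (individuals, > 0).
#' @param U mutation rate argument (per generation); the neutral limit of the
#'   returned rate equals `U`.
#' @param s heterozygous selection cost (\eqn{\ge 0}).
#' @return substitutions per generation (vectorized).
#' @export
fixation_rate <- function(Nf, U, s) {
  stopifnot(all(Nf > 0), all(U >= 0), all(s >= 0))
  k <- max(length(Nf), length(U), length(s))
  Nf <- rep_len(Nf, k); U <- rep_len(U, k); s <- rep_len(s, k)
  x <- 4 * Nf * s
  out <- numeric(k)
  tiny <- x < 1e-10
  big <- x > 700
  mid <- !tiny & !big
  out[tiny] <- U[tiny] * (1 - x[tiny] / 2)
  out[big] <- 4 * Nf[big] * U[big] * s[big] * exp(-x[big])
  out[mid] <- 4 * Nf[mid] * U[mid] * s[mid] / expm1(x[mid])
  out
}

#' Equilibrium additive fitness variance
#'
#' Steady-state additive genetic fitness variance under mutation-selection
#' balance with substitutions: \eqn{V_A = (U - 2R) s}, floored at zero. Each
#' substitution removes a segregating site's contribution, so the classic
#' balance \eqn{V_A = U s} is recovered only when \eqn{R = 0}.
#'
#' @param U diploid segment mutation rate per generation.
#' @param R substitution rate per generation (haploid scale; at most `U/2`).
#' @param s heterozygous selection cost.
#' @return \eqn{V_A} (vectorized), floored at 0; a warning is issued when
#'   `R` exceeds `U/2` beyond tolerance (convention violation).
#' @export
va_equilibrium <- function(U, R, s) {
  stopifnot(all(U >= 0), all(R >= 0), all(s >= 0))
  if (any(R > U / 2 + 1e-12 * pmax(U, 1)))
    warning("va_equilibrium: R exceeds U/2; variance clamped to 0")
  pmax((U - 2 * R) * s, 0)
}

#' Classic background-selection exponent of one segment
#'
#' Contribution of a segment to \eqn{-\log B} under the classic (strong
#' selection, no substitutions) background-selection model:
#' \deqn{\mu L s / (s + r(1-s))^2,}
#' which equals \eqn{\tfrac12 (U s)\, Q^2} with \eqn{U = 2\mu L} and
#' \eqn{Q =} [q_flank()] at \eqn{\kappa = s}.
#'
#' @param mu per-bp deleterious mutation rate.
#' @param L segment length (bp).
#' @param s heterozygous selection cost (> 0; the classic model is undefined
#'   at neutrality).
#' @param r recombination fraction between the focal site and the segment.
#' @return the exponent contribution (vectorized).
#' @export
classic_b_exponent <- function(mu, L, s, r) {
  if (any(s <= 0))
    stop("classic_b_exponent: undefined at s = 0 (classic model)")
  stopifnot(all(r >= 0), all(r <= 0.5), all(mu >= 0), all(L >= 0))
  mu * L * s / (s + r * (1 - s))^2
}

#' Solve the segment equilibrium system
#'
#' Jointly solves, for one conserved segment, the fitness-effective
#' population size equation \eqn{N_f = N \exp(-V_A Q^2 / 2)}, the
#' substitution-rate equation and the fitness-variance equation
#' \eqn{V_A = (U - 2R)s}, where \eqn{Q^2} is the within-segment inflation
#' factor [q2_segment()]. The substitution rate entering \eqn{V_A} uses the
#' haploid segment rate \eqn{U/2 = \mu L}, so \eqn{R} has the standard
#' neutral limit \eqn{\mu L} and \eqn{V_A \ge 0} holds for every \eqn{s}
#' without clamping; classic BGS is recovered exactly whenever \eqn{R
#' \approx 0}. The within-segment \eqn{Q^2} includes the drift term
#' \eqn{1/(2N)} in the retention factor (see [q2_segment()]), so
#' \eqn{N_f \to N} as \eqn{s \to 0}. After substituting \eqn{R(N_f)} the system is
#' one-dimensional and is solved by damped fixed-point iteration with a
#' guaranteed bracketed-bisection fallback (the map is monotone, so the
#' root is unique).
#'
#' @param seg a [segment_selection()] object.
#' @param pop a [population_context()] object.
#' @param tol relative convergence tolerance on \eqn{N_f / N}.
#' @param max_iter maximum fixed-point iterations before the bisection
#'   fallback engages.
#' @param va_form `"U-2R"` (default) or `"U-R"` (the alternative
#'   fitness-variance form, exposed for comparison).
#' @return A `bgs_equilibrium` list with fields `Nf`, `R`, `VA`, `B`
#'   (\eqn{N_f/N}) and `R_frac` (\eqn{R} as a fraction of the neutral rate
#'   \eqn{\mu L}, invariant to ploidy rate conventions).
#' @export
solve_equilibrium <- function(seg, pop, tol = 1e-8, max_iter = 500,
                              va_form = c("U-2R", "U-R")) {
  stopifnot(inherits(seg, "bgs_segment_input"),
            inherits(pop, "bgs_population"), tol > 0)
  va_form <- match.arg(va_form)
  N <- pop$N * pop$rescale
  sol <- .solve_equilibrium_batch(N, seg$U, seg$s, seg$M, tol, max_iter,
                                  if (va_form == "U-R") 1L else 0L)
  r_neutral <- seg$U / 2
  structure(list(Nf = sol$Nf, R = sol$R, VA = sol$VA,
                 B = sol$Nf / N,
                 R_frac = if (r_neutral > 0) sol$R / r_neutral else NA_real_),
            class = "bgs_equilibrium")
}

#' Solve segment equilibria across a (mutation, selection) grid
#'
#' Tabulates [solve_equilibrium()] for one segment across every grid cell,
#' with \eqn{U = 2 m_i L} in cell \eqn{(m_i, s_j)}.
#'
#' @param L segment length (bp).
#' @param M internal map length (Morgans).
#' @param pop a [population_context()].
#' @param grid a [grid_axes()].
#' @inheritParams solve_equilibrium
#' @return list of matrices `Nf`, `R`, `VA`, `B` with rows indexed by
#'   `s_values` and columns by `m_values`.
#' @export
solve_equilibrium_grid <- function(L, M, pop, grid, tol = 1e-8,
                                   max_iter = 500,
                                   va_form = c("U-2R", "U-R")) {
  stopifnot(inherits(pop, "bgs_population"), inherits(grid, "bgs_grid"))
  va_form <- match.arg(va_form)
  ns <- length(grid$s_values); nm <- length(grid$m_values)
  dims <- list(s = signif(grid$s_values, 6), m = signif(grid$m_values, 6))
  Nf <- R <- VA <- matrix(NA_real_, ns, nm, dimnames = dims)
  N <- pop$N * pop$rescale
  for (j in seq_len(ns)) {
    U <- 2 * grid$m_values * L
    sol <- .solve_equilibrium_batch(N, U, grid$s_values[j], M, tol,
                                    max_iter, if (va_form == "U-R") 1L else 0L)
    Nf[j, ] <- sol$Nf; R[j, ] <- sol$R; VA[j, ] <- sol$VA
  }
  list(Nf = Nf, R = R, VA = VA, B = Nf / N)
}
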