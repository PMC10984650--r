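# Composite-likelihood inference of (pi0, mu, W) from windowed pairwise
# diversity and precomputed reduction-map tensors, plus model assessment
# (in-sample and leave-one-chromosome-out R^2, block jackknife) and
# substitution-rate / divergence prediction.

#' Align a reduction map with windowed diversity for likelihood evaluation
#'
#' Collects the map's evaluation positions, their accessibility weights and
#' their window memberships into one flat structure so that
#' [composite_loglik()] can average \eqn{B(x)} exactly (position level, not
#' window level) for any candidate \eqn{(\mu, W)}.
#'
#' @param bmap a `bgs_bmap`.
#' @param windows a `bgs_windows` data frame (windows with `n = 0` are
#'   dropped).
#' @param mask optional accessibility track used to weight evaluation
#'   positions.
#' @return a `bgs_likdata` list: `logB` (matrix positions x flattened grid),
#'   `win` (window index per position), `wt` (weights), `windows`, `grid`,
#'   `classes`.
#' @export
likelihood_data <- function(bmap, windows, mask = NULL) {
  keep <- windows$n > 0
  if (!all(keep)) windows <- windows[keep, , drop = FALSE]
  if (nrow(windows) < 2)
    stop("likelihood_data: need at least two windows with data")
  ns <- length(bmap$grid$s_values); nm <- length(bmap$grid$m_values)
  K <- length(bmap$classes)
  logB_list <- list(); win_list <- list(); wt_list <- list()
  for (ch in bmap$chroms) {
    rows <- which(windows$chrom == ch)
    if (!length(rows)) next
    pos <- bmap$pos[[ch]]
    wi <- rep(NA_integer_, length(pos))
    for (r in rows)
      wi[pos >= windows$start[r] & pos < windows$end[r]] <- r
    sel <- which(!is.na(wi))
    if (!length(sel)) next
    wt <- .step_weights(ch, pos[sel], bmap$step,
                        max(windows$end[rows]), mask)
    arr <- bmap$logB[[ch]][sel, , , , drop = FALSE]
    logB_list[[ch]] <- matrix(arr, nrow = length(sel))
    win_list[[ch]] <- wi[sel]
    wt_list[[ch]] <- wt
  }
  logB <- do.call(rbind, logB_list)
  win <- unlist(win_list, use.names = FALSE)
  wt <- unlist(wt_list, use.names = FALSE)
  ok <- wt > 0
  out <- list(logB = logB[ok, , drop = FALSE], win = win[ok],
              wt = wt[ok], windows = windows, grid = bmap$grid,
              classes = bmap$classes, ns = ns, nm = nm, K = K)
  out$wt_den <- rowsum(out$wt, out$win, reorder = TRUE)
  structure(out, class = "bgs_likdata")
}

# column index into the flattened [position, s, m, class] tensor
.flat_idx <- function(ns, nm, j, i, k) j + ns * (i - 1) + ns * nm * (k - 1)

#' Mix reduction-map tensors at arbitrary mutation rates
#'
#' Evaluates \eqn{\log B(x; \mu, \mathbf W)} for a matrix \eqn{w = \mu
#' \mathbf W} (selection grid x feature classes) by interpolating each
#' class/selection layer of the precomputed tensor between the two
#' bracketing mutation-rate grid columns, then summing over selection
#' coefficients and classes. The default `"loglog"` rule interpolates
#' \eqn{\log(-\log B)} linearly in \eqn{\log_{10} m}, which is exact
#' wherever \eqn{\log B} is proportional to \eqn{m} (the strong-selection
#' regime); `"linear"` interpolates \eqn{\log B} itself. Both are exact at
#' grid nodes (returned bit-for-bit).
#'
#' @param lik a `bgs_likdata` (or `bgs_bmap`, in which case per-position
#'   values for its first chromosome are returned).
#' @param w matrix `length(s_values)` x `K` of per-class mutation rates
#'   \eqn{\mu W_{j,k}}; entries above the grid maximum are an error, entries
#'   below the minimum are clamped (their contribution is negligible).
#' @param interp interpolation rule.
#' @return vector of \eqn{\log B} per evaluation position.
#' @export
logB_mix <- function(lik, w, interp = c("loglog", "linear")) {
  interp <- match.arg(interp)
  if (inherits(lik, "bgs_bmap")) {
    ch <- lik$chroms[1]
    arr <- lik$logB[[ch]]
    lik <- list(logB = matrix(arr, nrow = dim(arr)[1]), grid = lik$grid,
                ns = dim(arr)[2], nm = dim(arr)[3], K = dim(arr)[4])
  }
  mg <- lik$grid$m_values
  ns <- lik$ns; nm <- lik$nm; K <- lik$K
  w <- matrix(w, nrow = ns, ncol = K)
  if (any(w > mg[nm] * (1 + 1e-9))) {
    bad <- which(w > mg[nm] * (1 + 1e-9), arr.ind = TRUE)[1, ]
    stop(sprintf("logB_mix: w[%d,%d] = %g above the mutation grid maximum %g",
                 bad[1], bad[2], w[bad[1], bad[2]], mg[nm]))
  }
  w <- pmax(w, mg[1])
  lx <- log10(mg)
  out <- numeric(nrow(lik$logB))
  for (k in seq_len(K)) {
    for (j in seq_len(ns)) {
      x <- log10(w[j, k])
      i <- findInterval(x, lx, rightmost.closed = TRUE)
      i <- min(max(i, 1L), nm - 1L)
      t <- (x - lx[i]) / (lx[i + 1] - lx[i])
      L1 <- lik$logB[, .flat_idx(ns, nm, j, i, k)]
      L2 <- lik$logB[, .flat_idx(ns, nm, j, i + 1L, k)]
      if (t <= 0) { out <- out + L1; next }
      if (t >= 1) { out <- out + L2; next }
      if (interp == "linear") {
        out <- out + (1 - t) * L1 + t * L2
      } else {
        v <- numeric(length(L1))
        pos <- L1 < -1e-300 & L2 < -1e-300
        v[pos] <- -exp((1 - t) * log(-L1[pos]) + t * log(-L2[pos]))
        v[!pos] <- (1 - t) * L1[!pos] + t * L2[!pos]
        out <- out + v
      }
    }
  }
  out
}

# window-averaged B for a candidate w: weighted mean of exp(logB) per window
.window_B <- function(lik, w, interp = "loglog") {
  b <- exp(logB_mix(lik, w, interp))
  num <- rowsum(b * lik$wt, lik$win, reorder = TRUE)
  den <- lik$wt_den %||% rowsum(lik$wt, lik$win, reorder = TRUE)
  bw <- rep(NA_real_, nrow(lik$windows))
  bw[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  bw
}

# profile maximum of the binomial composite likelihood over pi0 for fixed
# window means B-bar: Newton on the score sum(Y)/x - sum((n-Y) B/(1 - x B))
.profile_pi0 <- function(bw, Y, n, bounds) {
  x <- sum(Y) / sum(n * bw)
  for (it in 1:4) {
    q <- 1 - x * bw
    f <- sum(Y) / x - sum((n - Y) * bw / q)
    fp <- -sum(Y) / x^2 - sum((n - Y) * (bw / q)^2)
    xn <- x - f / fp
    if (!is.finite(xn) || xn <= 0) break
    x <- xn
  }
  min(max(x, bounds[1]), bounds[2])
}

#' Softmax DFE columns
#'
#' Maps unconstrained logits to probability-simplex columns of the DFE
#' matrix \eqn{\mathbf W}; invariant to adding a constant to any column's
#' logits.
#'
#' @param logits matrix `n_s` x `K`.
#' @return matrix of the same shape with non-negative entries and columns
#'   summing to one.
#' @export
dfe_softmax <- function(logits) {
  logits <- as.matrix(logits)
  if (ncol(logits) == 0) return(logits)
  apply(logits, 2, function(v) {
    e <- exp(v - max(v))
    e / sum(e)
  })
}

#' Composite log-likelihood of windowed diversity
#'
#' Binomial composite likelihood over windows: the number of differing
#' pairwise comparisons \eqn{Y_b} out of \eqn{n_b} is modelled as
#' Binomial\eqn{(n_b, \pi_0 \bar B(b; \mu, \mathbf W))}. Windows are treated
#' as independent (a composite, not a full, likelihood).
#'
#' @param params list with `pi0`, `mu`, `W` (matrix `n_s` x `K`).
#' @param lik a `bgs_likdata`.
#' @param interp see [logB_mix()].
#' @return the log composite likelihood (binomial coefficients omitted);
#'   `-Inf` with a `diagnostic` attribute when any window probability falls
#'   outside \eqn{(0, 1)}.
#' @export
composite_loglik <- function(params, lik, interp = "loglog") {
  W <- as.matrix(params$W)
  stopifnot(nrow(W) == lik$ns, ncol(W) == lik$K,
            all(abs(colSums(W) - 1) < 1e-6))
  bw <- .window_B(lik, params$mu * W, interp)
  p <- params$pi0 * bw
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    out <- -Inf
    attr(out, "diagnostic") <- "window probability outside (0,1)"
    return(out)
  }
  Y <- lik$windows$Y; n <- lik$windows$n
  sum(Y * log(p) + (n - Y) * log1p(-p))
}

# theta = (log10 mu, free logits); pi0 is profiled out analytically
.theta_unpack <- function(theta, ns, K) {
  mu <- 10^theta[1]
  if (K == 0)
    return(list(mu = mu, W = matrix(numeric(0), ns, 0)))
  lf <- matrix(theta[-1], nrow = ns - 1, ncol = K)
  logits <- rbind(0, lf) # reference logit fixed at 0 (smallest s)
  list(mu = mu, W = dfe_softmax(logits))
}

#' Maximum composite-likelihood fit
#'
#' Maximises [composite_loglik()] over \eqn{(\pi_0, \mu, \mathbf W)} with a
#' bounded derivative-free quadratic-model optimizer (BOBYQA). The DFE
#' columns are parameterised by softmax logits (first selection class fixed
#' as reference) and \eqn{\mu} by its log10; \eqn{\pi_0} is profiled out
#' analytically at every objective evaluation (Newton on the 1-D binomial
#' score), which removes the scale coupling between \eqn{\pi_0} and the
#' map amplitude. Starts comprise one deterministic point-mass start per
#' selection class plus seeded Dirichlet(1) random starts (\eqn{\mu}
#' log-uniform in its bounds); the best optimum is polished with a small
#' trust region.
#'
#' @param lik a `bgs_likdata`.
#' @param n_starts number of random starts (the spread of the top optima is
#'   returned as a stability diagnostic).
#' @param seed RNG seed (fits are deterministic given the seed).
#' @param mu_bounds optimisation bounds for \eqn{\mu} (default upper limit
#'   \eqn{8 \times 10^{-8}}).
#' @param pi0_bounds bounds for \eqn{\pi_0}.
#' @param interp see [logB_mix()].
#' @param logit_bound box half-width for free logits.
#' @param maxfun BOBYQA evaluation budget per start.
#' @return a `bgs_fit` list: `mle` (`pi0`, `mu`, `W`), `loglik`, `sbar`
#'   (mean selection coefficient per class), `r2` (in-sample, window-level
#'   \eqn{\pi} vs \eqn{\hat\pi}), `predicted` (per-window \eqn{\bar B} and
#'   \eqn{\hat\pi}), `top_optima` (stability diagnostic), `boundary_mu`
#'   flag, and the call ingredients needed to refit.
#' @export
fit_mle <- function(lik, n_starts = 50, seed = 1,
                    mu_bounds = c(1e-10, 8e-8), pi0_bounds = NULL,
                    interp = "loglog", logit_bound = 12, maxfun = 3000) {
  stopifnot(inherits(lik, "bgs_likdata"))
  if (nrow(lik$windows) < 2) stop("fit_mle: insufficient data (need >= 2 windows)")
  ns <- lik$ns; K <- lik$K
  Y <- lik$windows$Y; n <- lik$windows$n
  pi_raw <- sum(Y) / sum(n)
  if (is.null(pi0_bounds))
    pi0_bounds <- c(pi_raw / 20, min(20 * pi_raw, 0.99))
  nfree <- (ns - 1) * K
  lower <- c(log10(mu_bounds[1]), rep(-logit_bound, nfree))
  upper <- c(log10(mu_bounds[2]), rep(logit_bound, nfree))
  # cap w = mu * W at the mutation grid maximum via the objective
  mg_max <- max(lik$grid$m_values)
  obj <- function(theta) {
    par <- .theta_unpack(theta, ns, K)
    if (any(par$mu * par$W > mg_max)) return(1e10)
    bw <- .window_B(lik, par$mu * par$W, interp)
    pi0 <- .profile_pi0(bw, Y, n, pi0_bounds)
    p <- pi0 * bw
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) return(1e10)
    -sum(Y * log(p) + (n - Y) * log1p(-p))
  }
  bob <- function(theta0, rhobeg) {
    tryCatch(
      minqa::bobyqa(theta0, obj, lower = lower, upper = upper,
                    control = list(maxfun = maxfun, rhobeg = rhobeg,
                                   rhoend = 1e-8)),
      error = function(e) NULL)
  }
  # deterministic point-mass starts (all DFE mass on one selection class)
  # plus seeded Dirichlet(1) random starts
  pm_starts <- lapply(seq_len(ns), function(j) {
    lf <- matrix(0, ns - 1, K)
    if (j > 1) lf[j - 1, ] <- logit_bound - 2
    c(log10(1.5e-8), as.numeric(lf))
  })
  rand_starts <- .with_seed(seed, {
    lapply(seq_len(max(0, n_starts - ns)), function(st) {
      mu_0 <- 10^runif(1, log10(mu_bounds[1]), log10(mu_bounds[2]))
      dir <- matrix(rgamma(ns * K, 1), ns, K)
      dir <- sweep(dir, 2, colSums(dir), "/")
      logits <- log(pmax(dir, 1e-8))
      lf <- sweep(logits, 2, logits[1, ])[-1, , drop = FALSE]
      lf <- pmin(pmax(lf, -logit_bound + 0.1), logit_bound - 0.1)
      c(log10(mu_0), as.numeric(lf))
    })
  })
  runs <- lapply(c(pm_starts, rand_starts), function(theta0) {
    ans <- bob(theta0, rhobeg = 0.5)
    if (is.null(ans)) return(NULL)
    list(theta = ans$par, nll = ans$fval)
  })
  runs <- runs[!vapply(runs, is.null, TRUE)]
  if (!length(runs)) stop("fit_mle: all optimizer starts failed")
  nlls <- vapply(runs, `[[`, 0, "nll")
  best <- runs[[which.min(nlls)]]
  polish <- bob(best$theta, rhobeg = 0.02)
  if (!is.null(polish) && polish$fval < best$nll)
    best <- list(theta = polish$par, nll = polish$fval)
  par <- .theta_unpack(best$theta, ns, K)
  bw <- .window_B(lik, par$mu * par$W, interp)
  par$pi0 <- .profile_pi0(bw, Y, n, pi0_bounds)
  pihat <- par$pi0 * bw
  piobs <- lik$windows$Y / lik$windows$n
  r2 <- 1 - sum((piobs - pihat)^2) / sum((piobs - mean(piobs))^2)
  sbar <- colSums(par$W * lik$grid$s_values)
  names(sbar) <- lik$classes
  top <- sort(nlls)[seq_len(min(10, length(nlls)))]
  structure(list(
    mle = par, loglik = -best$nll, sbar = sbar, r2 = r2,
    predicted = data.frame(lik$windows[c("chrom", "start", "end")],
                           B = bw, pi_hat = pihat, pi_obs = piobs),
    top_optima = top, spread = diff(range(top)),
    boundary_mu = abs(log10(par$mu) - log10(mu_bounds[2])) < 1e-3,
    n_starts = n_starts, seed = seed, mu_bounds = mu_bounds,
    pi0_bounds = pi0_bounds, interp = interp, theta = best$theta),
    class = "bgs_fit")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Leave-one-chromosome-out cross-validated R^2
#'
#' For each chromosome, refits the model on all other chromosomes and
#' predicts the held-out windows' diversity; reports per-chromosome and
#' pooled \eqn{R^2_{\mathrm{LOCO}} = 1 - \sum (\pi_b - \hat\pi_b)^2 /
#' \sum (\pi_b - \bar\pi)^2} over held-out windows.
#'
#' @param bmap the `bgs_bmap` used for fitting.
#' @param windows a `bgs_windows` data frame.
#' @param mask optional accessibility track.
#' @param ... arguments passed to [fit_mle()].
#' @return list with `pooled` (scalar), `per_chrom`, and the held-out
#'   predictions.
#' @export
loco_r2 <- function(bmap, windows, mask = NULL, ...) {
  windows <- windows[windows$n > 0, , drop = FALSE]
  chroms <- unique(windows$chrom)
  if (length(chroms) < 2) stop("loco_r2: need at least two chromosomes")
  preds <- vector("list", length(chroms))
  names(preds) <- chroms
  for (ch in chroms) {
    train <- windows[windows$chrom != ch, , drop = FALSE]
    test <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(test)) { warning("no windows on ", ch, "; skipped"); next }
    fit <- fit_mle(likelihood_data(bmap, train, mask), ...)
    lik_test <- likelihood_data(bmap, test, mask)
    bw <- .window_B(lik_test, fit$mle$mu * fit$mle$W, fit$interp)
    preds[[ch]] <- data.frame(chrom = ch,
                              pi_obs = test$Y / test$n,
                              pi_hat = fit$mle$pi0 * bw)
  }
  all <- do.call(rbind, preds)
  ssr <- sum((all$pi_obs - all$pi_hat)^2)
  sst <- sum((all$pi_obs - mean(all$pi_obs))^2)
  per <- vapply(preds, function(d) {
    if (is.null(d)) return(NA_real_)
    1 - sum((d$pi_obs - d$pi_hat)^2) / sum((d$pi_obs - mean(all$pi_obs))^2)
  }, 0)
  list(pooled = 1 - ssr / sst, per_chrom = per, predictions = all)
}

#' Block-jackknife standard errors for fitted parameters
#'
#' Delete-one-block refits over contiguous genomic blocks (default 10 Mbp),
#' with the standard \eqn{(g-1)/g} jackknife scaling, for \eqn{\pi_0},
#' \eqn{\mu} and the per-class mean selection coefficient.
#'
#' @param bmap the `bgs_bmap` used for fitting.
#' @param windows a `bgs_windows` data frame.
#' @param block_bp jackknife block size in basepairs.
#' @param mask optional accessibility track.
#' @param min_blocks smallest acceptable number of blocks.
#' @param ... arguments passed to [fit_mle()].
#' @return list with `se` (named), `ci` (normal 95%), `estimates` (the
#'   delete-one-block parameter matrix), `g` (effective block count) and
#'   `failed` block labels.
#' @export
block_jackknife <- function(bmap, windows, block_bp = 1e7, mask = NULL,
                            min_blocks = 10, ...) {
  windows <- windows[windows$n > 0, , drop = FALSE]
  block <- paste0(windows$chrom, ":", floor(windows$start / block_bp))
  blocks <- unique(block)
  if (length(blocks) < 2) stop("block_jackknife: need at least two blocks")
  if (length(blocks) < min_blocks)
    warning("only ", length(blocks), " jackknife blocks (< ", min_blocks, ")")
  full <- fit_mle(likelihood_data(bmap, windows, mask), ...)
  est <- list(); failed <- character(0)
  for (b in blocks) {
    keep <- windows[block != b, , drop = FALSE]
    fit <- tryCatch(fit_mle(likelihood_data(bmap, keep, mask), ...),
                    error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, b); next }
    est[[b]] <- c(pi0 = fit$mle$pi0, mu = fit$mle$mu, .sbar_named(fit))
  }
  g <- length(est)
  if (g < 2) stop("block_jackknife: too many failed refits")
  em <- do.call(rbind, est)
  center <- colMeans(em)
  se <- sqrt((g - 1) / g * colSums(sweep(em, 2, center)^2))
  full_est <- c(pi0 = full$mle$pi0, mu = full$mle$mu, .sbar_named(full))
  ci <- cbind(lower = full_est - qnorm(0.975) * se,
              upper = full_est + qnorm(0.975) * se)
  list(se = se, ci = ci, estimates = em, g = g, failed = failed,
       full = full_est)
}

.sbar_named <- function(fit) {
  if (!length(fit$sbar)) return(NULL)
  setNames(fit$sbar, paste0("sbar_", names(fit$sbar)))
}

#' Predicted deleterious substitution rate per feature class
#'
#' Re-solves the segment equilibria at a fixed mutation rate and returns,
#' for each feature class, \eqn{\sum_j W_{j,k} \langle \tilde R_g(s_j) /
#' R_{g,\mathrm{neutral}} \rangle_g}, the DFE-weighted substitution rate as
#' a fraction of the neutral rate (so the result is invariant to ploidy
#' rate conventions and lies in \eqn{[0, 1]}).
#'
#' @param W DFE matrix (`n_s` x `K`, simplex columns) or a `bgs_fit`.
#' @param s_values the selection grid of `W` (taken from the fit if a fit is
#'   given).
#' @param segments annotated `bgs_segments` (classes must match `W`
#'   columns).
#' @param pop a [population_context()].
#' @param mu_fixed fixed per-bp mutation rate for prediction (default
#'   \eqn{1.5 \times 10^{-8}}; estimated rates can be biased, so a pedigree
#'   value is used).
#' @param classes column classes of `W`.
#' @param va_form see [solve_equilibrium()].
#' @return named vector of per-class substitution-rate fractions.
#' @export
predict_substitution <- function(W, s_values = NULL, segments, pop,
                                 mu_fixed = 1.5e-8, classes = NULL,
                                 va_form = c("U-2R", "U-R")) {
  va_form <- match.arg(va_form)
  if (inherits(W, "bgs_fit")) {
    fit <- W
    W <- fit$mle$W
    if (is.null(classes)) classes <- names(fit$sbar)
  }
  W <- as.matrix(W)
  if (is.null(classes)) classes <- colnames(W) %||% sort(unique(segments$class))
  stopifnot(!is.null(s_values), nrow(W) == length(s_values),
            all(abs(colSums(W) - 1) < 1e-6))
  vf <- if (va_form == "U-R") 1L else 0L
  out <- setNames(numeric(ncol(W)), classes)
  for (k in seq_len(ncol(W))) {
    segk <- segments[segments$class == classes[k], , drop = FALSE]
    if (!nrow(segk)) { out[k] <- NA_real_; next }
    frac_j <- vapply(s_values, function(sj) {
      U <- 2 * mu_fixed * segk$L
      sol <- .solve_equilibrium_batch(pop$N * pop$rescale, U, sj, segk$M,
                                      1e-10, 500, vf)
      mean(sol$R / (U / 2))
    }, 0)
    out[k] <- sum(W[, k] * frac_j)
  }
  out
}

#' Divergence implied by a substitution-rate fraction
#'
#' \eqn{d = f \mu t_{\mathrm{years}} / g} per basepair along one lineage,
#' evaluated at the ends of a divergence-time range.
#'
#' @param rate_fraction substitution rate as a fraction of the neutral rate.
#' @param mu per-bp per-generation mutation rate.
#' @param t_mya divergence-time range in millions of years (default 6-12).
#' @param gen_years generation time in years (default 28).
#' @return matrix with one row per `rate_fraction` and one column per end of
#'   `t_mya`.
#' @export
implied_divergence <- function(rate_fraction, mu = 1.5e-8,
                               t_mya = c(6, 12), gen_years = 28) {
  stopifnot(gen_years > 0)
  out <- outer(rate_fraction, t_mya * 1e6 / gen_years) * mu
  colnames(out) <- paste0(t_mya, "Mya")
  out
}

#' Coalescent-noise ceiling on explainable variance
#'
#' Approximates the largest window-level \eqn{R^2} any reduction-map model
#' could attain given irreducible neutral-coalescent noise: the expected
#' residual variance of window diversity is computed from the classic
#' pairwise-diversity sampling variance (Tajima's \eqn{a\,\theta + b\,
#' \theta^2} for a linked block) with the window-specific scaled size
#' \eqn{\bar B(b) N}, attenuated by the approximate number of independent
#' genealogical blocks per window (set by the population-scaled map length).
#' Returns \eqn{1 - \sum_b \mathrm{Var}_b / \sum_b (\pi_b - \bar\pi)^2},
#' in \eqn{(-\infty, 1]}.
#'
#' @param fit a `bgs_fit`.
#' @param lik the `bgs_likdata` used in fitting.
#' @param n_samples number of sampled chromosomes per window.
#' @param recmap optional `bgs_recmap` for per-window map lengths; without
#'   it a uniform 1 cM/Mb is assumed.
#' @param coal_var optional override: per-window residual variance vector
#'   (useful for the zero-noise limit).
#' @return list with `r2_coal`, per-window `var_coal`, and the observed
#'   total variance.
#' @export
r2_coal <- function(fit, lik, n_samples, recmap = NULL, coal_var = NULL) {
  wins <- lik$windows
  piobs <- wins$Y / wins$n
  tot <- sum((piobs - mean(piobs))^2)
  if (is.null(coal_var)) {
    theta <- fit$predicted$pi_hat
    Lb <- wins$accessible_bp %||% (wins$end - wins$start)
    n <- n_samples
    a1 <- (n + 1) / (3 * (n - 1))
    b1 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    Mw <- vapply(seq_len(nrow(wins)), function(i) {
      if (is.null(recmap)) return((wins$end[i] - wins$start[i]) * 1e-8)
      map_position(recmap, wins$chrom[i], wins$end[i]) -
        map_position(recmap, wins$chrom[i], wins$start[i])
    }, 0)
    # effective population size per window via pi0 = 4 N mu
    Nb <- fit$predicted$B * fit$mle$pi0 / (4 * fit$mle$mu)
    n_blocks <- 1 + 4 * Nb * Mw
    coal_var <- a1 * theta / pmax(Lb, 1) + b1 * theta^2 / n_blocks
  }
  list(r2_coal = 1 - sum(coal_var) / tot, var_coal = coal_var,
       total_var = tot)
}

#' Residual diagnostics for a fitted model
#'
#' Window-level residuals \eqn{\pi_b - \hat\pi_b} summarised against
#' covariates: binned means (deciles), a lowess curve, and the \eqn{R^2} of
#' a simple linear regression per covariate.
#'
#' @param fit a `bgs_fit`.
#' @param covariates data frame of per-window covariates aligned with the
#'   fit's windows.
#' @param nbins number of covariate bins.
#' @return list per covariate: `binned` (bin mean covariate, mean residual),
#'   `lowess`, `slope`, `r2`.
#' @export
residual_diagnostics <- function(fit, covariates, nbins = 10) {
  res <- fit$predicted$pi_obs - fit$predicted$pi_hat
  out <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = nbins + 1)))
    bin <- cut(x, qs, include.lowest = TRUE)
    binned <- data.frame(
      x = tapply(x, bin, mean),
      resid = tapply(res, bin, mean))
    fitlm <- stats::lm(res ~ x)
    out[[nm]] <- list(binned = binned, lowess = lowess(x, res),
                      slope = unname(stats::coef(fitlm)[2]),
                      r2 = summary(fitlm)$r.squared)
  }
  out
}
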