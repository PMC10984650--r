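# Composite likelihood machinery: tensor mixing, likelihood algebra,
# softmax, window-level R^2 pieces, substitution/divergence predictions.

.flat_idx_test <- function(lik, j, i) j + lik$ns * (i - 1)

make_lik_fixture <- function(seed = 13, n_chroms = 2, chrom_length = 4e6,
                             n_segments = 120, W = c(rep(0, 6), 1),
                             pi0 = 1e-3, mu = 1.5e-8, grid = grid_axes(),
                             window = 5e5, coal_noise = NULL) {
  cf <- synth_config(n_chroms = n_chroms, chrom_length = chrom_length,
                     n_segments = n_segments, W = W, pi0 = pi0, mu = mu,
                     window = window, coal_noise = coal_noise,
                     layout_seed = seed + 1000)
  sim <- synth_genome(cf, seed = seed)
  bm <- compute_bprime(sim$segments, sim$recmap, population_context(cf$N),
                       grid, chrom_lengths = sim$chrom_lengths)
  list(sim = sim, bm = bm, lik = likelihood_data(bm, sim$windows),
       grid = grid, cf = cf)
}

test_that("logB_mix is exact at grid nodes and near zero for vanishing w", {
  fx <- make_lik_fixture()
  lik <- fx$lik
  ns <- lik$ns
  # w at grid nodes: equals the direct tensor lookup, bit for bit
  i <- 9
  w <- matrix(0, ns, 1)
  w[ns, 1] <- lik$grid$m_values[i] # all mass at the top s, node i
  w[-ns, 1] <- lik$grid$m_values[1]
  got <- logB_mix(lik, w)
  cols <- c(.flat_idx_test(lik, seq_len(ns - 1), 1),
            .flat_idx_test(lik, ns, i))
  # accumulate in the same (j ascending) order so node values are bitwise
  direct <- Reduce(`+`, lapply(cols, function(cc) lik$logB[, cc]))
  expect_identical(got, direct)
  # vanishing mutation input: logB ~ 0 everywhere
  w0 <- matrix(lik$grid$m_values[1], ns, 1)
  expect_lt(max(abs(logB_mix(lik, w0))), 1e-3)
  # above-grid w errors with the offending cell named
  wbad <- w; wbad[ns, 1] <- 2e-7
  expect_error(logB_mix(lik, wbad), "above the mutation grid")
})

test_that("logB_mix matches a from-scratch map at off-grid w", {
  # oracle: rebuild the map with 1x1 grids at the exact w values and sum
  fx <- make_lik_fixture(seed = 23, n_chroms = 1, chrom_length = 2e6,
                         n_segments = 60, window = 2.5e5)
  lik <- fx$lik
  sim <- fx$sim
  set.seed(5)
  ns <- lik$ns
  w <- matrix(10^runif(ns, -10.5, -8.2), ns, 1)
  got <- logB_mix(lik, w)
  oracle <- 0
  for (j in seq_len(ns)) {
    bm1 <- compute_bprime(sim$segments, sim$recmap,
                          population_context(fx$cf$N),
                          grid_axes(s_values = lik$grid$s_values[j],
                                    m_values = w[j, 1]),
                          chrom_lengths = sim$chrom_lengths)
    oracle <- oracle + bm1$logB$chr1[, 1, 1, 1]
  }
  # align: lik keeps only positions inside windows with data
  expect_lt(max(abs(got - oracle[seq_along(got)])), 1e-3)
  # the plain linear rule is also available and close at this scale
  lin <- logB_mix(lik, w, interp = "linear")
  expect_lt(max(abs(lin - oracle[seq_along(got)])), 2e-2)
})

test_that("composite log-likelihood matches the binomial pmf and its algebra", {
  fx <- make_lik_fixture(seed = 17, n_chroms = 1, chrom_length = 2e6,
                         n_segments = 50, window = 2e5)
  lik <- fx$lik
  W <- matrix(c(rep(0, 6), 1), ncol = 1)
  params <- list(pi0 = 1e-3, mu = 1.5e-8, W = W)
  ll <- composite_loglik(params, lik)
  # direct pmf summation (binomial coefficients removed)
  bw <- bgsmap:::.window_B(lik, params$mu * W)
  p <- params$pi0 * bw
  Y <- lik$windows$Y; n <- lik$windows$n
  direct <- sum(stats::dbinom(Y, n, p, log = TRUE) - lchoose(n, Y))
  expect_equal(ll, direct, tolerance = 1e-8)
  # doubling the data doubles log-likelihood differences
  lik2 <- lik
  lik2$windows$Y <- 2 * Y; lik2$windows$n <- 2 * n
  p2 <- list(pi0 = 1.1e-3, mu = 1.5e-8, W = W)
  d1 <- composite_loglik(params, lik) - composite_loglik(p2, lik)
  d2 <- composite_loglik(params, lik2) - composite_loglik(p2, lik2)
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
  # window-order permutation invariance
  set.seed(2)
  perm <- sample(nrow(lik$windows))
  lik3 <- lik
  lik3$windows <- lik$windows[perm, , drop = FALSE]
  lik3$win <- match(lik$win, perm)
  lik3$wt_den <- rowsum(lik3$wt, lik3$win, reorder = TRUE)
  expect_equal(composite_loglik(params, lik3), ll, tolerance = 1e-10)
  # out-of-range probability diagnoses -Inf
  bad <- composite_loglik(list(pi0 = 2, mu = 1.5e-8, W = W), lik)
  expect_identical(as.numeric(bad), -Inf)
})

test_that("with B = 1 the profiled pi0 is the pooled heterozygosity", {
  Y <- c(120, 80, 100); n <- rep(1e5, 3)
  bw <- rep(1, 3)
  pi0 <- bgsmap:::.profile_pi0(bw, Y, n, c(1e-6, 0.5))
  expect_equal(pi0, sum(Y) / sum(n), tolerance = 1e-10)
})

test_that("softmax columns are simplexes and shift-invariant", {
  set.seed(3)
  logits <- matrix(rnorm(14), 7, 2)
  W <- dfe_softmax(logits)
  expect_true(all(W >= 0))
  expect_equal(colSums(W), c(1, 1), tolerance = 1e-12)
  shifted <- sweep(logits, 2, c(3, -5), "+")
  expect_equal(dfe_softmax(shifted), W, tolerance = 1e-12)
})

test_that("fit_mle errors on degenerate input", {
  fx <- make_lik_fixture(seed = 29, n_chroms = 1, chrom_length = 2e6,
                         n_segments = 40, window = 2e5)
  one <- fx$sim$windows[1, , drop = FALSE]
  expect_error(likelihood_data(fx$bm, one), "two windows")
})

test_that("neutral-only truth fits to B ~ 1 with near-zero R^2", {
  fx <- make_lik_fixture(seed = 37, n_chroms = 2, chrom_length = 3e6,
                         n_segments = 100, W = c(1, rep(0, 6)),
                         window = 3e5)
  fit <- fit_mle(fx$lik, n_starts = 10, seed = 2)
  expect_gt(min(fit$predicted$B), 0.995)
  expect_lt(abs(fit$r2), 0.25)
  expect_equal(fit$mle$pi0, 1e-3, tolerance = 0.02)
})

test_that("substitution-rate fractions mix linearly over the DFE", {
  toy <- toy_genome(10, 1e6, seed = 44)
  pop <- population_context(1e4)
  sv <- c(1e-8, 1e-2)
  # all mass neutral: fraction ~ 1; all mass strong: fraction ~ 0
  f_neu <- predict_substitution(matrix(c(1, 0), 2, 1), s_values = sv,
                                segments = toy$segments, pop = pop,
                                classes = "conserved")
  f_str <- predict_substitution(matrix(c(0, 1), 2, 1), s_values = sv,
                                segments = toy$segments, pop = pop,
                                classes = "conserved")
  f_mix <- predict_substitution(matrix(c(0.5, 0.5), 2, 1), s_values = sv,
                                segments = toy$segments, pop = pop,
                                classes = "conserved")
  expect_equal(unname(f_neu), 1, tolerance = 1e-3)
  expect_lt(f_str, 1e-6)
  expect_equal(unname(f_mix), unname((f_neu + f_str) / 2), tolerance = 1e-9)
})

test_that("implied divergence is plain arithmetic on the rate fraction", {
  expect_equal(unname(implied_divergence(1, 1.5e-8, 7, 28)[1, 1]), 3.75e-3)
  expect_equal(implied_divergence(0, 1.5e-8, c(6, 12), 28),
               matrix(0, 1, 2), ignore_attr = TRUE)
  expect_equal(unname(implied_divergence(0.5, 1.5e-8, 12, 28)[1, 1]),
               3.2142857e-3,
               tolerance = 1e-6)
})

test_that("r2_coal reduces to in-sample R^2 at zero coalescent variance", {
  fx <- make_lik_fixture(seed = 41, n_chroms = 2, chrom_length = 3e6,
                         n_segments = 150, window = 3e5)
  fit <- fit_mle(fx$lik, n_starts = 8, seed = 3)
  zero <- r2_coal(fit, fx$lik, n_samples = 50,
                  coal_var = (fit$predicted$pi_obs - fit$predicted$pi_hat)^2)
  expect_equal(zero$r2_coal, fit$r2, tolerance = 1e-10)
  # with real noise the ceiling is at most 1 and finite
  ceil <- r2_coal(fit, fx$lik, n_samples = 50)
  expect_lt(ceil$r2_coal, 1 + 1e-12)
  expect_true(is.finite(ceil$r2_coal))
})

test_that("residual diagnostics recover an injected linear trend", {
  fx <- make_lik_fixture(seed = 43, n_chroms = 1, chrom_length = 3e6,
                         n_segments = 80, window = 3e5)
  fit <- fit_mle(fx$lik, n_starts = 6, seed = 4)
  nw <- nrow(fit$predicted)
  x <- seq_len(nw)
  # inject a known positive trend into the residuals
  fit2 <- fit
  fit2$predicted$pi_obs <- fit$predicted$pi_hat + 1e-6 * x
  d <- residual_diagnostics(fit2, data.frame(cov = x))
  expect_gt(d$cov$slope, 0)
  expect_gt(d$cov$r2, 0.9)
  # perfect fit: all bins at zero
  fit3 <- fit
  fit3$predicted$pi_obs <- fit$predicted$pi_hat
  d3 <- residual_diagnostics(fit3, data.frame(cov = x))
  expect_true(all(abs(d3$cov$binned$resid) < 1e-15))
  # unrelated covariate: near-zero R^2
  set.seed(9)
  d4 <- residual_diagnostics(fit, data.frame(cov = rnorm(nw)))
  expect_lt(d4$cov$r2, 0.2)
})

test_that("jackknife SE matches the closed form for a mean-type statistic", {
  # no segments: B = 1 and pi0-hat is the pooled mean, so delete-one-block
  # jackknife must reproduce the classic SE of a mean over equal blocks
  chrom_lengths <- c(chr1 = 2e6)
  rm <- uniform_recmap(chrom_lengths)
  seg <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), class = character(0), L = numeric(0))
  class(seg) <- c("bgs_segments", "data.frame")
  seg <- annotate_map(seg, rm)
  bm <- compute_bprime(seg, rm, population_context(1000),
                       grid_axes(s_values = 0.01, m_values = 1e-8),
                       step = 1e4)
  wins <- tile_windows(chrom_lengths, 2e5)
  set.seed(6)
  n <- rep(1e6, nrow(wins))
  p <- 1e-3
  wins$Y <- rbinom(nrow(wins), n, p)
  wins$n <- n
  wins$accessible_bp <- wins$end - wins$start
  class(wins) <- c("bgs_windows", "data.frame")
  jk <- suppressWarnings(block_jackknife(bm, wins, block_bp = 2e5,
                                         n_starts = 2, seed = 8))
  g <- nrow(wins)
  # jackknife SE of the mean of g equal blocks equals sd/sqrt(g)
  xbar <- wins$Y / wins$n
  closed <- stats::sd(xbar) / sqrt(g)
  expect_equal(unname(jk$se["pi0"]), closed, tolerance = 1e-3)
  expect_equal(jk$g, g)
})
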