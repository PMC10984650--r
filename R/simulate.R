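# Ground-truth engines: a desk-scale Wright-Fisher forward simulator of
# purifying selection in a selected region (validating the equilibrium
# theory), and a synthetic-genome generator producing segment tracks,
# recombination maps and windowed diversity counts from a known truth
# (validating the inference machinery end to end).

#' Configuration for the Wright-Fisher forward simulator
#'
#' Diploid Wright-Fisher population with multiplicative purifying selection:
#' deleterious mutations (rate `mu` per bp per gamete per generation, cost
#' `s` in heterozygotes, `2s` in homozygotes, fitness truncated at zero)
#' and interleaved neutral mutations (rate `mu_neutral`) arise in a single
#' `L`-bp region with per-bp recombination rate `r_bp`. Diversity is
#' measured at the neutral sites, time-averaged over the sampling phase,
#' so `B_obs = pi_neutral / (4 N mu_neutral)`.
#'
#' @param N diploid population size.
#' @param L region length in bp.
#' @param mu per-bp deleterious mutation rate.
#' @param s heterozygous selection cost.
#' @param r_bp per-bp recombination rate (Morgans/bp).
#' @param mu_neutral per-bp neutral mutation rate (diversity tracer).
#' @param burnin burn-in generations (default `10 * N`; smaller values are
#'   flagged).
#' @param generations post-burn-in sampling generations (default `10 * N`).
#' @param replicates number of independent replicates.
#' @param tick bookkeeping interval (generations) for frequency censuses,
#'   fixation detection and diversity samples.
#' @return a `bgs_wf_config` list.
#' @export
wf_config <- function(N = 500, L = 5e4, mu = 1e-8, s = 0.01, r_bp = 1e-8,
                      mu_neutral = 5e-8, burnin = 10 * N,
                      generations = 10 * N, replicates = 10, tick = 25) {
  stopifnot(N >= 2, L > 0, mu >= 0, s >= 0, s <= 0.5, r_bp >= 0,
            mu_neutral > 0, generations > 0, replicates >= 1)
  if (burnin < 10 * N)
    warning("burn-in shorter than 10N generations; equilibrium quantities ",
            "may not have converged")
  structure(list(N = N, L = L, mu = mu, s = s, r_bp = r_bp,
                 mu_neutral = mu_neutral, burnin = as.integer(burnin),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 tick = as.integer(tick)),
            class = "bgs_wf_config")
}

#' Run the Wright-Fisher forward simulator
#'
#' @param config a [wf_config()].
#' @param seed RNG seed (runs are deterministic given the seed).
#' @param keep_traj retain the per-census time series of diversity, genic
#'   variance and mean fitness for every replicate.
#' @return a `bgs_wf_result`: per-replicate data frame (`B_obs`, `R_obs`
#'   in substitutions/generation, `R_frac` as a fraction of the neutral
#'   rate `mu*L`, time-averaged `VA_obs`, neutral-fixation check) plus a
#'   `summary` row with means and 95% CIs, and mutation-conservation
#'   totals.
#' @export
wf_forward <- function(config, seed = 1, keep_traj = FALSE) {
  stopifnot(inherits(config, "bgs_wf_config"))
  cf <- config
  traj <- if (keep_traj) list() else NULL
  reps <- .with_seed(seed, {
    lapply(seq_len(cf$replicates), function(i) {
      r <- .wf_forward_cpp(cf$N, cf$L, cf$mu, cf$s, cf$r_bp, cf$mu_neutral,
                           cf$burnin, cf$generations, cf$tick)
      if (keep_traj)
        traj[[i]] <<- data.frame(rep = i, gen = r$gen, pi = r$pi,
                                 va = r$va, wbar = r$wbar)
      data.frame(
        rep = i,
        B_obs = mean(r$pi) / (4 * cf$N * cf$mu_neutral),
        R_obs = r$fix_sel_post / cf$generations,
        R_frac = if (cf$mu > 0)
          r$fix_sel_post / cf$generations / (cf$mu * cf$L) else NA_real_,
        VA_obs = mean(r$va),
        R_neutral_frac = r$fix_neu_post / cf$generations /
          (cf$mu_neutral * cf$L),
        wbar = mean(r$wbar),
        created = r$created_sel + r$created_neu,
        lost = r$lost_sel + r$lost_neu,
        fixed = r$fixed_sel + r$fixed_neu,
        segregating = r$seg_sel + r$seg_neu)
    })
  })
  df <- do.call(rbind, reps)
  ci <- function(x) {
    m <- mean(x); se <- sd(x) / sqrt(length(x))
    c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se, se = se)
  }
  structure(list(replicates = df, config = cf, seed = seed,
                 B = ci(df$B_obs), R_frac = ci(df$R_frac),
                 VA = ci(df$VA_obs),
                 trajectories = if (keep_traj) do.call(rbind, traj)),
            class = "bgs_wf_result")
}

#' Compare simulator output with equilibrium-theory predictions
#'
#' Runs the Wright-Fisher simulator over a grid of parameter cells and
#' tabulates observed versus predicted reduction factor, substitution-rate
#' fraction and fitness variance, with z-scores and 95% CI inclusion for
#' both the B' and the classic background-selection prediction.
#'
#' @param cells data frame with columns `N`, `L`, `mu`, `s` and optionally
#'   `r_bp` (default 1e-8).
#' @param replicates replicates per cell (CI width scales as its inverse
#'   square root; undersampled cells are flagged).
#' @param seed RNG seed.
#' @param mu_neutral neutral tracer rate.
#' @param ... further arguments to [wf_config()].
#' @return data frame, one row per cell, with observed means/CIs,
#'   predictions, z-scores, CI-inclusion flags and relative errors.
#' @export
validate_theory <- function(cells, replicates = 100, seed = 1,
                            mu_neutral = 5e-8, ...) {
  if (!"r_bp" %in% names(cells)) cells$r_bp <- 1e-8
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    cf <- wf_config(N = ce$N, L = ce$L, mu = ce$mu, s = ce$s,
                    r_bp = ce$r_bp, mu_neutral = mu_neutral,
                    replicates = replicates, ...)
    res <- wf_forward(cf, seed = seed + i)
    M <- ce$r_bp * ce$L
    U <- 2 * ce$mu * ce$L
    eq <- solve_equilibrium(segment_selection(s = ce$s, L = ce$L, mu = ce$mu,
                                              M = M),
                            population_context(ce$N))
    b_classic <- if (ce$s > 0) exp(-0.5 * U * ce$s * q2_segment(s = ce$s, M = M))
      else 1
    zB <- (res$B[["mean"]] - eq$B) / max(res$B[["se"]], 1e-12)
    va_pred_obs <- (U - 2 * res$R_frac[["mean"]] * ce$mu * ce$L) * ce$s
    data.frame(
      N = ce$N, L = ce$L, mu = ce$mu, s = ce$s, two_Ns = 2 * ce$N * ce$s,
      B_obs = res$B[["mean"]], B_lo = res$B[["lo"]], B_hi = res$B[["hi"]],
      B_se = res$B[["se"]],
      B_pred = eq$B, B_classic = b_classic,
      bprime_in_ci = eq$B >= res$B[["lo"]] & eq$B <= res$B[["hi"]],
      classic_in_ci = b_classic >= res$B[["lo"]] & b_classic <= res$B[["hi"]],
      z_bprime = zB,
      R_frac_obs = res$R_frac[["mean"]], R_frac_pred = eq$R_frac,
      R_obs = res$R_frac[["mean"]] * ce$mu * ce$L,
      VA_obs = res$VA[["mean"]], VA_lo = res$VA[["lo"]],
      VA_hi = res$VA[["hi"]], VA_pred = eq$VA,
      VA_consistent = va_pred_obs >= res$VA[["lo"]] - 2 * res$VA[["se"]] &
        va_pred_obs <= res$VA[["hi"]] + 2 * res$VA[["se"]],
      rel_err_bprime = abs(eq$B - res$B[["mean"]]) / res$B[["mean"]],
      rel_err_classic = abs(b_classic - res$B[["mean"]]) / res$B[["mean"]],
      undersampled = replicates < 100)
  })
  do.call(rbind, rows)
}

#' Configuration for the synthetic-genome generator
#'
#' Defines a genome of independent chromosomes carrying non-overlapping
#' conserved segments on a piecewise-constant recombination map, and the
#' true parameters \eqn{(\pi_0, \mu, \mathbf W, N)} under which windowed
#' diversity counts are drawn: \eqn{Y_b \sim} Binomial\eqn{(n_b, \pi_0
#' \bar B(b))} with \eqn{\bar B} the window-averaged true reduction map.
#' The segment layout uses its own seed (`layout_seed`) so sampling noise
#' can be varied while holding the genome fixed.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_segments conserved segments per chromosome.
#' @param seg_len_range segment length range (bp, uniform).
#' @param rate_mean mean recombination rate (Morgans/bp); rates per 2-Mb
#'   map piece are log-normal around this with `rate_sdlog`.
#' @param rate_sdlog log-sd of piecewise rates.
#' @param pi0,mu,N true baseline diversity, per-bp deleterious mutation
#'   rate and diploid size.
#' @param s_values,W true DFE support and weights (single conserved class;
#'   `W` a probability vector over `s_values`).
#' @param window window width (bp).
#' @param n_samples sampled diploids (pairwise comparisons per site are
#'   `choose(2 * n_samples, 2)`).
#' @param coal_noise optional Gamma shape; when set, each window's success
#'   probability is multiplied by a Gamma(shape, rate = shape) factor
#'   (mean 1) to mimic genealogical variance.
#' @param truth_kernel flank kernel for the true reduction map:
#'   `"standard"` (kappa = s, matching the fitted model family) or
#'   `"physical"` (the drift-extended kernel, for misspecification
#'   experiments where data should not come from the estimator's own
#'   family).
#' @param layout_seed seed for the segment/map layout.
#' @return a `bgs_synth_config` list.
#' @export
synth_config <- function(n_chroms = 5, chrom_length = 2e7, n_segments = 800,
                         seg_len_range = c(500, 2000), rate_mean = 1e-8,
                         rate_sdlog = 0.5, pi0 = 1e-3, mu = 1.5e-8,
                         N = 1000, s_values = 10^seq(-8, -2),
                         W = c(rep(0, 6), 1), window = 1e6, n_samples = 25,
                         coal_noise = NULL,
                         truth_kernel = c("standard", "physical"),
                         layout_seed = 99) {
  truth_kernel <- match.arg(truth_kernel)
  stopifnot(length(W) == length(s_values), abs(sum(W) - 1) < 1e-8,
            all(W >= 0), pi0 > 0, pi0 < 1, mu > 0, N >= 2)
  structure(as.list(environment()), class = "bgs_synth_config")
}

# equilibrium VA per segment under the true (mu, W): array [G, n_active, 1]
.truth_logB <- function(segments, recmap, cf, step) {
  act <- which(cf$W > 0)
  sv <- cf$s_values[act]
  VA <- array(0, dim = c(nrow(segments), length(sv), 1))
  for (j in seq_along(act)) {
    U <- 2 * cf$mu * cf$W[act[j]] * segments$L
    sol <- .solve_equilibrium_batch(cf$N, U, sv[j], segments$M, 1e-10,
                                    500L, 0L)
    VA[, j, 1] <- sol$VA
  }
  grid <- grid_axes(s_values = sv, m_values = cf$mu)
  chrom_lengths <- setNames(rep(cf$chrom_length, cf$n_chroms),
                            names(recmap))
  kf <- if (identical(cf$truth_kernel, "physical")) "one_minus_z" else "s"
  bm <- .assemble_map(segments, recmap, grid, step, chrom_lengths, VA,
                      trunc_floor = 0, kappa_flank = kf, N = cf$N)
  # collapse the s and class dimensions: true logB per position
  lapply(bm$logB, function(arr) {
    apply(arr[, , 1, , drop = FALSE], 1, sum)
  })
}

#' Generate a synthetic genome with known truth
#'
#' Lays out conserved segments and a piecewise recombination map, computes
#' the true B' reduction map under the configured \eqn{(\mu, \mathbf W,
#' N)}, and draws windowed pairwise-diversity counts from the binomial
#' sampling model. Returns the exact structures the fitting pipeline
#' consumes, plus the serialized truth for recovery scoring.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed for the diversity sampling (the layout is governed
#'   by `config$layout_seed`).
#' @param step evaluation-position spacing used for the true map (bp).
#' @return a `bgs_synth` list: `segments` (annotated), `recmap`, `windows`
#'   (`bgs_windows` with `Y`, `n`), `truth` (config plus the per-window
#'   true \eqn{\bar B} and \eqn{\pi}), `chrom_lengths`.
#' @export
synth_genome <- function(config, seed = 1, step = 1e4) {
  stopifnot(inherits(config, "bgs_synth_config"))
  cf <- config
  chroms <- paste0("chr", seq_len(cf$n_chroms))
  layout <- .with_seed(cf$layout_seed, {
    segs <- list(); maps <- list()
    for (ch in chroms) {
      len <- runif(cf$n_segments, cf$seg_len_range[1], cf$seg_len_range[2])
      len <- round(len)
      free <- cf$chrom_length - sum(len)
      stopifnot(free > 0)
      gaps <- sort(runif(cf$n_segments, 0, free))
      start <- round(gaps + cumsum(c(0, len[-length(len)])))
      segs[[ch]] <- data.frame(chrom = ch, start = start,
                               end = start + len, class = "conserved",
                               L = len, stringsAsFactors = FALSE)
      knots <- unique(c(seq(0, cf$chrom_length, by = 2e6),
                        cf$chrom_length))
      rates <- stats::rlnorm(length(knots) - 1,
                             log(cf$rate_mean) - cf$rate_sdlog^2 / 2,
                             cf$rate_sdlog)
      cum <- c(0, cumsum(rates * diff(knots)))
      maps[[ch]] <- data.frame(chrom = ch, pos = knots, cum = cum)
    }
    list(segments = do.call(rbind, segs), map = do.call(rbind, maps))
  })
  segments <- layout$segments
  rownames(segments) <- NULL
  class(segments) <- c("bgs_segments", "data.frame")
  recmap <- recomb_map(layout$map)
  segments <- annotate_map(segments, recmap)
  chrom_lengths <- setNames(rep(cf$chrom_length, cf$n_chroms), chroms)

  logB <- .truth_logB(segments, recmap, cf, step)
  wins <- tile_windows(chrom_lengths, cf$window)
  Bbar <- numeric(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    ch <- wins$chrom[i]
    pos <- seq(0, chrom_lengths[[ch]] - 1, by = step)
    sel <- which(pos >= wins$start[i] & pos < wins$end[i])
    wt <- pmin(pos[sel] + step, wins$end[i]) - pos[sel]
    Bbar[i] <- sum(exp(logB[[ch]][sel]) * wt) / sum(wt)
  }
  n_pairs <- choose(2 * cf$n_samples, 2)
  nb <- (wins$end - wins$start) * n_pairs
  p <- cf$pi0 * Bbar
  wins$Y <- .with_seed(seed, {
    if (!is.null(cf$coal_noise))
      p <- p * rgamma(length(p), shape = cf$coal_noise, rate = cf$coal_noise)
    if (any(p >= 1)) stop("synth_genome: unphysical configuration (p >= 1)")
    .rbinom_big(nb, p)
  })
  wins$n <- nb
  wins$accessible_bp <- wins$end - wins$start
  wins$excluded <- FALSE
  class(wins) <- c("bgs_windows", "data.frame")
  truth <- list(pi0 = cf$pi0, mu = cf$mu, N = cf$N, s_values = cf$s_values,
                W = cf$W, sbar = sum(cf$W * cf$s_values), Bbar = Bbar,
                pi_true = p)
  list(segments = segments, recmap = recmap, windows = wins, truth = truth,
       chrom_lengths = chrom_lengths, config = cf)
}

# binomial draws that stay safe for very large size (normal approximation
# above 1e7 trials, where the relative error is far below sampling noise)
.rbinom_big <- function(size, prob) {
  out <- numeric(length(size))
  big <- size > 1e7
  if (any(!big))
    out[!big] <- rbinom(sum(!big), size[!big], prob[!big])
  if (any(big)) {
    m <- size[big] * prob[big]
    s <- sqrt(size[big] * prob[big] * (1 - prob[big]))
    out[big] <- pmax(0, pmin(size[big], round(rnorm(sum(big), m, s))))
  }
  out
}

#' Write a synthetic genome in the package's file formats
#'
#' Emits `segments.bed`, `recmap.tsv`, `windows.tsv` and `truth.json` so
#' the full pipeline can be run from files alone.
#'
#' @param synth result of [synth_genome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(synth$segments, file.path(dir, "segments.bed"))
  write_recmap(synth$recmap, file.path(dir, "recmap.tsv"))
  write_windows(synth$windows, file.path(dir, "windows.tsv"))
  truth <- synth$truth
  truth$Bbar <- NULL; truth$pi_true <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Bias/RMSE table for parameter recovery over a truth grid
#'
#' Summarises repeated fits against their generating truths and flags the
#' classic-model failure mode (inflated mean selection coefficient and
#' deflated mutation rate on weak-selection truths).
#'
#' @param results data frame with columns `method`, `truth_s`, `truth_mu`,
#'   `truth_pi0`, `pi0_hat`, `mu_hat`, `sbar_hat` (one row per fit).
#' @return data frame of per-(method, truth cell) bias and RMSE with a
#'   `weak_s_failure` flag.
#' @export
recovery_report <- function(results) {
  stopifnot(nrow(results) >= 1)
  key <- interaction(results$method, results$truth_s, results$truth_mu,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    data.frame(
      method = d$method[1], truth_s = d$truth_s[1], truth_mu = d$truth_mu[1],
      truth_pi0 = d$truth_pi0[1],
      bias_pi0 = mean(d$pi0_hat) - d$truth_pi0[1],
      rmse_pi0 = sqrt(mean((d$pi0_hat - d$truth_pi0[1])^2)),
      bias_mu = mean(d$mu_hat) - d$truth_mu[1],
      rmse_mu = sqrt(mean((d$mu_hat - d$truth_mu[1])^2)),
      bias_sbar = mean(d$sbar_hat) - d$truth_s[1],
      rmse_sbar = sqrt(mean((d$sbar_hat - d$truth_s[1])^2)),
      weak_s_failure = d$truth_s[1] < 1e-3 &
        mean(d$sbar_hat) > 3 * d$truth_s[1] &
        mean(d$mu_hat) < d$truth_mu[1] / 3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
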