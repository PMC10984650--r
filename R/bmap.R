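# Genome-wide diversity-reduction maps.  For every evaluation position x and
# every (m_i, s_j) grid cell, the log reduction is the sum over conserved
# segments g of -1/2 * VA_g(m_i, s_j) * Q^2(s_j, r_{x,g}), where VA_g is the
# segment's equilibrium additive fitness variance and Q is the flanking-site
# autocorrelation factor q_flank() at kappa = s_j.  The classic background
# selection map is the special case VA_g = U_g s_j (no substitutions).

.chrom_lengths_from_recmap <- function(recmap) {
  vapply(recmap, function(d) max(d$pos), 0)
}

# per-segment equilibrium VA over the grid: array [G, n_s, n_m]
.solve_va_array <- function(segments, grid, N, tol = 1e-10, max_iter = 500,
                            va_form = 0L) {
  G <- nrow(segments)
  ns <- length(grid$s_values); nm <- length(grid$m_values)
  VA <- array(0, dim = c(G, ns, nm))
  if (G == 0) return(VA)
  Nv <- rep_len(N, G)
  for (j in seq_len(ns)) {
    for (i in seq_len(nm)) {
      U <- 2 * grid$m_values[i] * segments$L
      sol <- .solve_equilibrium_batch(Nv, U, grid$s_values[j], segments$M,
                                      tol, max_iter, va_form)
      VA[, j, i] <- sol$VA
    }
  }
  VA
}

# classic-BGS VA over the grid (mutation-selection balance, R = 0)
.classic_va_array <- function(segments, grid) {
  G <- nrow(segments)
  ns <- length(grid$s_values); nm <- length(grid$m_values)
  VA <- array(0, dim = c(G, ns, nm))
  for (j in seq_len(ns))
    VA[, j, ] <- outer(segments$L, 2 * grid$m_values * grid$s_values[j])
  VA
}

# flank decay rate per segment: the classic kappa = s (default), or the
# drift-extended 1 - Z = s + M + 1/(2N) used for sensitivity analyses and
# for generating data from the physically wider kernel
.kappa_values <- function(s, M, kappa_flank, N) {
  if (kappa_flank == "s") return(rep(s, length(M)))
  pmin(s + M + 1 / (2 * N), 1)
}

# assemble logB tensors from per-segment VA values
.assemble_map <- function(segments, recmap, grid, step, chrom_lengths, VA,
                          trunc_floor = 1e-10, kappa_flank = "s", N = NA) {
  stopifnot(all(c("M", "map_mid", "class", "L") %in% names(segments)))
  classes <- sort(unique(segments$class))
  chroms <- names(chrom_lengths)
  ns <- length(grid$s_values); nm <- length(grid$m_values)
  K <- length(classes)
  # truncate segment contributions that cannot exceed the floor even at r=0
  if (trunc_floor > 0) {
    for (j in seq_len(ns)) {
      cap <- 0.5 / grid$s_values[j]^2 # q_flank(s_j, 0)^2 / 2
      VAj <- VA[, j, , drop = FALSE]
      VAj[VAj * cap < trunc_floor] <- 0
      VA[, j, ] <- VAj
    }
  }
  pos_list <- lapply(chroms, function(ch)
    seq(0, chrom_lengths[[ch]] - 1, by = step))
  names(pos_list) <- chroms
  logB <- list()
  for (ch in chroms) {
    P <- length(pos_list[[ch]])
    arr <- array(0, dim = c(P, ns, nm, K),
                 dimnames = list(NULL, NULL, NULL, classes))
    map_x <- map_position(recmap, ch, pos_list[[ch]])
    for (k in seq_len(K)) {
      cls <- classes[k]
      on_c <- which(segments$chrom == ch & segments$class == cls)
      off_c <- which(segments$chrom != ch & segments$class == cls)
      if (length(on_c)) {
        d <- abs(outer(map_x, segments$map_mid[on_c], "-"))
        r <- 0.5 * (1 - exp(-2 * d)) # Haldane map function, capped at 0.5
        for (j in seq_len(ns)) {
          kg <- .kappa_values(grid$s_values[j], segments$M[on_c],
                              kappa_flank, N)
          Qf2 <- 1 / (sweep(sweep(r, 2, 1 - kg, "*"), 2, kg, "+"))^2
          arr[, j, , k] <- arr[, j, , k] -
            0.5 * (Qf2 %*% VA[on_c, j, , drop = TRUE])
        }
      }
      if (length(off_c)) {
        for (j in seq_len(ns)) {
          kg <- .kappa_values(grid$s_values[j], segments$M[off_c],
                              kappa_flank, N)
          qf2u <- 1 / (kg + 0.5 * (1 - kg))^2 # unlinked: r = 1/2
          sumVA <- colSums(matrix(VA[off_c, j, ], nrow = length(off_c)) *
                             qf2u)
          arr[, j, , k] <- sweep(arr[, j, , k, drop = FALSE],
                                 3, 0.5 * sumVA)[, , , 1]
        }
      }
    }
    logB[[ch]] <- arr
  }
  structure(list(chroms = chroms, pos = pos_list, logB = logB, grid = grid,
                 step = step, classes = classes,
                 chrom_lengths = chrom_lengths),
            class = "bgs_bmap")
}

#' Compute the B' reduction map
#'
#' Solves the segment equilibrium system for every conserved segment across
#' the \eqn{(m, s)} grid, then evaluates
#' \deqn{\log B(x; m_i, s_j, k) = -\tfrac12 \sum_{g \in k}
#'   \tilde V_{A,g}(m_i, s_j)\, Q^2(s_j, r_{x,g})}
#' at fixed-step evaluation positions (left edges) along every chromosome,
#' with per-feature-class tensors stored separately so a DFE can later mix
#' classes. Recombination fractions use Haldane's map function on the map
#' distance to the segment midpoint; segments on other chromosomes enter at
#' \eqn{r = 1/2} (the unlinked fitness-variance effect is retained, not
#' dropped).
#'
#' @param segments a `bgs_segments` data frame annotated by [annotate_map()].
#' @param recmap a `bgs_recmap`.
#' @param pop a [population_context()]; `N` may be scaled per segment via
#'   [local_rescale()].
#' @param grid a [grid_axes()].
#' @param step evaluation-position spacing in bp (default 10 kb).
#' @param chrom_lengths named lengths; default taken from the map extent.
#' @param trunc_floor drop a segment's contribution to a grid cell when even
#'   its fully linked contribution to \eqn{|\log B|} is below this floor.
#' @param kappa_flank flanking decay rate: `"s"` (classic, the default;
#'   required for exact classic-BGS equivalence under strong selection) or
#'   `"one_minus_z"` (the drift-extended kernel
#'   \eqn{\kappa = s + M + 1/(2N)}, a sensitivity switch).
#' @param va_form fitness-variance form, see [solve_equilibrium()].
#' @return a `bgs_bmap` object: per-chromosome positions and
#'   `logB[position, s_j, m_i, class]` tensors (log scale, always
#'   \eqn{\le 0}), plus grid and metadata.
#' @export
compute_bprime <- function(segments, recmap, pop, grid, step = 1e4,
                           chrom_lengths = NULL, trunc_floor = 1e-10,
                           kappa_flank = c("s", "one_minus_z"),
                           va_form = c("U-2R", "U-R")) {
  va_form <- match.arg(va_form)
  kappa_flank <- match.arg(kappa_flank)
  stopifnot(inherits(pop, "bgs_population"))
  if (is.null(chrom_lengths))
    chrom_lengths <- .chrom_lengths_from_recmap(recmap)
  VA <- .solve_va_array(segments, grid, pop$N * pop$rescale,
                        va_form = if (va_form == "U-R") 1L else 0L)
  out <- .assemble_map(segments, recmap, grid, step, chrom_lengths, VA,
                       trunc_floor, kappa_flank, pop$N * pop$rescale)
  out$N <- pop$N * pop$rescale
  out$kind <- "bprime"
  out$va_form <- va_form
  out
}

#' Compute the classic background-selection B map
#'
#' Same layout as [compute_bprime()] but with the mutation-selection-balance
#' variance \eqn{V_A = U s} (no substitutions), so each segment's exponent
#' contribution is [classic_b_exponent()]; independent of \eqn{N}.
#'
#' @inheritParams compute_bprime
#' @return a `bgs_bmap` with `kind = "classic"`.
#' @export
compute_classic_b <- function(segments, recmap, grid, step = 1e4,
                              chrom_lengths = NULL, trunc_floor = 1e-10) {
  if (any(grid$s_values <= 0)) {
    warning("classic model undefined at s = 0; such cells excluded")
    grid$s_values <- grid$s_values[grid$s_values > 0]
  }
  if (is.null(chrom_lengths))
    chrom_lengths <- .chrom_lengths_from_recmap(recmap)
  VA <- .classic_va_array(segments, grid)
  out <- .assemble_map(segments, recmap, grid, step, chrom_lengths, VA,
                       trunc_floor)
  out$N <- NA_real_
  out$kind <- "classic"
  out
}

#' Window-averaged reduction factors
#'
#' Arithmetic mean of \eqn{B = e^{\log B}} over the accessible evaluation
#' positions of each window, per grid cell and feature class. Each
#' evaluation position is weighted by the accessible basepairs of its step
#' interval (all of it when `mask` is `NULL`).
#'
#' @param bmap a `bgs_bmap`.
#' @param windows data frame with `chrom`, `start`, `end` (e.g. from
#'   [tile_windows()]).
#' @param mask optional accessibility track.
#' @return array `[window, s_j, m_i, class]` of mean B, with attribute
#'   `flagged` marking windows with no accessible positions.
#' @export
window_mean_B <- function(bmap, windows, mask = NULL) {
  ns <- length(bmap$grid$s_values); nm <- length(bmap$grid$m_values)
  K <- length(bmap$classes)
  W <- nrow(windows)
  out <- array(NA_real_, dim = c(W, ns, nm, K),
               dimnames = list(NULL, NULL, NULL, bmap$classes))
  flagged <- logical(W)
  for (w in seq_len(W)) {
    ch <- windows$chrom[w]
    pos <- bmap$pos[[ch]]
    sel <- which(pos >= windows$start[w] & pos < windows$end[w])
    if (!length(sel)) { flagged[w] <- TRUE; next }
    wt <- .step_weights(ch, pos[sel], bmap$step, windows$end[w], mask)
    if (sum(wt) == 0) { flagged[w] <- TRUE; next }
    Bsub <- exp(bmap$logB[[ch]][sel, , , , drop = FALSE])
    out[w, , , ] <- apply(Bsub, c(2, 3, 4), function(v) sum(v * wt) / sum(wt))
  }
  attr(out, "flagged") <- flagged
  out
}

# accessible-bp weight of each step interval [pos, pos + step) clipped at end
.step_weights <- function(chrom, pos, step, clip_end, mask = NULL) {
  ends <- pmin(pos + step, clip_end)
  if (is.null(mask)) return(ends - pos)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, ends))
  mgr <- GenomicRanges::reduce(methods::as(mask, "GRanges"))
  ov <- GenomicRanges::findOverlaps(gr, mgr)
  inter <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                     mgr[S4Vectors::subjectHits(ov)])
  wt <- numeric(length(pos))
  tab <- rowsum(GenomicRanges::width(inter), S4Vectors::queryHits(ov))
  wt[as.integer(rownames(tab))] <- tab[, 1]
  wt
}

#' Export one grid cell of a reduction map as BedGraph
#'
#' Writes `chrom start end B` lines (0-based half-open step intervals) for
#' a chosen grid cell, suitable for genome browsers.
#'
#' @param bmap a `bgs_bmap`.
#' @param path output file.
#' @param s,m grid-cell coordinates (nearest grid values are used).
#' @param class feature class (default: total across classes).
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(bmap, path, s, m, class = NULL) {
  j <- which.min(abs(log10(bmap$grid$s_values) - log10(s)))
  i <- which.min(abs(log10(bmap$grid$m_values) - log10(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"B %s\"", bmap$kind), con)
  for (ch in bmap$chroms) {
    pos <- bmap$pos[[ch]]
    arr <- bmap$logB[[ch]]
    lb <- if (is.null(class)) {
      if (dim(arr)[4] == 0) rep(0, length(pos))
      else rowSums(matrix(arr[, j, i, ], nrow = length(pos)))
    } else arr[, j, i, class]
    writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, as.integer(pos),
                       as.integer(pmin(pos + bmap$step,
                                       bmap$chrom_lengths[[ch]])),
                       exp(lb)), con)
  }
  invisible(path)
}

#' Locally rescaled B' map
#'
#' Re-solves every segment's equilibrium with the drift-effective size
#' replaced by \eqn{\hat B(x_g) N}, where \eqn{\hat B} is a previously
#' fitted reduction map averaged over a window of `scale` bp around the
#' segment midpoint, then rebuilds the map. This approximates selective
#' (Hill-Robertson) interference between segments; it is exactly
#' [compute_bprime()] when \eqn{\hat B \equiv 1}, and leaves strong-selection
#' cells unchanged (substitution rates there are zero either way).
#'
#' @inheritParams compute_bprime
#' @param bhat data frame `chrom`, `start`, `end`, `B` giving the fitted
#'   reduction \eqn{\hat B(x)}; must cover all segment midpoints, values in
#'   \eqn{(0, 1]}.
#' @param scale averaging window around the segment midpoint (bp).
#' @return a `bgs_bmap` with `kind = "bprime_rescaled"`.
#' @export
local_rescale <- function(segments, recmap, pop, grid, bhat, step = 1e4,
                          chrom_lengths = NULL, scale = 1e3,
                          trunc_floor = 1e-10, va_form = c("U-2R", "U-R")) {
  va_form <- match.arg(va_form)
  if (any(bhat$B <= 0)) stop("local_rescale: bhat must be positive")
  if (is.null(chrom_lengths))
    chrom_lengths <- .chrom_lengths_from_recmap(recmap)
  mid <- (segments$start + segments$end) / 2
  bg <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    lo <- mid[i] - scale / 2; hi <- mid[i] + scale / 2
    rows <- which(bhat$chrom == segments$chrom[i] &
                    bhat$end > lo & bhat$start < hi)
    if (!length(rows))
      stop("local_rescale: bhat does not cover segment at ",
           segments$chrom[i], ":", segments$start[i])
    w <- pmin(bhat$end[rows], hi) - pmax(bhat$start[rows], lo)
    bg[i] <- sum(bhat$B[rows] * w) / sum(w)
  }
  Nv <- pmin(bg, 1) * pop$N * pop$rescale
  VA <- .solve_va_array(segments, grid, pmax(Nv, 2),
                        va_form = if (va_form == "U-R") 1L else 0L)
  out <- .assemble_map(segments, recmap, grid, step, chrom_lengths, VA,
                       trunc_floor)
  out$N <- pop$N * pop$rescale
  out$kind <- "bprime_rescaled"
  out$va_form <- va_form
  out
}
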