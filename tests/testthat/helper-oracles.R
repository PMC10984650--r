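# Shared oracles and fixture builders.  Oracles are deliberately written as
# plain, independent computations (series summation, grid + bisection,
# brute-force scans) so they share no code path with the implementation.

# brute-force geometric-series sum for the flanking autocorrelation factor
q_series_oracle <- function(kappa, r, tol = 1e-14) {
  a <- (1 - r) * (1 - kappa)
  total <- 1
  term <- 1
  t <- 0
  while (TRUE) {
    term <- term * a
    total <- total + term
    t <- t + 1
    if (term < tol * total || t > 1e7) break
  }
  total
}

# independent bracketed-bisection solver for the segment equilibrium system,
# restated from the model equations (not calling the package solver)
equilibrium_oracle <- function(N, U, s, M, tol = 1e-12) {
  drift <- 1 / (2 * N)
  Z <- 1 - s - M - drift
  Q2 <- 2 / ((1 - Z) * (2 - (2 - M) * Z))
  R_of <- function(Nf) {
    x <- 4 * Nf * s
    if (x > 700) return(0)
    if (x < 1e-12) return(U / 2)
    4 * Nf * (U / 2) * s / expm1(x)
  }
  g <- function(Nf) {
    R <- R_of(Nf)
    VA <- max((U - 2 * R) * s, 0)
    Nf - N * exp(-VA * Q2 / 2)
  }
  lo <- N * 1e-12; hi <- N
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) / N < tol) break
  }
  Nf <- (lo + hi) / 2
  R <- R_of(Nf)
  list(Nf = Nf, R = R, VA = max((U - 2 * R) * s, 0))
}

# brute-force per-basepair priority scan over interval tracks
priority_scan_oracle <- function(tracks_df, priority, genome_len) {
  per_bp <- rep(NA_character_, genome_len)
  for (cls in rev(priority)) { # lowest priority first, overwritten by higher
    rows <- tracks_df[tracks_df$class == cls, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      per_bp[(rows$start[i] + 1):rows$end[i]] <- cls
  }
  per_bp
}

# a small deterministic toy genome for map tests
toy_genome <- function(n_segments = 20, chrom_len = 2e6, seed = 1,
                       classes = "conserved", rate_cM_Mb = 1) {
  set.seed(seed)
  len <- round(runif(n_segments, 200, 1500))
  free <- chrom_len - sum(len)
  gaps <- sort(runif(n_segments, 0, free))
  start <- round(gaps + cumsum(c(0, len[-n_segments])))
  seg <- data.frame(chrom = "chr1", start = start, end = start + len,
                    class = sample(classes, n_segments, replace = TRUE),
                    L = len, stringsAsFactors = FALSE)
  class(seg) <- c("bgs_segments", "data.frame")
  rm <- uniform_recmap(c(chr1 = chrom_len), rate_cM_Mb = rate_cM_Mb)
  list(segments = annotate_map(seg, rm), recmap = rm,
       chrom_lengths = c(chr1 = chrom_len))
}

# total log-reduction per position: sum of a map's class layers at one cell
total_logB <- function(bmap, chrom, j, i) {
  arr <- bmap$logB[[chrom]]
  if (dim(arr)[4] == 0) return(rep(0, dim(arr)[1]))
  rowSums(matrix(arr[, j, i, ], nrow = dim(arr)[1]))
}
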