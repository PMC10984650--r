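# Reduction-map algebra: single-segment closed forms, log-additivity,
# classic-vs-B' ordering, window averaging, local rescaling.

make_single_segment <- function(start = 4500, end = 5500, chrom_len = 1e4,
                                rate_cM_Mb = 1) {
  seg <- data.frame(chrom = "chr1", start = start, end = end,
                    class = "conserved", L = end - start)
  class(seg) <- c("bgs_segments", "data.frame")
  rm <- uniform_recmap(c(chr1 = chrom_len), rate_cM_Mb)
  list(segments = annotate_map(seg, rm), recmap = rm,
       chrom_lengths = c(chr1 = chrom_len))
}

test_that("empty segment set gives B = 1 everywhere", {
  g <- make_single_segment()
  empty <- g$segments[0, ]
  bm <- compute_bprime(empty, g$recmap, population_context(1000),
                       grid_axes(s_values = 0.01, m_values = 1e-8),
                       step = 5e3)
  expect_equal(dim(bm$logB$chr1)[4], 0)
  expect_equal(total_logB(bm, "chr1", 1, 1), rep(0, 2))
})

test_that("single strong segment at r = 0 reproduces exp(-mu L / s)", {
  # evaluation position 5000 sits at the segment midpoint (r = 0); large N
  # keeps selection strong so R = 0 and the classic closed form is exact
  g <- make_single_segment(4500, 5500, 1e4, rate_cM_Mb = 0.001)
  grid <- grid_axes(s_values = 0.01, m_values = 1e-8)
  bm <- compute_bprime(g$segments, g$recmap, population_context(1e6), grid,
                       step = 5e3, chrom_lengths = g$chrom_lengths)
  lb <- total_logB(bm, "chr1", 1, 1)
  # position 2 is 5000 = midpoint
  expect_equal(lb[2], -1e-8 * 1000 / 0.01, tolerance = 1e-3)
  expect_equal(exp(lb[2]), exp(-1e-3), tolerance = 1e-4)
  # the flanking position (0) is reduced less
  expect_gt(lb[1], -1e-3)
  expect_lt(lb[1], 0)
})

test_that("maps are log-additive over disjoint segment sets", {
  set.seed(31)
  toy <- toy_genome(12, 2e6, seed = 31)
  segA <- toy$segments[1:6, ]
  segB <- toy$segments[7:12, ]
  grid <- grid_axes(s_values = c(1e-4, 1e-2), m_values = c(1e-9, 1e-8))
  pop <- population_context(1000)
  bmA <- compute_bprime(segA, toy$recmap, pop, grid, step = 1e5)
  bmB <- compute_bprime(segB, toy$recmap, pop, grid, step = 1e5)
  bmAB <- compute_bprime(toy$segments, toy$recmap, pop, grid, step = 1e5)
  expect_equal(bmAB$logB$chr1, bmA$logB$chr1 + bmB$logB$chr1,
               tolerance = 1e-12)
  # monotonicity: adding segments can only decrease B
  expect_true(all(bmAB$logB$chr1 <= bmA$logB$chr1 + 1e-15))
})

test_that("classic B is a lower bound on B' and matches it under strong selection", {
  grid <- grid_axes(s_values = 10^seq(-6, -2), m_values = 10^seq(-9, -8))
  for (seed in 1:10) {
    toy <- toy_genome(15, 1e6, seed = seed)
    pop <- population_context(1000)
    bp <- compute_bprime(toy$segments, toy$recmap, pop, grid, step = 1e5)
    cl <- compute_classic_b(toy$segments, toy$recmap, grid, step = 1e5)
    expect_true(all(cl$logB$chr1 <= bp$logB$chr1 + 1e-12))
  }
  # strong-selection cells agree to high relative accuracy
  toy <- toy_genome(15, 1e6, seed = 99)
  gridS <- grid_axes(s_values = c(0.02, 0.1), m_values = c(1e-9, 1e-8))
  pop <- population_context(1000) # 2Ns >= 40000 * 0.001
  bp <- compute_bprime(toy$segments, toy$recmap, pop, gridS, step = 1e5)
  cl <- compute_classic_b(toy$segments, toy$recmap, gridS, step = 1e5)
  expect_equal(bp$logB$chr1, cl$logB$chr1, tolerance = 1e-8)
})

test_that("unlinked segments still contribute at r = 1/2", {
  # two chromosomes; segments only on chr1; chr2 map must show the
  # unlinked-variance effect mu L s / (s + (1-s)/2)^2 per segment
  seg <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                    class = "conserved", L = 1000)
  class(seg) <- c("bgs_segments", "data.frame")
  rm <- uniform_recmap(c(chr1 = 1e4, chr2 = 1e4))
  segs <- annotate_map(seg, rm)
  grid <- grid_axes(s_values = 0.01, m_values = 1e-8)
  bm <- compute_bprime(segs, rm, population_context(1e6), grid, step = 5e3)
  expected <- -classic_b_exponent(1e-8, 1000, 0.01, 0.5)
  expect_equal(total_logB(bm, "chr2", 1, 1), rep(expected, 2),
               tolerance = 1e-6)
})

test_that("B' map over s is U-shaped near a segment, classic is monotone", {
  g <- make_single_segment(4000, 6000, 1e4, rate_cM_Mb = 1)
  sv <- 10^seq(-8, -2, length.out = 25)
  grid <- grid_axes(s_values = sv, m_values = 1e-8)
  pop <- population_context(1000)
  bm <- compute_bprime(g$segments, g$recmap, pop, grid, step = 2500,
                       chrom_lengths = g$chrom_lengths)
  cl <- compute_classic_b(g$segments, g$recmap, grid, step = 2500,
                          chrom_lengths = g$chrom_lengths)
  # nearest evaluation position to the segment (small positive r)
  lb <- bm$logB$chr1[2, , 1, 1] # position 2500, ~2.5 kb from midpoint
  lc <- cl$logB$chr1[2, , 1, 1]
  k <- which.min(lb)
  expect_gt(k, 1); expect_lt(k, length(sv)) # interior minimum
  expect_gt(2 * 1000 * sv[k], 0.1)
  expect_lt(2 * 1000 * sv[k], 20)
  expect_gt(exp(lb[1]), 0.9999) # neutral end: essentially no reduction
  # weak-selection contrast (2Ns ~ 0.2, still s >> r): moving below the B'
  # dip, B' recovers toward neutrality while the classic reduction deepens
  j <- which.min(abs(sv - 1e-4))
  expect_gt(lb[j], lb[k])  # B' shallower than at its dip
  expect_lt(lc[j], lc[k])  # classic deeper than at the B' dip
  expect_gt(lc[k] - lc[j], 5 * (lb[j] - lb[k]))
})

test_that("window_mean_B averages with mask weights", {
  g <- make_single_segment()
  grid <- grid_axes(s_values = 0.01, m_values = 1e-8)
  bm <- compute_bprime(g$segments, g$recmap, population_context(1000), grid,
                       step = 1e3, chrom_lengths = g$chrom_lengths)
  wins <- tile_windows(g$chrom_lengths, 5e3)
  wb <- window_mean_B(bm, wins)
  # direct recomputation
  for (w in 1:2) {
    pos <- bm$pos$chr1
    sel <- pos >= wins$start[w] & pos < wins$end[w]
    expect_equal(unname(wb[w, 1, 1, 1]),
                 mean(exp(bm$logB$chr1[sel, 1, 1, 1])))
  }
  # random mask: equals brute-force masked (weighted) mean
  set.seed(4)
  st <- sort(sample(seq(0, 9000, by = 250), 12))
  mask <- feature_track(rep("chr1", 12), st, st + 200, "acc")
  wbm <- window_mean_B(bm, wins, mask = mask)
  pos <- bm$pos$chr1
  wt <- sapply(pos, function(p) {
    sum(pmax(0, pmin(st + 200, p + 1e3) - pmax(st, p)))
  })
  for (w in 1:2) {
    sel <- pos >= wins$start[w] & pos < wins$end[w]
    expect_equal(unname(wbm[w, 1, 1, 1]),
                 sum(exp(bm$logB$chr1[sel, 1, 1, 1]) * wt[sel]) / sum(wt[sel]))
  }
  # fully masked window is flagged
  mask2 <- feature_track("chr1", 0, 4999, "acc")
  wbf <- window_mean_B(bm, wins, mask = mask2)
  expect_true(attr(wbf, "flagged")[2])
})

test_that("local rescaling is a no-op at B-hat = 1 and under strong selection", {
  toy <- toy_genome(10, 1e6, seed = 8)
  grid <- grid_axes(s_values = c(1e-4, 1e-3, 1e-2), m_values = c(1e-9, 1e-8))
  pop <- population_context(1000)
  bm <- compute_bprime(toy$segments, toy$recmap, pop, grid, step = 1e5)
  bhat1 <- data.frame(chrom = "chr1", start = 0, end = 1e6, B = 1)
  rs1 <- local_rescale(toy$segments, toy$recmap, pop, grid, bhat1,
                       step = 1e5)
  expect_equal(rs1$logB$chr1, bm$logB$chr1, tolerance = 1e-12)
  # with a genuine reduction, strong-selection cells (2Ns = 20 at the
  # rescaled size) are unchanged; weak cells move toward neutrality
  bhat <- data.frame(chrom = "chr1", start = 0, end = 1e6, B = 0.7)
  rs <- local_rescale(toy$segments, toy$recmap, pop, grid, bhat, step = 1e5)
  # s = 1e-2: 2 * 0.7 * 1000 * s = 14 >> 1, R = 0 either way
  expect_equal(rs$logB$chr1[, 3, , ], bm$logB$chr1[, 3, , ],
               tolerance = 1e-9)
  # s = 1e-4 (2Ns ~ 0.2): reduced efficacy pushes B' toward 1
  expect_true(all(rs$logB$chr1[, 1, , ] >= bm$logB$chr1[, 1, , ] - 1e-12))
  expect_gt(sum(rs$logB$chr1[, 1, , ] - bm$logB$chr1[, 1, , ]), 0)
  expect_error(local_rescale(toy$segments, toy$recmap, pop, grid,
                             data.frame(chrom = "chr1", start = 0, end = 1e6,
                                        B = 0), step = 1e5),
               "positive")
  # averaging-scale robustness: a smoothly varying B-hat gives nearly the
  # same rescaled map whether averaged over 1 kb or 100 kb
  bsm <- data.frame(chrom = "chr1", start = seq(0, 9e5, by = 1e5),
                    end = seq(1e5, 1e6, by = 1e5),
                    B = seq(0.75, 0.95, length.out = 10))
  r1 <- local_rescale(toy$segments, toy$recmap, pop, grid, bsm,
                      step = 1e5, scale = 1e3)
  r2 <- local_rescale(toy$segments, toy$recmap, pop, grid, bsm,
                      step = 1e5, scale = 1e5)
  expect_lt(max(abs(r1$logB$chr1 - r2$logB$chr1)),
            0.05 * max(abs(r1$logB$chr1)))
})
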