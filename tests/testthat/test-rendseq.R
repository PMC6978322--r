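test_that("Delta_S finds the 3'-end peak in the 10-bp terminator window", {
  tr <- make_spike_tracks(spike3 = 8L)
  ds <- compute_delta_S(tr, 1000, "+")
  expect_identical(ds$k_max, 8L)
  expect_equal(ds$Delta_S, 3)
  expect_identical(ds$position, 1000L)

  # k_max = 1 gives Delta_S = 0; empty window gives NA
  tr1 <- make_spike_tracks(spike3 = 1L)
  expect_equal(compute_delta_S(tr1, 1000, "+")$Delta_S, 0)
  tr0 <- make_spike_tracks(spike3 = 0L)
  expect_true(is.na(compute_delta_S(tr0, 1000, "+")$Delta_S))

  # ties resolve to the leftmost coordinate
  trt <- make_spike_tracks(spike3 = 5L)
  trt$three_plus[998] <- 5L
  expect_identical(compute_delta_S(trt, 1000, "+")$position, 998L)

  # a strong spike dominates Poisson background in the window
  set.seed(5)
  trb <- end_tracks(rpois(2000, 2), rpois(2000, 2), rpois(2000, 2),
                    rpois(2000, 2))
  trb$three_plus[1000] <- trb$three_plus[1000] + 64L
  dsb <- compute_delta_S(trb, 1000, "+")
  expect_identical(dsb$position, 1000L)
  expect_equal(dsb$Delta_S, log2(trb$three_plus[1000]))
})

test_that("Delta_AS searches +/-500 bp on the opposite strand", {
  tr <- make_spike_tracks(spike3 = 8L, spike5 = 16L, as_offset = 120L)
  da <- compute_delta_AS(tr, 1000, "+")
  expect_identical(da$k_max2, 16L)
  expect_equal(da$Delta_AS, 4)
  expect_identical(da$position, 1120L)
  expect_identical(da$distance, 120L)

  # minus-strand terminator: distance follows the terminator orientation
  trm <- make_spike_tracks(strand = "-", spike3 = 8L, spike5 = 16L,
                           as_offset = 120L)
  dam <- compute_delta_AS(trm, 1000, "-")
  expect_identical(dam$position, 880L)
  expect_identical(dam$distance, 120L)

  # empty search window
  tre <- make_spike_tracks(spike3 = 8L, spike5 = 0L)
  expect_true(is.na(compute_delta_AS(tre, 1000, "+")$Delta_AS))
})

test_that("Delta is monotone in the underlying counts", {
  tr <- make_spike_tracks(spike3 = 8L, spike5 = 16L)
  base_S <- compute_delta_S(tr, 1000, "+")$Delta_S
  base_AS <- compute_delta_AS(tr, 1000, "+")$Delta_AS
  for (bump in c(1L, 10L, 100L)) {
    tr2 <- tr
    tr2$three_plus[1003] <- tr2$three_plus[1003] + bump
    tr2$five_minus[900] <- tr2$five_minus[900] + bump
    expect_gte(compute_delta_S(tr2, 1000, "+")$Delta_S, base_S)
    expect_gte(compute_delta_AS(tr2, 1000, "+")$Delta_AS, base_AS)
  }
})

test_that("peak z-score follows the Poisson oracle and the floor rule", {
  # flat track: sd floored, z exactly 0
  expect_equal(peak_zscore(rep(5L, 200), 100), 0)

  # spike over i.i.d. Poisson flanks: z ~= (h - lambda)/sqrt(lambda)
  lam <- 4; h <- 40
  set.seed(9)
  zs <- replicate(300, {
    track <- rpois(301, lam)
    track[151] <- h
    peak_zscore(track, 151, flank = 150)
  })
  oracle <- (h - lam) / sqrt(lam)
  expect_lt(abs(mean(zs) - oracle) / oracle, 0.05)

  # vectorised track transform agrees with the single-position version
  set.seed(10)
  track <- rpois(400, 3)
  zt <- zscore_track(track, flank = 50, exclusion = 2)
  for (p in c(60, 200, 341))
    expect_equal(zt[p], peak_zscore(track, p, flank = 50, exclusion = 2),
                 tolerance = 1e-12)
})

test_that("terminator eligibility requires same-orientation flanking genes", {
  genes <- data.frame(start = c(100, 400, 700), end = c(200, 500, 800),
                      strand = c("+", "+", "+"))
  t_ok <- filter_terminators(data.frame(position = 300, strand = "+"), genes)
  expect_true(t_ok$eligible)

  # convergent pair downstream: ineligible
  genes2 <- data.frame(start = c(100, 400), end = c(200, 500),
                       strand = c("+", "-"))
  t_bad <- filter_terminators(data.frame(position = 300, strand = "+"),
                              genes2)
  expect_false(t_bad$eligible)

  # synthetic genome: eligible count matches the construction (the last
  # operon of each same-orientation run borders the next run)
  g <- synthetic_genome(n_operons = 12, operon_run = 3)
  term <- filter_terminators(g$terminators, g$genes)
  expect_identical(sum(term$eligible), 8L)
})

test_that("distance profile localises planted offsets and fractions", {
  g <- synthetic_genome(n_operons = 8)
  cfg <- rend_sim_config(g$genome_length, g$genes, g$terminators,
                         background_rate = 0, term_peak_height = 8L,
                         antisense_peak_height = 40L,
                         fraction_with_antisense = 1,
                         antisense_offset = function(n) rep(120L, n),
                         seed = 4)
  sim <- simulate_rendseq(cfg)
  term <- filter_terminators(g$terminators, g$genes)
  prof <- distance_profile(sim$tracks, term)
  hot <- prof$distance[prof$fraction > 0]
  expect_identical(hot, 200L)  # the only bin whose window contains +120

  # no antisense planted: all fractions zero on clean background
  cfg0 <- rend_sim_config(g$genome_length, g$genes, g$terminators,
                          background_rate = 0, fraction_with_antisense = 0,
                          seed = 4)
  sim0 <- simulate_rendseq(cfg0)
  prof0 <- distance_profile(sim0$tracks, term)
  expect_true(all(prof0$fraction == 0))

  # planted fraction is recovered within 3 binomial s.e.
  g2 <- synthetic_genome(n_operons = 60, operon_run = 30)
  cfg2 <- rend_sim_config(g2$genome_length, g2$genes, g2$terminators,
                          background_rate = 0.2, term_peak_height = 64L,
                          antisense_peak_height = 40L,
                          fraction_with_antisense = 0.2,
                          antisense_offset = function(n)
                            sample(c(-80:-20, 20:80), n, replace = TRUE),
                          seed = 5)
  sim2 <- simulate_rendseq(cfg2)
  term2 <- filter_terminators(g2$terminators, g2$genes)
  prof2 <- distance_profile(sim2$tracks, term2, bin = 200, max_dist = 0)
  n_el <- sum(term2$eligible)
  se <- sqrt(0.2 * 0.8 / n_el)
  expect_lt(abs(prof2$fraction - 0.2), 3 * se)
})

test_that("strand-aware statistics are invariant under genome mirroring", {
  set.seed(13)
  g <- synthetic_genome(n_operons = 4)
  cfg <- rend_sim_config(g$genome_length, g$genes, g$terminators,
                         background_rate = 0.5, term_peak_height = 32L,
                         antisense_peak_height = 24L,
                         fraction_with_antisense = 1,
                         antisense_offset = function(n) rep(75L, n),
                         seed = 6)
  sim <- simulate_rendseq(cfg)
  L <- g$genome_length
  mirrored <- mirror_tracks(sim$tracks)
  for (i in seq_len(nrow(g$terminators))) {
    p <- g$terminators$position[i]
    s <- g$terminators$strand[i]
    pm <- mirror_position(p, L)
    sm <- flip_strand(s)
    expect_equal(compute_delta_S(sim$tracks, p, s)$Delta_S,
                 compute_delta_S(mirrored, pm, sm)$Delta_S)
    a <- compute_delta_AS(sim$tracks, p, s)
    am <- compute_delta_AS(mirrored, pm, sm)
    expect_equal(a$Delta_AS, am$Delta_AS)
    expect_equal(a$distance, am$distance)
    z <- peak_zscore(track_for_test(sim$tracks, s), a$position)
    zm <- peak_zscore(track_for_test(mirrored, sm), am$position)
    expect_equal(z, zm, tolerance = 1e-12)
  }
})

test_that("control locations always satisfy both constraints", {
  g <- synthetic_genome(n_operons = 12)
  for (seed in 1:5) {
    loc <- sample_control_locations(g$genes, g$terminators, n = 30,
                                    seed = seed)
    # > 700 nt from every terminator
    dmin <- vapply(loc$position, function(p)
      min(abs(p - g$terminators$position)), numeric(1))
    expect_true(all(dmin > 700))
    # inside a run of >= 3 same-orientation genes, on the run's strand
    genes <- g$genes[order(g$genes$start), ]
    run_id <- cumsum(c(1, diff(as.integer(factor(genes$strand))) != 0))
    for (j in seq_len(nrow(loc))) {
      inside <- genes$start <= loc$position[j] & genes$end >= loc$position[j]
      expect_true(any(inside))
      expect_identical(unique(genes$strand[inside]), loc$strand[j])
    }
  }
  # impossible constraints produce an informative error
  expect_error(sample_control_locations(g$genes, g$terminators, n = 10,
                                        min_dist = 1e7),
               "pool has 0")
})

test_that("information content separates conserved from random sequence", {
  # identical sequences: 2 bits per position without correction
  gen <- random_genome(600, seed = 3)
  pos <- rep(300L, 10)
  info <- tss_information_content(gen, pos, rep("+", 10), correct = FALSE)
  expect_equal(nrow(info), 7L)
  expect_equal(info$bits, rep(2, 7))

  # i.i.d. uniform windows: ~0 bits after small-sample correction
  gen2 <- random_genome(60000, seed = 4)
  pos2 <- seq(100L, 59900L, length.out = 500)
  info2 <- tss_information_content(gen2, as.integer(pos2),
                                   rep("+", 500), correct = TRUE)
  expect_lt(max(abs(info2$bits)), 0.05)

  # minus-strand windows are reverse-complemented: a planted motif on the
  # minus strand is recovered in motif orientation
  motif <- "TATAATG"
  gseq <- paste(rep("ACGT", 250), collapse = "")
  gs <- Biostrings::DNAString(gseq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  # plant rc at positions so that minus-strand read-out is the motif
  starts <- c(101L, 301L, 501L)
  for (s in starts)
    gs <- Biostrings::replaceLetterAt(
      gs, s:(s + 6L), rc)
  centers <- starts + 3L
  infom <- tss_information_content(gs, centers, rep("-", 3),
                                   correct = FALSE)
  freq <- attr(infom, "freq")
  expect_equal(unname(freq["T", 1]), 1)   # motif position 1 is T
  expect_equal(unname(freq["A", 2]), 1)
  expect_equal(infom$bits, rep(2, 7))     # all three reads identical

  expect_error(tss_information_content(gen, 1L, "+"), "two peak")
})
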