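# Base-wise depth extraction and background normalisation.

test_that("single-read and empty-window pileups are exact", {
  bam <- make_bam(data.frame(pos1 = 101L, cigar = "150M"))
  rd <- extract_rd_vector(bam, screening_window("chrT", 100L, 100L))
  expect_equal(rd$values, rep(1L, 100L))
  expect_false(rd$normalized)
  rd0 <- extract_rd_vector(bam, screening_window("chrT", 5000L, 100L))
  expect_equal(rd0$values, rep(0L, 100L))
})

test_that("overlapping reads stack and partial overlaps clip correctly", {
  # reads spanning [100,250) and [150,300), 0-based
  bam <- make_bam(data.frame(pos1 = c(101L, 151L), cigar = "150M"))
  rd <- extract_rd_vector(bam, screening_window("chrT", 100L, 200L))
  expect_equal(rd$values, c(rep(1L, 50), rep(2L, 100), rep(1L, 50)))
})

test_that("depth counting is CIGAR-aware: deletions covered, clips not", {
  bam <- make_bam(data.frame(pos1 = c(11L, 11L),
                             cigar = c("10M5D10M", "5S20M")))
  rd <- extract_rd_vector(bam, screening_window("chrT", 0L, 50L))
  # both reads span reference [10, 35) and [10, 30): depth 2 on [10,30), 1 on [30,35)
  exp <- integer(50)
  exp[11:30] <- 2L; exp[31:35] <- 1L
  expect_equal(rd$values, exp)
})

test_that("mapping-quality and secondary-alignment filters apply", {
  bam <- make_bam(data.frame(pos1 = c(101L, 101L, 101L),
                             cigar = "50M",
                             mapq = c(0L, 60L, 60L),
                             flag = c(0L, 0L, 256L)))   # one secondary
  all_reads <- extract_rd_vector(bam, screening_window("chrT", 100L, 50L))
  expect_equal(unique(all_reads$values), 2L)   # secondary dropped
  hi <- extract_rd_vector(bam, screening_window("chrT", 100L, 50L),
                          min_mapq = 30L)
  expect_equal(unique(hi$values), 1L)
})

test_that("extraction equals a brute-force span count on a random fixture", {
  set.seed(11)
  n <- 150L
  pos1 <- sample.int(2000L, n, replace = TRUE)
  len <- sample(20:120, n, replace = TRUE)
  bam <- make_bam(data.frame(pos1 = pos1, cigar = sprintf("%dM", len)))
  w <- screening_window("chrT", 500L, 800L)
  rd <- extract_rd_vector(bam, w)
  brute <- vapply(w$start + seq_len(w$length) - 1L, function(b) {
    sum(pos1 - 1L <= b & pos1 - 1L + len > b)
  }, numeric(1))
  expect_equal(rd$values, as.integer(brute))
})

test_that("bad windows raise classed errors", {
  bam <- make_bam(data.frame(pos1 = 101L, cigar = "50M"))
  expect_error(extract_rd_vector(bam, screening_window("chrZ", 0L, 50L)),
               class = "contig_not_found")
  expect_error(extract_rd_vector(bam, screening_window("chrT", 9990L, 50L)),
               class = "window_out_of_bounds")
})

test_that("z-normalisation matches hand arithmetic and is invertible", {
  w <- screening_window("chrT", 0L, 3L)
  stats <- structure(list(mean = 20, std = 10, n_bins_sampled = 10L,
                          bin_size = 100L, seed = 1L), class = "depth_stats")
  rd <- rd_vector(w, c(10L, 20L, 40L))
  z <- normalize_rd(rd, stats)
  expect_equal(z$values, c(-1, 0, 2))
  expect_true(z$normalized)
  expect_identical(z$window, w)
  # constant at the mean -> zeros; mean + sd -> exactly 1
  expect_equal(normalize_rd(rd_vector(w, rep(20L, 3)), stats)$values,
               rep(0, 3))
  expect_equal(normalize_rd(rd_vector(w, rep(30L, 3)), stats)$values[1], 1.0)
  expect_error(normalize_rd(z, stats), class = "double_normalization")
  back <- denormalize_rd(z, stats)
  expect_equal(as.numeric(back$values), as.numeric(rd$values),
               tolerance = 1e-9)
})

test_that("background stats recover the simulated Poisson depth", {
  sim <- small_sim()
  st <- small_stats()
  # pooled mean within 3 standard errors of lambda = 30 (reads are 125 bp
  # long so adjacent bases are correlated; ~1 independent draw per read
  # length of pooled bin sequence)
  n_eff <- st$n_bins_sampled * st$bin_size / sim$cfg$read_length
  se <- sqrt(30 / n_eff)
  expect_lt(abs(st$mean - 30), 3 * se)
  expect_gt(st$std, 0)
  # deterministic given the seed
  st2 <- estimate_background_stats(
    sim$source, genome = sim$genome,
    exclude = GenomicRanges::GRanges(
      sim$svs$chrom, IRanges::IRanges(sim$svs$start + 1L, sim$svs$end)),
    n_bins = 80L, bin_size = 500L, seed = 7L)
  expect_identical(st[c("mean", "std", "n_bins_sampled")],
                   st2[c("mean", "std", "n_bins_sampled")])
})

test_that("degenerate and exhausted backgrounds raise classed errors", {
  # perfectly regular read spacing -> constant interior depth
  rl <- 50L
  s0 <- seq(0L, 10000L - rl, by = 5L)
  src <- svrefine:::sim_reads_source(data.frame(start = s0, end = s0 + rl),
                                     "c", 10000L)
  edges <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 9800), c(200, 10000)))
  expect_error(
    estimate_background_stats(src, exclude = edges, n_bins = 10L,
                              bin_size = 200L, seed = 2L),
    class = "degenerate_background")
  whole <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 10000))
  expect_error(
    estimate_background_stats(src, exclude = whole, n_bins = 10L,
                              bin_size = 200L, seed = 2L),
    class = "no_background_available")
})
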