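# Training-window construction and per-base SV-overlap labels.

plain_svs <- function(start, end, chrom = "c", svtype = "DEL") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             svtype = rep_len(svtype, n),
             id = sprintf("s%d", seq_len(n)),
             source = rep_len("test", n), stringsAsFactors = FALSE)
}

test_that("overlap_mask marks exactly the SV-covered bases", {
  w <- screening_window("c", 0L, 10L)
  m <- overlap_mask(w, plain_svs(4L, 8L))
  expect_equal(m$marks, c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0))
  expect_equal(overlap_mask(w, plain_svs(integer(0), integer(0)))$marks,
               rep(0L, 10L))
  expect_equal(overlap_mask(w, plain_svs(0L, 50L))$marks, rep(1L, 10L))
})

test_that("overlap_mask agrees with brute-force membership (1000 trials)", {
  set.seed(21)
  for (trial in seq_len(1000)) {
    ws <- sample.int(500L, 1L) - 1L
    wl <- sample(5:40, 1L)
    k <- sample.int(4L, 1L)
    st <- sample.int(600L, k) - 1L
    en <- st + sample.int(80L, k)
    svs <- plain_svs(st, en)
    m <- overlap_mask(screening_window("c", ws, wl), svs)$marks
    base <- ws + seq_len(wl) - 1L
    brute <- vapply(base, function(b) any(st <= b & b < en), logical(1))
    if (!identical(m, as.integer(brute))) {
      fail(sprintf("mismatch at trial %d", trial))
    }
  }
  succeed()
})

test_that("positive-window shifts are uniform on [10, l-10]", {
  n_sv <- 5000L
  svs <- sv_set("c", seq(0, by = 2000, length.out = n_sv),
                seq(0, by = 2000, length.out = n_sv) + 500L, "DEL")
  pos <- sample_positive_windows(svs, l = 400L, seed = 33L)
  expect_gte(nrow(pos), 9999)        # two windows per SV, few boundary drops
  expect_true(all(pos$delta >= 10L & pos$delta <= 390L))
  expect_true(all(pos$start == ifelse(pos$side == "left",
                                      svs$start[match(pos$sv_id, svs$id)],
                                      svs$end[match(pos$sv_id, svs$id)]) -
                    pos$delta))
  # chi-square goodness of fit against the discrete uniform on [10, 390]
  tab <- table(factor(pos$delta, levels = 10:390))
  p <- stats::chisq.test(as.integer(tab))$p.value
  expect_gt(p, 0.01)
})

test_that("windows with under 10 bp of anchor overlap are excluded", {
  # an SV of exactly 50 bp: right-breakpoint windows with delta < 10 would
  # have < 10 bp overlap, but delta >= 10 by construction, so all survive;
  # verify the recorded overlap is always >= 10 bp.
  svs <- sv_set("c", 1000L, 1050L, "DEL")
  pos <- sample_positive_windows(svs, l = 400L, seed = 5L)
  for (i in seq_len(nrow(pos))) {
    ov <- min(1050L, pos$start[i] + 400L) - max(1000L, pos$start[i])
    expect_gte(ov, 10L)
  }
  expect_equal(nrow(sample_positive_windows(svs[0, ], 400L, 1L)), 0L)
})

test_that("negative windows avoid SVs and exhaust gracefully", {
  sim <- small_sim()
  neg <- sample_negative_windows(sim$genome, sim$svs, n = 50L, l = 200L,
                                 seed = 9L)
  expect_equal(nrow(neg), 50L)
  for (i in seq_len(nrow(neg))) {
    m <- overlap_mask(screening_window(neg$chrom[i], neg$start[i], 200L),
                      sim$svs)
    expect_equal(sum(m$marks), 0L)
  }
  expect_equal(nrow(sample_negative_windows(sim$genome, sim$svs, 0L, 200L, 1L)),
               0L)
  tiling <- sv_set("sim1", 0L, sim$genome[["sim1"]], "DEL")
  expect_error(
    sample_negative_windows(sim$genome, tiling, 5L, 200L, 1L),
    class = "sampling_exhausted")
})

test_that("build_training_set balances classes, filters, and is seeded", {
  sim <- small_sim()
  st <- small_stats()
  ts <- build_training_set(sim$source, sim$svs, st, sim$genome, l = 96L,
                           seed = 12L)
  expect_s3_class(ts, "training_set")
  expect_equal(sum(ts$meta$role == "positive"),
               sum(ts$meta$role == "negative"))
  expect_equal(ncol(ts$x), 96L)
  expect_equal(dim(ts$x), dim(ts$y))
  # no raw all-zero window survives: a raw zero maps to (0 - mean)/sd
  zero_z <- (0 - st$mean) / st$std
  expect_false(any(apply(ts$x, 1, function(r) all(abs(r - zero_z) < 1e-12))))
  # masks are consistent with the truthset
  i <- which(ts$meta$role == "positive")[1]
  m <- overlap_mask(screening_window(ts$meta$chrom[i], ts$meta$start[i], 96L),
                    sim$svs)
  expect_equal(ts$y[i, ], m$marks)
  ts2 <- build_training_set(sim$source, sim$svs, st, sim$genome, l = 96L,
                            seed = 12L)
  expect_identical(ts$x, ts2$x)
  expect_identical(ts$meta, ts2$meta)
})

test_that("a coverage-free sample yields an empty-training-set error", {
  sim <- small_sim()
  st <- small_stats()
  empty_src <- svrefine:::sim_reads_source(
    data.frame(start = integer(0), end = integer(0)),
    "sim1", sim$cfg$genome_length)
  expect_error(
    build_training_set(empty_src, sim$svs, st, sim$genome, l = 96L, seed = 1L),
    class = "empty_training_set")
})

test_that("training sets round-trip through the text archive", {
  sim <- small_sim()
  st <- small_stats()
  ts <- build_training_set(sim$source, sim$svs, st, sim$genome, l = 96L,
                           seed = 12L)
  dir <- tempfile("tsarchive")
  save_training_set(ts, dir)
  expect_true(all(file.exists(file.path(dir, c("depth.tsv", "labels.tsv",
                                               "windows.tsv",
                                               "manifest.json")))))
  back <- load_training_set(dir)
  expect_equal(back$x, ts$x, tolerance = 1e-12)
  expect_identical(back$y, matrix(as.integer(ts$y), nrow(ts$y)))
  expect_equal(back$meta$role, ts$meta$role)
  expect_equal(back$l, ts$l)
  expect_equal(back$seed, ts$seed)
  expect_equal(back$stats$mean, st$mean)
})
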