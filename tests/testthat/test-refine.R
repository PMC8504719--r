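# Mask-to-breakpoint refinement and VCF post-processing.

test_that("mask_to_candidates finds run boundaries per side", {
  w <- screening_window("c", 100L, 7L)
  m <- label_mask(w, c(0, 0, 0, 1, 1, 1, 0))
  expect_equal(mask_to_candidates(m, "left"), 103L)
  expect_equal(mask_to_candidates(m, "right"), 106L)
  expect_equal(mask_to_candidates(label_mask(w, rep(0L, 7L)), "left"),
               integer(0))
  m2 <- label_mask(w, c(0, 1, 1, 0, 0, 1, 1))
  expect_equal(mask_to_candidates(m2, "left"), c(101L, 105L))
  expect_equal(mask_to_candidates(m2, "right"), c(103L, 107L))
})

test_that("refine_breakpoint handles n = 0 / 1 / >1 and breaks ties low", {
  expect_equal(refine_breakpoint(200L, 195L), 195L)
  expect_equal(refine_breakpoint(200L, c(180L, 205L)), 205L)
  expect_equal(refine_breakpoint(200L, integer(0)), 200L)
  expect_equal(refine_breakpoint(200L, c(195L, 205L)), 195L)  # tie -> smaller
})

test_that("enhance_sv recovers exact truth breakpoints from oracle masks", {
  sim <- small_sim()
  st <- small_stats()
  model <- oracle_model(sim$svs, l = 400L)
  # pick an SV away from the contig ends
  sv <- sim$svs[which(sim$svs$start > 1000 &
                        sim$svs$end < sim$cfg$genome_length - 1000)[3], ]
  off <- list(chrom = sv$chrom, start = sv$start + 30L, end = sv$end - 20L,
              id = sv$id)
  rec <- enhance_sv(off, model, sim$source, st, l = 400L)
  expect_equal(rec$new_start, sv$start)
  expect_equal(rec$new_end, sv$end)
  expect_true(all(c(rec$left_outcome, rec$right_outcome) %in%
                    c("updated", "multi-candidate-nearest")))
  # refined coordinates stay inside the screening windows
  expect_lte(abs(rec$new_start - off$start), 200L)
  expect_lte(abs(rec$new_end - off$end), 200L)
})

test_that("the 50 bp size guard restores both original boundaries", {
  truth <- sv_set("c", 1000L, 1060L, "DEL")
  s0 <- seq(0L, 9950L, by = 5L)
  src <- svrefine:::sim_reads_source(data.frame(start = s0, end = s0 + 50L),
                                     "c", 10000L)
  st <- structure(list(mean = 10, std = 2), class = "depth_stats")
  # oracle truth much narrower than the candidate: guard must trigger
  narrow <- data.frame(chrom = "c", start = 1020L, end = 1045L,
                       svtype = "DEL", id = "n1", source = "t")
  model <- oracle_model(narrow, l = 400L)
  cand <- list(chrom = "c", start = 1000L, end = 1060L, id = "sv1")
  rec <- enhance_sv(cand, model, src, st, l = 400L)
  expect_equal(rec$new_start, 1000L)
  expect_equal(rec$new_end, 1060L)
  expect_equal(rec$left_outcome, "retained-size-guard")
  expect_equal(rec$right_outcome, "retained-size-guard")
})

test_that("all-zero masks and off-contig windows retain the original SV", {
  s0 <- seq(0L, 4950L, by = 5L)
  src <- svrefine:::sim_reads_source(data.frame(start = s0, end = s0 + 50L),
                                     "c", 5000L)
  st <- structure(list(mean = 10, std = 2), class = "depth_stats")
  model <- oracle_model(sv_set("zzz", 0L, 100L, "DEL"), l = 400L)  # no overlap
  cand <- list(chrom = "c", start = 2000L, end = 2300L, id = "sv1")
  rec <- enhance_sv(cand, model, src, st, l = 400L)
  expect_equal(rec$new_start, 2000L)
  expect_equal(rec$new_end, 2300L)
  expect_equal(rec$left_outcome, "retained-no-candidate")
  # windows falling off the contig retain coordinates with a warning
  edge <- list(chrom = "c", start = 50L, end = 4990L, id = "sv2")
  expect_warning(rec2 <- enhance_sv(edge, model, src, st, l = 400L),
                 class = "window_off_contig")
  expect_equal(rec2$new_start, 50L)
  expect_equal(rec2$new_end, 4990L)
})

test_that("a short screening window triggers the four-bin warning", {
  s0 <- seq(0L, 4950L, by = 5L)
  src <- svrefine:::sim_reads_source(data.frame(start = s0, end = s0 + 50L),
                                     "c", 5000L)
  st <- structure(list(mean = 10, std = 2), class = "depth_stats")
  model <- oracle_model(sv_set("c", 2000L, 2200L, "DEL"), l = 400L)
  cand <- list(chrom = "c", start = 2000L, end = 2200L, id = "s")
  expect_warning(enhance_sv(cand, model, src, st, l = 400L, bin_size = 150L),
                 class = "short_window")
})

test_that("enhance_callset updates DEL/DUP records and passes others through", {
  sim <- small_sim()
  st <- small_stats()
  model <- oracle_model(sim$svs, l = 400L)
  cand <- degrade_candidates(sim)
  keep <- cand$start > 1000 & cand$end < sim$cfg$genome_length - 1000
  cand <- cand[keep, ][1:10, ]
  vcf_in <- tempfile(fileext = ".vcf")
  write_sv_vcf(cand, vcf_in, genome = sim$genome)
  # append an INV record that must pass through untouched
  lines <- readLines(vcf_in)
  inv <- sprintf("%s\t%d\tinv1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=%d",
                 "sim1", 500L, 900L)
  writeLines(c(lines, inv), vcf_in)
  out_vcf <- tempfile(fileext = ".vcf")
  report <- tempfile(fileext = ".tsv")
  res <- enhance_callset(vcf_in, model, sim$source, st,
                         out_vcf = out_vcf, report = report)
  expect_equal(nrow(res$records), 10L)
  out <- vcfR::read.vcfR(out_vcf, verbose = FALSE)
  expect_equal(nrow(out@fix), 11L)              # record count preserved
  info <- out@fix[, "INFO"]
  inv_row <- which(out@fix[, "ID"] == "inv1")
  expect_false(grepl("ORIG_POS", info[inv_row]))
  expect_equal(as.integer(out@fix[inv_row, "POS"]), 500L)
  # enhanced records carry original coordinates and outcomes
  enh_rows <- setdiff(seq_len(11L), inv_row)
  expect_true(all(grepl("ORIG_POS=", info[enh_rows])))
  expect_true(all(grepl("BKE_LEFT=", info[enh_rows])))
  expect_true(file.exists(report))
  rep_df <- read.delim(report)
  expect_equal(nrow(rep_df), 10L)
  # oracle masks land the refined coordinates on the truth
  truth <- sim$svs[match(res$records$sv_id, sim$svs$id), ]
  expect_true(all(abs(res$records$new_start - truth$start) <= 1L))
  expect_true(all(abs(res$records$new_end - truth$end) <= 1L))
})

test_that("VCF coordinate conversion round-trips losslessly", {
  svs <- sv_set(c("c1", "c1", "c2"), c(100L, 5000L, 777L),
                c(450L, 5300L, 1000L), c("DEL", "DUP", "DEL"),
                id = c("a", "b", "d"))
  p <- tempfile(fileext = ".vcf")
  write_sv_vcf(svs, p, genome = c(c1 = 10000, c2 = 5000))
  back <- read_svs(p)
  expect_equal(back$chrom, svs$chrom)
  expect_equal(back$start, svs$start)
  expect_equal(back$end, svs$end)
  expect_equal(back$svtype, svs$svtype)
  expect_equal(back$id, svs$id)
  # parse-write-parse fixed point
  p2 <- tempfile(fileext = ".vcf")
  write_sv_vcf(back, p2, genome = c(c1 = 10000, c2 = 5000))
  expect_identical(read_svs(p2)[, 1:5], back[, 1:5])
})
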