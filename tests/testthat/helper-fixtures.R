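# Shared fixture builders.  Everything is generated in code at test time;
# expensive artifacts are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Write a small BAM from explicit alignment records.
# reads: data.frame with pos1 (1-based), cigar, and optional mapq, flag.
make_bam <- function(reads, contig = "chrT", contig_len = 10000L,
                     dir = tempfile("bam")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sam <- file.path(dir, "t.sam")
  if (is.null(reads$mapq)) reads$mapq <- 60L
  if (is.null(reads$flag)) reads$flag <- 0L
  ord <- order(reads$pos1)
  reads <- reads[ord, , drop = FALSE]
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len),
             sprintf("r%04d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                     seq_len(nrow(reads)), reads$flag, contig,
                     reads$pos1, reads$mapq, reads$cigar))
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# Reference-span length consumed by a CIGAR string (M/D/N/=/X consume).
cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  sum(vapply(ops, function(o) {
    n <- as.integer(sub("[MIDNSHP=X]", "", o))
    if (grepl("[MDN=X]", o)) n else 0L
  }, integer(1)))
}

# Small shared simulation (training-sample scale for unit tests).
small_sim <- function() {
  cache_get("small_sim", function() {
    simulate_sv_data(sim_config(genome_length = 8e5, n_svs = 80L,
                                size_range = c(60L, 2000L), mean_depth = 30,
                                spacing = 400L, seed = 424L))
  })
}

small_stats <- function() {
  cache_get("small_stats", function() {
    sim <- small_sim()
    estimate_background_stats(
      sim$source, genome = sim$genome,
      exclude = GenomicRanges::GRanges(
        sim$svs$chrom, IRanges::IRanges(sim$svs$start + 1L, sim$svs$end)),
      n_bins = 80L, bin_size = 500L, seed = 7L)
  })
}

# An "oracle" segmentation stub: predicts the exact truth overlap mask for
# its windows.  Used to test the refinement algorithm independently of any
# trained network.
oracle_model <- function(truth_svs, l = 400L) {
  structure(list(config = list(input_length = l, threshold = 0.5),
                 truth = truth_svs),
            class = "oracle_model")
}

predict.oracle_model <- function(object, x, type = "mask", ...) {
  stopifnot(inherits(x, "rd_vector"))
  overlap_mask(x$window, object$truth)
}

registerS3method("predict", "oracle_model", predict.oracle_model,
                 envir = asNamespace("stats"))
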