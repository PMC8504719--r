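# Base-wise read-depth extraction and background normalisation.
#
# Coordinates are 0-based half-open throughout the package; VCF POS/END are
# converted at the I/O boundary (see read_sv_vcf / write_sv_vcf).

#' Screening window
#'
#' A fixed-length genomic interval anchored on (or around) a candidate
#' breakpoint.  The segmentation model consumes the base-wise read depth over
#' such a window, so its length must be divisible by the model's total
#' pooling factor (`2^pooling_levels`, checked at model time, not here).
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start coordinate (bp).
#' @param length window length in bp (> 0).
#' @return An object of class `screening_window` with fields `chrom`,
#'   `start`, `length`.
#' @examples
#' screening_window("chr1", 1000, 400)
#' @export
screening_window <- function(chrom, start, length) {
  if (!is.character(chrom) || base::length(chrom) != 1L)
    sv_stop("config_error", "chrom must be a single chromosome name")
  check_scalar(start, "start", min = 0)
  check_scalar(length, "length", min = 1)
  structure(list(chrom = chrom, start = as.integer(start),
                 length = as.integer(length)),
            class = "screening_window")
}

#' @method print screening_window
#' @export
print.screening_window <- function(x, ...) {
  cat(sprintf("<screening_window> %s:[%d, %d)  (l = %d bp)\n",
              x$chrom, x$start, x$start + x$length, x$length))
  invisible(x)
}

#' Read-depth vector
#'
#' Per-base read depth over a screening window, either raw integer counts or
#' background z-scores (see [normalize_rd()]).
#'
#' @param window a [screening_window()].
#' @param values numeric vector of length `window$length`; raw depths must be
#'   non-negative integers.
#' @param normalized logical; whether `values` are z-scores.
#' @return An object of class `rd_vector`.
#' @export
rd_vector <- function(window, values, normalized = FALSE) {
  stopifnot(inherits(window, "screening_window"))
  if (length(values) != window$length)
    sv_stop("shape_error", "value count (%d) != window length (%d)",
            length(values), window$length)
  if (!normalized) {
    if (any(values < 0) || any(values != round(values)))
      sv_stop("config_error", "raw depths must be non-negative integers")
    values <- as.integer(values)
  }
  structure(list(window = window, values = values,
                 normalized = isTRUE(normalized)),
            class = "rd_vector")
}

#' @method print rd_vector
#' @export
print.rd_vector <- function(x, ...) {
  cat(sprintf("<rd_vector> %s:[%d, %d)  %s  mean = %.3f\n",
              x$window$chrom, x$window$start,
              x$window$start + x$window$length,
              if (x$normalized) "z-normalised" else "raw counts",
              mean(x$values)))
  invisible(x)
}

# Named integer vector of contig lengths from a BAM header.
bam_contigs <- function(bam) {
  Rsamtools::scanBamHeader(bam)[[1L]]$targets
}

#' Extract a base-wise read-depth vector
#'
#' Counts, for every base of a screening window, the reads whose aligned
#' reference span covers that base.  The span is CIGAR-aware in the usual
#' depth-caller sense: deletions within a read still count as covered,
#' soft-clipped bases do not.  Secondary/supplementary/unmapped alignments
#' are excluded; reads below `min_mapq` are dropped.
#'
#' @param source an alignment source: path to a coordinate-sorted, indexed
#'   BAM file, or an in-memory `sim_reads` object from the simulator.
#' @param window a [screening_window()]; must lie within the contig.
#' @param min_mapq minimum mapping quality (default 0 = no filter).
#' @return A raw [rd_vector()].
#' @export
extract_rd_vector <- function(source, window, min_mapq = 0L) {
  UseMethod("extract_rd_vector")
}

#' @export
extract_rd_vector.character <- function(source, window, min_mapq = 0L) {
  stopifnot(inherits(window, "screening_window"))
  targets <- bam_contigs(source)
  check_window_bounds(window, targets)
  gr <- GenomicRanges::GRanges(
    window$chrom,
    IRanges::IRanges(window$start + 1L, window$start + window$length))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(which = gr, flag = flag,
                                   mapqFilter = as.integer(min_mapq))
  aln <- GenomicAlignments::readGAlignments(source, param = param)
  vals <- integer(window$length)
  if (length(aln)) {
    # granges() keeps the full aligned reference span (deletions covered)
    cov <- GenomicRanges::coverage(GenomicRanges::granges(aln))[[window$chrom]]
    lo <- window$start + 1L
    hi <- min(length(cov), window$start + window$length)
    if (hi >= lo) {
      seg <- as.integer(S4Vectors::window(cov, lo, hi))
      vals[seq_along(seg)] <- seg
    }
  }
  rd_vector(window, vals, normalized = FALSE)
}

#' @export
extract_rd_vector.sim_reads <- function(source, window, min_mapq = 0L) {
  stopifnot(inherits(window, "screening_window"))
  targets <- stats::setNames(source$genome_length, source$contig)
  check_window_bounds(window, targets)
  b <- window$start + seq_len(window$length) - 1L   # 0-based bases
  # a segment [s, e) covers b iff s <= b and e > b
  vals <- findInterval(b, source$starts) - findInterval(b, source$ends)
  rd_vector(window, vals, normalized = FALSE)
}

check_window_bounds <- function(window, targets) {
  if (!(window$chrom %in% names(targets)))
    sv_stop("contig_not_found", "contig '%s' not present in alignment source",
            window$chrom)
  clen <- unname(targets[[window$chrom]])
  if (window$start + window$length > clen)
    sv_stop("window_out_of_bounds",
            "window [%d, %d) exceeds contig '%s' length %d",
            window$start, window$start + window$length, window$chrom, clen)
  invisible(TRUE)
}

#' Estimate background depth statistics
#'
#' Samples non-overlapping bins uniformly at random from the genomic
#' "background" -- regions intersecting neither known SVs nor any other
#' excluded (e.g. low-mappability) intervals -- and pools their base-wise
#' depths into a mean and standard deviation used for z-normalisation.
#'
#' @param source alignment source (BAM path or `sim_reads`).
#' @param genome named vector of contig lengths; defaulted from the BAM
#'   header when `NULL`.
#' @param exclude optional `GRanges` (or `NULL`) of regions to avoid.
#' @param n_bins number of bins to sample (default 10,000).
#' @param bin_size bin width in bp (default 1,000).
#' @param seed integer seed; sampling is deterministic given
#'   `(seed, n_bins, bin_size, exclude)`.
#' @return An object of class `depth_stats` with fields `mean`, `std`,
#'   `n_bins_sampled`, `bin_size`, `seed`.
#' @export
estimate_background_stats <- function(source, genome = NULL, exclude = NULL,
                                      n_bins = 10000L, bin_size = 1000L,
                                      seed) {
  check_scalar(n_bins, "n_bins", min = 1)
  check_scalar(bin_size, "bin_size", min = 1)
  if (is.null(genome)) {
    if (is.character(source)) genome <- bam_contigs(source)
    else if (inherits(source, "sim_reads"))
      genome <- stats::setNames(source$genome_length, source$contig)
    else sv_stop("config_error", "genome lengths required for this source")
  }
  usable <- genome[genome >= bin_size]
  if (!length(usable))
    sv_stop("no_background_available", "no contig can hold a %d bp bin",
            bin_size)
  bins <- with_seed(seed, {
    chosen <- GenomicRanges::GRanges()
    tries <- 0L
    max_tries <- max(200L * n_bins, 1000L)
    while (length(chosen) < n_bins && tries < max_tries) {
      tries <- tries + 1L
      ci <- sample.int(length(usable), 1L, prob = as.numeric(usable))
      start0 <- floor(stats::runif(1L, 0, usable[[ci]] - bin_size + 1))
      cand <- GenomicRanges::GRanges(
        names(usable)[ci], IRanges::IRanges(start0 + 1, start0 + bin_size))
      if (!is.null(exclude) && length(exclude) &&
          length(GenomicRanges::findOverlaps(cand, exclude)))
        next
      if (length(chosen) && length(GenomicRanges::findOverlaps(cand, chosen)))
        next
      chosen <- c(chosen, cand)
    }
    chosen
  })
  if (!length(bins))
    sv_stop("no_background_available",
            "could not place any background bin outside excluded regions")
  depths <- unlist(lapply(seq_along(bins), function(i) {
    w <- screening_window(as.character(GenomicRanges::seqnames(bins)[i]),
                          GenomicRanges::start(bins)[i] - 1L,
                          bin_size)
    extract_rd_vector(source, w)$values
  }))
  m <- mean(depths)
  s <- stats::sd(depths)
  if (!is.finite(s) || s == 0)
    sv_stop("degenerate_background",
            "background depth has zero variance (mean %.3f)", m)
  structure(list(mean = m, std = s, n_bins_sampled = length(bins),
                 bin_size = as.integer(bin_size), seed = as.integer(seed)),
            class = "depth_stats")
}

#' @method print depth_stats
#' @export
print.depth_stats <- function(x, ...) {
  cat(sprintf(
    "<depth_stats> mean = %.3f, sd = %.3f  (%d bins x %d bp, seed %d)\n",
    x$mean, x$std, x$n_bins_sampled, x$bin_size, x$seed))
  invisible(x)
}

#' Z-normalise a read-depth vector
#'
#' `(raw - mean) / sd` against pooled background statistics.  Normalising an
#' already-normalised vector is an error (the operation is not idempotent).
#'
#' @param rd a raw [rd_vector()].
#' @param stats a `depth_stats` object with `std > 0`.
#' @return A normalised `rd_vector` over the same window.
#' @seealso [denormalize_rd()] for the exact inverse.
#' @export
normalize_rd <- function(rd, stats) {
  stopifnot(inherits(rd, "rd_vector"), inherits(stats, "depth_stats"))
  if (rd$normalized)
    sv_stop("double_normalization", "rd_vector is already normalised")
  if (!is.finite(stats$std) || stats$std <= 0)
    sv_stop("degenerate_background", "stats$std must be > 0")
  rd_vector(rd$window, (as.numeric(rd$values) - stats$mean) / stats$std,
            normalized = TRUE)
}

#' Invert [normalize_rd()]
#' @param rd a normalised [rd_vector()].
#' @param stats the `depth_stats` used to normalise it.
#' @return A raw `rd_vector` (values rounded back to integer counts).
#' @export
denormalize_rd <- function(rd, stats) {
  stopifnot(inherits(rd, "rd_vector"), inherits(stats, "depth_stats"))
  if (!rd$normalized)
    sv_stop("double_normalization", "rd_vector is not normalised")
  raw <- rd$values * stats$std + stats$mean
  rd_vector(rd$window, as.integer(round(raw)), normalized = FALSE)
}
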