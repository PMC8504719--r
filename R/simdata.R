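# Synthetic SV truthsets, Poisson read placement, and BAM/VCF fixtures.
#
# The simulator works at the read-placement level: reads of fixed length are
# dropped with a per-base start rate of depth/read_length, thinned by the
# copy-state multiplier of the start position (hom DEL 0, het DEL 0.5,
# het DUP 1.5, hom DUP 2).  The same placements back both the in-memory
# depth profiles and the written alignment file, so depth extracted from the
# fixture BAM matches the simulated profile exactly.

#' Simulation configuration
#'
#' Defaults emulate a short-read WGS regime: 125 bp reads at 30x mean depth,
#' SV sizes log-uniform on \[50, 10000\] bp, a DEL:DUP mix of roughly 2:1,
#' and an even het/hom split.  SVs are placed non-overlapping with at least
#' `spacing` bp between them (default 800 = twice the default screening
#' window) so each training window sees a single event.
#'
#' @param genome_length simulated contig length (bp).
#' @param n_svs number of SVs to place.
#' @param size_range min/max SV size, sampled log-uniformly.
#' @param mean_depth mean background depth lambda (reads).
#' @param read_length read length (bp).
#' @param het_fraction fraction of heterozygous events.
#' @param del_fraction fraction of deletions (rest are duplications).
#' @param spacing minimum gap between SVs (bp).
#' @param contig contig name.
#' @param bin_size bin grid used to degrade truth into a caller-like
#'   candidate set.
#' @param jitter extra uniform +/- jitter (bp) on candidate breakpoints.
#' @param seed integer seed; the whole simulation is deterministic given the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6, n_svs = 500L,
                       size_range = c(50L, 10000L), mean_depth = 30,
                       read_length = 125L, het_fraction = 0.5,
                       del_fraction = 0.68, spacing = 800L,
                       contig = "sim1", bin_size = 50L, jitter = 0L,
                       seed = 1L) {
  check_scalar(mean_depth, "mean_depth", min = 1e-9)
  check_scalar(read_length, "read_length", min = 1)
  if (size_range[1L] < 50L)
    sv_stop("config_error", "minimum SV size is 50 bp")
  structure(list(genome_length = as.integer(genome_length),
                 n_svs = as.integer(n_svs),
                 size_range = as.integer(size_range),
                 mean_depth = mean_depth,
                 read_length = as.integer(read_length),
                 het_fraction = het_fraction,
                 del_fraction = del_fraction,
                 spacing = as.integer(spacing),
                 contig = contig,
                 bin_size = as.integer(bin_size),
                 jitter = as.integer(jitter),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Copy-state depth multiplier per SV record.
sv_multiplier <- function(svtype, genotype) {
  ifelse(svtype == "DEL", ifelse(genotype == "hom", 0, 0.5),
         ifelse(genotype == "hom", 2, 1.5))
}

#' Simulate a non-overlapping DEL/DUP truthset
#'
#' Sizes are log-uniform over `cfg$size_range`; placement distributes the
#' free space between events uniformly at random while keeping every gap at
#' least `cfg$spacing` bp, so the set is non-overlapping by construction.
#'
#' @param cfg a [sim_config()].
#' @return An [sv_set()] with an extra `genotype` column ("het"/"hom").
#' @export
simulate_sv_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_svs
    sizes <- round(exp(stats::runif(n, log(cfg$size_range[1L]),
                                    log(cfg$size_range[2L]))))
    free <- cfg$genome_length - sum(sizes) - (n + 1L) * cfg$spacing
    if (free < 0)
      sv_stop("infeasible_packing",
              "genome of %d bp cannot hold %d SVs totalling %d bp with %d bp spacing",
              cfg$genome_length, n, sum(sizes), cfg$spacing)
    gaps <- diff(c(0, sort(stats::runif(n, 0, free)), free))
    starts <- cfg$spacing + cumsum(gaps[seq_len(n)]) +
      c(0, cumsum(sizes[-n] + cfg$spacing))
    starts <- as.integer(round(starts))
    svtype <- ifelse(stats::runif(n) < cfg$del_fraction, "DEL", "DUP")
    genotype <- ifelse(stats::runif(n) < cfg$het_fraction, "het", "hom")
    svs <- sv_set(cfg$contig, starts, starts + sizes, svtype,
                  source = "simulated-truth")
    svs$genotype <- genotype
    svs
  })
}

#' Simulate aligned read segments
#'
#' Reads are placed independently per haplotype at a per-base start rate of
#' `mean_depth / (2 * read_length)`.  On a haplotype carrying a deletion,
#' no read starts inside the deleted interval, and reads spanning a
#' breakpoint are split the way an aligner maps junction reads: the aligned
#' span is clipped at the left breakpoint and the remainder continues from
#' the right breakpoint.  A carried (tandem) duplication contributes an
#' extra copy's worth of reads whose spans wrap around the duplication
#' junction.  The resulting expected depth is exactly piecewise constant --
#' `lambda` in neutral sequence and `lambda * multiplier` inside SVs (hom
#' DEL 0, het DEL 0.5, het DUP 1.5, hom DUP 2) -- with sharp transitions at
#' the true breakpoints, as in aligned short-read data.
#'
#' @param cfg a [sim_config()].
#' @param svs the truthset from [simulate_sv_set()] (needs `genotype`).
#' @return A `data.frame` of aligned segments with 0-based half-open
#'   `start`/`end` columns, sorted by start.
#' @export
simulate_reads <- function(cfg, svs) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    rl <- cfg$read_length
    L <- cfg$genome_length
    span <- L - rl + 1L
    half_rate <- cfg$mean_depth / (2 * rl)
    seg_start <- integer(0); seg_end <- integer(0)
    add <- function(s, e) {
      keep <- e > s
      seg_start <<- c(seg_start, s[keep]); seg_end <<- c(seg_end, e[keep])
    }
    for (h in 1:2) {
      carried <- NROW(svs) > 0 &
        (svs$genotype == "hom" | (svs$genotype == "het" & h == 1L))
      dels <- svs[carried & svs$svtype == "DEL", , drop = FALSE]
      dups <- svs[carried & svs$svtype == "DUP", , drop = FALSE]
      n <- stats::rpois(1L, half_rate * span)
      s <- floor(stats::runif(n, 0, span))
      # no reads start inside a carried deletion
      if (nrow(dels)) {
        idx <- findInterval(s, dels$start)
        inside <- idx > 0L & s < dels$end[pmax(idx, 1L)]
        s <- s[!inside]
      }
      e <- s + rl
      if (nrow(dels)) {
        # split reads spanning a deletion breakpoint: clip at the left
        # breakpoint, continue from the right breakpoint
        idx <- findInterval(e - 1L, dels$start)
        cross <- idx > 0L & s < dels$start[pmax(idx, 1L)] &
          e > dels$start[pmax(idx, 1L)]
        if (any(cross)) {
          d <- idx[cross]
          rem <- e[cross] - dels$start[d]
          e[cross] <- dels$start[d]
          add(dels$end[d], pmin(dels$end[d] + rem, L))
        }
      }
      add(s, e)
      # extra tandem copy for carried duplications, wrapping the junction
      if (nrow(dups)) for (k in seq_len(nrow(dups))) {
        dlen <- dups$end[k] - dups$start[k]
        ne <- stats::rpois(1L, half_rate * dlen)
        se <- dups$start[k] + floor(stats::runif(ne, 0, dlen))
        ee <- se + rl
        over <- pmax(ee - dups$end[k], 0L)
        add(se, pmin(ee, dups$end[k]))
        add(rep(dups$start[k], sum(over > 0)),
            dups$start[k] + over[over > 0])
      }
    }
    ord <- order(seg_start)
    data.frame(start = as.integer(seg_start[ord]),
               end = as.integer(seg_end[ord]))
  })
}

# Depth source backed by in-memory aligned segments; start/end columns are
# kept pre-sorted separately so depth lookup is two binary searches.
sim_reads_source <- function(segs, contig, genome_length) {
  structure(list(contig = contig,
                 genome_length = as.integer(genome_length),
                 starts = sort(as.integer(segs$start)),
                 ends = sort(as.integer(segs$end)),
                 segments = segs),
            class = "sim_reads")
}

#' Run a full simulation
#'
#' Draws the truthset and the read placements, and wraps the placements as
#' an in-memory alignment source usable anywhere a BAM path is accepted.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sv_simulation`: list with `cfg`, `svs`,
#'   `source` (a `sim_reads` depth source), and `genome` (named
#'   contig-length vector).
#' @export
simulate_sv_data <- function(cfg) {
  svs <- simulate_sv_set(cfg)
  segs <- simulate_reads(cfg, svs)
  source <- sim_reads_source(segs, cfg$contig, cfg$genome_length)
  structure(list(cfg = cfg, svs = svs, source = source,
                 genome = stats::setNames(cfg$genome_length, cfg$contig)),
            class = "sv_simulation")
}

#' @method print sv_simulation
#' @export
print.sv_simulation <- function(x, ...) {
  cat(sprintf(
    "<sv_simulation> %s (%d bp), %d SVs (%d DEL / %d DUP), %d aligned segments at %gx\n",
    x$cfg$contig, x$cfg$genome_length, nrow(x$svs),
    sum(x$svs$svtype == "DEL"), sum(x$svs$svtype == "DUP"),
    nrow(x$source$segments), x$cfg$mean_depth))
  invisible(x)
}

#' Degrade the truthset into a caller-like candidate set
#'
#' Rounds every truth breakpoint to the nearest multiple of
#' `cfg$bin_size` and adds optional uniform jitter -- the bin-resolution
#' input the refinement pipeline is meant to fix.  Candidates whose
#' degraded length would fall below 50 bp keep their truth coordinates.
#'
#' @param sim an [simulate_sv_data()] result.
#' @return An [sv_set()] of candidate calls (ids shared with the truthset).
#' @export
degrade_candidates <- function(sim) {
  stopifnot(inherits(sim, "sv_simulation"))
  cfg <- sim$cfg
  with_seed(cfg$seed + 2L, {
    svs <- sim$svs
    bs <- cfg$bin_size
    jit <- function(n) if (cfg$jitter > 0)
      sample.int(2L * cfg$jitter + 1L, n, replace = TRUE) - cfg$jitter - 1L
    else integer(n)
    n <- nrow(svs)
    start <- as.integer(round(svs$start / bs) * bs + jit(n))
    end <- as.integer(round(svs$end / bs) * bs + jit(n))
    bad <- end - start < 50L | start < 0L | end > cfg$genome_length
    start[bad] <- svs$start[bad]; end[bad] <- svs$end[bad]
    sv_set(svs$chrom, start, end, svs$svtype, id = svs$id,
           source = "degraded-candidate")
  })
}

#' Write simulation fixtures: BAM, truth VCF, candidate VCF
#'
#' Emits a coordinate-sorted, indexed BAM of the simulated reads (via a SAM
#' intermediate), the truth VCF, and the bin-degraded candidate VCF.
#'
#' @param sim an [simulate_sv_data()] result.
#' @param out_dir output directory (created if needed).
#' @return List of paths: `bam`, `truth_vcf`, `candidate_vcf`.
#' @export
write_fixtures <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sv_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$cfg
  sam <- file.path(out_dir, "reads.sam")
  segs <- sim$source$segments
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", cfg$contig, cfg$genome_length)),
             con)
  if (nrow(segs)) {
    writeLines(sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(segs)), cfg$contig, segs$start + 1L,
                       segs$end - segs$start),
               con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  truth_vcf <- file.path(out_dir, "truth.vcf")
  write_sv_vcf(sim$svs, truth_vcf, genome = sim$genome)
  cand_vcf <- file.path(out_dir, "candidates.vcf")
  write_sv_vcf(degrade_candidates(sim), cand_vcf, genome = sim$genome)
  list(bam = bam, truth_vcf = truth_vcf, candidate_vcf = cand_vcf)
}
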