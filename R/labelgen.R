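# Training/evaluation window construction and per-base SV-overlap labels.

#' Construct a validated SV record table
#'
#' The package-internal SV container is a plain `data.frame` with 0-based
#' half-open coordinates and columns `chrom`, `start`, `end`, `svtype`,
#' `id`, `source`.  Only deletions and duplications are representable (the
#' depth signal carries no information about balanced events), and records
#' must satisfy the usual SV size definition of > 50 bp (operationally
#' `end - start >= 50`).
#'
#' @param chrom,start,end,svtype vectors of equal length; `svtype` in
#'   `{"DEL","DUP"}`.
#' @param id record identifiers (generated when missing).
#' @param source free-text provenance tag (caller name or truthset tag).
#' @return A `data.frame` with class `c("sv_set", "data.frame")`.
#' @export
sv_set <- function(chrom, start, end, svtype, id = NULL, source = "unknown") {
  n <- length(start)
  if (is.null(id)) id <- sprintf("sv%05d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   svtype = as.character(svtype),
                   id = as.character(id),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  validate_sv_set(df)
}

validate_sv_set <- function(df) {
  need <- c("chrom", "start", "end", "svtype", "id")
  if (!all(need %in% names(df)))
    sv_stop("config_error", "SV table must have columns %s",
            paste(need, collapse = ", "))
  if (any(df$end <= df$start))
    sv_stop("config_error", "SV records must satisfy end > start")
  if (any(df$end - df$start < 50L))
    sv_stop("config_error", "SVs must be at least 50 bp long")
  if (!all(df$svtype %in% c("DEL", "DUP")))
    sv_stop("config_error", "svtype must be DEL or DUP")
  class(df) <- unique(c("sv_set", class(df)))
  df
}

#' SV records as a GRanges
#'
#' Convenience conversion of an [sv_set()] (0-based half-open) to a
#' `GRanges`, e.g. for the `exclude` arguments of
#' [estimate_background_stats()] and [sample_negative_windows()].
#'
#' @param svs an [sv_set()] or compatible data.frame.
#' @return A `GRanges` with one range per record.
#' @export
sv_granges <- function(svs) {
  GenomicRanges::GRanges(svs$chrom,
                         IRanges::IRanges(svs$start + 1L, svs$end))
}

#' Per-base SV-overlap label mask
#'
#' `marks[i] = 1` iff base `window$start + i - 1` (0-based) lies inside any
#' SV interval.
#'
#' @param window a [screening_window()].
#' @param svs an [sv_set()] (may be empty).
#' @return An object of class `label_mask` with fields `window` and `marks`
#'   (integer 0/1 vector of length `window$length`).
#' @export
overlap_mask <- function(window, svs) {
  stopifnot(inherits(window, "screening_window"))
  marks <- integer(window$length)
  if (NROW(svs)) {
    hit <- svs$chrom == window$chrom &
      svs$start < window$start + window$length & svs$end > window$start
    for (k in which(hit)) {
      lo <- max(svs$start[k], window$start) - window$start + 1L
      hi <- min(svs$end[k], window$start + window$length) - window$start
      marks[lo:hi] <- 1L
    }
  }
  label_mask(window, marks)
}

#' Label mask constructor
#' @param window a [screening_window()].
#' @param marks integer vector of 0/1, one per window base.
#' @export
label_mask <- function(window, marks) {
  stopifnot(inherits(window, "screening_window"))
  if (length(marks) != window$length)
    sv_stop("shape_error", "mark count (%d) != window length (%d)",
            length(marks), window$length)
  if (!all(marks %in% c(0L, 1L)))
    sv_stop("config_error", "marks must be 0 or 1")
  structure(list(window = window, marks = as.integer(marks)),
            class = "label_mask")
}

#' Sample positive (SV-anchored) training windows
#'
#' Every SV contributes windows for both of its breakpoints.  For each
#' breakpoint a window start of `breakpoint - delta` is drawn with `delta`
#' uniform on the integers `[10, l - 10]`, so the breakpoint falls at a
#' random in-window offset rather than always at the centre.  Windows whose
#' anchor SV overlaps the window by fewer than 10 bp are excluded (too
#' little signal to segment from depth alone), as are windows that overhang
#' a contig end when `genome` is supplied.
#'
#' @param svs an [sv_set()].
#' @param l window length in bp (>= 20).
#' @param seed integer seed.
#' @param genome optional named contig-length vector for bounds filtering.
#' @return A `data.frame` with columns `chrom`, `start`, `length`, `sv_id`,
#'   `side` ("left"/"right"), `delta`, one row per retained window.
#' @export
sample_positive_windows <- function(svs, l, seed, genome = NULL) {
  check_scalar(l, "l", min = 20)
  if (!NROW(svs)) {
    return(data.frame(chrom = character(), start = integer(),
                      length = integer(), sv_id = character(),
                      side = character(), delta = integer()))
  }
  svs <- validate_sv_set(svs)
  with_seed(seed, {
    bp <- c(svs$start, svs$end)
    side <- rep(c("left", "right"), each = nrow(svs))
    sv_id <- rep(svs$id, 2L)
    chrom <- rep(svs$chrom, 2L)
    anchor_start <- rep(svs$start, 2L)
    anchor_end <- rep(svs$end, 2L)
    delta <- sample(seq.int(10L, l - 10L), length(bp), replace = TRUE)
    win_start <- bp - delta
    ok <- win_start >= 0L
    if (!is.null(genome))
      ok <- ok & win_start + l <= unname(genome[chrom])
    # anchor-SV overlap with the window must be >= 10 bp
    ov <- pmin(anchor_end, win_start + l) - pmax(anchor_start, win_start)
    ok <- ok & ov >= 10L
    data.frame(chrom = chrom[ok], start = as.integer(win_start[ok]),
               length = l, sv_id = sv_id[ok], side = side[ok],
               delta = as.integer(delta[ok]), stringsAsFactors = FALSE)
  })
}

#' Sample negative (SV-free) windows
#'
#' Draws `n` windows uniformly at random from the genome, rejecting any that
#' intersect a known SV or an excluded region; their label masks are all
#' zero by construction.
#'
#' @param genome named vector of contig lengths.
#' @param svs an [sv_set()] of known SVs to avoid.
#' @param n number of windows.
#' @param l window length (bp).
#' @param seed integer seed.
#' @param exclude optional `GRanges` of additional regions to avoid.
#' @return A `data.frame` with columns `chrom`, `start`, `length`.
#' @export
sample_negative_windows <- function(genome, svs, n, l, seed, exclude = NULL) {
  check_scalar(n, "n", min = 0)
  check_scalar(l, "l", min = 1)
  if (n == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      length = integer()))
  }
  usable <- genome[genome >= l]
  if (!length(usable))
    sv_stop("sampling_exhausted", "no contig can hold an %d bp window", l)
  svgr <- if (NROW(svs)) sv_granges(svs) else GenomicRanges::GRanges()
  with_seed(seed, {
    out_chrom <- character(0); out_start <- integer(0)
    tries <- 0L; max_tries <- max(1000L, 200L * n)
    while (length(out_start) < n && tries < max_tries) {
      tries <- tries + 1L
      ci <- sample.int(length(usable), 1L, prob = as.numeric(usable))
      s0 <- floor(stats::runif(1L, 0, usable[[ci]] - l + 1))
      cand <- GenomicRanges::GRanges(names(usable)[ci],
                                     IRanges::IRanges(s0 + 1, s0 + l))
      if (length(svgr) && length(GenomicRanges::findOverlaps(cand, svgr)))
        next
      if (!is.null(exclude) && length(exclude) &&
          length(GenomicRanges::findOverlaps(cand, exclude)))
        next
      out_chrom <- c(out_chrom, names(usable)[ci])
      out_start <- c(out_start, as.integer(s0))
    }
    if (length(out_start) < n)
      sv_stop("sampling_exhausted",
              "could only place %d of %d SV-free windows", length(out_start), n)
    data.frame(chrom = out_chrom, start = out_start, length = as.integer(l),
               stringsAsFactors = FALSE)
  })
}

#' Build a balanced training set of depth windows and label masks
#'
#' Positives come from [sample_positive_windows()]; raw all-zero depth
#' vectors (unmappable or empty regions) are filtered out; negatives are
#' drawn from SV-free regions to match the surviving positive count exactly;
#' finally every depth vector is z-normalised against `stats`.
#'
#' @param source alignment source (BAM path or `sim_reads`).
#' @param svs known SVs ([sv_set()]).
#' @param stats background [estimate_background_stats()] result.
#' @param genome named contig-length vector.
#' @param l window length (bp).
#' @param seed integer seed driving every sampling step.
#' @param exclude optional `GRanges` negatives must also avoid.
#' @return An object of class `training_set`: list with `x` (n x l matrix of
#'   z-scores), `y` (n x l 0/1 matrix), `meta` (per-window provenance:
#'   `role`, `sv_id`, `side`, `delta`, `chrom`, `start`), `l`, `seed`,
#'   `stats`.
#' @export
build_training_set <- function(source, svs, stats, genome, l, seed,
                               exclude = NULL) {
  stopifnot(inherits(stats, "depth_stats"))
  pos <- sample_positive_windows(svs, l, seed, genome = genome)
  if (!nrow(pos))
    sv_stop("empty_training_set", "no positive windows could be generated")
  raw_pos <- windows_to_matrix(source, pos)
  keep <- rowSums(raw_pos) > 0
  pos <- pos[keep, , drop = FALSE]
  raw_pos <- raw_pos[keep, , drop = FALSE]
  if (!nrow(pos))
    sv_stop("empty_training_set",
            "all positive windows had zero coverage and were filtered out")
  y_pos <- t(vapply(seq_len(nrow(pos)), function(i) {
    overlap_mask(screening_window(pos$chrom[i], pos$start[i], l), svs)$marks
  }, integer(l)))

  n_need <- nrow(pos)
  neg <- sample_negative_windows(genome, svs, n_need, l, seed + 1L,
                                 exclude = exclude)
  raw_neg <- windows_to_matrix(source, neg)
  keep_n <- rowSums(raw_neg) > 0
  extra_seed <- seed + 2L
  while (sum(keep_n) < n_need && extra_seed < seed + 30L) {
    more <- sample_negative_windows(genome, svs, n_need, l, extra_seed,
                                    exclude = exclude)
    raw_more <- windows_to_matrix(source, more)
    neg <- rbind(neg, more)
    raw_neg <- rbind(raw_neg, raw_more)
    keep_n <- rowSums(raw_neg) > 0
    extra_seed <- extra_seed + 1L
  }
  if (sum(keep_n) < n_need)
    sv_stop("sampling_exhausted",
            "could not find %d negative windows with non-zero coverage", n_need)
  take <- which(keep_n)[seq_len(n_need)]
  neg <- neg[take, , drop = FALSE]
  raw_neg <- raw_neg[take, , drop = FALSE]

  x <- (rbind(raw_pos, raw_neg) - stats$mean) / stats$std
  y <- rbind(y_pos, matrix(0L, n_need, l))
  meta <- data.frame(
    role = rep(c("positive", "negative"), c(nrow(pos), n_need)),
    sv_id = c(pos$sv_id, rep(NA_character_, n_need)),
    side = c(pos$side, rep(NA_character_, n_need)),
    delta = c(pos$delta, rep(NA_integer_, n_need)),
    chrom = c(pos$chrom, neg$chrom),
    start = c(pos$start, neg$start),
    stringsAsFactors = FALSE)
  structure(list(x = x, y = y, meta = meta, l = as.integer(l),
                 seed = as.integer(seed), stats = stats),
            class = "training_set")
}

#' @method print training_set
#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "<training_set> %d windows of %d bp (%d positive, %d negative), seed %d\n",
    nrow(x$x), x$l, sum(x$meta$role == "positive"),
    sum(x$meta$role == "negative"), x$seed))
  invisible(x)
}

# Raw depth rows for a data.frame of windows.
windows_to_matrix <- function(source, windows) {
  if (!nrow(windows)) return(matrix(0L, 0L, 0L))
  l <- windows$length[1L]
  t(vapply(seq_len(nrow(windows)), function(i) {
    extract_rd_vector(source,
                      screening_window(windows$chrom[i], windows$start[i],
                                       l))$values
  }, integer(l)))
}

#' Save / load a training set as a plain-text archive
#'
#' Writes the depth matrix, label matrix and per-window provenance as
#' tab-separated files plus a JSON manifest recording the seed, window
#' length and background statistics, so a training set can be rebuilt
#' elsewhere bit-for-bit or audited by eye.
#'
#' @param ts a `training_set` from [build_training_set()].
#' @param dir output directory (created if needed).
#' @return `save_training_set` returns `dir` invisibly; `load_training_set`
#'   returns the restored `training_set`.
#' @export
save_training_set <- function(ts, dir) {
  stopifnot(inherits(ts, "training_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ts$x, file.path(dir, "depth.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ts$y, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ts$meta, file.path(dir, "windows.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(format = "svrefine_training_set", version = 1L,
         n_windows = nrow(ts$x), l = ts$l, seed = ts$seed,
         stats = ts$stats[c("mean", "std", "n_bins_sampled", "bin_size",
                            "seed")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_training_set
#' @export
load_training_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(man$format, "svrefine_training_set"))
    sv_stop("parse_error", "'%s' is not a training-set archive", dir)
  x <- as.matrix(utils::read.table(file.path(dir, "depth.tsv"), sep = "\t"))
  y <- as.matrix(utils::read.table(file.path(dir, "labels.tsv"), sep = "\t"))
  dimnames(x) <- dimnames(y) <- NULL
  meta <- utils::read.table(file.path(dir, "windows.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  stats <- structure(man$stats, class = "depth_stats")
  structure(list(x = x, y = y, meta = meta, l = as.integer(man$l),
                 seed = as.integer(man$seed), stats = stats),
            class = "training_set")
}
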