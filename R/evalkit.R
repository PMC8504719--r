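# Benchmarking metrics: Jaccard matching against a gold standard,
# precise-boundary summaries, distance-range change matrices, and
# segmentation/classification scores.

#' Jaccard similarity of two SV intervals
#'
#' `|A intersect B| / |A union B|`, i.e.
#' `l_overlap / (l_gold + l_pred - l_overlap)`; 0 for intervals on
#' different chromosomes.  Always less than or equal to the reciprocal
#' overlap of the same pair, so a 0.5 cutoff is the stricter criterion.
#'
#' @param a,b SV records: lists/one-row data.frames with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return A number in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  la <- a$end - a$start
  lb <- b$end - b$start
  if (ov == 0) return(0)
  ov / (la + lb - ov)
}

#' Match predicted SVs to a gold standard by Jaccard similarity
#'
#' Each prediction is assigned to the type-concordant gold SV maximising
#' Jaccard similarity, one-to-one and greedily by descending similarity
#' (each gold record is used at most once).  A prediction counts as
#' gold-standard-overlapping ("matched") iff its similarity is strictly
#' greater than `threshold`.
#'
#' @param pred,gold [sv_set()] tables.
#' @param threshold Jaccard cutoff (default 0.5, strict inequality).
#' @return A `data.frame` with one row per prediction: `pred_id`, `gold_id`
#'   (NA when unmatched), `jaccard`, `left_distance`, `right_distance`
#'   (absolute bp distances to the matched gold boundaries, NA when
#'   unmatched), `matched`.
#' @export
match_to_gold <- function(pred, gold, threshold = 0.5) {
  pred <- validate_sv_set(pred); gold <- validate_sv_set(gold)
  res <- data.frame(pred_id = pred$id, gold_id = NA_character_,
                    jaccard = 0, left_distance = NA_integer_,
                    right_distance = NA_integer_, matched = FALSE,
                    stringsAsFactors = FALSE)
  if (!nrow(pred) || !nrow(gold)) return(res)
  hits <- GenomicRanges::findOverlaps(sv_granges(pred), sv_granges(gold))
  pi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  ok <- pred$svtype[pi] == gold$svtype[gi]
  pi <- pi[ok]; gi <- gi[ok]
  if (!length(pi)) return(res)
  ov <- pmin(pred$end[pi], gold$end[gi]) - pmax(pred$start[pi], gold$start[gi])
  js <- ov / ((pred$end[pi] - pred$start[pi]) +
                (gold$end[gi] - gold$start[gi]) - ov)
  ord <- order(-js)
  used_p <- logical(nrow(pred)); used_g <- logical(nrow(gold))
  for (k in ord) {
    if (js[k] <= threshold) break
    p <- pi[k]; g <- gi[k]
    if (used_p[p] || used_g[g]) next
    used_p[p] <- TRUE; used_g[g] <- TRUE
    res$gold_id[p] <- gold$id[g]
    res$jaccard[p] <- js[k]
    res$left_distance[p] <- abs(pred$start[p] - gold$start[g])
    res$right_distance[p] <- abs(pred$end[p] - gold$end[g])
    res$matched[p] <- TRUE
  }
  # record the best similarity even for unmatched predictions
  bp <- tapply(js, pi, max)
  un <- !res$matched
  idx <- intersect(which(un), as.integer(names(bp)))
  res$jaccard[idx] <- pmax(res$jaccard[idx], unname(bp[as.character(idx)]))
  res
}

#' Precise-boundary proportion from match counts
#'
#' `100 * (lr_match + lrr_match) / gs_ov` -- the percentage of
#' gold-overlapping SVs whose boundaries are precise on at least one side.
#'
#' @param gs_ov number of gold-standard-overlapping SVs.
#' @param lr_match SVs with exactly one boundary within tolerance
#'   (partial-boundary-match).
#' @param lrr_match SVs with both boundaries within tolerance
#'   (both-boundary-match).
#' @return Percentage (scalar).
#' @export
precise_proportion <- function(gs_ov, lr_match, lrr_match) {
  if (gs_ov <= 0)
    sv_stop("undefined_proportion",
            "no gold-overlapping SVs: precise proportion undefined")
  if (lr_match + lrr_match > gs_ov)
    sv_stop("config_error", "match counts exceed gs_ov")
  100 * (lr_match + lrr_match) / gs_ov
}

#' Summarise boundary precision of matched SVs
#'
#' A boundary is "precise" when within `tolerance` bp (default 1) of the
#' matched gold boundary; SVs split into both-boundary-match, partial
#' (exactly one side), and neither.
#'
#' @param matches output of [match_to_gold()].
#' @param tolerance precision tolerance in bp.
#' @return An object of class `boundary_summary`: list with `gs_ov`,
#'   `lr_match`, `lrr_match`, `precise_proportion` (percent).
#' @export
boundary_match_summary <- function(matches, tolerance = 1L) {
  m <- matches[matches$matched, , drop = FALSE]
  gs_ov <- nrow(m)
  if (gs_ov == 0)
    sv_stop("undefined_proportion",
            "no gold-overlapping SVs: precise proportion undefined")
  lp <- m$left_distance <= tolerance
  rp <- m$right_distance <= tolerance
  lrr <- sum(lp & rp)
  lr <- sum(xor(lp, rp))
  structure(list(gs_ov = gs_ov, lr_match = lr, lrr_match = lrr,
                 precise_proportion = precise_proportion(gs_ov, lr, lrr)),
            class = "boundary_summary")
}

#' @method print boundary_summary
#' @export
print.boundary_summary <- function(x, ...) {
  cat(sprintf(
    "<boundary_summary> GS-ov %d | l/r match %d | l&r match %d | precise %.2f%%\n",
    x$gs_ov, x$lr_match, x$lrr_match, x$precise_proportion))
  invisible(x)
}

#' Relative change, in percent
#'
#' `100 * (after - before) / before`; the worked-example arithmetic for
#' "x% increase/decrease" statements.
#'
#' @param before,after scalar quantities.
#' @return Signed percentage.
#' @export
relative_change <- function(before, after) {
  check_scalar(abs(before), "abs(before)", min = .Machine$double.xmin)
  100 * (after - before) / before
}

# The fixed to-gold-distance ranges used by the change matrix.
dr_breaks <- c(0, 5, 10, 20, 50, 100, 200, 500, 1000, Inf)
dr_labels <- c("[0,5)", "[5,10)", "[10,20)", "[20,50)", "[50,100)",
               "[100,200)", "[200,500)", "[500,1000)", "[1000,)")

#' Breakpoint change matrix
#'
#' Counts breakpoints moving between to-gold-distance ranges
#' `DR = [0,5), [5,10), [10,20), [20,50), [50,100), [100,200), [200,500),
#' [500,1000), [1000,)` before vs after enhancement.  Entry `c[i, j]` is the
#' number of breakpoints whose distance was in range i before and range j
#' after; unchanged breakpoints are ignored (by default, those whose
#' distance did not change).
#'
#' @param before,after paired non-negative bp distances to the gold
#'   breakpoint, one element per breakpoint.
#' @param changed logical vector: which breakpoints actually moved.
#'   Defaults to `before != after`.
#' @return A 9 x 9 integer matrix of class `change_matrix` with range
#'   labels as dimnames (before in rows, after in columns).
#' @export
change_matrix <- function(before, after, changed = before != after) {
  if (length(before) != length(after))
    sv_stop("shape_error", "before/after lengths differ")
  if (any(before < 0) || any(after < 0))
    sv_stop("input_error", "distances must be non-negative")
  bi <- cut(before[changed], dr_breaks, right = FALSE, labels = dr_labels)
  ai <- cut(after[changed], dr_breaks, right = FALSE, labels = dr_labels)
  m <- table(factor(bi, levels = dr_labels), factor(ai, levels = dr_labels))
  m <- unclass(m)
  dimnames(m) <- list(before = dr_labels, after = dr_labels)
  structure(m, class = c("change_matrix", "matrix"))
}

#' @method print change_matrix
#' @export
print.change_matrix <- function(x, ...) {
  cat("<change_matrix> breakpoints moving between to-gold-distance ranges\n")
  print(unclass(x))
  invisible(x)
}

#' Plot a change matrix as a heatmap
#' @param x a [change_matrix()].
#' @param ... passed to [graphics::image()].
#' @method plot change_matrix
#' @export
plot.change_matrix <- function(x, ...) {
  m <- unclass(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  axes = FALSE, xlab = "after", ylab = "before",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1L, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2L, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Window-classification metrics
#'
#' Standard binary precision/recall/F1 plus the false-discovery rate
#' `FDR = 1 - precision`.  With no positive predictions the precision (and
#' hence FDR, F1) is reported as `NA`; likewise recall with no true
#' positives in the truth.
#'
#' @param predicted,truth logical (or 0/1) vectors of equal length.
#' @return A list with `precision`, `recall`, `F1`, `FDR`, and the raw
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    sv_stop("shape_error", "predicted/truth lengths differ")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, F1 = f1,
       FDR = 1 - precision, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Mean segmentation Dice over a test set
#'
#' `subset = "ALL"` averages the per-window Dice coefficient over every
#' window including negatives (two empty masks score 1 by the epsilon
#' limit); `subset = "BK"` restricts to windows whose gold mask contains at
#' least one SV mark.
#'
#' @param pred,gold lists of [label_mask()]s, or 0/1 matrices with one
#'   window per row.
#' @param subset `"ALL"` or `"BK"`.
#' @param epsilon Dice epsilon.
#' @return Mean Dice (scalar).
#' @export
segmentation_metrics <- function(pred, gold, subset = c("ALL", "BK"),
                                 epsilon = 1e-7) {
  subset <- match.arg(subset)
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, function(m)
      if (inherits(m, "label_mask")) m$marks else m))
  }
  p <- as_mat(pred); g <- as_mat(gold)
  if (!all(dim(p) == dim(g)))
    sv_stop("shape_error", "prediction/gold dimensions differ")
  if (subset == "BK") {
    keep <- rowSums(g) > 0
    p <- p[keep, , drop = FALSE]; g <- g[keep, , drop = FALSE]
  }
  if (!nrow(p))
    sv_stop("empty_subset", "no windows in the requested subset")
  mean((2 * rowSums(g * p) + epsilon) / (rowSums(g) + rowSums(p) + epsilon))
}
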