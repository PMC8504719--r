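# Breakpoint refinement: turn segmentation masks around candidate
# breakpoints into single-nucleotide breakpoints and an updated callset.

#' Breakpoint candidates from a label mask
#'
#' Maximal runs of 1-marks are located; for `side = "left"` the candidates
#' are the genomic coordinates of run starts, for `side = "right"` the
#' coordinates one past run ends (0-based half-open), so a run refining both
#' sides of the same SV keeps start < end.
#'
#' @param mask a [label_mask()].
#' @param side which SV boundary the candidates are for.
#' @return Integer vector of 0-based genomic coordinates (possibly empty).
#' @export
mask_to_candidates <- function(mask, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(mask, "label_mask"))
  r <- rle(mask$marks)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  one <- r$values == 1L
  if (!any(one)) return(integer(0))
  if (side == "left") mask$window$start + starts[one] - 1L
  else                mask$window$start + ends[one]
}

#' Refine one breakpoint against its candidates
#'
#' With exactly one candidate, the breakpoint moves there; with several, the
#' candidate closest to the original breakpoint wins (ties broken toward the
#' smaller coordinate); with none, the original breakpoint is retained.
#'
#' @param original 0-based original breakpoint coordinate.
#' @param candidates integer vector from [mask_to_candidates()].
#' @return The refined coordinate (a single integer).
#' @export
refine_breakpoint <- function(original, candidates) {
  if (!length(candidates)) return(as.integer(original))
  candidates <- sort(as.integer(candidates))
  candidates[which.min(abs(candidates - original))]
}

#' Enhance a single SV's breakpoints
#'
#' Implements the per-SV refinement loop: a screening window of length `l`
#' is centred on each of the SV's two breakpoints, segmented independently,
#' and each side refined via [refine_breakpoint()] with side-appropriate
#' candidates.  If the refined interval would be shorter than 50 bp (the SV
#' size definition), both original boundaries are restored and the outcome
#' is recorded as `retained-size-guard`.
#'
#' @param sv one-row [sv_set()] (or list with `chrom`, `start`, `end`, `id`).
#' @param model trained `rd_unet` (or any object with a
#'   `predict(model, rd, type = "mask")` method).
#' @param source alignment source for [extract_rd_vector()].
#' @param stats background `depth_stats` for normalisation.
#' @param l screening-window length; must equal the model input length.
#' @param bin_size optional bin size of the upstream caller; when given and
#'   `l < 4 * bin_size` a warning is emitted (a window covering at least
#'   four bins is preferred).
#' @return A one-row `data.frame` (an enhancement record): `sv_id`, `chrom`,
#'   `orig_start`, `orig_end`, `new_start`, `new_end`, `left_outcome`,
#'   `right_outcome`, with outcomes in `{"updated",
#'   "multi-candidate-nearest", "retained-no-candidate",
#'   "retained-size-guard"}`.
#' @export
enhance_sv <- function(sv, model, source, stats,
                       l = model$config$input_length, bin_size = NULL) {
  if (inherits(model, "rd_unet") && l != model$config$input_length)
    sv_stop("config_error", "l (%d) != model input length (%d)",
            l, model$config$input_length)
  if (!is.null(bin_size) && l < 4L * bin_size)
    sv_warn("short_window",
            "screening window (%d bp) covers fewer than four caller bins (%d bp); refinement may miss the true breakpoint",
            l, bin_size)
  half <- l %/% 2L
  refine_side <- function(bp, side) {
    win_start <- bp - half
    if (win_start < 0)
      return(list(coord = bp, outcome = "retained-no-candidate",
                  warn = TRUE))
    rd <- tryCatch(
      extract_rd_vector(source, screening_window(sv$chrom, win_start, l)),
      contig_not_found = function(e) NULL,
      window_out_of_bounds = function(e) NULL)
    if (is.null(rd))
      return(list(coord = bp, outcome = "retained-no-candidate",
                  warn = TRUE))
    mask <- predict(model, normalize_rd(rd, stats), type = "mask")
    cand <- mask_to_candidates(mask, side)
    coord <- refine_breakpoint(bp, cand)
    outcome <- if (!length(cand)) "retained-no-candidate"
               else if (length(cand) == 1L) "updated"
               else "multi-candidate-nearest"
    list(coord = coord, outcome = outcome, warn = FALSE)
  }
  left <- refine_side(sv$start, "left")
  right <- refine_side(sv$end, "right")
  if (left$warn || right$warn)
    sv_warn("window_off_contig",
            "screening window for SV %s falls off the contig; breakpoint retained",
            sv$id)
  new_start <- left$coord; new_end <- right$coord
  lo <- left$outcome; ro <- right$outcome
  if (new_end - new_start < 50L) {
    new_start <- sv$start; new_end <- sv$end
    lo <- ro <- "retained-size-guard"
  }
  data.frame(sv_id = sv$id, chrom = sv$chrom,
             orig_start = sv$start, orig_end = sv$end,
             new_start = as.integer(new_start),
             new_end = as.integer(new_end),
             left_outcome = lo, right_outcome = ro,
             stringsAsFactors = FALSE)
}

#' Enhance every DEL/DUP record of a VCF callset
#'
#' Reads a candidate callset, refines each DEL/DUP record via
#' [enhance_sv()], and writes an updated VCF in which POS/END carry the
#' refined coordinates while the original coordinates and the per-side
#' outcomes are added as INFO tags (`ORIG_POS`, `ORIG_END`, `BKE_LEFT`,
#' `BKE_RIGHT`).  Records of any other type pass through untouched.
#'
#' @param vcf_in path to the candidate VCF (records need SVTYPE and END).
#' @param model trained `rd_unet`.
#' @param source alignment source.
#' @param stats background `depth_stats`.
#' @param out_vcf optional output VCF path (plain text unless it ends in
#'   `.gz`).
#' @param report optional path for a TSV of enhancement records.
#' @param l screening-window length (defaults to the model input length).
#' @param bin_size optional caller bin size (see [enhance_sv()]).
#' @return Invisibly, a list with `records` (the enhancement table) and
#'   `svs` (the refined [sv_set()]).
#' @export
enhance_callset <- function(vcf_in, model, source, stats, out_vcf = NULL,
                            report = NULL, l = model$config$input_length,
                            bin_size = NULL) {
  vcf <- vcfR::read.vcfR(vcf_in, verbose = FALSE)
  fix <- vcf@fix
  info <- fix[, "INFO"]
  svtype <- vcf_info_field(info, "SVTYPE")
  vend <- suppressWarnings(as.integer(vcf_info_field(info, "END")))
  target <- which(svtype %in% c("DEL", "DUP") & !is.na(vend))
  if (!is.null(bin_size) && l < 4L * bin_size)
    sv_warn("short_window",
            "screening window (%d bp) covers fewer than four caller bins (%d bp)",
            l, bin_size)
  records <- NULL
  for (i in target) {
    sv <- list(chrom = fix[i, "CHROM"],
               start = as.integer(fix[i, "POS"]) - 1L,
               end = vend[i],
               id = if (is.na(fix[i, "ID"])) sprintf("rec%d", i)
                    else fix[i, "ID"])
    rec <- enhance_sv(sv, model, source, stats, l = l)
    records <- rbind(records, cbind(rec, svtype = svtype[i],
                                    stringsAsFactors = FALSE))
    fix[i, "POS"] <- as.character(rec$new_start + 1L)
    new_info <- sub("(^|;)END=[^;]*", sprintf("\\1END=%d", rec$new_end),
                    info[i])
    new_info <- paste0(new_info,
                       sprintf(";ORIG_POS=%d;ORIG_END=%d;BKE_LEFT=%s;BKE_RIGHT=%s",
                               sv$start + 1L, sv$end,
                               rec$left_outcome, rec$right_outcome))
    fix[i, "INFO"] <- new_info
  }
  vcf@fix <- fix
  vcf@meta <- c(vcf@meta,
    '##INFO=<ID=ORIG_POS,Number=1,Type=Integer,Description="POS before breakpoint enhancement">',
    '##INFO=<ID=ORIG_END,Number=1,Type=Integer,Description="END before breakpoint enhancement">',
    '##INFO=<ID=BKE_LEFT,Number=1,Type=String,Description="Left-breakpoint enhancement outcome">',
    '##INFO=<ID=BKE_RIGHT,Number=1,Type=String,Description="Right-breakpoint enhancement outcome">')
  if (!is.null(out_vcf)) write_vcfR(vcf, out_vcf)
  if (!is.null(report) && !is.null(records))
    utils::write.table(records, report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  svs <- if (is.null(records)) NULL else
    sv_set(records$chrom, records$new_start, records$new_end,
           records$svtype, id = records$sv_id, source = "enhanced")
  invisible(list(records = records, svs = svs, vcf = vcf))
}
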