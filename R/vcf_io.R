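# VCF/BED input and output for SV sets.  VCF coordinates are 1-based with
# inclusive END; the package-internal representation is 0-based half-open,
# so start = POS - 1 and end = END at the boundary in both directions.

# Pull a single key out of semicolon-separated INFO strings (vectorised).
vcf_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(sprintf("(?:^|;)%s=([^;]*)", key), info,
                                perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- regexpr(sprintf("(?:^|;)%s=([^;]*)", key), info, perl = TRUE) > 0
  out[hit] <- sub(sprintf("^;?%s=", key), "", m)
  out
}

#' Read an SV set from VCF or BED
#'
#' VCF records must carry `SVTYPE` (DEL/DUP) and `END` in INFO; other
#' SVTYPEs are dropped with a message.  BED input is 0-based half-open with
#' at least four columns (chrom, start, end, svtype) and an optional fifth
#' id column.
#'
#' @param path input file; format chosen by extension (`.bed` vs VCF).
#' @param source provenance tag stored on the records.
#' @return An [sv_set()].
#' @export
read_svs <- function(path, source = basename(path)) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
    read_sv_bed(path, source)
  else read_sv_vcf(path, source)
}

#' @rdname read_svs
#' @export
read_sv_vcf <- function(path, source = basename(path)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (!nrow(fix))
    return(sv_set(character(), integer(), integer(), character()))
  info <- fix[, "INFO"]
  svtype <- vcf_info_field(info, "SVTYPE")
  vend <- suppressWarnings(as.integer(vcf_info_field(info, "END")))
  keep <- svtype %in% c("DEL", "DUP") & !is.na(vend)
  dropped <- sum(!keep)
  if (dropped)
    message(sprintf("read_sv_vcf: dropped %d non-DEL/DUP or END-less records",
                    dropped))
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("rec%d", which(keep)[is.na(ids) | ids == "."])
  sv_set(fix[keep, "CHROM"],
         as.integer(fix[keep, "POS"]) - 1L,
         vend[keep],
         svtype[keep], id = ids, source = source)
}

read_sv_bed <- function(path, source = basename(path)) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    sv_stop("parse_error", "BED SV input needs >= 4 columns (type in col 4)")
  id <- if (ncol(df) >= 5L) as.character(df[[5L]]) else NULL
  sv_set(df[[1L]], df[[2L]], df[[3L]], df[[4L]], id = id, source = source)
}

#' Write an SV set as VCF
#'
#' Emits a minimal VCF 4.2 with symbolic ALT alleles and SVTYPE/END/SVLEN
#' INFO fields; the inverse of [read_sv_vcf()] (round-trips are lossless in
#' coordinates, type and id).
#'
#' @param svs an [sv_set()].
#' @param path output path; gzipped iff it ends in `.gz`.
#' @param genome optional named contig-length vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, genome = NULL) {
  svs <- validate_sv_set(svs)
  meta <- c("##fileformat=VCFv4.2",
            "##source=svrefine",
            if (!is.null(genome))
              sprintf("##contig=<ID=%s,length=%d>", names(genome),
                      as.integer(genome)),
            '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
            '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
            '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant">',
            '##ALT=<ID=DEL,Description="Deletion">',
            '##ALT=<ID=DUP,Description="Duplication">')
  ord <- order(svs$chrom, svs$start)
  svs <- svs[ord, , drop = FALSE]
  svlen <- ifelse(svs$svtype == "DEL", -(svs$end - svs$start),
                  svs$end - svs$start)
  fix <- cbind(CHROM = svs$chrom,
               POS = as.character(svs$start + 1L),
               ID = svs$id,
               REF = "N",
               ALT = sprintf("<%s>", svs$svtype),
               QUAL = ".",
               FILTER = "PASS",
               INFO = sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                              svs$svtype, svs$end, svlen))
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  vcf <- methods::new(cls, meta = meta, fix = fix,
                      gt = matrix(character(0), nrow = 0, ncol = 0))
  write_vcfR(vcf, path)
}

# vcfR::write.vcf always gzips; decompress when the caller asked for a
# plain-text .vcf path.
write_vcfR <- function(vcf, path) {
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(vcf, path)
  } else {
    tmp <- tempfile(fileext = ".vcf.gz")
    on.exit(unlink(tmp), add = TRUE)
    vcfR::write.vcf(vcf, tmp)
    con <- gzfile(tmp, "rt")
    lines <- readLines(con)
    close(con)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read excluded regions from a BED file
#' @param path BED path (0-based half-open intervals).
#' @return A `GRanges` suitable for the `exclude` arguments.
#' @export
read_exclude_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1L]], IRanges::IRanges(df[[2L]] + 1L, df[[3L]]))
}
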