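# End-to-end orchestration: background stats -> training-set construction
# -> UNet training -> callset enhancement -> evaluation, with a JSON run
# manifest for reproducibility and stage resumption.

#' Pipeline configuration
#'
#' @param alignment BAM path (or a `sim_reads` source).
#' @param candidate_vcf bin-resolution candidate callset (VCF).
#' @param known_sv_vcf validated/known SV set (VCF or BED) used for
#'   training and evaluation.
#' @param out_dir output directory.
#' @param mode `"in-sample"`: a seeded fraction of the known SVs trains the
#'   model and is excluded from evaluation; `"cross-sample"`: a pre-trained
#'   checkpoint enhances this sample.
#' @param train_fraction fraction of known SVs used for training in
#'   in-sample mode (default 0.2).
#' @param checkpoint pre-trained model checkpoint (required for
#'   cross-sample mode).
#' @param exclude_bed optional BED of regions excluded from background
#'   sampling and negative windows.
#' @param window_length screening-window length l (bp).
#' @param bin_size upstream caller bin size (bp), used for the
#'   four-bin-coverage warning.
#' @param model a [unet_config()] (defaults to `unet_config(window_length)`).
#' @param control a [train_control()].
#' @param n_background_bins,background_bin_size background sampling size.
#' @param seed master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, candidate_vcf, known_sv_vcf, out_dir,
                            mode = c("in-sample", "cross-sample"),
                            train_fraction = 0.2, checkpoint = NULL,
                            exclude_bed = NULL, window_length = 400L,
                            bin_size = 50L, model = NULL, control = NULL,
                            n_background_bins = 200L,
                            background_bin_size = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "cross-sample" && is.null(checkpoint))
    sv_stop("config_error", "cross-sample mode requires a model checkpoint")
  if (mode == "in-sample" &&
      (train_fraction <= 0 || train_fraction >= 1))
    sv_stop("config_error", "train_fraction must lie in (0, 1)")
  if (is.null(model)) model <- unet_config(input_length = window_length)
  if (model$input_length != window_length)
    sv_stop("config_error", "model input length != window_length")
  if (is.null(control)) control <- train_control(seed = seed)
  structure(list(alignment = alignment, candidate_vcf = candidate_vcf,
                 known_sv_vcf = known_sv_vcf, out_dir = out_dir, mode = mode,
                 train_fraction = train_fraction, checkpoint = checkpoint,
                 exclude_bed = exclude_bed,
                 window_length = as.integer(window_length),
                 bin_size = as.integer(bin_size),
                 model = model, control = control,
                 n_background_bins = as.integer(n_background_bins),
                 background_bin_size = as.integer(background_bin_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with `pipeline_config` fields (nested `model` and
#'   `control` blocks are passed to [unet_config()] / [train_control()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$model)) y$model <- do.call(unet_config, y$model)
  if (!is.null(y$control)) y$control <- do.call(train_control, y$control)
  do.call(pipeline_config, y)
}

file_fingerprint <- function(path) {
  if (is.character(path) && file.exists(path))
    unname(tools::md5sum(path)) else NA_character_
}

#' Run the full breakpoint-enhancement pipeline
#'
#' Stages: (1) background depth statistics; (2) known-SV split (in-sample)
#' or checkpoint load (cross-sample); (3) training-set construction and
#' UNet training; (4) enhancement of the candidate callset; (5) evaluation
#' against the known SVs, excluding any SV used in training.  Every stage
#' is logged in `manifest.json` together with input fingerprints and seeds;
#' re-running with an existing manifest whose fingerprints match skips the
#' (expensive) training stage and reloads its checkpoint.
#'
#' @param cfg a [pipeline_config()] or path to a YAML file.
#' @param quiet suppress stage messages.
#' @return A list with `model`, `stats`, `enhanced` (enhancement records),
#'   `evaluation` (before/after [boundary_match_summary()]s and the
#'   [change_matrix()]), and `paths` of all artifacts.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("candidate_vcf", "known_sv_vcf"))
    if (!file.exists(cfg[[f]]))
      sv_stop("config_error", "input file %s = '%s' does not exist", f,
              cfg[[f]])
  if (is.character(cfg$alignment) && !file.exists(cfg$alignment))
    sv_stop("config_error", "alignment '%s' does not exist", cfg$alignment)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  genome <- if (is.character(cfg$alignment)) bam_contigs(cfg$alignment)
            else stats::setNames(cfg$alignment$genome_length,
                                 cfg$alignment$contig)
  exclude <- if (!is.null(cfg$exclude_bed)) read_exclude_bed(cfg$exclude_bed)
  known <- read_svs(cfg$known_sv_vcf, source = "known")

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  fp <- list(alignment = file_fingerprint(cfg$alignment),
             candidate_vcf = file_fingerprint(cfg$candidate_vcf),
             known_sv_vcf = file_fingerprint(cfg$known_sv_vcf),
             seed = cfg$seed, mode = cfg$mode,
             window_length = cfg$window_length)
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL

  say("[1/5] background depth statistics")
  stats <- estimate_background_stats(
    cfg$alignment, genome = genome,
    exclude = combine_exclusions(exclude, known),
    n_bins = cfg$n_background_bins, bin_size = cfg$background_bin_size,
    seed = cfg$seed)

  ckpt_path <- file.path(cfg$out_dir, "model.ckpt")
  train_ids <- character(0)
  if (cfg$mode == "cross-sample") {
    say("[2/5] cross-sample: loading checkpoint %s", cfg$checkpoint)
    model <- load_model(cfg$checkpoint)
    if (model$config$input_length != cfg$window_length)
      sv_stop("config_error",
              "checkpoint input length %d != configured window length %d",
              model$config$input_length, cfg$window_length)
  } else {
    train_ids <- with_seed(cfg$seed, {
      n_train <- max(1L, round(cfg$train_fraction * nrow(known)))
      sample(known$id, n_train)
    })
    say("[2/5] in-sample split: %d of %d known SVs for training",
        length(train_ids), nrow(known))
    reuse <- !is.null(old_manifest) &&
      identical(old_manifest$fingerprints, fp) && file.exists(ckpt_path)
    if (reuse) {
      say("[3/5] inputs unchanged; reloading checkpoint")
      model <- load_model(ckpt_path)
    } else {
      say("[3/5] building training set and training the UNet")
      ts <- build_training_set(cfg$alignment,
                               known[known$id %in% train_ids, , drop = FALSE],
                               stats, genome, cfg$window_length, cfg$seed,
                               exclude = exclude)
      model <- build_unet(cfg$model, seed = cfg$seed)
      model <- train_model(model, ts, cfg$control, quiet = quiet)
      save_model(model, ckpt_path)
    }
  }

  say("[4/5] enhancing the candidate callset")
  out_vcf <- file.path(cfg$out_dir, "enhanced.vcf")
  report <- file.path(cfg$out_dir, "enhancements.tsv")
  enh <- enhance_callset(cfg$candidate_vcf, model, cfg$alignment, stats,
                         out_vcf = out_vcf, report = report,
                         l = cfg$window_length, bin_size = cfg$bin_size)

  say("[5/5] evaluation (training SVs excluded)")
  eval_gold <- known[!(known$id %in% train_ids), , drop = FALSE]
  before <- read_svs(cfg$candidate_vcf, source = "candidate")
  evaluation <- evaluate_enhancement(before, enh$svs, eval_gold)

  manifest <- list(fingerprints = fp,
                   package_version = as.character(utils::packageVersion("svrefine")),
                   n_known = nrow(known), n_train = length(train_ids),
                   train_ids = as.list(sort(train_ids)),
                   background = stats[c("mean", "std", "n_bins_sampled")],
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(model = model, stats = stats, enhanced = enh$records,
                 evaluation = evaluation,
                 paths = list(vcf = out_vcf, report = report,
                              checkpoint = ckpt_path,
                              manifest = manifest_path)))
}

combine_exclusions <- function(exclude, svs) {
  gr <- if (NROW(svs)) sv_granges(svs) else GenomicRanges::GRanges()
  if (!is.null(exclude)) gr <- c(gr, exclude)
  if (length(gr)) gr else NULL
}

#' Evaluate an enhancement run against a gold standard
#'
#' Matches both the original candidates and the enhanced calls to the gold
#' set, summarises boundary precision, and builds the breakpoint change
#' matrix over SVs matched in both states.
#'
#' @param before,after candidate and enhanced [sv_set()]s.
#' @param gold the gold-standard [sv_set()].
#' @return A list with `before`/`after` [boundary_match_summary()]s (NULL
#'   when nothing matched), matched tables, the [change_matrix()], and
#'   breakpoint counts within 5 bp of gold before/after.
#' @export
evaluate_enhancement <- function(before, after, gold) {
  mb <- match_to_gold(before, gold)
  ma <- match_to_gold(after, gold)
  sb <- tryCatch(boundary_match_summary(mb),
                 undefined_proportion = function(e) NULL)
  sa <- tryCatch(boundary_match_summary(ma),
                 undefined_proportion = function(e) NULL)
  shared <- intersect(mb$pred_id[mb$matched], ma$pred_id[ma$matched])
  bi <- match(shared, mb$pred_id); ai <- match(shared, ma$pred_id)
  dist_before <- c(mb$left_distance[bi], mb$right_distance[bi])
  dist_after <- c(ma$left_distance[ai], ma$right_distance[ai])
  cm <- change_matrix(dist_before, dist_after)
  list(before = sb, after = sa,
       matches_before = mb, matches_after = ma,
       change_matrix = cm,
       bp_within5_before = sum(dist_before < 5),
       bp_within5_after = sum(dist_after < 5))
}
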