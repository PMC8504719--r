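# Acceptance-scale fixtures (built lazily, cached for the whole run).
#
# Study conditions: 2,000 training windows of 400 bp at 30x mean depth,
# an 8-filter 4-level UNet, Adam 1e-3 with batch 64, early stopping
# (min 10, max 40 epochs, patience 8), all seeded.

ACC_SEED <- 1L

acc_train_sim <- function() {
  cache_get("acc_train_sim", function() {
    simulate_sv_data(sim_config(genome_length = 4e6, n_svs = 550L,
                                mean_depth = 30, seed = ACC_SEED))
  })
}

acc_stats <- function() {
  cache_get("acc_stats", function() {
    sim <- acc_train_sim()
    estimate_background_stats(
      sim$source, genome = sim$genome,
      exclude = GenomicRanges::GRanges(
        sim$svs$chrom, IRanges::IRanges(sim$svs$start + 1L, sim$svs$end)),
      n_bins = 200L, bin_size = 1000L, seed = ACC_SEED)
  })
}

# Trim a training set to n_pos positives + n_pos negatives.
trim_training_set <- function(ts, n_pos) {
  keep <- c(which(ts$meta$role == "positive")[seq_len(n_pos)],
            which(ts$meta$role == "negative")[seq_len(n_pos)])
  ts$x <- ts$x[keep, , drop = FALSE]
  ts$y <- ts$y[keep, , drop = FALSE]
  ts$meta <- ts$meta[keep, , drop = FALSE]
  ts
}

acc_model <- function() {
  cache_get("acc_model", function() {
    sim <- acc_train_sim()
    ts <- build_training_set(sim$source, sim$svs, acc_stats(), sim$genome,
                             l = 400L, seed = ACC_SEED)
    ts <- trim_training_set(ts, 1000L)
    cfg <- unet_config(input_length = 400L, base_filters = 8L)
    ctrl <- train_control(seed = ACC_SEED, max_epochs = 40L, patience = 8L)
    train_model(build_unet(cfg), ts, ctrl, quiet = TRUE)
  })
}

acc_test_set <- function() {
  cache_get("acc_test_set", function() {
    sim <- simulate_sv_data(sim_config(genome_length = 1.5e6, n_svs = 160L,
                                       mean_depth = 30, seed = ACC_SEED + 100L))
    ts <- build_training_set(sim$source, sim$svs, acc_stats(), sim$genome,
                             l = 400L, seed = ACC_SEED + 1L)
    trim_training_set(ts, 250L)
  })
}

# Fixture sample (with a real BAM on disk) for end-to-end enhancement.
acc_enhance_fixture <- function() {
  cache_get("acc_enhance_fixture", function() {
    sim <- simulate_sv_data(sim_config(genome_length = 1.2e6, n_svs = 120L,
                                       mean_depth = 30, bin_size = 50L,
                                       seed = ACC_SEED + 200L))
    paths <- write_fixtures(sim, tempfile("acc_fx"))
    list(sim = sim, paths = paths)
  })
}
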