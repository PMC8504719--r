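# The 1-D UNet: architecture contract, Dice loss, training behaviour.

tiny_cfg <- function(l = 64L, levels = 2L, base = 3L)
  unet_config(input_length = l, pooling_levels = levels, base_filters = base)

test_that("configuration enforces divisibility and threshold bounds", {
  expect_s3_class(unet_config(400L), "unet_config")
  expect_error(unet_config(100L, pooling_levels = 4L), class = "config_error")
  expect_error(unet_config(400L, kernel_size = 4L), class = "config_error")
  expect_error(unet_config(400L, threshold = 1), class = "config_error")
  w <- svrefine:::unet_widths(unet_config(400L, base_filters = 32L))
  expect_equal(w$enc, c(32L, 64L, 128L, 256L))
  expect_equal(w$bottleneck, 256L)   # capped at 8 x base
})

test_that("output length equals input length and scores stay in (0,1)", {
  cases <- list(c(96L, 4L), c(192L, 4L), c(400L, 4L), c(800L, 4L),
                c(1000L, 3L))   # 1000 is divisible by 2^3, not 2^4
  for (case in cases) {
    l <- case[1]
    cfg <- unet_config(l, pooling_levels = case[2], base_filters = 2L)
    m <- build_unet(cfg, seed = 3L)
    flat <- svrefine:::flat_params(m$params)
    n <- 2L
    sc <- svrefine:::unet_scores(flat, cfg, rnorm(n * l), n)
    expect_length(sc, n * l)
    expect_true(all(sc > 0 & sc < 1))
  }
})

test_that("dice_coefficient matches its definition and edge cases", {
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1,
               tolerance = 1e-6)
  expect_equal(dice_coefficient(c(0, 0), c(0, 0)), 1)   # epsilon limit
  expect_equal(dice_coefficient(c(1, 1, 1, 1), c(1, 1, 0, 0)),
               (2 * 2 + 1e-7) / (2 + 4 + 1e-7))
  expect_error(dice_coefficient(c(1, 0), c(1, 0, 0)), class = "shape_error")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- tiny_cfg(l = 16L, levels = 2L, base = 3L)
  m <- build_unet(cfg, seed = 7L)
  paths <- svrefine:::flat_paths(m$params)
  flat <- svrefine:::flat_params(m$params, paths)
  stat <- svrefine:::flat_stat_slots(paths)
  n <- 3L; l <- 16L
  x <- rnorm(n * l); g <- as.numeric(runif(n * l) < 0.4)
  res <- svrefine:::unet_train_step(flat, cfg, x, g, n)
  loss_fn <- function(fl) svrefine:::unet_train_step(fl, cfg, x, g, n)$loss
  eps <- 1e-6
  for (si in which(!stat)) {
    leaf <- flat[[si]]
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      fp <- flat; fp[[si]][i] <- fp[[si]][i] + eps
      fm <- flat; fm[[si]][i] <- fm[[si]][i] - eps
      num <- (loss_fn(fp) - loss_fn(fm)) / (2 * eps)
      ana <- res$grads[[si]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("training is seeded-deterministic and respects epoch bounds", {
  set.seed(99)
  l <- 32L
  n <- 40L
  x <- matrix(rnorm(n * l), n)
  y <- matrix(0L, n, l); y[seq_len(n / 2), 9:24] <- 1L
  x[seq_len(n / 2), 9:24] <- x[seq_len(n / 2), 9:24] - 2
  data <- list(x = x, y = y)
  cfg <- tiny_cfg(l = 32L, levels = 2L, base = 2L)
  ctrl <- train_control(min_epochs = 2L, max_epochs = 4L, patience = 2L,
                        batch_size = 16L, seed = 5L)
  m1 <- train_model(build_unet(cfg), data, ctrl)
  m2 <- train_model(build_unet(cfg), data, ctrl)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_gte(nrow(m1$history), 2L)
  expect_lte(nrow(m1$history), 4L)
  expect_error(train_model(build_unet(cfg), list(x = NULL, y = NULL), ctrl),
               class = "empty_training_set")
})

test_that("the UNet separates clean step signals almost perfectly", {
  # 200 noiseless step-signal windows: depth drop of 2 SDs over the marked
  # segment, flat background elsewhere
  set.seed(17)
  l <- 96L; n <- 200L
  x <- matrix(0, n, l); y <- matrix(0L, n, l)
  for (i in seq_len(n)) {
    a <- sample(10:40, 1L); b <- a + sample(20:50, 1L)
    x[i, a:b] <- -2
    y[i, a:b] <- 1L
  }
  cfg <- unet_config(96L, pooling_levels = 3L, base_filters = 4L)
  ctrl <- train_control(batch_size = 32L, min_epochs = 10L, max_epochs = 25L,
                        patience = 10L, seed = 2L)
  m <- train_model(build_unet(cfg), list(x = x, y = y), ctrl)
  pred <- predict(m, x, type = "mask")
  expect_gt(segmentation_metrics(pred, y, "ALL"), 0.95)
})

test_that("prediction validates its input contract", {
  cfg <- tiny_cfg()
  m <- build_unet(cfg, seed = 1L)
  m$trained <- TRUE
  w <- screening_window("c", 0L, 64L)
  raw <- rd_vector(w, rep(5L, 64L))
  expect_error(predict(m, raw), class = "unnormalized_input")
  expect_error(predict(m, rnorm(32L)), class = "shape_error")
  st <- structure(list(mean = 5, std = 2), class = "depth_stats")
  mask <- predict(m, normalize_rd(raw, st), type = "mask")
  expect_s3_class(mask, "label_mask")
  expect_length(mask$marks, 64L)
  expect_true(all(mask$marks %in% c(0L, 1L)))
  sc <- predict(m, normalize_rd(raw, st), type = "score")
  expect_equal(mask$marks, as.integer(sc > 0.5))
})

test_that("classify_window flags any SV-overlap mark", {
  w <- screening_window("c", 0L, 5L)
  expect_false(classify_window(label_mask(w, rep(0L, 5L))))
  expect_true(classify_window(label_mask(w, c(0L, 0L, 0L, 0L, 1L))))
  expect_true(classify_window(label_mask(w, rep(1L, 5L))))
})

test_that("checkpoints round-trip through save_model/load_model", {
  cfg <- tiny_cfg()
  m <- build_unet(cfg, seed = 4L)
  m$trained <- TRUE
  p <- tempfile(fileext = ".ckpt")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(m2$config, m$config)
  x <- matrix(rnorm(2 * 64), 2)
  expect_identical(predict(m, x, type = "score"),
                   predict(m2, x, type = "score"))
  expect_error(suppressWarnings(load_model(tempfile())), "cannot open")
})
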