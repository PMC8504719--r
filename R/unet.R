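# The 1-D UNet segmentation model: configuration, construction, training,
# and prediction.  The network maps a z-normalised read-depth window of
# length l to per-base SV-overlap scores of the same length.

#' UNet model configuration
#'
#' The encoder applies pairs of (convolution, ReLU, batch-norm) blocks with a
#' max-pool after every pair; the decoder mirrors it with 2x up-convolutions
#' and skip concatenation; a 1x1 convolution with a sigmoid produces per-base
#' scores.  Channel width doubles per level from `base_filters`, capped at
#' `8 * base_filters` (32 -> 256 with the defaults).
#'
#' @param input_length screening-window length l in bp; must be divisible by
#'   `2^pooling_levels`.  Default 400.
#' @param pooling_levels number of max-pool (and mirror up-sample) stages.
#' @param base_filters channel width of the first encoder level.
#' @param kernel_size odd convolution kernel width.
#' @param threshold score cutoff for calling a base SV-overlapping; strictly
#'   greater-than is used, so a score of exactly `threshold` yields mark 0.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_length = 400L, pooling_levels = 4L,
                        base_filters = 32L, kernel_size = 3L,
                        threshold = 0.5) {
  check_scalar(input_length, "input_length", min = 1)
  check_scalar(pooling_levels, "pooling_levels", min = 1)
  check_scalar(base_filters, "base_filters", min = 1)
  if (kernel_size %% 2 != 1)
    sv_stop("config_error", "kernel_size must be odd")
  if (threshold <= 0 || threshold >= 1)
    sv_stop("config_error", "threshold must lie in (0, 1)")
  pf <- 2L^as.integer(pooling_levels)
  if (input_length %% pf != 0)
    sv_stop("config_error",
            "input_length %d is not divisible by the pooling factor %d",
            input_length, pf)
  structure(list(input_length = as.integer(input_length),
                 pooling_levels = as.integer(pooling_levels),
                 pool_size = 2L,
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 threshold = threshold),
            class = "unet_config")
}

unet_widths <- function(config) {
  L <- config$pooling_levels
  cap <- 8L * config$base_filters
  w <- pmin(config$base_filters * 2L^(0:(L - 1L)), cap)
  list(enc = w, bottleneck = min(config$base_filters * 2L^L, cap))
}

#' Build an (untrained) 1-D UNet
#'
#' Initialises all weights (He-scaled Gaussian, seeded) for the architecture
#' described by `config`.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `rd_unet`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  w <- unet_widths(config)
  k <- config$kernel_size
  params <- with_seed(seed, {
    p <- list(enc = list(), bott = NULL, dec = list(), head = NULL)
    c_prev <- 1L
    for (i in seq_len(config$pooling_levels)) {
      ci <- w$enc[i]
      p$enc[[paste0("l", i)]] <- list(
        c1 = init_conv(c_prev, ci, k), b1 = init_bn(ci),
        c2 = init_conv(ci, ci, k),     b2 = init_bn(ci))
      c_prev <- ci
    }
    cb <- w$bottleneck
    p$bott <- list(c1 = init_conv(c_prev, cb, k), b1 = init_bn(cb),
                   c2 = init_conv(cb, cb, k),     b2 = init_bn(cb))
    c_below <- cb
    for (i in rev(seq_len(config$pooling_levels))) {
      ci <- w$enc[i]
      p$dec[[paste0("l", i)]] <- list(
        up = init_up(c_below, ci),
        c1 = init_conv(2L * ci, ci, k), b1 = init_bn(ci),
        c2 = init_conv(ci, ci, k),      b2 = init_bn(ci))
      c_below <- ci
    }
    p$head <- list(W = he_matrix(1L, c_below, c_below), b = 0)
    p
  })
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE),
            class = "rd_unet")
}

# Thin wrappers over the compiled whole-network engine (src/unet_core.cpp).
# `flat` is the canonical flat parameter list; `xvec` the sample-major
# input signal of n windows of length l.

unet_scores <- function(flat, config, xvec, n) {
  unet_run_cpp(flat, xvec, numeric(0), as.integer(n),
               config$input_length, config$pooling_levels,
               FALSE, FALSE, 1e-7)$scores
}

unet_train_step <- function(flat, config, xvec, gold, n, epsilon = 1e-7) {
  unet_run_cpp(flat, xvec, gold, as.integer(n),
               config$input_length, config$pooling_levels,
               TRUE, TRUE, epsilon)
}

#' Training control parameters
#'
#' Defaults follow the study conditions: Adam with learning rate 0.001,
#' batch size 64, early stopping on validation Dice with a minimum of 10 and
#' a maximum of 100 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param min_epochs,max_epochs early-stopping bounds (inclusive).
#' @param patience epochs without validation improvement before stopping.
#' @param validation_fraction fraction of windows held out for early
#'   stopping, in (0, 1).
#' @param seed integer seed driving initialisation, the split, and shuffling.
#' @return An object of class `train_control`.
#' @export
train_control <- function(learning_rate = 0.001, batch_size = 64L,
                          min_epochs = 10L, max_epochs = 100L,
                          patience = 10L, validation_fraction = 0.1,
                          seed = 1L) {
  if (min_epochs > max_epochs)
    sv_stop("config_error", "min_epochs must be <= max_epochs")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    sv_stop("config_error", "validation_fraction must lie in (0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Train the UNet on a labelled window set
#'
#' Minimises the soft Dice loss (1 - DSC computed on continuous sigmoid
#' scores) with Adam; early stopping monitors the mean thresholded Dice on a
#' held-out validation split and restores the best weights.  All randomness
#' (weight initialisation, the split, per-epoch shuffling) flows from
#' `control$seed`, so runs are bit-reproducible on CPU.
#'
#' @param model an `rd_unet` from [build_unet()] (its weights are
#'   re-initialised from `control$seed` so a fit is fully determined by
#'   config + data + control).
#' @param data a `training_set` (or any list with matrices `x` and `y`).
#' @param control a [train_control()].
#' @param quiet suppress per-epoch progress.
#' @return The fitted `rd_unet`, with `history` (one row per epoch:
#'   `epoch`, `train_loss`, `val_dsc`) and `trained = TRUE`.
#' @export
train_model <- function(model, data, control = train_control(),
                        quiet = TRUE) {
  stopifnot(inherits(model, "rd_unet"), inherits(control, "train_control"))
  x <- data$x; y <- data$y
  if (is.null(x) || nrow(x) == 0)
    sv_stop("empty_training_set", "training data is empty")
  if (ncol(x) != model$config$input_length)
    sv_stop("shape_error", "window length %d != model input length %d",
            ncol(x), model$config$input_length)
  cfg <- model$config
  n_all <- nrow(x)

  with_seed(control$seed, {
    model <- build_unet(cfg, seed = sample.int(2^30, 1L))
    n_val <- max(1L, round(control$validation_fraction * n_all))
    if (n_val >= n_all) n_val <- max(1L, n_all %/% 5L)
    val_idx <- sample.int(n_all, n_val)
    tr_idx <- setdiff(seq_len(n_all), val_idx)
    if (!length(tr_idx)) tr_idx <- val_idx
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx, , drop = FALSE]
    xt <- x[tr_idx, , drop = FALSE];  yt <- y[tr_idx, , drop = FALSE]

    paths <- flat_paths(model$params)
    flat <- flat_params(model$params, paths)
    opt <- adam_init(flat, flat_stat_slots(paths))
    best <- list(dsc = -Inf, flat = flat, epoch = 0L)
    hist <- NULL
    n_tr <- nrow(xt)
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n_tr)
      losses <- numeric(0)
      for (b0 in seq(1L, n_tr, by = control$batch_size)) {
        idx <- ord[b0:min(b0 + control$batch_size - 1L, n_tr)]
        nb <- length(idx)
        xb <- as.numeric(t(xt[idx, , drop = FALSE]))
        gb <- as.numeric(t(yt[idx, , drop = FALSE]))
        res <- unet_train_step(flat, cfg, xb, gb, nb)
        losses <- c(losses, res$loss)
        upd <- adam_step(flat, res$grads, opt, control$learning_rate)
        flat <- upd$flat; opt <- upd$state
      }
      val_dsc <- mean(eval_dsc(flat, cfg, xv, yv))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     val_dsc = val_dsc))
      if (!quiet)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.4f",
                        epoch, mean(losses), val_dsc))
      if (val_dsc > best$dsc) {
        best <- list(dsc = val_dsc, flat = flat, epoch = epoch)
      }
      if (epoch >= control$min_epochs &&
          epoch - best$epoch >= control$patience)
        break
    }
    model$params <- unflatten_params(model$params, best$flat, paths)
    model$history <- hist
    model$trained <- TRUE
    model$control <- control
    model
  })
}

# Thresholded per-window DSC in evaluation mode (running BN stats), batched.
eval_dsc <- function(flat, cfg, x, y, batch = 256L) {
  l <- cfg$input_length
  out <- numeric(0)
  for (b0 in seq(1L, nrow(x), by = batch)) {
    idx <- b0:min(b0 + batch - 1L, nrow(x))
    nb <- length(idx)
    scores <- unet_scores(flat, cfg, as.numeric(t(x[idx, , drop = FALSE])), nb)
    marks <- as.numeric(scores > cfg$threshold)
    gold <- as.numeric(t(y[idx, , drop = FALSE]))
    grp <- rep.int(seq_len(nb), rep.int(l, nb))
    sg <- rowsum(gold, grp, reorder = FALSE)
    sp <- rowsum(marks, grp, reorder = FALSE)
    sgp <- rowsum(gold * marks, grp, reorder = FALSE)
    out <- c(out, as.numeric((2 * sgp + 1e-7) / (sg + sp + 1e-7)))
  }
  out
}

#' Dice similarity coefficient
#'
#' `(2 * sum(gold * pred) + eps) / (sum(gold) + sum(pred) + eps)`.  Accepts
#' binary masks or continuous scores (the soft variant used as training
#' loss); two empty masks score 1 by the epsilon limit.
#'
#' @param pred predicted marks or scores (`label_mask` or numeric vector).
#' @param gold gold-standard marks (`label_mask` or numeric vector).
#' @param epsilon numeric tolerance guarding against division by zero.
#' @return A single number in (0, 1].
#' @export
dice_coefficient <- function(pred, gold, epsilon = 1e-7) {
  p <- if (inherits(pred, "label_mask")) pred$marks else as.numeric(pred)
  g <- if (inherits(gold, "label_mask")) gold$marks else as.numeric(gold)
  if (length(p) != length(g))
    sv_stop("shape_error", "mask lengths differ (%d vs %d)",
            length(p), length(g))
  (2 * sum(g * p) + epsilon) / (sum(g) + sum(p) + epsilon)
}

#' Predict per-base scores or SV-overlap marks
#'
#' @param object a trained `rd_unet`.
#' @param x a normalised [rd_vector()], or an n x l numeric matrix of
#'   z-scores, or a plain numeric vector of length l.
#' @param type `"mask"` for thresholded 0/1 marks (score strictly greater
#'   than the configured threshold), `"score"` for raw sigmoid scores.
#' @param ... unused.
#' @return For an `rd_vector` input with `type = "mask"`, a [label_mask()];
#'   otherwise a vector (or n x l matrix) of marks/scores.
#' @method predict rd_unet
#' @export
predict.rd_unet <- function(object, x, type = c("mask", "score"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  win <- NULL
  if (inherits(x, "rd_vector")) {
    if (!x$normalized)
      sv_stop("unnormalized_input",
              "rd_vector must be normalised before prediction")
    win <- x$window
    x <- matrix(x$values, nrow = 1L)
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != cfg$input_length)
    sv_stop("shape_error", "input length %d != model input length %d",
            ncol(x), cfg$input_length)
  n <- nrow(x)
  flat <- flat_params(object$params)
  scores <- matrix(NA_real_, n, cfg$input_length)
  batch <- 256L
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    nb <- length(idx)
    sc <- unet_scores(flat, cfg, as.numeric(t(x[idx, , drop = FALSE])), nb)
    scores[idx, ] <- matrix(sc, nb, cfg$input_length, byrow = TRUE)
  }
  out <- if (type == "mask") (scores > cfg$threshold) * 1L else scores
  if (!is.null(win)) {
    if (type == "mask") return(label_mask(win, as.integer(out[1L, ])))
    return(as.numeric(out[1L, ]))
  }
  if (n == 1L) out[1L, ] else out
}

#' Segment one depth window into a label mask
#'
#' Thin wrapper over [predict.rd_unet()] keeping the window coordinates
#' attached: a base is marked 1 iff its score is strictly greater than the
#' configured threshold (0.5 by default).
#'
#' @param model a trained `rd_unet`.
#' @param rd a normalised [rd_vector()] of the model's input length.
#' @return A [label_mask()] over the same window.
#' @export
predict_mask <- function(model, rd) {
  predict(model, rd, type = "mask")
}

#' Classify a window from its segmentation
#'
#' A screening window is called positive iff any base carries an SV-overlap
#' mark.
#'
#' @param mask a [label_mask()] or 0/1 vector.
#' @return `TRUE` (positive) or `FALSE`.
#' @export
classify_window <- function(mask) {
  m <- if (inherits(mask, "label_mask")) mask$marks else mask
  any(m == 1L)
}

#' @method print rd_unet
#' @export
print.rd_unet <- function(x, ...) {
  w <- unet_widths(x$config)
  cat(sprintf("<rd_unet> 1-D UNet, input %d bp, %d levels (widths %s | %d)\n",
              x$config$input_length, x$config$pooling_levels,
              paste(w$enc, collapse = "-"), w$bottleneck))
  cat(if (x$trained)
        sprintf("  trained: %d epochs, best validation DSC %.4f\n",
                nrow(x$history), max(x$history$val_dsc))
      else "  untrained\n")
  invisible(x)
}

#' @method summary rd_unet
#' @export
summary.rd_unet <- function(object, ...) {
  npar <- sum(vapply(nested_leaf_paths(object$params),
                     function(p) length(object$params[[p]]), numeric(1)))
  cat(sprintf("1-D UNet with %s trainable parameters\n",
              format(npar, big.mark = ",")))
  print(object)
  if (object$trained) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @method coef rd_unet
#' @export
coef.rd_unet <- function(object, ...) object$params

#' Plot the training history
#' @param x a trained `rd_unet`.
#' @param ... passed to [graphics::plot()].
#' @method plot rd_unet
#' @export
plot.rd_unet <- function(x, ...) {
  if (is.null(x$history)) sv_stop("config_error", "model has no history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "soft Dice loss",
                 main = "UNet training", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_dsc, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4L)
  graphics::mtext("validation DSC", side = 4L, line = 2L)
  graphics::legend("right", legend = c("train loss", "val DSC"),
                   col = c("firebrick", "steelblue"), lty = 1L, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full `unet_config` so a loaded model validates its
#' own input length; training history travels with the weights.
#'
#' @param model a `rd_unet`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `rd_unet`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rd_unet"))
  saveRDS(list(format = "svrefine_unet_checkpoint", version = 1L,
               config = model$config, params = model$params,
               history = model$history, trained = model$trained),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "svrefine_unet_checkpoint"))
    sv_stop("config_error", "'%s' is not a svrefine checkpoint", path)
  structure(list(config = obj$config, params = obj$params,
                 history = obj$history, trained = isTRUE(obj$trained)),
            class = "rd_unet")
}
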