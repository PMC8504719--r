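# R-side support for the UNet core: parameter initialisation, the
# canonical flat parameter layout shared with the C++ engine, and Adam.
#
# The network itself (forward pass, batch-level soft Dice loss, backward
# pass) runs in compiled code -- see src/unet_core.cpp.  Parameters are
# held user-facing as a nested named list (see build_unet()); training
# flattens them once into the canonical slot order and hands the flat list
# to C++ for each minibatch.

# ---- parameter initialisation ----------------------------------------------

he_matrix <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# W stored (c_out x k*c_in), column blocks ordered by kernel offset.
init_conv <- function(c_in, c_out, k) {
  list(W = he_matrix(c_out, k * c_in, k * c_in), b = numeric(c_out))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

init_up <- function(c_in, c_out) {
  list(W1 = he_matrix(c_out, c_in, c_in),
       W2 = he_matrix(c_out, c_in, c_in),
       b = numeric(c_out))
}

# ---- canonical flat layout -------------------------------------------------

# The nested parameter list is built in exactly the traversal order the C++
# engine consumes, so a depth-first walk over numeric leaves *is* the
# canonical flat order.
flat_paths <- function(params) nested_leaf_paths(params, skip = character())

flat_params <- function(params, paths = flat_paths(params)) {
  lapply(paths, function(p) params[[p]])
}

# Slots holding batch-norm running statistics: the engine returns refreshed
# values (not gradients) for these, and Adam must skip them.
flat_stat_slots <- function(paths) {
  vapply(paths, function(p) p[length(p)] %in% c("run_mean", "run_var"),
         logical(1))
}

unflatten_params <- function(params, flat, paths) {
  for (i in seq_along(paths)) params[[paths[[i]]]] <- flat[[i]]
  params
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(flat, stat) {
  idx <- which(!stat)
  list(idx = idx, stat_idx = which(stat),
       m = lapply(flat[idx], function(x) x * 0),
       v = lapply(flat[idx], function(x) x * 0),
       t = 0L)
}

# flat/grads: canonical flat lists; stat slots in grads carry refreshed
# running statistics and are copied through verbatim.
adam_step <- function(flat, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (j in seq_along(state$idx)) {
    i <- state$idx[j]
    g <- grads[[i]]
    if (!is.null(dim(flat[[i]]))) dim(g) <- dim(flat[[i]])
    else g <- as.numeric(g)
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * g
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * g * g
    flat[[i]] <- flat[[i]] -
      lr * (state$m[[j]] / bc1) / (sqrt(state$v[[j]] / bc2) + eps)
  }
  for (i in state$stat_idx) flat[[i]] <- as.numeric(grads[[i]])
  list(flat = flat, state = state)
}
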