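# Internal helpers: classed conditions, seeded evaluation, nested-list walkers.

#' Signal a classed svrefine error
#'
#' All package errors carry a specific condition class (e.g.
#' `"contig_not_found"`, `"degenerate_background"`) plus the umbrella class
#' `"svrefine_error"`, so callers can branch with `tryCatch()`.
#'
#' @param class character scalar, the specific condition class.
#' @param msg sprintf-style message.
#' @param ... values interpolated into `msg`.
#' @keywords internal
#' @noRd
sv_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "svrefine_error")))
}

sv_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "svrefine_warning")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded package internals never perturb the user's random stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    sv_stop("config_error", "seed must be a single integer")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  } else {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Stop unless x is a single finite number
check_scalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    sv_stop("config_error", "%s must be a single finite number >= %s", name, min)
  invisible(x)
}

# Recursively walk two same-shaped nested lists of numeric leaves, applying f.
nested_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- nested_map2(a[[nm]], b[[nm]], f)
    return(out)
  }
  f(a, b)
}

nested_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- nested_map(a[[nm]], f)
    return(out)
  }
  f(a)
}

# Collect the [[-paths of all numeric leaves of a nested named list,
# optionally skipping leaf names in `skip` (used to keep batch-norm running
# statistics out of the optimizer).
nested_leaf_paths <- function(x, skip = character()) {
  paths <- list()
  recurse <- function(node, path) {
    if (is.list(node)) {
      for (nm in names(node)) recurse(node[[nm]], c(path, nm))
    } else if (is.numeric(node) && !(path[length(path)] %in% skip)) {
      paths[[length(paths) + 1L]] <<- path
    }
  }
  recurse(x, character())
  paths
}
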