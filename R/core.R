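#' Reference model: a set of cell-type mixtures plus abundances
#'
#' Bundles one [cell_type_gmm()] per cell type with the cell-type abundance
#' vector (or a per-batch matrix of abundances). Produced by
#' [generate_cell_type_params()] (creation mode) or [fit_reference()]
#' (emulation mode), consumed by [simulate_cells()].
#'
#' @param gmms Named list of [cell_type_gmm()] objects (names = cell types).
#' @param abundances Probability vector over cell types, or a `B x P` matrix
#'   with one row per batch. Columns/entries may be named by cell type.
#' @param channels Optional character vector of channel names.
#' @return An object of class `cytosim_model`.
#' @export
reference_model <- function(gmms, abundances, channels = NULL) {
  if (is.null(names(gmms)) || anyDuplicated(names(gmms))) {
    abort("`gmms` must be a named list with unique cell-type labels.")
  }
  P <- length(gmms)
  for (g in gmms) stopifnot(inherits(g, "cytosim_gmm"))
  M <- ncol(gmms[[1]]$means)
  if (any(vapply(gmms, function(g) ncol(g$means), 0L) != M)) {
    abort("All cell-type mixtures must share the same channel dimension.")
  }
  if (is.matrix(abundances)) {
    if (ncol(abundances) != P) abort("`abundances` matrix must have one column per cell type.")
    apply(abundances, 1, check_probability_vector)
    colnames(abundances) <- names(gmms)
  } else {
    if (length(abundances) != P) abort("`abundances` must have one entry per cell type.")
    check_probability_vector(abundances)
    names(abundances) <- names(gmms)
  }
  channels <- channels %||% gmms[[1]]$channels %||% sprintf("ch%02d", seq_len(M))
  structure(
    list(cell_types = names(gmms), gmms = gmms, abundances = abundances,
         channels = channels),
    class = "cytosim_model"
  )
}

#' @export
print.cytosim_model <- function(x, ...) {
  k <- vapply(x$gmms, function(g) length(g$weights), 0L)
  cat(sprintf("<cytosim_model: %d cell type(s), %d channel(s)>\n",
              length(x$cell_types), length(x$channels)))
  cat("  components per type:", paste(k, collapse = ", "), "\n")
  ab <- if (is.matrix(x$abundances)) colMeans(x$abundances) else x$abundances
  cat("  abundances:", paste(sprintf("%s=%.3f", x$cell_types, ab), collapse = ", "), "\n")
  invisible(x)
}

# Per-type mixture means as a P x M matrix (used for trajectories, tidiers).
model_type_means <- function(model) {
  out <- t(vapply(model$gmms, gmm_mean, numeric(length(model$channels))))
  dimnames(out) <- list(model$cell_types, model$channels)
  out
}

#' Sample cell-type labels from an abundance vector
#'
#' Cell types are drawn from a categorical distribution over the `P` types.
#'
#' @param abundances Nonnegative probability vector summing to 1.
#' @param n_cells Number of cells.
#' @param seed Optional seed.
#' @return Integer vector of length `n_cells` with values in `1..P`.
#' @export
#' @examples
#' table(sample_cell_labels(c(0.2, 0.8), 1000, seed = 1))
sample_cell_labels <- function(abundances, n_cells, seed = NULL) {
  check_probability_vector(abundances)
  stopifnot(n_cells >= 1)
  with_seed_(seed,
    sample.int(length(abundances), n_cells, replace = TRUE, prob = abundances))
}

#' Truncate expressions below zero
#'
#' Element-wise clipping at 0: protein abundances cannot be negative before
#' machine noise, so negative latent values are replaced by exactly 0.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with `max(x, 0)` applied element-wise.
#' @export
truncate_below_zero <- function(x) {
  x[x < 0] <- 0
  x
}

#' Machine-noise model
#'
#' Zero-mean error added after truncation, mimicking the data randomization a
#' CyTOF system applies; this is what re-introduces small negative values in
#' real matrices. Gaussian by default; a mean-zero uniform with matching
#' standard deviation is also available.
#'
#' @param sd Standard deviation on the arcsinh scale (`>= 0`).
#' @param family `"gaussian"` or `"uniform"`.
#' @return An object of class `cytosim_noise`.
#' @export
noise_model <- function(sd = 0, family = c("gaussian", "uniform")) {
  family <- match.arg(family)
  stopifnot(is.numeric(sd), length(sd) == 1, sd >= 0)
  structure(list(family = family, sd = sd), class = "cytosim_noise")
}

#' Add machine noise to an expression matrix
#'
#' @param x Numeric matrix.
#' @param noise A [noise_model()] (or a bare nonnegative sd).
#' @param seed Optional seed.
#' @return `x` plus i.i.d. zero-mean draws; identical to `x` when `sd = 0`.
#' @export
add_machine_noise <- function(x, noise, seed = NULL) {
  if (is.numeric(noise)) noise <- noise_model(noise)
  stopifnot(inherits(noise, "cytosim_noise"))
  if (noise$sd == 0) return(x)
  with_seed_(seed, {
    e <- switch(noise$family,
      gaussian = stats::rnorm(length(x), 0, noise$sd),
      # half-width sqrt(3)*sd gives a mean-zero uniform with the requested sd
      uniform = stats::runif(length(x), -sqrt(3) * noise$sd, sqrt(3) * noise$sd))
    x + matrix(e, nrow(x), ncol(x))
  })
}
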