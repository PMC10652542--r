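#' Per-cell-type Gaussian mixture model
#'
#' The building block of the simulator: each cell type is described by a
#' Gaussian mixture over the `M` protein channels (arcsinh(x/5) scale).
#' Component weights must sum to 1 and every covariance must be symmetric
#' positive semi-definite. `zero_target` optionally records, per channel, the
#' near-zero frequency observed in reference data (used by
#' [apply_zero_matching()] in emulation mode).
#'
#' @param weights Numeric vector of component weights (sums to 1).
#' @param means `K x M` matrix of component means (rows = components).
#' @param covariances List of `K` symmetric PSD `M x M` matrices.
#' @param zero_target Optional length-`M` vector of per-channel near-zero
#'   probabilities in `[0, 1]`.
#' @param channels Optional character vector of channel names.
#' @return An object of class `cytosim_gmm`.
#' @export
#' @examples
#' g <- cell_type_gmm(1, matrix(c(2, 3), 1), list(diag(0.1, 2)))
#' sample_latent_expressions(g, 5, seed = 1)
cell_type_gmm <- function(weights, means, covariances, zero_target = NULL,
                          channels = NULL) {
  weights <- as.numeric(weights)
  if (is.numeric(means) && !is.matrix(means)) means <- matrix(means, nrow = 1)
  if (is.matrix(covariances)) covariances <- list(covariances)
  check_probability_vector(weights, "weights")
  K <- length(weights)
  M <- ncol(means)
  if (nrow(means) != K || length(covariances) != K) {
    abort("`means` rows and `covariances` length must equal length(weights).")
  }
  for (k in seq_len(K)) {
    S <- covariances[[k]]
    if (!is.matrix(S) || nrow(S) != M || ncol(S) != M) {
      abort(sprintf("covariance %d is not %d x %d.", k, M, M))
    }
    if (max(abs(S - t(S))) > 1e-8) abort(sprintf("covariance %d is not symmetric.", k))
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      abort(sprintf(
        "covariance %d is not PSD (min eigenvalue %.3g); consider adding diagonal jitter.",
        k, ev))
    }
    covariances[[k]] <- (S + t(S)) / 2
  }
  if (!is.null(zero_target)) {
    stopifnot(length(zero_target) == M, all(zero_target >= 0 & zero_target <= 1))
    zero_target <- as.numeric(zero_target)
  }
  if (is.null(channels)) channels <- colnames(means)
  if (!is.null(channels)) colnames(means) <- channels
  structure(
    list(weights = weights, means = means, covariances = covariances,
         zero_target = zero_target, channels = channels),
    class = "cytosim_gmm"
  )
}

#' @export
print.cytosim_gmm <- function(x, ...) {
  cat(sprintf("<cytosim_gmm: %d component(s), %d channel(s)%s>\n",
              length(x$weights), ncol(x$means),
              if (is.null(x$zero_target)) "" else ", zero-matching targets"))
  invisible(x)
}

# Mixture mean: weighted average of component means (length M).
gmm_mean <- function(gmm) {
  drop(crossprod(gmm$weights, gmm$means))
}

# Cholesky factor with diagonal jitter fallback (1e-6 * I), warning once.
chol_jitter <- function(S, label = "covariance") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    warn(sprintf("%s is numerically singular; adding 1e-6 diagonal jitter.", label))
    R <- chol(S + diag(1e-6, nrow(S)))
  }
  R
}

#' Sample latent (pre-truncation) expressions from a cell-type mixture
#'
#' Draws a component per cell from the mixture weights and then a
#' multivariate normal vector from that component. No truncation or noise is
#' applied at this stage.
#'
#' @param gmm A [cell_type_gmm()].
#' @param n_cells Number of cells to draw.
#' @param seed Optional seed (caller RNG is untouched when supplied).
#' @return `n_cells x M` numeric matrix.
#' @export
sample_latent_expressions <- function(gmm, n_cells, seed = NULL) {
  stopifnot(inherits(gmm, "cytosim_gmm"), n_cells >= 1)
  with_seed_(seed, {
    M <- ncol(gmm$means)
    comp <- sample_cell_labels(gmm$weights, n_cells)
    X <- matrix(0, n_cells, M, dimnames = list(NULL, gmm$channels))
    for (k in unique(comp)) {
      idx <- which(comp == k)
      S <- gmm$covariances[[k]]
      if (all(S == 0)) {
        X[idx, ] <- matrix(gmm$means[k, ], length(idx), M, byrow = TRUE)
      } else {
        R <- chol_jitter(S, sprintf("component %d covariance", k))
        Z <- matrix(stats::rnorm(length(idx) * M), length(idx), M)
        X[idx, ] <- sweep(Z %*% R, 2, gmm$means[k, ], "+")
      }
    }
    X
  })
}
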