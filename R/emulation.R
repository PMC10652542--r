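#' Settings for emulation-mode mixture fitting
#'
#' @param min_components,max_components BIC model-selection range for the
#'   number of mixture components per cell type (defaults 1 and 9).
#' @param covariance `"full"` (unrestricted per-component covariance) or
#'   `"diagonal"` (independent channels; the "IG" reduced model when combined
#'   with `max_components = 1`).
#' @param near_zero_threshold Values with `|x| <= threshold` (arcsinh units)
#'   count as near-zero when recording zero-matching targets.
#' @param tol EM convergence tolerance.
#' @param init_subset Size of the seeded subsample used for model-based
#'   hierarchical initialization of EM (keeps fitting deterministic and fast
#'   on large matrices).
#' @return An object of class `cytosim_fit_settings`.
#' @export
fit_settings <- function(min_components = 1, max_components = 9,
                         covariance = c("full", "diagonal"),
                         near_zero_threshold = 1e-6, tol = 1e-4,
                         init_subset = 2000) {
  covariance <- match.arg(covariance)
  stopifnot(min_components >= 1, min_components <= max_components,
            near_zero_threshold >= 0, tol > 0, init_subset >= 10)
  structure(
    list(min_components = as.integer(min_components),
         max_components = as.integer(max_components),
         covariance = covariance,
         near_zero_threshold = near_zero_threshold,
         tol = tol, init_subset = as.integer(init_subset)),
    class = "cytosim_fit_settings"
  )
}

mclust_model_name <- function(covariance, M) {
  if (M == 1) "V" else if (covariance == "full") "VVV" else "VVI"
}

#' Fit a Gaussian mixture to one cell type's expressions
#'
#' EM fits are run for every component count in
#' `min_components:max_components` and the count minimizing
#' `BIC = -2 logL + k log(n)` is kept. The BIC curve is retained in the
#' result (`$bic`) for inspection. Per-channel near-zero frequencies of the
#' input are recorded as `zero_target` for later [apply_zero_matching()].
#'
#' @param x Cells-by-channels numeric matrix (or data frame; annotation
#'   columns are dropped).
#' @param settings A [fit_settings()].
#' @param seed Optional seed controlling the initialization subsample.
#' @return A [cell_type_gmm()] with extra elements `bic` (tibble with
#'   `components`, `bic`) and `n` (cells used).
#' @export
fit_cell_type_gmm <- function(x, settings = fit_settings(), seed = NULL) {
  stopifnot(inherits(settings, "cytosim_fit_settings"))
  x <- channel_matrix(x)
  if (anyNA(x)) abort("expression matrix contains missing values.")
  # canonical row order: the fit (and its seeded initialization subsample)
  # is invariant to how the caller happened to order the cells
  x <- x[do.call(order, as.data.frame(x)), , drop = FALSE]
  n <- nrow(x); M <- ncol(x)
  kmax <- settings$max_components
  if (n < kmax + 1) {
    kmax <- max(1L, n - 1L)
    warn(sprintf("only %d cells: shrinking max_components to %d.", n, kmax))
  }
  kmin <- min(settings$min_components, kmax)
  model <- mclust_model_name(settings$covariance, M)

  run_mclust <- function(xx) {
    init <- if (nrow(xx) > settings$init_subset) {
      list(subset = sample.int(nrow(xx), settings$init_subset))
    }
    suppressWarnings(mclust::Mclust(
      xx, G = kmin:kmax, modelNames = model, verbose = FALSE,
      initialization = init,
      control = mclust::emControl(tol = rep(settings$tol, 2))))
  }

  fit <- with_seed_(seed, {
    f <- tryCatch(run_mclust(x), error = function(e) NULL)
    if (is.null(f)) {
      warn("EM fit failed; retrying once with jittered data (sd 1e-6).")
      xj <- x + matrix(stats::rnorm(length(x), 0, 1e-6), n, M)
      f <- tryCatch(run_mclust(xj), error = function(e) NULL)
    }
    f
  })
  if (is.null(fit)) abort("EM fitting failed even after jitter regularization.")

  par <- fit$parameters
  K <- fit$G
  means <- if (M == 1) matrix(par$mean, K, 1) else t(par$mean)
  covs <- if (M == 1) {
    lapply(rep_len(par$variance$sigmasq, K), function(s) matrix(s, 1, 1))
  } else {
    lapply(seq_len(K), function(k) as.matrix(par$variance$sigma[, , k]))
  }
  w <- if (K == 1) 1 else par$pro
  g <- cell_type_gmm(w / sum(w), means, covs,
                     zero_target = colMeans(abs(x) <= settings$near_zero_threshold),
                     channels = colnames(x))
  # mclust reports 2 logL - k log n (higher better); flip to the usual sign
  bic_raw <- -as.numeric(fit$BIC[, model])
  g$bic <- tibble(components = kmin:kmax, bic = bic_raw[seq_len(kmax - kmin + 1)])
  g$n <- n
  g
}

#' Fit a reference model from a labeled expression table (emulation mode)
#'
#' Groups cells by their type label, fits one BIC-selected Gaussian mixture
#' per type with [fit_cell_type_gmm()], and records empirical label
#' frequencies as abundances. The grouping is canonical (labels sorted), so
#' permuting rows leaves the fitted model unchanged.
#'
#' @param data Data frame with numeric channel columns and a label column, or
#'   a numeric matrix (then supply `labels`).
#' @param cell_type Name of the label column (default `"cell_type"`).
#' @param labels Optional explicit label vector (one per row).
#' @param settings A [fit_settings()].
#' @param seed Optional seed (one derived stream per cell type).
#' @return A [reference_model()] whose mixtures carry BIC curves and
#'   zero-matching targets.
#' @export
#' @examples
#' fx <- generate_fixture(P = 2, M = 3, n = 400, seed = 1)
#' fit_reference(fx$data, seed = 1)
fit_reference <- function(data, cell_type = "cell_type", labels = NULL,
                          settings = fit_settings(), seed = NULL) {
  if (is.null(labels)) {
    if (!is.data.frame(data) || !cell_type %in% names(data)) {
      abort(sprintf("`data` must contain a `%s` column (or pass `labels`).", cell_type))
    }
    labels <- as.character(data[[cell_type]])
  } else {
    labels <- as.character(labels)
  }
  x <- channel_matrix(data)
  if (length(labels) != nrow(x)) {
    abort(sprintf("labels (%d) and expression rows (%d) differ.",
                  length(labels), nrow(x)))
  }
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warn(sprintf("excluding cell type(s) with < 2 cells: %s",
                 paste(small, collapse = ", ")))
  }
  keep <- sort(setdiff(names(counts), small))
  if (length(keep) == 0) abort("no cell type has >= 2 cells.")
  gmms <- lapply(keep, function(lab) {
    fit_cell_type_gmm(x[labels == lab, , drop = FALSE], settings,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, "fit", lab))
  })
  names(gmms) <- keep
  n_kept <- sum(counts[keep])
  reference_model(gmms, as.numeric(counts[keep]) / n_kept, channels = colnames(x))
}

#' Match simulated near-zero frequencies to reference targets
#'
#' A fitted mixture can under-produce (near-)zero values relative to the
#' reference data. Per channel, if the simulated near-zero fraction `q` falls
#' short of the target `q*`, cells above the threshold are zeroed out at
#' random with probabilities inversely proportional to their magnitude
#' (`p_i` proportional to `1/(|y_i| + 1e-6)`, capped at 1 and rescaled so the
#' expected number of new zeros is `(q* - q) * n`). Channels already at or
#' above target are untouched.
#'
#' @param x Cells-by-channels matrix for one cell type.
#' @param zero_target Length-`M` vector of target near-zero probabilities.
#' @param threshold Near-zero threshold (arcsinh units).
#' @param seed Optional seed.
#' @return The adjusted matrix (selected entries set to exactly 0).
#' @export
apply_zero_matching <- function(x, zero_target, threshold = 1e-6, seed = NULL) {
  x <- channel_matrix(x)
  stopifnot(length(zero_target) == ncol(x),
            all(zero_target >= 0 & zero_target <= 1))
  with_seed_(seed, {
    n <- nrow(x)
    for (m in seq_len(ncol(x))) {
      near <- abs(x[, m]) <= threshold
      deficit <- zero_target[m] - mean(near)
      if (deficit <= 0) next
      cand <- which(!near)
      w <- 1 / (abs(x[cand, m]) + 1e-6)
      target_hits <- min(deficit * n, length(cand))
      # scale, cap at 1, and rescale the uncapped mass so the expected number
      # of new zeros equals the deficit exactly
      p <- w * target_hits / sum(w)
      repeat {
        over <- p >= 1
        if (!any(over) || all(over)) break
        p[over] <- 1
        slack <- target_hits - sum(over)
        p[!over] <- w[!over] * slack / sum(w[!over])
        if (all(p <= 1 + 1e-12)) break
      }
      p <- pmin(p, 1)
      hit <- cand[stats::runif(length(cand)) < p]
      x[hit, m] <- 0
    }
    x
  })
}
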