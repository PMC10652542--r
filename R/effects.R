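#' Generate batch effects with sum-to-zero identifiability constraints
#'
#' Batch effects decompose ANOVA-style into a global per-batch shift
#' `psi_b ~ N(0, sigma_psi^2)` and local cell-type-by-channel interactions
#' `Psi[b, p, ] ~ N(psi_b, sigma^2 I)`. Identifiability is enforced by
#' projection: `psi` is centered across batches, and each batch's `P x M`
#' interaction slice is double-centered so that sums over cell types and over
#' channels both vanish. The effect applied to a cell of type `p` in batch
#' `b` is `psi_b + Psi[b, p, ]` per channel.
#'
#' @param n_batches,n_types,n_channels Dimensions (`B`, `P`, `M`).
#' @param sigma_psi Between-batch standard deviation of the global shifts.
#' @param sigma Within-batch standard deviation of the interactions.
#' @param seed Optional seed.
#' @return An object of class `cytosim_batch_effects` with elements `psi`
#'   (length `B`) and `Psi` (`B x P x M` array).
#' @export
#' @examples
#' be <- batch_effects(2, 3, 4, seed = 1)
#' rowSums(be$Psi[1, , ])  # ~0 for every cell type
batch_effects <- function(n_batches, n_types, n_channels,
                          sigma_psi = 0.1, sigma = 0.1, seed = NULL) {
  stopifnot(n_batches >= 1, n_types >= 1, n_channels >= 1,
            sigma_psi >= 0, sigma >= 0)
  with_seed_(seed, {
    B <- n_batches; P <- n_types; M <- n_channels
    psi <- stats::rnorm(B, 0, sigma_psi)
    psi <- psi - mean(psi)
    Psi <- array(0, c(B, P, M))
    for (b in seq_len(B)) {
      S <- matrix(stats::rnorm(P * M, psi[b], sigma), P, M)
      # double-centering is the minimum-norm projection onto both constraint
      # families; iterate to squeeze below 1e-12 in floating point
      repeat {
        S <- S - rowMeans(S)
        S <- sweep(S, 2, colMeans(S))
        if (max(abs(rowSums(S)), abs(colSums(S))) < 1e-12) break
      }
      Psi[b, , ] <- S
    }
    structure(list(psi = psi, Psi = Psi, sigma = sigma, sigma_psi = sigma_psi),
              class = "cytosim_batch_effects")
  })
}

#' @export
print.cytosim_batch_effects <- function(x, ...) {
  d <- dim(x$Psi)
  cat(sprintf("<cytosim_batch_effects: %d batch(es), %d type(s), %d channel(s)>\n",
              d[1], d[2], d[3]))
  cat("  psi:", paste(sprintf("%.3f", x$psi), collapse = ", "), "\n")
  invisible(x)
}

new_temporal <- function(fn, kind, params) {
  structure(list(fn = fn, kind = kind, params = params),
            class = "cytosim_temporal")
}

#' Evaluate a temporal-effect function
#'
#' @param tf A `cytosim_temporal` object.
#' @param t Times in `[0, 1]`.
#' @return Numeric vector of effects, one per time.
#' @export
temporal_eval <- function(tf, t) {
  stopifnot(inherits(tf, "cytosim_temporal"), all(t >= 0 & t <= 1))
  as.numeric(tf$fn(t))
}

#' @export
print.cytosim_temporal <- function(x, ...) {
  cat(sprintf("<cytosim_temporal: %s; f(0) = 0, f(1) = %.4f>\n",
              x$kind, temporal_eval(x, 1)))
  invisible(x)
}

#' Brownian-bridge temporal effect
#'
#' Signal drift over acquisition time, anchored at 0 at the start of the run.
#' The ending value is drawn from `N(0, end_sd^2)`; a discrete Brownian
#' bridge from 0 to that value is simulated on `n_knots + 2` equispaced times
#' and interpolated with an Akima spline.
#'
#' @param n_knots Interior knots of the bridge grid (default 6: smooth, slow
#'   drift).
#' @param end_sd Standard deviation of the drift at the end of the run.
#' @param seed Optional seed.
#' @return A `cytosim_temporal` object with `f(0) = 0`.
#' @export
#' @examples
#' tf <- temporal_brownian_bridge(seed = 3)
#' temporal_eval(tf, c(0, 0.5, 1))
temporal_brownian_bridge <- function(n_knots = 6, end_sd = 1, seed = NULL) {
  stopifnot(n_knots >= 3, end_sd >= 0)
  with_seed_(seed, {
    tk <- seq(0, 1, length.out = n_knots + 2)
    e <- stats::rnorm(1, 0, end_sd)
    dt <- diff(tk)
    B <- c(0, cumsum(stats::rnorm(length(dt), 0, sqrt(dt))))
    vals <- e * tk + B - tk * B[length(B)]
    vals[1] <- 0; vals[length(vals)] <- e
    fn <- function(t) pracma::akimaInterp(tk, vals, pmin(pmax(t, 0), 1))
    new_temporal(fn, "brownian_bridge",
                 list(knots = tk, values = vals, end = e))
  })
}

#' Polynomial temporal effect
#'
#' The user supplies the rough drift shape as polynomial coefficients
#' (ascending powers, intercept first); a linear transformation anchors the
#' curve at 0 at time 0 and at an `N(0, end_sd^2)` draw at time 1. A constant
#' polynomial falls back to a linear ramp with a warning.
#'
#' @param coefficients Numeric vector of polynomial coefficients.
#' @param end_sd Standard deviation of the ending value.
#' @param seed Optional seed.
#' @return A `cytosim_temporal` object.
#' @export
temporal_polynomial <- function(coefficients, end_sd = 1, seed = NULL) {
  stopifnot(length(coefficients) >= 1, end_sd >= 0)
  with_seed_(seed, {
    e <- stats::rnorm(1, 0, end_sd)
    q <- function(t) drop(outer(t, seq_along(coefficients) - 1, "^") %*% coefficients)
    span <- q(1) - q(0)
    if (span == 0) {
      warn("constant polynomial shape; falling back to the linear ramp e * t.")
      fn <- function(t) e * t
      return(new_temporal(fn, "polynomial", list(coefficients = coefficients,
                                                 end = e, fallback = TRUE)))
    }
    a <- e / span; c0 <- -a * q(0)
    fn <- function(t) a * q(t) + c0
    new_temporal(fn, "polynomial",
                 list(coefficients = coefficients, end = e, fallback = FALSE))
  })
}

#' Smoothing-spline temporal effect from observed residuals
#'
#' Replays a temporal effect extracted from a user's own preprocessing (e.g.,
#' spline residuals of bead signals): times are rescaled to `[0, 1]`, the
#' residuals are anchored so the effect starts at 0, and a smoothing spline
#' provides the evaluable function.
#'
#' @param times Acquisition times (any scale; strictly increasing).
#' @param residuals Observed drift values, one per time.
#' @param df Optional equivalent degrees of freedom passed to
#'   [stats::smooth.spline()].
#' @return A `cytosim_temporal` object.
#' @export
temporal_spline <- function(times, residuals, df = NULL) {
  if (length(times) < 4 || length(residuals) != length(times)) {
    abort("need at least 4 (time, residual) pairs of equal length.")
  }
  o <- order(times)
  times <- times[o]; residuals <- residuals[o]
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  ts <- (times - times[1]) / (times[length(times)] - times[1])
  rs <- residuals - residuals[1]
  fit <- if (is.null(df)) {
    tryCatch(stats::smooth.spline(ts, rs),
             error = function(e) stats::smooth.spline(ts, rs, df = length(ts) / 2))
  } else {
    stats::smooth.spline(ts, rs, df = df)
  }
  f0 <- stats::predict(fit, 0)$y
  fn <- function(t) stats::predict(fit, pmin(pmax(t, 0), 1))$y - f0
  new_temporal(fn, "spline", list(fit = fit))
}
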