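#' L2 distance between simulated and observed mean expressions
#'
#' @param sim,real Cells-by-channels matrices or data frames (annotation
#'   columns dropped) for one cell type.
#' @return Euclidean norm of the difference of column means.
#' @export
#' @examples
#' l2_mean_distance(matrix(c(1, 1, 2, 2), 2), matrix(c(1, 1, 4, 4), 2))  # 2
l2_mean_distance <- function(sim, real) {
  sim <- channel_matrix(sim); real <- channel_matrix(real)
  if (ncol(sim) != ncol(real)) abort("channel counts differ.")
  if (nrow(sim) == 0 || nrow(real) == 0) abort("empty expression matrix.")
  sqrt(sum((colMeans(sim) - colMeans(real))^2))
}

#' Frobenius distance between simulated and observed covariances
#'
#' @inheritParams l2_mean_distance
#' @return Frobenius norm of the difference of sample covariance matrices.
#' @export
frobenius_cov_distance <- function(sim, real) {
  sim <- channel_matrix(sim); real <- channel_matrix(real)
  if (ncol(sim) != ncol(real)) abort("channel counts differ.")
  if (nrow(sim) < 2 || nrow(real) < 2) abort("need at least 2 rows per matrix.")
  sqrt(sum((stats::cov(sim) - stats::cov(real))^2))
}

#' k-nearest-neighbour estimate of the Kullback-Leibler divergence
#'
#' Nonparametric estimate of `KL(P || Q)` from two samples, based on the
#' ratio of k-th nearest-neighbour distances:
#' \deqn{\hat D = \frac{M}{n} \sum_i \log \frac{s_k(x_i)}{r_k(x_i)} +
#'   \log \frac{m}{n - 1}}
#' where `r_k(x_i)` is the distance from `x_i` to its k-th neighbour within
#' the `P`-sample (self excluded) and `s_k(x_i)` to its k-th neighbour in the
#' `Q`-sample. Coincident points are separated by a `1e-12` jitter on the
#' distance. Estimates can be slightly negative at small `n`; they are
#' reported as-is.
#'
#' @param p_sample,q_sample Samples from `P` and `Q` (matrices or data
#'   frames, same channel count).
#' @param k Neighbour order (default 1, the canonical choice).
#' @return Scalar divergence estimate (nats).
#' @export
kl_divergence_knn <- function(p_sample, q_sample, k = 1) {
  X <- channel_matrix(p_sample); Y <- channel_matrix(q_sample)
  if (ncol(X) != ncol(Y)) abort("dimension mismatch between the two samples.")
  n <- nrow(X); m <- nrow(Y)
  stopifnot(n >= k + 1, m >= k)
  r <- RANN::nn2(X, X, k = k + 1)$nn.dists[, k + 1]
  s <- RANN::nn2(Y, X, k = k)$nn.dists[, k]
  r <- pmax(r, 1e-12); s <- pmax(s, 1e-12)
  ncol(X) / n * sum(log(s / r)) + log(m / (n - 1))
}

# Ridge-penalized logistic regression via Newton iterations (intercept
# unpenalized). Tiny ridge keeps the fit defined under perfect separation.
logistic_ridge <- function(X, y, lambda = 1e-6, max_iter = 100, tol = 1e-8) {
  Xd <- cbind(1, scale(X))
  Xd[is.nan(Xd)] <- 0  # constant columns scale to NaN; drop their effect
  D <- diag(c(0, rep(lambda, ncol(Xd) - 1)))
  beta <- numeric(ncol(Xd))
  beta[1] <- stats::qlogis(mean(y))
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xd, Xd * W) + D
    g <- crossprod(Xd, y - p) - D %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::plogis(drop(Xd %*% beta))
}

#' Propensity mean squared error between simulated and real data
#'
#' Stacks the real rows (indicator 0) and simulated rows (indicator 1), fits
#' a logistic propensity model of the indicator on the channels, and reports
#' the mean squared deviation of the fitted propensities from the simulated
#' fraction `c = n_sim / N`. Values near 0 mean the classifier cannot tell
#' simulated from real; the separable limit is `c (1 - c)`. A ridge penalty
#' of `1e-6` is always applied for numerical stability.
#'
#' The default `"quadratic"` propensity model uses main effects, squares,
#' and pairwise interactions of the channels, so mismatches in covariance
#' structure are visible to the classifier even when per-channel means
#' agree; `"main"` restricts to main effects.
#'
#' @inheritParams l2_mean_distance
#' @param terms Propensity model terms: `"quadratic"` or `"main"`.
#' @return Nonnegative scalar.
#' @export
pmse <- function(sim, real, terms = c("quadratic", "main")) {
  terms <- match.arg(terms)
  S <- channel_matrix(sim); R <- channel_matrix(real)
  if (ncol(S) != ncol(R)) abort("channel counts differ.")
  if (nrow(S) == 0 || nrow(R) == 0) abort("empty expression matrix.")
  X <- rbind(R, S)
  if (terms == "quadratic") X <- quadratic_expand(X)
  y <- rep(c(0, 1), c(nrow(R), nrow(S)))
  cc <- mean(y)
  p <- logistic_ridge(X, y)
  mean((p - cc)^2)
}

# Main effects + squares + pairwise products of the columns.
quadratic_expand <- function(X) {
  M <- ncol(X)
  sq <- X^2
  if (M == 1) return(cbind(X, sq))
  pairs <- utils::combn(M, 2)
  inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  cbind(X, sq, inter)
}

#' Number of predictors of the pMSE propensity model
#'
#' Useful for the analytic null expectation `k c (1 - c) / N` of [pmse()]
#' under identical distributions.
#'
#' @param n_channels Number of channels.
#' @param terms Propensity model terms, as in [pmse()].
#' @return Integer predictor count (excluding the intercept).
#' @export
pmse_n_predictors <- function(n_channels, terms = c("quadratic", "main")) {
  terms <- match.arg(terms)
  if (terms == "main") return(as.integer(n_channels))
  as.integer(2 * n_channels + choose(n_channels, 2))
}

#' Relative efficiency of the reference simulator's pMSE
#'
#' The ratio `pmse_reference / pmse_other`. Values above 1 favor the other
#' method; the reference compared with itself gives exactly 1.
#'
#' @param pmse_reference pMSE of the reference method.
#' @param pmse_other pMSE of the competitor (must be positive).
#' @return Scalar ratio.
#' @export
relative_efficiency <- function(pmse_reference, pmse_other) {
  if (pmse_other <= 0) abort("`pmse_other` must be positive.")
  pmse_reference / pmse_other
}

#' Score a simulated dataset against a reference, per cell type
#'
#' Computes the four fidelity metrics per cell type — mean L2 distance,
#' covariance Frobenius distance, kNN KL divergence, and pMSE — and
#' aggregates each as a weighted average with weights given by the reference
#' cell abundances.
#'
#' @param sim,real Data frames with channel columns and a shared cell-type
#'   label column (e.g. [simulate_cells()] output and the reference table).
#' @param cell_type Label column name.
#' @param k Neighbour order for the KL estimator.
#' @return An object of class `cytosim_eval`: list with `by_type` (tibble:
#'   `cell_type`, `weight`, `n_sim`, `n_real`, `mean_l2`, `cov_frobenius`,
#'   `kl_divergence`, `pmse`) and `aggregate` (named numeric).
#' @export
#' @examples
#' fx <- generate_fixture(P = 2, M = 4, n = 300, seed = 1)
#' sim <- simulate_cells(fit_reference(fx$data, seed = 1), 300, seed = 2)
#' evaluate_simulation(sim, fx$data)
evaluate_simulation <- function(sim, real, cell_type = "cell_type", k = 1) {
  stopifnot(is.data.frame(sim), is.data.frame(real),
            cell_type %in% names(sim), cell_type %in% names(real))
  sim_lab <- as.character(sim[[cell_type]])
  real_lab <- as.character(real[[cell_type]])
  types <- sort(unique(real_lab))
  miss <- symdiff_report(sort(unique(sim_lab)), types)
  if (!is.null(miss)) {
    abort(paste0("cell-type sets differ between sim and real: ",
                 sub("trajectory", "sim", miss)))
  }
  Xs <- channel_matrix(sim); Xr <- channel_matrix(real)
  w <- as.numeric(table(real_lab)[types]) / length(real_lab)
  rows <- purrr::map2_dfr(types, w, function(tp, wt) {
    s <- Xs[sim_lab == tp, , drop = FALSE]
    r <- Xr[real_lab == tp, , drop = FALSE]
    tibble(
      cell_type = tp, weight = wt, n_sim = nrow(s), n_real = nrow(r),
      mean_l2 = l2_mean_distance(s, r),
      cov_frobenius = frobenius_cov_distance(s, r),
      kl_divergence = kl_divergence_knn(s, r, k = k),
      pmse = pmse(s, r))
  })
  metrics <- c("mean_l2", "cov_frobenius", "kl_divergence", "pmse")
  agg <- vapply(metrics, function(mm) sum(rows$weight * rows[[mm]]), 0)
  structure(list(by_type = rows, aggregate = agg), class = "cytosim_eval")
}

#' Aggregate per-type metric values with abundance weights
#'
#' @param values Numeric vector of per-type metric values.
#' @param weights Abundance weights (sum to 1), matched by position or name.
#' @return Weighted mean.
#' @export
aggregate_metric <- function(values, weights) {
  check_probability_vector(weights, "weights")
  if (length(values) != length(weights)) {
    abort("`values` and `weights` must have equal length.")
  }
  if (!is.null(names(values)) && !is.null(names(weights))) {
    miss <- symdiff_report(names(values), names(weights))
    if (!is.null(miss)) abort(paste0("type sets differ: ", miss))
    weights <- weights[names(values)]
  }
  sum(values * weights)
}

#' @export
print.cytosim_eval <- function(x, ...) {
  cat("<cytosim_eval>\n  aggregate (abundance-weighted):\n")
  for (nm in names(x$aggregate)) {
    cat(sprintf("    %-14s %.6g\n", nm, x$aggregate[[nm]]))
  }
  cat(sprintf("  per-type values over %d cell type(s) in $by_type\n",
              nrow(x$by_type)))
  invisible(x)
}

#' Write a metric report as JSON and tidy CSV
#'
#' @param x A [evaluate_simulation()] result.
#' @param path Output path without extension; `<path>.json` and `<path>.csv`
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
write_metric_report <- function(x, path) {
  stopifnot(inherits(x, "cytosim_eval"))
  json <- paste0(path, ".json"); csv <- paste0(path, ".csv")
  jsonlite::write_json(
    list(aggregate = as.list(x$aggregate), by_type = x$by_type),
    json, auto_unbox = TRUE, digits = NA)
  long <- tidyr::pivot_longer(
    x$by_type, c("mean_l2", "cov_frobenius", "kl_divergence", "pmse"),
    names_to = "metric", values_to = "value")
  readr::write_csv(long[, c("cell_type", "metric", "value", "weight")], csv)
  invisible(c(json, csv))
}
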