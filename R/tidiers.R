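#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reference model into one row per component and channel
#'
#' @param x A [reference_model()].
#' @param ... Unused.
#' @return Tibble with `cell_type`, `abundance`, `component`, `weight`,
#'   `channel`, `mean`, `sd` (component-wise channel standard deviation).
#' @export
tidy.cytosim_model <- function(x, ...) {
  ab <- if (is.matrix(x$abundances)) colMeans(x$abundances) else x$abundances
  purrr::map_dfr(x$cell_types, function(tp) {
    g <- x$gmms[[tp]]
    purrr::map_dfr(seq_along(g$weights), function(k) {
      tibble(cell_type = tp, abundance = unname(ab[tp]), component = k,
             weight = g$weights[k], channel = x$channels,
             mean = g$means[k, ], sd = sqrt(diag(g$covariances[[k]])))
    })
  })
}

#' One-row summary of a reference model
#'
#' @inheritParams tidy.cytosim_model
#' @return Tibble with counts of types/channels/batches and the component
#'   range.
#' @export
glance.cytosim_model <- function(x, ...) {
  k <- vapply(x$gmms, function(g) length(g$weights), 0L)
  tibble(
    n_cell_types = length(x$cell_types),
    n_channels = length(x$channels),
    n_batches = if (is.matrix(x$abundances)) nrow(x$abundances) else 1L,
    min_components = min(k), max_components = max(k),
    zero_matching = !is.null(x$gmms[[1]]$zero_target))
}

#' Tidy an evaluation report into long metric form
#'
#' @param x A [evaluate_simulation()] result.
#' @param ... Unused.
#' @return Tibble with `cell_type`, `weight`, `metric`, `value`.
#' @export
tidy.cytosim_eval <- function(x, ...) {
  tidyr::pivot_longer(x$by_type,
                      c("mean_l2", "cov_frobenius", "kl_divergence", "pmse"),
                      names_to = "metric", values_to = "value")[
    , c("cell_type", "weight", "metric", "value")]
}

#' One-row summary of an evaluation report (aggregated metrics)
#'
#' @inheritParams tidy.cytosim_eval
#' @return One-row tibble with the four abundance-weighted aggregates.
#' @export
glance.cytosim_eval <- function(x, ...) {
  as_tibble(as.list(x$aggregate))
}

#' Tidy a trajectory into its edge list
#'
#' @param x A [build_trajectory()] result.
#' @param ... Unused.
#' @return Tibble with `parent`, `child`, and the number of changing
#'   channels per edge.
#' @export
tidy.cytosim_trajectory <- function(x, ...) {
  dplyr::mutate(x$edges,
                n_changing = vapply(x$changing, length, 0L))
}
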