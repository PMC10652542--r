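#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a simulated dataset in principal-component space
#'
#' Standard first look at a CyTOF simulation: cells projected on the first
#' two principal components, colored by cell type.
#'
#' @param object A [simulate_cells()] tibble.
#' @param color One of `"cell_type"`, `"batch"`, `"pseudotime"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cytosim_sim <- function(object, color = "cell_type", ...) {
  X <- channel_matrix(object)
  pc <- stats::prcomp(X, rank. = 2)
  df <- tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  df[[color]] <- if (color == "batch") factor(object[[color]]) else object[[color]]
  ggplot(df, aes(.data$PC1, .data$PC2, color = .data[[color]])) +
    geom_point(size = 0.4, alpha = 0.6) +
    labs(title = "Simulated cells (PCA)") +
    theme_minimal()
}

#' Plot per-type fidelity metrics
#'
#' @param object A [evaluate_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @export
autoplot.cytosim_eval <- function(object, ...) {
  ggplot(tidy(object), aes(.data$cell_type, .data$value)) +
    geom_col() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Simulation fidelity by cell type") +
    theme_minimal()
}

#' Plot a temporal-effect function
#'
#' @param object A `cytosim_temporal` object.
#' @param n Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cytosim_temporal <- function(object, n = 201, ...) {
  t <- seq(0, 1, length.out = n)
  ggplot(tibble(t = t, effect = temporal_eval(object, t)),
         aes(.data$t, .data$effect)) +
    geom_line() +
    labs(x = "relative acquisition time", y = "signal drift",
         title = sprintf("Temporal effect (%s)", object$kind)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
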