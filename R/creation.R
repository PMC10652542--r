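#' Settings for creation mode
#'
#' Creation mode builds a [reference_model()] from user settings alone, with
#' no reference dataset. Each cell type gets a random on/off expression
#' pattern over the channels: "on" channels draw their mean from a
#' zero-truncated normal around `on_level_mean` (arcsinh units), "off"
#' channels sit near zero, which — together with truncation at 0 during
#' simulation — reproduces the zero-inflated, bell-shaped marker structure of
#' real CyTOF data.
#'
#' @param n_cell_types,n_channels,n_batches Problem dimensions (`P`, `M`, `B`).
#' @param n_cells Cells per batch (scalar or length-`B` vector).
#' @param n_components Mixture components per cell type (scalar or per-type
#'   vector). Default 1: intra-type multimodality is opt-in.
#' @param abundance_mode `"fixed"` (uniform `1/P`) or `"dirichlet"`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for
#'   `abundance_mode = "dirichlet"`; the small default 0.1 yields the skewed
#'   abundances typical of immune panels.
#' @param expressed_fraction Probability a channel is "on" for a given type.
#' @param on_level_mean,on_level_sd Location/scale of expressed-channel means
#'   (arcsinh units; expressed CyTOF markers typically sit around 2-5).
#' @param off_level_sd Scale of near-zero means for unexpressed channels.
#' @param covariance_scale Typical per-channel standard deviation implied by
#'   the random covariances.
#' @param component_spread Standard deviation of the jitter applied to
#'   component means around the type mean (controls mode separation when
#'   `n_components > 1`).
#' @param noise_sd Machine-noise standard deviation used by [simulate_cells()]
#'   defaults in creation mode.
#' @return An object of class `cytosim_creation_config`.
#' @export
creation_config <- function(n_cell_types = 5, n_channels = 30, n_batches = 1,
                            n_cells = 10000, n_components = 1,
                            abundance_mode = c("fixed", "dirichlet"),
                            dirichlet_alpha = 0.1,
                            expressed_fraction = 0.4,
                            on_level_mean = 3, on_level_sd = 1,
                            off_level_sd = 0.2,
                            covariance_scale = 0.3,
                            component_spread = 1,
                            noise_sd = 0.1) {
  abundance_mode <- match.arg(abundance_mode)
  stopifnot(n_cell_types >= 1, n_channels >= 1, n_batches >= 1,
            all(n_cells >= 1), all(n_components >= 1),
            expressed_fraction >= 0, expressed_fraction <= 1,
            on_level_sd >= 0, off_level_sd >= 0, covariance_scale >= 0,
            component_spread >= 0, noise_sd >= 0, dirichlet_alpha > 0)
  structure(
    list(n_cell_types = as.integer(n_cell_types),
         n_channels = as.integer(n_channels),
         n_batches = as.integer(n_batches),
         n_cells = as.integer(rep_len(n_cells, n_batches)),
         n_components = as.integer(rep_len(n_components, n_cell_types)),
         abundance_mode = abundance_mode, dirichlet_alpha = dirichlet_alpha,
         expressed_fraction = expressed_fraction,
         on_level_mean = on_level_mean, on_level_sd = on_level_sd,
         off_level_sd = off_level_sd, covariance_scale = covariance_scale,
         component_spread = component_spread, noise_sd = noise_sd),
    class = "cytosim_creation_config"
  )
}

# Zero-truncated normal draws via inverse-CDF (lower bound 0).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmax(mean, 0), length.out = n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Generate cell-type abundances
#'
#' @param P Number of cell types.
#' @param mode `"fixed"` (uniform) or `"dirichlet"` (one symmetric Dirichlet
#'   draw, concentration `alpha`).
#' @param alpha Positive Dirichlet concentration.
#' @param seed Optional seed.
#' @return Probability vector of length `P`.
#' @export
#' @examples
#' generate_abundances(4)
#' generate_abundances(14, "dirichlet", alpha = 0.1, seed = 1)
generate_abundances <- function(P, mode = c("fixed", "dirichlet"), alpha = 0.1,
                                seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(P >= 1)
  if (mode == "fixed") return(rep(1 / P, P))
  if (alpha <= 0) abort("`alpha` must be positive for dirichlet abundances.")
  with_seed_(seed, {
    g <- stats::rgamma(P, shape = alpha, rate = 1)
    # guard against all-zero underflow at tiny alpha
    if (sum(g) == 0) g[sample.int(P, 1)] <- 1
    g / sum(g)
  })
}

#' Generate a reference model from creation-mode settings
#'
#' For each cell type, channels are switched on with probability
#' `expressed_fraction` (patterns resampled until pairwise distinct whenever
#' `2^M > P`); type means combine truncated-normal "on" levels with near-zero
#' "off" levels; component means are jittered around the type mean; random
#' PSD covariances are built as `s^2 * (A A' / M + 0.1 I)` with standard
#' normal `A`; component weights come from a symmetric Dirichlet(2).
#'
#' @param config A [creation_config()].
#' @param seed Optional seed.
#' @return A [reference_model()].
#' @export
generate_cell_type_params <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cytosim_creation_config"))
  P <- config$n_cell_types; M <- config$n_channels
  if (P > 1 && 2^min(M, 30) < P) {
    abort(sprintf(
      "cannot draw %d distinct on/off patterns from %d channel(s); increase n_channels.",
      P, M))
  }
  with_seed_(seed, {
    channels <- sprintf("ch%02d", seq_len(M))
    # distinct on/off patterns per type (uniqueness feasible since 2^M > P)
    patterns <- matrix(FALSE, P, M)
    for (try in seq_len(1000)) {
      patterns <- matrix(stats::runif(P * M) < config$expressed_fraction, P, M)
      if (P == 1 || !anyDuplicated(apply(patterns, 1, paste, collapse = ""))) break
      # with expressed_fraction 0 or 1 patterns are forced equal; type means
      # still differ through their random expression levels
      if (config$expressed_fraction %in% c(0, 1)) break
    }
    gmms <- vector("list", P)
    for (p in seq_len(P)) {
      mu <- numeric(M)
      on <- patterns[p, ]
      mu[on] <- rtruncnorm0(sum(on), config$on_level_mean, config$on_level_sd)
      mu[!on] <- abs(stats::rnorm(sum(!on), 0, config$off_level_sd))
      K <- config$n_components[p]
      means <- matrix(mu, K, M, byrow = TRUE)
      if (K > 1) {
        means <- means + matrix(stats::rnorm(K * M, 0, config$component_spread), K, M)
        means[, !on] <- abs(means[, !on])  # off channels stay near zero
      }
      covs <- lapply(seq_len(K), function(k) {
        A <- matrix(stats::rnorm(M * M), M, M)
        config$covariance_scale^2 * (tcrossprod(A) / M + diag(0.1, M))
      })
      w <- if (K == 1) 1 else {
        g <- stats::rgamma(K, shape = 2); g / sum(g)
      }
      gmms[[p]] <- cell_type_gmm(w, means, covs, channels = channels)
    }
    names(gmms) <- sprintf("type%02d", seq_len(P))
    ab <- generate_abundances(P, config$abundance_mode, config$dirichlet_alpha)
    reference_model(gmms, ab, channels = channels)
  })
}

#' One-call creation-mode model
#'
#' Thin wrapper assembling a [creation_config()] and calling
#' [generate_cell_type_params()].
#'
#' @param n_types,n_channels Dimensions.
#' @param n_components Components per type.
#' @param ... Passed to [creation_config()].
#' @param seed Optional seed.
#' @return A [reference_model()].
#' @export
#' @examples
#' m <- create_model(3, 10, seed = 7)
#' m
create_model <- function(n_types = 5, n_channels = 30, n_components = 1, ...,
                         seed = NULL) {
  cfg <- creation_config(n_cell_types = n_types, n_channels = n_channels,
                         n_components = n_components, ...)
  generate_cell_type_params(cfg, seed = seed)
}
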