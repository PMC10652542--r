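#' Simulate a CyTOF dataset from a reference model
#'
#' The final generative model, assembled in two steps per cell `n` of type
#' `p` in batch `b`:
#' \deqn{Z = X + g^{p \to c}(T) + \psi^b + \Psi^{b,p} + \Phi^b(n / N^b)}
#' \deqn{Y = \max(Z, 0) + E}
#' where `X` is a latent draw from the type's Gaussian mixture, `g` the
#' differentiation path evaluated at the cell's Beta pseudotime (0 without a
#' trajectory), `psi/Psi` the batch effect for `(b, p)` (0 without batch
#' effects), `Phi` the batch's temporal drift at the cell's relative
#' acquisition time (0 without temporal effects), and `E` zero-mean machine
#' noise. Cells are ordered by batch and then by acquisition index, so
#' temporal drift is monotone in row order. When a mixture carries
#' zero-matching targets (emulation mode), [apply_zero_matching()] runs on
#' the latent draws before any effect is added.
#'
#' @param model A [reference_model()].
#' @param n_cells Cells per batch: scalar, or length-`B` vector.
#' @param batch_effects Optional [batch_effects()] (defines `B` when given).
#' @param temporal Optional temporal effect: one `cytosim_temporal`, or a
#'   list with one per batch.
#' @param trajectory Optional [build_trajectory()] result.
#' @param noise A [noise_model()] or bare sd (default 0: emulated reference
#'   data already carries machine noise).
#' @param seed Optional root seed; child streams are derived per
#'   (component, batch) so enabling one effect never perturbs another.
#' @return A tibble of class `cytosim_sim`: one row per cell with the channel
#'   columns plus `cell_type` and `batch`, and `child_type`/`pseudotime` when
#'   a trajectory is present.
#' @export
#' @examples
#' m <- create_model(3, 8, seed = 5)
#' sim <- simulate_cells(m, 200, seed = 5)
#' dplyr::count(sim, cell_type)
simulate_cells <- function(model, n_cells, batch_effects = NULL,
                           temporal = NULL, trajectory = NULL,
                           noise = noise_model(0), seed = NULL) {
  stopifnot(inherits(model, "cytosim_model"))
  if (is.numeric(noise)) noise <- noise_model(noise)
  P <- length(model$cell_types)
  M <- length(model$channels)
  B <- if (!is.null(batch_effects)) length(batch_effects$psi)
       else if (is.matrix(model$abundances)) nrow(model$abundances)
       else max(1L, length(n_cells))
  n_cells <- as.integer(rep_len(n_cells, B))
  stopifnot(all(n_cells >= 1))
  if (!is.null(batch_effects)) {
    d <- dim(batch_effects$Psi)
    if (d[2] != P || d[3] != M) {
      abort(sprintf("batch effects sized for %d type(s) x %d channel(s); model has %d x %d.",
                    d[2], d[3], P, M))
    }
  }
  if (!is.null(temporal)) {
    if (inherits(temporal, "cytosim_temporal")) temporal <- list(temporal)
    temporal <- rep_len(temporal, B)
    for (tf in temporal) stopifnot(inherits(tf, "cytosim_temporal"))
  }
  if (!is.null(trajectory)) {
    extra <- symdiff_report(trajectory$cell_types, model$cell_types)
    if (!is.null(extra)) {
      abort(paste0("trajectory and model cell types differ: ", extra))
    }
  }

  batches <- vector("list", B)
  for (b in seq_len(B)) {
    nb <- n_cells[b]
    ab <- if (is.matrix(model$abundances)) model$abundances[b, ] else model$abundances
    lab_idx <- sample_cell_labels(
      ab, nb, seed = if (is.null(seed)) NULL else derive_seed(seed, "labels", b))
    type <- model$cell_types[lab_idx]
    X <- matrix(0, nb, M)
    child <- type
    pst <- rep(NA_real_, nb)
    for (p in seq_len(P)) {
      idx <- which(lab_idx == p)
      if (length(idx) == 0) next
      g <- model$gmms[[p]]
      Xp <- sample_latent_expressions(
        g, length(idx),
        seed = if (is.null(seed)) NULL else derive_seed(seed, "latent", b, p))
      if (!is.null(g$zero_target)) {
        Xp <- apply_zero_matching(
          Xp, g$zero_target,
          seed = if (is.null(seed)) NULL else derive_seed(seed, "zero", b, p))
      }
      if (!is.null(trajectory)) {
        dd <- sample_differentiation(
          trajectory, model$cell_types[p], b, length(idx),
          seed = if (is.null(seed)) NULL else derive_seed(seed, "traj", b, p))
        Xp <- Xp + dd$shift
        child[idx] <- dd$child
        pst[idx] <- dd$pseudotime
      }
      if (!is.null(batch_effects)) {
        eff <- batch_effects$psi[b] + batch_effects$Psi[b, p, ]
        Xp <- sweep(Xp, 2, eff, "+")
      }
      X[idx, ] <- Xp
    }
    if (!is.null(temporal)) {
      drift <- temporal_eval(temporal[[b]], seq_len(nb) / nb)
      X <- X + drift  # column-major recycling adds drift[i] to every channel of row i
    }
    batches[[b]] <- list(X = X, type = type, child = child, pst = pst)
  }

  Y <- do.call(rbind, lapply(batches, `[[`, "X"))
  Y <- truncate_below_zero(Y)
  Y <- add_machine_noise(Y, noise,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, "noise"))
  colnames(Y) <- model$channels
  out <- as_tibble(Y)
  out$cell_type <- unlist(lapply(batches, `[[`, "type"))
  out$batch <- rep(seq_len(B), n_cells)
  if (!is.null(trajectory)) {
    out$child_type <- unlist(lapply(batches, `[[`, "child"))
    out$pseudotime <- unlist(lapply(batches, `[[`, "pst"))
  }
  class(out) <- c("cytosim_sim", class(out))
  attr(out, "channels") <- model$channels
  out
}

# Human-readable symmetric set difference, NULL when sets agree.
symdiff_report <- function(a, b) {
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  if (length(only_a) == 0 && length(only_b) == 0) return(NULL)
  paste0(
    if (length(only_a)) paste0("only in trajectory: ", paste(only_a, collapse = ", ")),
    if (length(only_a) && length(only_b)) "; ",
    if (length(only_b)) paste0("only in model: ", paste(only_b, collapse = ", ")))
}
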