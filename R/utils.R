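#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Column names reserved for per-cell annotations in simulation tibbles;
# everything else in a result is a protein channel.
RESERVED_COLS <- c("cell_type", "batch", "child_type", "pseudotime", "cell_id")

#' Derive a deterministic child seed from a root seed and a stream tag
#'
#' Every stochastic component of a simulation draws from its own stream,
#' identified by a tag such as `("latent", batch)`. Child seeds are computed
#' with a small polynomial string hash so that enabling one effect never
#' perturbs the draws of another. All seeds stay below 2^31.
#'
#' @param seed Integer root seed.
#' @param ... Tag components (coerced to character) identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "latent", 1)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 69069 + code) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under `seed` when non-NULL, restoring the caller's RNG state;
# with seed = NULL the global stream is consumed as-is.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Probability-vector check used by samplers and constructors.
check_probability_vector <- function(p, what = "abundances", tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1 || anyNA(p)) {
    abort(sprintf("`%s` must be a numeric probability vector without NAs.", what))
  }
  bad <- which(p < 0)
  if (length(bad) > 0) {
    abort(sprintf("`%s` has negative entries at index %s.", what,
                  paste(bad, collapse = ", ")))
  }
  if (sum(p) == 0) {
    abort(sprintf("`%s` sums to zero and cannot be normalized.", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(p)))
  }
  invisible(p)
}

# Extract the channel matrix from a data frame or matrix. Data frames drop
# the reserved annotation columns; matrices are passed through.
channel_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  if (!is.data.frame(data)) {
    abort("Expected a data frame or numeric matrix of expressions.")
  }
  keep <- setdiff(names(data), RESERVED_COLS)
  keep <- keep[vapply(data[keep], is.numeric, TRUE)]
  if (length(keep) == 0) abort("No numeric channel columns found.")
  as.matrix(data[keep])
}
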