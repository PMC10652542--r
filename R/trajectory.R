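#' @importFrom igraph graph_from_adjacency_matrix mst components dfs E V
#'   cluster_fast_greedy membership ends vcount ecount as_edgelist
#'   graph_from_data_frame is_forest
NULL

# Complete weighted graph on `labels` from a symmetric weight matrix.
complete_graph <- function(W, labels) {
  dimnames(W) <- list(labels, labels)
  graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                              diag = FALSE)
}

#' Sketch the differentiation forest in creation mode
#'
#' Cell types are randomly partitioned into `n_trees` nonempty groups; within
#' each group a complete graph with i.i.d. Uniform(0,1) weights is reduced to
#' its minimum spanning tree.
#'
#' @param cell_types Character vector of type labels.
#' @param n_trees Number of trees in the polyforest.
#' @param seed Optional seed.
#' @return An undirected `igraph` forest on `cell_types`.
#' @export
build_graph_creation <- function(cell_types, n_trees = 1, seed = NULL) {
  P <- length(cell_types)
  if (n_trees < 1 || n_trees > P) {
    abort(sprintf("`n_trees` must be in 1..%d (got %d).", P, n_trees))
  }
  with_seed_(seed, {
    # one type per group first, remainder assigned uniformly: groups nonempty
    grp <- integer(P)
    grp[sample.int(P, n_trees)] <- seq_len(n_trees)
    grp[grp == 0] <- sample.int(n_trees, sum(grp == 0), replace = TRUE)
    sub <- lapply(seq_len(n_trees), function(g) {
      members <- cell_types[grp == g]
      k <- length(members)
      if (k == 1) {
        return(graph_from_data_frame(data.frame(from = character(), to = character()),
                                     directed = FALSE,
                                     vertices = data.frame(name = members)))
      }
      W <- matrix(0, k, k)
      W[upper.tri(W)] <- stats::runif(k * (k - 1) / 2)
      mst(complete_graph(W + t(W), members))
    })
    Reduce(igraph::disjoint_union, sub)
  })
}

#' Sketch the differentiation forest in emulation mode
#'
#' The complete graph over cell types is weighted by pairwise L2 distances of
#' the observed average expressions; Clauset-Newman-Moore greedy modularity
#' maximization partitions the types into communities and a minimum spanning
#' tree is kept within each community.
#'
#' @param type_means `P x M` matrix of per-type mean expressions (rownames =
#'   cell types), e.g. from a fitted [reference_model()].
#' @param seed Optional seed (tie-breaking only; the construction is
#'   deterministic for distinct distances).
#' @return An undirected `igraph` forest.
#' @export
build_graph_emulation <- function(type_means, seed = NULL) {
  stopifnot(is.matrix(type_means), nrow(type_means) >= 1)
  labels <- rownames(type_means) %||% sprintf("type%02d", seq_len(nrow(type_means)))
  P <- nrow(type_means)
  if (P == 1) {
    return(graph_from_data_frame(data.frame(from = character(), to = character()),
                                 directed = FALSE,
                                 vertices = data.frame(name = labels)))
  }
  D <- as.matrix(stats::dist(type_means))
  g <- complete_graph(D, labels)
  # two types always form one edge; modularity on K2 degenerates to singletons
  comm <- if (P == 2) stats::setNames(c(1, 1), labels) else {
    membership(cluster_fast_greedy(g, weights = E(g)$weight))
  }
  sub <- lapply(sort(unique(comm)), function(cm) {
    members <- labels[comm == cm]
    if (length(members) == 1) {
      return(graph_from_data_frame(data.frame(from = character(), to = character()),
                                   directed = FALSE,
                                   vertices = data.frame(name = members)))
    }
    mst(complete_graph(D[members, members, drop = FALSE], members))
  })
  Reduce(igraph::disjoint_union, sub)
}

#' Root a forest into a polyforest by depth-first search
#'
#' Per connected component, a root is chosen at random and a DFS orients
#' every edge from parent to child, so that each non-root node has exactly
#' one parent.
#'
#' @param forest Undirected `igraph` forest.
#' @param seed Optional seed (root selection).
#' @return Tibble of directed edges with columns `parent`, `child`.
#' @export
root_forest <- function(forest, seed = NULL) {
  if (!is_forest(forest, mode = "all")) {
    abort("input graph has a cycle; expected a forest.")
  }
  with_seed_(seed, {
    comp <- components(forest)
    edges <- list()
    for (cm in seq_len(comp$no)) {
      nodes <- which(comp$membership == cm)
      root <- nodes[sample.int(length(nodes), 1)]
      d <- dfs(forest, root = root, mode = "all", unreachable = FALSE,
               father = TRUE)
      father <- as.integer(d$father)
      for (v in nodes) {
        if (!is.na(father[v]) && father[v] > 0) {
          edges[[length(edges) + 1]] <- c(V(forest)$name[father[v]],
                                          V(forest)$name[v])
        }
      }
    }
    if (length(edges) == 0) {
      return(tibble(parent = character(), child = character()))
    }
    m <- do.call(rbind, edges)
    tibble(parent = m[, 1], child = m[, 2])
  })
}

#' Brownian-bridge expression path along one differentiation edge
#'
#' For each changing channel `m`, a path `g_m(t) = t * delta_m + B_t - t * B_1`
#' is simulated from a standard Brownian motion on an equispaced grid and
#' interpolated with a natural cubic spline, so `g(0) = 0` and
#' `g(1) = mu_child - mu_parent` exactly. Non-changing channels are
#' identically 0.
#'
#' @param mu_parent,mu_child Mean expression vectors of the two types.
#' @param changing_channels Integer or logical index of channels that change
#'   along the edge.
#' @param n_knots Number of grid points (including endpoints).
#' @param seed Optional seed.
#' @return A function mapping `t` in `[0, 1]` to an `length(t) x M` matrix of
#'   shifts.
#' @export
sample_edge_path <- function(mu_parent, mu_child, changing_channels,
                             n_knots = 10, seed = NULL) {
  stopifnot(length(mu_parent) == length(mu_child), n_knots >= 3)
  M <- length(mu_parent)
  delta <- mu_child - mu_parent
  if (is.logical(changing_channels)) changing_channels <- which(changing_channels)
  with_seed_(seed, {
    tk <- seq(0, 1, length.out = n_knots)
    splines <- vector("list", M)
    for (m in changing_channels) {
      B <- c(0, cumsum(stats::rnorm(n_knots - 1, 0, sqrt(diff(tk)))))
      vals <- tk * delta[m] + B - tk * B[n_knots]
      vals[1] <- 0; vals[n_knots] <- delta[m]
      splines[[m]] <- stats::splinefun(tk, vals, method = "natural")
    }
    function(t) {
      out <- matrix(0, length(t), M)
      for (m in changing_channels) out[, m] <- splines[[m]](t)
      out
    }
  })
}

#' Build a differentiation trajectory over a model's cell types
#'
#' Combines the forest sketch ([build_graph_creation()] in creation mode,
#' [build_graph_emulation()] on the fitted type means in emulation mode),
#' DFS rooting, per-edge Brownian-bridge paths, and per-node child-selection
#' probabilities into a polyforest ready for [simulate_cells()].
#'
#' Channels "change" along an edge when their absolute mean difference
#' exceeds `change_frac` of the largest absolute difference for that edge
#' (the top channel always changes). Cells keep their identity with
#' probability `stay_prob`; otherwise a child is drawn uniformly. Pseudotime
#' follows `Beta(beta_alpha, beta_beta)`; the U-shaped default concentrates
#' cells near the endpoints so discrete type labels stay meaningful.
#'
#' @param model A [reference_model()].
#' @param mode `"creation"` (random forest sketch) or `"emulation"`
#'   (modularity communities + MST on fitted mean distances).
#' @param n_trees Number of trees (creation mode).
#' @param stay_prob Probability a cell stays at its own type.
#' @param beta_alpha,beta_beta Pseudotime Beta parameters (scalars, or
#'   length-`B` vectors for per-batch control).
#' @param change_frac Fraction of the top channel shift below which a channel
#'   is held fixed along an edge.
#' @param n_knots Grid points per edge path.
#' @param seed Optional seed.
#' @return An object of class `cytosim_trajectory`.
#' @export
#' @examples
#' m <- create_model(4, 8, seed = 2)
#' tr <- build_trajectory(m, seed = 2)
#' tr$edges
build_trajectory <- function(model, mode = c("creation", "emulation"),
                             n_trees = 1, stay_prob = 0.5,
                             beta_alpha = 0.4, beta_beta = 0.4,
                             change_frac = 0.1, n_knots = 10, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "cytosim_model"),
            stay_prob >= 0, stay_prob <= 1,
            all(beta_alpha > 0), all(beta_beta > 0),
            change_frac >= 0, change_frac <= 1)
  means <- model_type_means(model)
  forest <- if (mode == "creation") {
    build_graph_creation(model$cell_types, n_trees,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, "forest"))
  } else {
    build_graph_emulation(means,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, "forest"))
  }
  edges <- root_forest(forest,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, "root"))
  paths <- vector("list", nrow(edges))
  changing <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    delta <- means[edges$child[i], ] - means[edges$parent[i], ]
    ad <- abs(delta)
    ch <- which(ad >= change_frac * max(ad))
    ch <- union(which.max(ad), ch)
    changing[[i]] <- ch
    paths[[i]] <- sample_edge_path(
      means[edges$parent[i], ], means[edges$child[i], ], ch, n_knots,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "path", i))
  }
  omega <- lapply(model$cell_types, function(p) {
    kids <- edges$child[edges$parent == p]
    if (length(kids) == 0) {
      stats::setNames(1, p)
    } else {
      stats::setNames(c(stay_prob, rep((1 - stay_prob) / length(kids), length(kids))),
                      c(p, kids))
    }
  })
  names(omega) <- model$cell_types
  structure(
    list(cell_types = model$cell_types, edges = edges, omega = omega,
         paths = paths, changing = changing,
         beta_alpha = beta_alpha, beta_beta = beta_beta,
         channels = model$channels),
    class = "cytosim_trajectory"
  )
}

#' @export
print.cytosim_trajectory <- function(x, ...) {
  cat(sprintf("<cytosim_trajectory: %d type(s), %d edge(s)>\n",
              length(x$cell_types), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges$parent, " -> ", x$edges$child, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Sample differentiation states for cells of one type
#'
#' For each cell: a child type is drawn from the type's child-selection
#' probabilities (including the "stay" mass on the type itself), a
#' pseudotime from `Beta(alpha_b, beta_b)`, and the expression shift is the
#' edge path evaluated at that pseudotime. Cells that stay (and leaf types)
#' get a zero shift; their pseudotime is reported but inert.
#'
#' @param trajectory A [build_trajectory()] result.
#' @param cell_type Type label of the cells.
#' @param batch Batch index (selects per-batch Beta parameters when vectors
#'   were supplied).
#' @param n Number of cells.
#' @param seed Optional seed.
#' @return List with `child` (character), `pseudotime` (numeric in `[0,1]`),
#'   and `shift` (`n x M` matrix).
#' @export
sample_differentiation <- function(trajectory, cell_type, batch = 1, n,
                                   seed = NULL) {
  stopifnot(inherits(trajectory, "cytosim_trajectory"))
  if (!cell_type %in% trajectory$cell_types) {
    abort(sprintf("unknown cell type '%s'.", cell_type))
  }
  with_seed_(seed, {
    om <- trajectory$omega[[cell_type]]
    a <- rep_len(trajectory$beta_alpha, batch)[batch]
    b <- rep_len(trajectory$beta_beta, batch)[batch]
    child <- names(om)[sample_cell_labels(as.numeric(om), n)]
    tt <- stats::rbeta(n, a, b)
    M <- length(trajectory$channels)
    shift <- matrix(0, n, M)
    for (ch in setdiff(unique(child), cell_type)) {
      i <- which(trajectory$edges$parent == cell_type &
                   trajectory$edges$child == ch)
      idx <- which(child == ch)
      shift[idx, ] <- trajectory$paths[[i]](tt[idx])
    }
    list(child = child, pseudotime = tt, shift = shift)
  })
}
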