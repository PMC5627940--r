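# Onnela geometric-mean weighted clustering, weights rescaled by the max.
onnela_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(rep(0, n))
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- colSums(W > 0)
  ifelse(k >= 2, num / (k * (k - 1)), 0)
}

#' Weighted clustering coefficient
#'
#' Per-node geometric-mean (Onnela) weighted clustering on weights rescaled
#' by the maximum weight: for node i,
#' \eqn{c_i = \frac{1}{k_i (k_i - 1)} \sum_{j,k} (\hat w_{ij} \hat w_{jk} \hat w_{ki})^{1/3}}.
#' Nodes with fewer than two neighbours get 0.
#'
#' @param W symmetric non-negative weight matrix (n >= 3).
#' @return Tibble with `node` and `clustering`; the network value is the
#'   mean of the `clustering` column.
#' @export
weighted_clustering <- function(W) {
  check_square_matrix(W)
  if (nrow(W) < 3) {
    abort("clustering is undefined for networks with fewer than 3 nodes.")
  }
  tibble::tibble(node = seq_len(nrow(W)), clustering = onnela_clustering(W))
}

#' Normalized weighted clustering (gamma)
#'
#' Mean weighted clustering of `W` divided by the mean clustering of
#' surrogate networks obtained by permuting the upper-triangle weights
#' (preserving symmetry, density and the weight distribution).
#'
#' @param W symmetric non-negative weight matrix.
#' @param n_surrogates number of surrogate networks (>= 10).
#' @param seed RNG seed for surrogate generation.
#' @return gamma (dimensionless), `NA` if the surrogate clustering is zero.
#' @export
normalized_gamma <- function(W, n_surrogates = 50, seed = NULL) {
  check_square_matrix(W)
  if (n_surrogates < 10) abort("`n_surrogates` must be >= 10.")
  cw <- mean(onnela_clustering(W))
  ut <- upper.tri(W)
  vals <- W[ut]
  surr <- with_seed(seed, vapply(seq_len(n_surrogates), function(i) {
    S <- matrix(0, nrow(W), ncol(W))
    S[ut] <- sample(vals)
    mean(onnela_clustering(S + t(S)))
  }, numeric(1)))
  m <- mean(surr)
  if (m <= 0) return(NA_real_)
  cw / m
}

as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted modularity via seeded multilevel (Louvain) maximization
#'
#' Best Newman weighted modularity over `n_restarts` seeded Louvain runs.
#'
#' @param W symmetric non-negative weight matrix.
#' @param seed RNG seed; the same seed yields the same partition.
#' @param n_restarts number of restarts.
#' @return List with `membership` (integer community per node) and
#'   `modularity_q`.
#' @export
graph_modularity <- function(W, seed = NULL, n_restarts = 10) {
  check_square_matrix(W)
  if (nrow(W) == 0 || all(W == 0)) abort("modularity needs a non-empty graph.")
  gr <- as_igraph(W)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_restarts)) {
      perm <- sample(igraph::vcount(gr))
      gp <- igraph::permute(gr, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
      q <- igraph::modularity(cl)
      if (is.null(best) || q > best$modularity_q) {
        memb <- integer(length(perm))
        memb[perm] <- igraph::membership(cl)
        best <- list(membership = memb, modularity_q = q)
      }
    }
    best
  })
}

#' Algebraic connectivity
#'
#' Second-smallest eigenvalue of the weighted graph Laplacian
#' \eqn{L = D - W}. Non-negative; exactly 0 iff the network is
#' disconnected. Larger values indicate a network that is harder to
#' fragment.
#'
#' @param W symmetric non-negative weight matrix (n >= 2).
#' @return The eigenvalue (dimensionless).
#' @export
algebraic_connectivity <- function(W) {
  check_square_matrix(W)
  if (nrow(W) < 2) abort("need at least 2 nodes.")
  L <- diag(colSums(W)) - W
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  max(ev[2], 0)
}

#' Leaf number of the maximum-weight spanning tree
#'
#' Builds the maximum-weight spanning tree (equivalently, the minimum
#' spanning tree on distances `1/weight` -- the tree depends only on the
#' weight ordering) and counts its degree-1 nodes. A high leaf number
#' indicates a star-like, hub-dominated architecture.
#'
#' @param W symmetric weight matrix with positive weights on edges; must be
#'   connected.
#' @return List with `leaf_number` and `leaf_fraction` (= leaves / (n - 1)).
#' @export
mst_leaf_number <- function(W) {
  check_square_matrix(W)
  gr <- as_igraph(W)
  comp <- igraph::components(gr)
  if (comp$no > 1) {
    abort(sprintf("graph is disconnected (%d components of sizes %s).",
                  comp$no, paste(comp$csize, collapse = ", ")))
  }
  tr <- igraph::mst(gr, weights = 1 / igraph::E(gr)$weight)
  leaves <- sum(igraph::degree(tr) == 1)
  list(leaf_number = leaves, leaf_fraction = leaves / (igraph::vcount(tr) - 1))
}

#' All four topological outcome measures of a weighted network
#'
#' Computes normalized clustering (gamma), modularity, algebraic
#' connectivity and MST leaf number, typically on a PLI functional
#' connectivity matrix (analyzed fully weighted, no thresholding).
#'
#' @param W symmetric non-negative weight matrix (e.g. `pli_matrix$values`).
#' @param n_surrogates surrogates for the gamma normalization.
#' @param seed RNG seed (surrogates and modularity restarts).
#' @param n_restarts Louvain restarts.
#' @return One-row tibble: `gamma`, `modularity_q`, `algebraic_connectivity`,
#'   `mst_leaf_number`, `mst_leaf_fraction`.
#' @export
graph_metrics <- function(W, n_surrogates = 50, seed = NULL, n_restarts = 10) {
  if (inherits(W, "pli_matrix")) W <- W$values
  mst <- mst_leaf_number(W)
  tibble::tibble(
    gamma = normalized_gamma(W, n_surrogates, seed = seed),
    modularity_q = graph_modularity(W, seed = seed,
                                    n_restarts = n_restarts)$modularity_q,
    algebraic_connectivity = algebraic_connectivity(W),
    mst_leaf_number = mst$leaf_number,
    mst_leaf_fraction = mst$leaf_fraction)
}
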