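new_connectome <- function(W0, labels = NULL, T_delay = 0.01, g = 3.0,
                           W = NULL) {
  check_square_matrix(W0, "W0")
  n <- nrow(W0)
  dimnames(W0) <- NULL
  W0 <- pmax(W0, t(W0))
  diag(W0) <- 0
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(n))
  if (length(labels) != n) abort("`labels` length must match the matrix size.")
  if (T_delay < 0) abort("`T_delay` must be >= 0.")
  if (g < 0) abort("`g` must be >= 0.")
  structure(list(n_nodes = n, labels = as.character(labels),
                 W0 = W0, W = if (is.null(W)) W0 else W,
                 T_delay = T_delay, g = g),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  deg <- colSums(x$W0 > 0)
  cat(sprintf("<connectome> %d nodes, %d edges, mean degree %.1f\n",
              x$n_nodes, sum(x$W0 > 0) / 2, mean(deg)))
  cat(sprintf("  coupling gain g = %g, delay T = %g ms\n",
              x$g, 1000 * x$T_delay))
  frac <- sum(x$W) / max(sum(x$W0), .Machine$double.eps)
  cat(sprintf("  current / original total weight: %.3f\n", frac))
  invisible(x)
}

#' Load a structural connectome from a CSV/TSV matrix file
#'
#' Reads a square, non-negative weight matrix (comma- or tab-separated; an
#' optional single header row is used as region labels), symmetrizes it by
#' taking the elementwise maximum of the two triangles, and zeroes the
#' diagonal. Coupling between regions is treated as reciprocal and
#' excitatory; a single conduction delay applies to all edges.
#'
#' @param path path to the matrix file.
#' @param g global coupling gain (dimensionless).
#' @param T_delay inter-mass conduction delay in seconds.
#' @return A `connectome` object carrying both the original matrix `W0` and
#'   the current (possibly degenerated) matrix `W`.
#' @export
load_connectome <- function(path, g = 3.0, T_delay = 0.01) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("[A-Za-z]", gsub("[eE][+-]?[0-9]+", "", first))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, strip.white = TRUE)
  M <- as.matrix(df)
  if (!is.numeric(M)) abort("matrix file contains non-numeric entries.")
  labels <- if (has_header) colnames(df) else NULL
  new_connectome(M, labels = labels, T_delay = T_delay, g = g)
}

#' Write a connectome weight matrix to CSV
#'
#' @param conn a `connectome`.
#' @param path output path.
#' @param which `"W"` (current) or `"W0"` (original).
#' @export
write_connectome <- function(conn, path, which = c("W", "W0")) {
  which <- match.arg(which)
  M <- conn[[which]]
  colnames(M) <- conn$labels
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Generate a synthetic modular, hub-bearing cortical connectome
#'
#' Emulates the gross features of a DTI cortical connectome: a sparse,
#' binary, connected graph with planted modules (dense within, sparse
#' between) and a small set of hub nodes that receive extra long-range
#' edges. All initial coupling strengths are identical (weight 1); the only
#' difference between regions is their connectivity.
#'
#' @param n_nodes number of regions (default 78).
#' @param n_modules number of planted modules; nodes are split as evenly as
#'   possible.
#' @param intra_p edge probability within a module.
#' @param inter_p edge probability between modules.
#' @param hub_count number of hub nodes (spread over modules).
#' @param hub_extra_p probability of an extra edge from each hub to each
#'   node outside its module.
#' @param g,T_delay coupling gain and delay stored on the connectome.
#' @param seed RNG seed; the same seed reproduces the same matrix.
#' @param max_tries connected-graph rejection-sampling attempts.
#' @return A `connectome`.
#' @examples
#' conn <- synthetic_connectome(n_nodes = 20, n_modules = 4,
#'                              intra_p = 0.9, inter_p = 0.25,
#'                              hub_count = 2, seed = 1)
#' @export
synthetic_connectome <- function(n_nodes = 78, n_modules = 6,
                                 intra_p = 0.5, inter_p = 0.03,
                                 hub_count = 5, hub_extra_p = 0.35,
                                 g = 3.0, T_delay = 0.01,
                                 seed = NULL, max_tries = 100) {
  probs <- c(intra_p = intra_p, inter_p = inter_p, hub_extra_p = hub_extra_p)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  if (hub_count >= n_nodes) abort("`hub_count` must be < `n_nodes`.")
  if (n_modules < 1 || n_modules > n_nodes) {
    abort("`n_modules` must be between 1 and `n_nodes`.")
  }
  module <- sort(rep_len(seq_len(n_modules), n_nodes))
  hubs <- integer(0)
  if (hub_count > 0) {
    # one hub per module, cycling, so hubs are spread over the partition
    hubs <- unlist(lapply(seq_len(hub_count), function(k) {
      m <- ((k - 1) %% n_modules) + 1
      which(module == m)[ceiling(k / n_modules)]
    }))
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      same <- outer(module, module, "==")
      P <- ifelse(same, intra_p, inter_p)
      W <- matrix(0, n_nodes, n_nodes)
      ut <- upper.tri(W)
      W[ut] <- (stats::runif(sum(ut)) < P[ut]) * 1
      W <- W + t(W)
      if (length(hubs) > 0) {
        for (h in hubs) {
          extra <- which(stats::runif(n_nodes) < hub_extra_p & !same[h, ] &
                           W[h, ] == 0)
          W[h, extra] <- W[extra, h] <- 1
        }
      }
      diag(W) <- 0
      gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
      if (igraph::is_connected(gr)) {
        conn <- new_connectome(W, T_delay = T_delay, g = g)
        attr(conn, "module") <- module
        attr(conn, "hubs") <- hubs
        return(conn)
      }
    }
    abort(sprintf(
      "no connected graph in %d attempts; increase `intra_p`/`inter_p`.",
      max_tries))
  })
}

#' Normalized node strength
#'
#' Per region, the sum of incident current structural weights divided by the
#' sum of incident original weights: 1 for an intact node, smaller under
#' degeneration. Tracks structural damage and exposes hub vulnerability.
#'
#' @param conn a `connectome`, or a current weight matrix `W` (then `W0`
#'   must be supplied).
#' @param W0 original weight matrix when `conn` is a bare matrix.
#' @return A tibble with columns `node`, `label`, `degree0`, `strength0`,
#'   `strength`, `strength_ratio` (`NA` for nodes isolated in `W0`).
#' @export
normalized_node_strength <- function(conn, W0 = NULL) {
  if (inherits(conn, "connectome")) {
    W <- conn$W; W0 <- conn$W0; labels <- conn$labels
  } else {
    W <- conn
    if (is.null(W0)) abort("supply `W0` when passing a bare matrix.")
    if (!all(dim(W) == dim(W0))) abort("`W` and `W0` must have equal shape.")
    labels <- sprintf("R%02d", seq_len(nrow(W)))
  }
  s0 <- unname(colSums(W0)); s <- unname(colSums(W))
  tibble::tibble(
    node = seq_along(s0),
    label = labels,
    degree0 = colSums(W0 > 0),
    strength0 = s0,
    strength = s,
    strength_ratio = ifelse(s0 > 0, s / s0, NA_real_))
}
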