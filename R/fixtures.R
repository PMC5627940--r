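# --- independent brute-force oracles (enumeration / closed forms) --------

# triangle enumeration of Onnela clustering, no matrix products
bf_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  Wh <- if (mx > 0) W / mx else W
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (l in nb) {
      if (j != l) s <- s + (Wh[i, j] * Wh[j, l] * Wh[l, i])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# count eigenvalues of symmetric M below t via the inertia of M - t I
# (symmetric Gaussian elimination), then bisect for the second-smallest
# Laplacian eigenvalue. Independent of eigen().
inertia_below <- function(M, t) {
  A <- M - diag(t, nrow(M))
  n <- nrow(A)
  neg <- 0
  for (k in seq_len(n)) {
    piv <- A[k, k]
    if (abs(piv) < 1e-12) piv <- 1e-12  # nudge off a singular pivot
    if (piv < 0) neg <- neg + 1
    if (k < n) {
      rows <- (k + 1):n
      A[rows, rows] <- A[rows, rows] -
        tcrossprod(A[rows, k]) / piv
    }
  }
  neg
}

bf_lambda2 <- function(W, tol = 1e-11) {
  L <- diag(colSums(W)) - W
  lo <- 0
  hi <- 2 * max(colSums(W)) + 1
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (inertia_below(L, mid) >= 2) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# exhaustive maximum-weight spanning tree over all (n-1)-edge subsets
bf_mst_leaves <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(idx)
  best_w <- -Inf; best_deg <- NULL
  subsets <- utils::combn(m, n - 1)
  for (c in seq_len(ncol(subsets))) {
    rows <- idx[subsets[, c], , drop = FALSE]
    deg <- tabulate(c(rows[, 1], rows[, 2]), nbins = n)
    # spanning + acyclic check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in seq_len(nrow(rows))) {
      a <- find(rows[e, 1]); b <- find(rows[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok || length(unique(vapply(seq_len(n), find, integer(1)))) != 1) next
    w <- sum(W[rows])
    if (w > best_w) { best_w <- w; best_deg <- deg }
  }
  list(leaf_number = sum(best_deg == 1), total_weight = best_w)
}

# exhaustive best 2-partition weighted Newman modularity
bf_modularity2 <- function(W) {
  n <- nrow(W)
  m2 <- sum(W)           # 2m
  k <- colSums(W)
  Bmat <- W - outer(k, k) / m2
  best_q <- -Inf; best_part <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    same <- outer(memb, memb, "==")
    q <- sum(Bmat[same]) / m2
    if (q > best_q) { best_q <- q; best_part <- memb }
  }
  list(modularity_q = best_q, membership = best_part + 1L)
}

# --- fixture generators ---------------------------------------------------

#' Multichannel sinusoids with known phase lags
#'
#' A common sinusoid with fixed per-channel phase offsets plus independent
#' Gaussian noise; the ground-truth PLI is 1 for channel pairs whose lag
#' difference is nonzero (mod pi) at zero noise, and 0 for zero-lag pairs.
#'
#' @param n number of channels (used when `lags` is a scalar recycled).
#' @param freq oscillation frequency (Hz).
#' @param lags per-channel phase offsets (radians), length `n`.
#' @param noise_sd independent noise s.d. relative to unit amplitude.
#' @param duration length in seconds.
#' @param fs sample rate (Hz); must be at least `4 * freq`.
#' @param seed RNG seed for the noise.
#' @return List with `signals` (time x channels), `true_pli` (matrix; `NA`
#'   when `noise_sd > 0`), `fs`, `lags`.
#' @export
make_lagged_oscillators <- function(n = 2, freq = 10, lags = NULL,
                                    noise_sd = 0, duration = 10, fs = 500,
                                    seed = NULL) {
  if (fs < 4 * freq) {
    abort(sprintf("fs = %g is too low for freq = %g Hz (need fs >= 4*freq).",
                  fs, freq))
  }
  if (is.null(lags)) lags <- seq(0, by = pi / 4, length.out = n)
  n <- length(lags)
  tt <- seq_len(round(duration * fs)) / fs
  sig <- vapply(lags, function(l) sin(2 * pi * freq * tt + l),
                numeric(length(tt)))
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, matrix(rnorm(length(sig), 0, noise_sd),
                                        nrow = nrow(sig)))
  }
  truth <- matrix(NA_real_, n, n)
  if (noise_sd == 0) {
    dl <- outer(lags, lags, "-")
    truth <- ifelse(abs(sin(dl)) > 1e-12, 1, 0)
    diag(truth) <- 0
  }
  list(signals = sig, true_pli = truth, fs = fs, lags = lags)
}

#' Library of small graphs with brute-force ground truths
#'
#' Named toy graphs (triangle, path, star, complete K5, two bridged
#' 5-cliques, a seeded random weighted 8-node graph), each bundled with
#' ground-truth metric values computed at generation time by independent
#' exhaustive algorithms: triangle enumeration for clustering, inertia
#' bisection for the second Laplacian eigenvalue, enumeration of all
#' spanning trees for the maximum-weight tree, and exhaustive 2-partition
#' search for modularity (stored only where the optimum is a 2-partition).
#'
#' @return Named list; each element has `W` and `truth` (a list with
#'   `clustering`, `mean_clustering`, `lambda2`, `mst_leaf_number`, and for
#'   the bridged cliques `modularity_q`/`membership`).
#' @export
make_toy_graphs <- function() {
  unw <- function(A) { A <- pmax(A, t(A)); diag(A) <- 0; A }
  graphs <- list()

  tri <- unw(matrix(1, 3, 3))
  graphs$triangle <- list(W = tri)

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1
  graphs$path3 <- list(W = unw(p3))

  s6 <- matrix(0, 6, 6); s6[1, 2:6] <- 1
  graphs$star6 <- list(W = unw(s6))

  graphs$k5 <- list(W = unw(matrix(1, 5, 5)))

  tc <- matrix(0, 10, 10)
  tc[1:5, 1:5] <- 1; tc[6:10, 6:10] <- 1; tc[5, 6] <- 1
  graphs$two_clique_bridge <- list(W = unw(tc))

  W8 <- with_seed(20011, {
    A <- matrix(0, 8, 8)
    repeat {
      A[] <- 0
      ut <- which(upper.tri(A))
      on <- ut[stats::runif(length(ut)) < 0.45]
      A[on] <- round(stats::runif(length(on), 0.2, 1), 3)
      A <- pmax(A, t(A))
      gr <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
      if (igraph::is_connected(gr)) break
    }
    A
  })
  graphs$random8 <- list(W = W8)

  # Leaf numbers: for graphs whose maximum-weight spanning tree is unique
  # (distinct weights, or a unique tree topology) the exhaustive search
  # gives one value; for uniform-weight graphs every spanning tree is
  # maximal, so the truth is the set of achievable leaf counts (any tree on
  # n nodes has 2..n-1 leaves, and a complete graph realizes them all).
  mst_truth <- list(
    triangle = 2L,                      # every 3-node tree is a path
    path3 = 2L, star6 = 5L,             # unique spanning tree
    k5 = 2:4,                           # all trees on 5 nodes occur in K5
    two_clique_bridge = 2:9,
    random8 = bf_mst_leaves(graphs$random8$W)$leaf_number)

  for (nm in names(graphs)) {
    W <- graphs[[nm]]$W
    truth <- list(
      clustering = bf_clustering(W),
      mean_clustering = mean(bf_clustering(W)),
      lambda2 = bf_lambda2(W),
      mst_leaf_number = mst_truth[[nm]])
    if (nm == "two_clique_bridge") {
      bm <- bf_modularity2(W)
      truth$modularity_q <- bm$modularity_q
      truth$membership <- bm$membership
    }
    graphs[[nm]]$truth <- truth
  }
  graphs
}
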