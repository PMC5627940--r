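#' Activity-dependent degeneration parameters
#'
#' Controls the per-cycle loss of structural coupling. After each cycle,
#' every edge (i, j) is multiplied by `1 - lam * L(s_ij)` where
#' \eqn{L(s) = e^{k (s - s_{ref})}} and `s_ij` summarizes the excitatory
#' spike density of the edge's endpoints. Damage never stops entirely:
#' regions at or below the reference activity are damaged too, just
#' exponentially less.
#'
#' @param lam loss-rate scale per cycle (dimensionless, >= 0). 0 disables
#'   degeneration.
#' @param s_ref reference spike density (1/s) at which the loss factor is
#'   exactly `lam`.
#' @param k exponential sensitivity (s); larger values punish hyperactive
#'   regions more steeply.
#' @param w_floor minimum weight an existing edge can decay to.
#' @param mode how edge activity `s_ij` is formed from the endpoint
#'   densities: `"mean"` (default, `(s_i + s_j)/2`) or `"endpoint"` (each
#'   endpoint damages the edge independently, multiplicatively).
#' @return Object of class `add_params`.
#' @export
add_params <- function(lam = 0.03, s_ref = 2.0, k = 1.1, w_floor = 0,
                       mode = c("mean", "endpoint")) {
  mode <- match.arg(mode)
  assert_scalar_num(lam, "lam"); assert_scalar_num(k, "k")
  assert_scalar_num(s_ref, "s_ref"); assert_scalar_num(w_floor, "w_floor")
  if (lam < 0 || k < 0 || w_floor < 0) {
    abort("`lam`, `k`, `w_floor` must be >= 0.")
  }
  structure(list(lam = lam, s_ref = s_ref, k = k, w_floor = w_floor,
                 mode = mode),
            class = "add_params")
}

#' @export
print.add_params <- function(x, ...) {
  cat(sprintf(
    "<add_params> lam=%g, s_ref=%g /s, k=%g s, w_floor=%g, mode=%s\n",
    x$lam, x$s_ref, x$k, x$w_floor, x$mode))
  invisible(x)
}

#' Apply one cycle of activity-dependent degeneration
#'
#' Lowers the structural coupling strengths as an increasing (exponential)
#' function of local excitatory spike density. Weights never increase,
#' symmetry is preserved, and weights are clamped at `w_floor` (with a
#' warning when the loss factor saturates above 1).
#'
#' @param conn a `connectome`.
#' @param mean_spike_density per-node mean excitatory spike density of the
#'   cycle just simulated (1/s).
#' @param params `add_params`.
#' @return The `connectome` with updated current weights `W`.
#' @export
apply_add <- function(conn, mean_spike_density, params = add_params()) {
  s <- mean_spike_density
  if (length(s) != conn$n_nodes) {
    abort("`mean_spike_density` must have one value per node.")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("spike densities must be finite and non-negative.")
  }
  if (params$lam == 0) return(conn)
  L_node <- exp(params$k * (s - params$s_ref))
  if (params$mode == "mean") {
    s_edge <- outer(s, s, function(a, b) (a + b) / 2)
    loss <- params$lam * exp(params$k * (s_edge - params$s_ref))
  } else {
    # each endpoint damages the edge independently
    keep_i <- pmax(0, 1 - params$lam * L_node)
    loss <- 1 - outer(keep_i, keep_i)
  }
  if (any(loss[conn$W > 0] > 1)) {
    warn("degeneration loss factor exceeded 1 on some edges; weights clamped.")
  }
  W_new <- conn$W * pmax(0, 1 - loss)
  on_edge <- conn$W0 > 0
  W_new[on_edge] <- pmax(W_new[on_edge], pmin(params$w_floor,
                                              conn$W[on_edge]))
  diag(W_new) <- 0
  conn$W <- W_new
  conn
}

#' Per-node activity summaries of a cycle
#'
#' Mean excitatory spike density (the quantity that drives degeneration)
#' and mean squared membrane potential ("total power") per node.
#'
#' @param output a `cycle_output`.
#' @return Tibble with `node`, `label`, `mean_spike_density`,
#'   `mean_sq_potential`.
#' @export
total_activity <- function(output) {
  if (nrow(output$signals) == 0) abort("empty cycle output.")
  tibble::tibble(
    node = seq_len(ncol(output$signals)),
    label = colnames(output$signals),
    mean_spike_density = unname(colMeans(output$spike_density)),
    mean_sq_potential = unname(colMeans(output$signals^2)))
}
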