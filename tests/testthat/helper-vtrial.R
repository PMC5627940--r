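# shared fixtures for the test suite

# single isolated mass wrapped as a 1-node network (no coupling)
one_node_connectome <- function() {
  vtrial:::new_connectome(matrix(0, 1, 1), g = 0, T_delay = 0.01)
}

# reduced-scale trial connectome: 20 nodes, 4 tight modules, 2 strong hubs.
# Mean degree and coupling drive are matched to the 78-node default so the
# network sits in the same collective alpha regime.
test_connectome <- function(seed) {
  synthetic_connectome(n_nodes = 20, n_modules = 4, intra_p = 1.0,
                       inter_p = 0.15, hub_count = 2, hub_extra_p = 0.4,
                       g = 4.0, seed = seed)
}

# degeneration at the reduced scale: slower loss so collapse lands after
# the default therapy start, around cycle 20
test_add_params <- function() add_params(lam = 0.015)

# quick 2-cycle settle + snapshot of a network's output
settle_and_run <- function(conn, params = mass_params(), n_settle = 2,
                           seed = 1, duration = 4) {
  st <- init_network_states(conn, params)
  for (i in seq_len(n_settle)) {
    r <- run_cycle(conn, st, params, duration = duration, seed = seed + i)
    st <- r$states
  }
  r$output
}

# synthetic cycle_output wrapper around a plain signal matrix
as_cycle_output <- function(signals, fs = 500, spike = NULL) {
  if (is.null(spike)) spike <- signals * 0
  colnames(signals) <- colnames(spike) <- sprintf("R%02d", seq_len(ncol(signals)))
  structure(list(signals = signals, spike_density = spike,
                 mean_spike_density = colMeans(spike), fs = fs,
                 cycle_index = 0L),
            class = "cycle_output")
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- atan2(sin(dp), cos(dp))
  cumsum(c(p[1], dp))
}

# hand-rolled metric table for trial-level unit tests
fake_metrics <- function(condition, values_by_cycle, metric = "pli",
                         runs = 3, noise = 0) {
  rows <- list()
  for (run in seq_len(runs)) {
    rows[[run]] <- tibble::tibble(
      condition = condition, run = run,
      cycle = seq_along(values_by_cycle),
      metric = metric,
      value = values_by_cycle + noise * (run - (runs + 1) / 2))
  }
  dplyr::bind_rows(rows)
}
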