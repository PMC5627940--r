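#' Initialize the per-node dynamic state of a network
#'
#' @param conn a `connectome`.
#' @param params `mass_params`.
#' @param dt integration step (s), used to size the delay buffer.
#' @param init `"baseline"` starts each mass at its threshold potentials
#'   (`Ve = Vd1`, `Vi = Vd2`, zero derivatives), `"zero"` at the origin.
#' @return A `network_states` list: vectors `ve`, `ze`, `vi`, `zi` and the
#'   delay ring buffer `E_hist` (oldest row first), pre-filled with the
#'   initial excitatory pulse density.
#' @export
init_network_states <- function(conn, params = mass_params(), dt = 0.001,
                                init = c("baseline", "zero")) {
  init <- match.arg(init)
  n <- conn$n_nodes
  delay_steps <- delay_steps_for(conn$T_delay, dt)
  Vd1 <- rep_len(params$Vd1, n); Vd2 <- rep_len(params$Vd2, n)
  ve <- if (init == "baseline") Vd1 else rep(0, n)
  vi <- if (init == "baseline") Vd2 else rep(0, n)
  E0 <- sigmoid_transfer(ve, Vd1, params$q, params$r)
  structure(list(ve = ve, ze = rep(0, n), vi = vi, zi = rep(0, n),
                 E_hist = matrix(rep(E0, each = max(delay_steps, 1)),
                                 nrow = max(delay_steps, 1), ncol = n)),
            class = "network_states")
}

delay_steps_for <- function(T_delay, dt) {
  steps <- T_delay / dt
  if (abs(steps - round(steps)) > 1e-8) {
    abort(sprintf("delay T = %g s is not an integral number of dt = %g s steps.",
                  T_delay, dt))
  }
  as.integer(round(steps))
}

#' Simulate one virtual-time cycle of the coupled network
#'
#' Advances every mass jointly: the external input of node i at time t is
#' \eqn{g \sum_j W_{ij} E_j(t - T)}, with a fixed conduction delay T handled
#' by a ring buffer of past excitatory pulse densities. The multichannel
#' output is the excitatory membrane potential and spike density of each
#' node, sampled at `fs` after discarding an initial transient.
#'
#' @param conn a `connectome` (its current `W` is used).
#' @param states `network_states` carried over from the previous cycle, or
#'   `NULL` to initialize at baseline.
#' @param params `mass_params`; `Vd1`/`Vd2` may be per-node vectors.
#' @param duration simulated seconds per cycle (>= 2 s recommended for
#'   stable spectral and PLI estimates).
#' @param dt integration step (s).
#' @param fs output sample rate (Hz); `1/dt` must be a multiple of `fs`.
#' @param transient leading seconds discarded from the returned series (the
#'   dynamic state itself carries through unchanged).
#' @param seed RNG seed for the thalamic noise (`NULL`: current RNG stream).
#' @param noise optional pre-generated drive matrix (`duration/dt` rows x
#'   nodes); overrides `seed`.
#' @param cycle_index virtual-time index stored on the output.
#' @return A list with `output` (a `cycle_output`: `signals`, `spike_density`,
#'   `mean_spike_density`, `fs`, `cycle_index`) and `states` (to pass to the
#'   next cycle).
#' @export
run_cycle <- function(conn, states = NULL, params = mass_params(),
                      duration = 4, dt = 0.001, fs = 500,
                      transient = 0.5, seed = NULL, noise = NULL,
                      cycle_index = 0L) {
  if (duration <= transient) abort("`duration` must exceed `transient`.")
  record_every <- (1 / dt) / fs
  if (abs(record_every - round(record_every)) > 1e-8) {
    abort("`1/dt` must be an integer multiple of `fs`.")
  }
  record_every <- as.integer(round(record_every))
  n <- conn$n_nodes
  n_steps <- as.integer(round(duration / dt))
  delay_steps <- delay_steps_for(conn$T_delay, dt)
  if (is.null(states)) states <- init_network_states(conn, params, dt)
  if (is.null(noise)) {
    noise <- with_seed(seed, matrix(
      pmax(0, rnorm(n_steps * n, params$P_mean, params$P_sd)),
      nrow = n_steps, ncol = n))
  }
  if (nrow(noise) != n_steps || ncol(noise) != n) {
    abort(sprintf("`noise` must be %d x %d.", n_steps, n))
  }
  Vd1 <- rep_len(params$Vd1, n); Vd2 <- rep_len(params$Vd2, n)
  res <- simulate_network_cpp(conn$W, conn$g, delay_steps, Vd1, Vd2,
                              params$A, params$B, params$a, params$b,
                              params$C1, params$C2, params$q, params$r,
                              noise, dt,
                              states$ve, states$ze, states$vi, states$zi,
                              states$E_hist, record_every)
  keep <- seq_len(nrow(res$signals)) > round(transient * fs)
  sig <- res$signals[keep, , drop = FALSE]
  spk <- res$spike_density[keep, , drop = FALSE]
  colnames(sig) <- colnames(spk) <- conn$labels
  out <- structure(list(signals = sig, spike_density = spk,
                        mean_spike_density = colMeans(spk),
                        fs = fs, cycle_index = cycle_index),
                   class = "cycle_output")
  new_states <- structure(list(ve = res$ve, ze = res$ze, vi = res$vi,
                               zi = res$zi, E_hist = res$E_hist),
                          class = "network_states")
  list(output = out, states = new_states)
}

#' @export
print.cycle_output <- function(x, ...) {
  cat(sprintf("<cycle_output> cycle %d: %d nodes x %d samples at %g Hz\n",
              x$cycle_index, ncol(x$signals), nrow(x$signals), x$fs))
  cat(sprintf("  mean spike density: %.2f /s (range %.2f-%.2f)\n",
              mean(x$mean_spike_density), min(x$mean_spike_density),
              max(x$mean_spike_density)))
  invisible(x)
}

#' Tidy a cycle output into a long tibble
#'
#' @param x a `cycle_output`.
#' @param ... unused.
#' @return Tibble with `time`, `node`, `label`, `potential`, `spike_density`.
#' @export
tidy.cycle_output <- function(x, ...) {
  n <- ncol(x$signals); len <- nrow(x$signals)
  tibble::tibble(
    time = rep(seq_len(len) / x$fs, times = n),
    node = rep(seq_len(n), each = len),
    label = rep(colnames(x$signals), each = len),
    potential = as.vector(x$signals),
    spike_density = as.vector(x$spike_density))
}

#' Write the multichannel signals of a cycle to CSV
#'
#' @param output a `cycle_output`.
#' @param path destination file.
#' @export
write_cycle_signals <- function(output, path) {
  df <- as.data.frame(output$signals)
  df <- cbind(time = seq_len(nrow(df)) / output$fs, df)
  utils::write.table(df, path, sep = ",", row.names = FALSE)
  invisible(path)
}
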