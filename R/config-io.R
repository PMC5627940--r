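#' Write a trial configuration (and strategy) to JSON
#'
#' The connectome is stored either as a reference to a matrix file or as
#' the synthetic-generator parameters recorded on it; mass, degeneration
#' and trial parameters are stored verbatim.
#'
#' @param config a `trial_config`.
#' @param path output JSON path.
#' @param connectome_file optional path of a matrix file to reference
#'   instead of embedding the weight matrix.
#' @export
write_trial_config <- function(config, path, connectome_file = NULL) {
  conn <- config$connectome
  conn_spec <- if (!is.null(connectome_file)) {
    list(file = connectome_file, g = conn$g, T_delay = conn$T_delay)
  } else {
    list(matrix = unname(conn$W0), labels = conn$labels,
         g = conn$g, T_delay = conn$T_delay)
  }
  obj <- list(
    connectome = conn_spec,
    mass = unclass(config$mass),
    add = unclass(config$add),
    trial = list(n_runs = config$n_runs, n_cycles = config$n_cycles,
                 duration = config$duration, dt = config$dt, fs = config$fs,
                 transient = config$transient, base_seed = config$base_seed,
                 metrics = config$metrics, alpha = config$alpha,
                 pli_band = config$pli_band,
                 n_surrogates = config$n_surrogates,
                 n_restarts = config$n_restarts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trial configuration from JSON
#'
#' @param path JSON file written by [write_trial_config()] (or hand-edited
#'   in the same layout).
#' @return A `trial_config`.
#' @export
read_trial_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- obj$connectome
  conn <- if (!is.null(cs$file)) {
    load_connectome(cs$file, g = cs$g, T_delay = cs$T_delay)
  } else {
    new_connectome(as.matrix(cs$matrix), labels = cs$labels,
                   T_delay = cs$T_delay, g = cs$g)
  }
  mass <- do.call(mass_params, obj$mass)
  add <- do.call(add_params, obj$add)
  tr <- obj$trial
  trial_config(conn, mass = mass, add = add, n_runs = tr$n_runs,
               n_cycles = tr$n_cycles, duration = tr$duration, dt = tr$dt,
               fs = tr$fs, transient = tr$transient,
               base_seed = tr$base_seed, metrics = tr$metrics,
               alpha = tr$alpha, pli_band = tr$pli_band,
               n_surrogates = tr$n_surrogates, n_restarts = tr$n_restarts)
}

#' Write trial outputs to disk
#'
#' Writes the tidy per-cycle metric table as CSV and the performance
#' scores plus p-value grid as JSON.
#'
#' @param trial a `virtual_trial`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_trial_results <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(trial$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  ns <- dplyr::bind_rows(lapply(names(trial$conditions), function(cn) {
    dplyr::mutate(trial$conditions[[cn]]$node_strength, condition = cn,
                  .before = 1)
  }))
  utils::write.csv(ns, file.path(dir, "node_strength.csv"),
                   row.names = FALSE)
  summ <- list()
  if (all(c("control", "no_intervention") %in% names(trial$conditions))) {
    summ$performance <- performance_scores(trial)
    ctrl <- trial$conditions$control
    summ$comparison <- purrr::map_dfr(
      setdiff(names(trial$conditions), "control"),
      function(cn) {
        dplyr::mutate(
          compare_to_control(trial$conditions[[cn]], ctrl),
          condition = cn, .before = 1)
      })
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
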