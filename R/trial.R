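METRIC_NAMES <- c("rel_alpha", "peak_freq", "pli", "gamma", "modularity",
                  "algebraic_connectivity", "mst_leaf")

METRIC_CATEGORIES <- list(
  oscillatory  = c("rel_alpha", "peak_freq"),
  connectivity = "pli",
  topology     = c("gamma", "modularity", "algebraic_connectivity",
                   "mst_leaf"))

#' Configuration of a virtual trial
#'
#' Bundles everything a trial needs: the structural connectome, the mass and
#' degeneration parameters, the cycle geometry, the number of runs and
#' cycles, seeding, and which outcome measures to compute per cycle.
#'
#' @param connectome a `connectome`.
#' @param mass `mass_params`.
#' @param add `add_params` governing degeneration.
#' @param n_runs independent runs per condition (>= 2; t-tests need
#'   variance).
#' @param n_cycles degeneration cycles per run.
#' @param duration,dt,fs,transient cycle geometry passed to [run_cycle()].
#' @param base_seed base seed; run r of every condition uses seeds derived
#'   from `base_seed + r`, so conditions share noise streams (common random
#'   numbers).
#' @param metrics subset of `r paste(METRIC_NAMES, collapse = ", ")`.
#' @param alpha significance level of the per-cycle t-tests.
#' @param pli_band phase-estimation band (Hz).
#' @param n_surrogates surrogates for gamma.
#' @param n_restarts Louvain restarts.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(connectome, mass = mass_params(),
                         add = add_params(), n_runs = 10, n_cycles = 50,
                         duration = 4, dt = 0.001, fs = 500,
                         transient = 0.5, base_seed = 1,
                         metrics = METRIC_NAMES, alpha = 0.05,
                         pli_band = c(4, 13), n_surrogates = 20,
                         n_restarts = 5) {
  if (!inherits(connectome, "connectome")) abort("`connectome` required.")
  if (n_runs < 2) abort("`n_runs` must be >= 2 (t-tests need variance).")
  if (is.null(metrics)) metrics <- character(0)
  bad <- setdiff(metrics, METRIC_NAMES)
  if (length(bad) > 0) {
    abort(sprintf("unknown metrics: %s", paste(bad, collapse = ", ")))
  }
  structure(list(connectome = connectome, mass = mass, add = add,
                 n_runs = n_runs, n_cycles = n_cycles, duration = duration,
                 dt = dt, fs = fs, transient = transient,
                 base_seed = base_seed, metrics = metrics, alpha = alpha,
                 pli_band = pli_band, n_surrogates = n_surrogates,
                 n_restarts = n_restarts),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("<trial_config> %d nodes, %d runs x %d cycles (%g s at %g Hz)\n",
              x$connectome$n_nodes, x$n_runs, x$n_cycles, x$duration, x$fs))
  cat(sprintf("  base seed %s; metrics: %s\n", format(x$base_seed),
              paste(x$metrics, collapse = ", ")))
  invisible(x)
}

# per-cycle outcome measures for one simulated cycle
cycle_metrics <- function(output, config, analysis_seed) {
  vals <- numeric(0)
  if (length(config$metrics) == 0) return(vals)
  want <- config$metrics
  if (any(c("rel_alpha", "peak_freq") %in% want)) {
    sm <- spectral_metrics(output)
    if ("rel_alpha" %in% want) {
      vals["rel_alpha"] <- mean(sm$rel_lower_alpha, na.rm = TRUE)
    }
    if ("peak_freq" %in% want) {
      vals["peak_freq"] <- mean(sm$peak_freq, na.rm = TRUE)
    }
  }
  graph_wanted <- intersect(c("gamma", "modularity",
                              "algebraic_connectivity", "mst_leaf"), want)
  if ("pli" %in% want || length(graph_wanted) > 0) {
    pm <- pli_matrix(output, band = config$pli_band)
    if ("pli" %in% want) vals["pli"] <- pm$global_mean
    if (length(graph_wanted) > 0) {
      gm <- graph_metrics(pm$values, n_surrogates = config$n_surrogates,
                          seed = analysis_seed,
                          n_restarts = config$n_restarts)
      if ("gamma" %in% want) vals["gamma"] <- gm$gamma
      if ("modularity" %in% want) vals["modularity"] <- gm$modularity_q
      if ("algebraic_connectivity" %in% want) {
        vals["algebraic_connectivity"] <- gm$algebraic_connectivity
      }
      if ("mst_leaf" %in% want) vals["mst_leaf"] <- gm$mst_leaf_number
    }
  }
  vals
}

#' Run one trial condition (strategy) across runs and cycles
#'
#' For each run, a fresh copy of the connectome is simulated cycle by cycle:
#' the strategy's thresholds apply from its start cycle, outcome measures
#' are collected every cycle, and (if the strategy has degeneration on) the
#' ADD weight update follows each cycle. Dynamic states carry over between
#' cycles within a run.
#'
#' @param config a `trial_config`.
#' @param strategy a `strategy` (or a builtin strategy name).
#' @return A `condition_result`: list with `strategy`, `metrics` (tibble:
#'   condition, run, cycle, metric, value), `node_strength` (tibble: run,
#'   cycle, node, degree0, strength_ratio), `failed_runs`.
#' @export
run_condition <- function(config, strategy) {
  if (is.character(strategy)) strategy <- builtin_strategy(strategy)
  rows <- list()
  ns_rows <- list()
  failed <- integer(0)
  for (run in seq_len(config$n_runs)) {
    res <- tryCatch(
      run_single(config, strategy, run),
      error = function(e) {
        warn(sprintf("run %d of '%s' failed: %s", run, strategy$name,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { failed <- c(failed, run); next }
    rows[[length(rows) + 1]] <- res$metrics
    ns_rows[[length(ns_rows) + 1]] <- res$node_strength
  }
  if (length(failed) > 0.2 * config$n_runs) {
    abort(sprintf("condition '%s': %d of %d runs failed.", strategy$name,
                  length(failed), config$n_runs))
  }
  structure(list(strategy = strategy,
                 metrics = dplyr::bind_rows(rows),
                 node_strength = dplyr::bind_rows(ns_rows),
                 failed_runs = failed),
            class = "condition_result")
}

run_single <- function(config, strategy, run) {
  conn <- config$connectome
  conn$W <- conn$W0
  states <- init_network_states(conn, config$mass, config$dt)
  out_rows <- vector("list", config$n_cycles)
  ns_list <- vector("list", config$n_cycles)
  for (cycle in seq_len(config$n_cycles)) {
    params_c <- apply_strategy(config$mass, strategy, cycle)
    noise_seed <- derive_seed(config$base_seed, run, cycle)
    analysis_seed <- derive_seed(config$base_seed, run, cycle,
                                 offset = 1000003)
    sim <- run_cycle(conn, states, params_c,
                     duration = config$duration, dt = config$dt,
                     fs = config$fs, transient = config$transient,
                     seed = noise_seed, cycle_index = cycle)
    states <- sim$states
    vals <- cycle_metrics(sim$output, config, analysis_seed)
    out_rows[[cycle]] <- tibble::tibble(
      condition = strategy$name, run = run, cycle = cycle,
      metric = names(vals), value = unname(vals))
    ns <- normalized_node_strength(conn)
    ns_list[[cycle]] <- tibble::tibble(
      run = run, cycle = cycle, node = ns$node, degree0 = ns$degree0,
      strength_ratio = ns$strength_ratio)
    if (strategy$degeneration_on) {
      conn <- apply_add(conn, sim$output$mean_spike_density, config$add)
    }
  }
  list(metrics = dplyr::bind_rows(out_rows),
       node_strength = dplyr::bind_rows(ns_list))
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> '%s': %d runs x %d cycles\n",
              x$strategy$name, length(unique(x$metrics$run)),
              max(x$metrics$cycle)))
  invisible(x)
}

#' Run a full virtual trial over several conditions
#'
#' @param config a `trial_config`.
#' @param strategies character vector of builtin strategy names and/or a
#'   list of `strategy` objects. `control` and `no_intervention` are always
#'   included.
#' @param start_cycle start cycle for the builtin interventions.
#' @return A `virtual_trial`: list with `config`, `conditions` (named list
#'   of `condition_result`), `metrics` (combined tidy tibble).
#' @export
run_trial <- function(config,
                      strategies = setdiff(names(STRATEGY_TABLE),
                                           c("control", "no_intervention")),
                      start_cycle = 11) {
  strat_list <- list(builtin_strategy("control", start_cycle),
                     builtin_strategy("no_intervention", start_cycle))
  for (s in strategies) {
    st <- if (is.character(s)) builtin_strategy(s, start_cycle) else s
    if (!st$name %in% c("control", "no_intervention")) {
      strat_list[[length(strat_list) + 1]] <- st
    }
  }
  conditions <- list()
  for (st in strat_list) {
    conditions[[st$name]] <- run_condition(config, st)
  }
  structure(list(config = config, conditions = conditions,
                 metrics = dplyr::bind_rows(
                   lapply(conditions, function(c) c$metrics))),
            class = "virtual_trial")
}

#' @export
print.virtual_trial <- function(x, ...) {
  cat(sprintf("<virtual_trial> %d conditions: %s\n", length(x$conditions),
              paste(names(x$conditions), collapse = ", ")))
  print(x$config)
  invisible(x)
}

# core per-cycle two-sample comparison of two per-run metric tables
compare_metric_tables <- function(metrics, control_metrics, alpha = 0.05) {
  joined <- dplyr::inner_join(
    metrics |> dplyr::group_by(.data$cycle, .data$metric) |>
      dplyr::summarize(vals = list(.data$value), .groups = "drop"),
    control_metrics |> dplyr::group_by(.data$cycle, .data$metric) |>
      dplyr::summarize(ctrl = list(.data$value), .groups = "drop"),
    by = c("cycle", "metric"))
  purrr::pmap_dfr(joined, function(cycle, metric, vals, ctrl) {
    x <- vals[is.finite(vals)]; y <- ctrl[is.finite(ctrl)]
    m_x <- mean(x); m_y <- mean(y)
    p <- if (length(x) < 2 || length(y) < 2 ||
             (sd(x) == 0 && sd(y) == 0)) {
      NA_real_
    } else {
      tryCatch(t.test(x, y, var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    }
    normal <- if (is.na(p)) isTRUE(all.equal(m_x, m_y)) || m_x >= m_y
              else !(p < alpha && m_x < m_y)
    tibble::tibble(cycle = cycle, metric = metric, mean = m_x,
                   mean_control = m_y, p_value = p, normal = normal)
  })
}

#' Per-cycle t-test comparison of a condition against control
#'
#' Two-sample two-tailed t-tests of the condition's runs against the control
#' runs, per cycle and metric. A measure is flagged `normal` when it is not
#' significantly lower than control.
#'
#' @param result a `condition_result` (or its `metrics` tibble).
#' @param control the control `condition_result` (or tibble).
#' @param alpha significance level.
#' @return Tibble with `cycle`, `metric`, `mean`, `mean_control`,
#'   `p_value`, `normal`.
#' @export
compare_to_control <- function(result, control, alpha = 0.05) {
  m <- if (inherits(result, "condition_result")) result$metrics else result
  cm <- if (inherits(control, "condition_result")) control$metrics else control
  compare_metric_tables(m, cm, alpha)
}

count_normal_cycles <- function(result, control, category, alpha = 0.05) {
  cmp <- compare_to_control(result, control, alpha)
  sum(cmp$normal[cmp$metric %in% METRIC_CATEGORIES[[category]]], na.rm = TRUE)
}

#' Performance score of a condition for one metric category
#'
#' Counts the cycles (summed over the category's measures) in which the
#' condition stays at or near a normal level -- i.e. not significantly
#' lower than control -- and divides by the same count for the untreated
#' (no-intervention) arm.
#'
#' @param condition_result,control_result,no_intervention_result
#'   `condition_result` objects sharing the cycle grid.
#' @param category one of `"oscillatory"`, `"connectivity"`, `"topology"`.
#' @param alpha significance level of the underlying t-tests.
#' @return List with `normal_cycles`, `reference_cycles` and `ratio`
#'   (`Inf` if the untreated arm never scores a normal cycle).
#' @export
performance_score <- function(condition_result, control_result,
                              no_intervention_result,
                              category = names(METRIC_CATEGORIES),
                              alpha = 0.05) {
  category <- match.arg(category)
  n_cond <- count_normal_cycles(condition_result, control_result,
                                category, alpha)
  n_ref <- count_normal_cycles(no_intervention_result, control_result,
                               category, alpha)
  list(normal_cycles = n_cond, reference_cycles = n_ref,
       ratio = if (n_ref == 0) Inf else n_cond / n_ref)
}

#' Performance scores of all conditions in a trial
#'
#' @param trial a `virtual_trial` containing `control` and
#'   `no_intervention` conditions.
#' @param alpha significance level.
#' @return Tibble with `condition`, `category`, `normal_cycles`, `ratio`.
#' @export
performance_scores <- function(trial, alpha = 0.05) {
  stopifnot(all(c("control", "no_intervention") %in% names(trial$conditions)))
  ctrl <- trial$conditions$control
  ref <- trial$conditions$no_intervention
  purrr::map_dfr(names(trial$conditions), function(cn) {
    purrr::map_dfr(names(METRIC_CATEGORIES), function(cat) {
      sc <- performance_score(trial$conditions[[cn]], ctrl, ref, cat, alpha)
      tibble::tibble(condition = cn, category = cat,
                     normal_cycles = sc$normal_cycles, ratio = sc$ratio)
    })
  })
}

#' Intervention-timing experiment
#'
#' Runs the same strategy with several intervention start cycles (default
#' 0, 10 and 20) plus the control and untreated arms, so PLI trajectories
#' can be compared across timings.
#'
#' @param config a `trial_config`.
#' @param strategy strategy name or object whose start cycle is varied.
#' @param start_cycles vector of start cycles.
#' @return A `virtual_trial` whose intervention conditions are named
#'   `<strategy>_start<k>`.
#' @export
timing_experiment <- function(config, strategy = "stim_excitatory",
                              start_cycles = c(0, 10, 20)) {
  base <- if (is.character(strategy)) builtin_strategy(strategy)
  else strategy
  conditions <- list(
    control = run_condition(config, builtin_strategy("control")),
    no_intervention = run_condition(config,
                                    builtin_strategy("no_intervention")))
  for (sc in start_cycles) {
    st <- new_strategy(sprintf("%s_start%d", base$name, sc),
                       base$Vd1, base$Vd2, sc, base$degeneration_on)
    conditions[[st$name]] <- run_condition(config, st)
  }
  structure(list(config = config, conditions = conditions,
                 metrics = dplyr::bind_rows(
                   lapply(conditions, function(c) c$metrics))),
            class = "virtual_trial")
}

#' Threshold sweep within a strategy family
#'
#' Runs one condition per threshold value (0.5-increment sweeps reproduce
#' the calibration analysis of the built-in strategies). For families that
#' target the excitatory population the swept value sets `Vd1`; for
#' inhibitory targets `Vd2`; for global families both.
#'
#' @param config a `trial_config`.
#' @param family one of the six intervention names.
#' @param vd_values threshold values (mV); refused outside \[4, 10\] unless
#'   `allow_extreme`.
#' @param start_cycle intervention start cycle.
#' @param allow_extreme override the plausibility range check.
#' @return A `virtual_trial` with conditions named `<family>_vd<value>`.
#' @export
vd_sweep <- function(config, family = "stim_excitatory",
                     vd_values = seq(4, 6.5, by = 0.5), start_cycle = 11,
                     allow_extreme = FALSE) {
  if (!family %in% setdiff(names(STRATEGY_TABLE),
                           c("control", "no_intervention"))) {
    abort(sprintf("unknown strategy family '%s'.", family))
  }
  if (!allow_extreme && !check_vd_range(vd_values)) {
    abort("sweep values outside [4, 10] mV; set `allow_extreme = TRUE`.")
  }
  conditions <- list(
    control = run_condition(config, builtin_strategy("control")),
    no_intervention = run_condition(config,
                                    builtin_strategy("no_intervention")))
  base <- STRATEGY_TABLE[[family]]
  targets_e <- grepl("excitatory|global", family)
  targets_i <- grepl("inhibitory|global", family)
  for (v in vd_values) {
    st <- new_strategy(sprintf("%s_vd%g", family, v),
                       if (targets_e) v else base$Vd1,
                       if (targets_i) v else base$Vd2,
                       start_cycle, TRUE)
    conditions[[st$name]] <- run_condition(config, st)
  }
  structure(list(config = config, conditions = conditions,
                 metrics = dplyr::bind_rows(
                   lapply(conditions, function(c) c$metrics))),
            class = "virtual_trial")
}
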