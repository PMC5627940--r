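BASELINE_VD <- 7

STRATEGY_TABLE <- list(
  control          = list(Vd1 = 7, Vd2 = 7,   degeneration_on = FALSE),
  no_intervention  = list(Vd1 = 7, Vd2 = 7,   degeneration_on = TRUE),
  global_stim      = list(Vd1 = 6, Vd2 = 6,   degeneration_on = TRUE),
  global_inhib     = list(Vd1 = 8, Vd2 = 8,   degeneration_on = TRUE),
  stim_excitatory  = list(Vd1 = 5, Vd2 = 7,   degeneration_on = TRUE),
  stim_inhibitory  = list(Vd1 = 7, Vd2 = 5,   degeneration_on = TRUE),
  inhib_excitatory = list(Vd1 = 8, Vd2 = 7,   degeneration_on = TRUE),
  inhib_inhibitory = list(Vd1 = 7, Vd2 = 6.5, degeneration_on = TRUE)
)

new_strategy <- function(name, Vd1, Vd2, start_cycle, degeneration_on) {
  structure(list(name = name, Vd1 = Vd1, Vd2 = Vd2,
                 start_cycle = start_cycle,
                 degeneration_on = degeneration_on),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy> %s: Vd1=%g, Vd2=%g mV from cycle %g (degeneration %s)\n",
              x$name, x$Vd1, x$Vd2, x$start_cycle,
              if (x$degeneration_on) "on" else "off"))
  invisible(x)
}

#' Built-in intervention strategies
#'
#' The eight named conditions: a healthy `control` (no degeneration), the
#' untreated `no_intervention` arm, and six excitability interventions that
#' re-set the threshold potentials globally from `start_cycle` onward:
#' `global_stim` (Vd1 = 6, Vd2 = 6), `global_inhib` (8, 8),
#' `stim_excitatory` (5, 7), `stim_inhibitory` (7, 5),
#' `inhib_excitatory` (8, 7) and `inhib_inhibitory` (7, 6.5). Thresholds are
#' constant once applied. The default start is cycle 11: ten degeneration
#' cycles run before therapy begins.
#'
#' @param name strategy name (see above).
#' @param start_cycle first cycle at which the thresholds apply.
#' @return A `strategy` object.
#' @examples
#' builtin_strategy("stim_excitatory")
#' @export
builtin_strategy <- function(name, start_cycle = 11) {
  if (!name %in% names(STRATEGY_TABLE)) {
    abort(sprintf("unknown strategy '%s'; valid names: %s",
                  name, paste(names(STRATEGY_TABLE), collapse = ", ")))
  }
  s <- STRATEGY_TABLE[[name]]
  new_strategy(name, s$Vd1, s$Vd2, start_cycle, s$degeneration_on)
}

#' Custom intervention strategy
#'
#' @param Vd1,Vd2 threshold potentials (mV) applied from `start_cycle`.
#' @param start_cycle first cycle at which the thresholds apply.
#' @param degeneration_on whether the degeneration process runs.
#' @param name label for reporting.
#' @param allow_extreme permit thresholds outside the plausible 4-10 mV
#'   band (such settings rapidly drive the network into non-functional
#'   states and are refused by default).
#' @export
custom_strategy <- function(Vd1, Vd2, start_cycle = 11,
                            degeneration_on = TRUE, name = "custom",
                            allow_extreme = FALSE) {
  if (!allow_extreme && !(check_vd_range(Vd1) && check_vd_range(Vd2))) {
    abort("Vd outside [4, 10] mV; set `allow_extreme = TRUE` to override.")
  }
  new_strategy(name, Vd1, Vd2, start_cycle, degeneration_on)
}

#' Apply a strategy's thresholds at a given cycle
#'
#' From `start_cycle` onward every node's `Vd1`/`Vd2` are set (globally and
#' uniformly) to the strategy's values; before that, the baseline is kept.
#' Application is idempotent.
#'
#' @param params `mass_params` (per-node thresholds allowed).
#' @param strategy a `strategy`.
#' @param cycle current virtual-time index.
#' @return Possibly modified `mass_params`.
#' @export
apply_strategy <- function(params, strategy, cycle) {
  if (cycle >= strategy$start_cycle) {
    params$Vd1 <- rep_len(strategy$Vd1, length(params$Vd1))
    params$Vd2 <- rep_len(strategy$Vd2, length(params$Vd2))
  }
  params
}

#' Check that a threshold potential is biologically plausible
#'
#' Thresholds below 4 mV or above 10 mV push the model into non-functional
#' states (functional shutdown or runaway, seizure-like activity) and are
#' flagged invalid.
#'
#' @param Vd threshold potential(s), mV.
#' @return `TRUE` if all values lie in \eqn{[4, 10]}.
#' @export
check_vd_range <- function(Vd) {
  if (any(!is.finite(Vd))) abort("`Vd` must be finite.")
  all(Vd >= 4 & Vd <= 10)
}
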