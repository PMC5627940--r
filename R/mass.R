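#' Neural mass parameters
#'
#' Bundles the parameters of a single alpha-rhythm neural mass: one lumped
#' excitatory and one lumped inhibitory population, coupled through sigmoid
#' rate functions and critically damped second-order synaptic filters with
#' kernels \eqn{h_e(t) = A a t e^{-at}} and \eqn{h_i(t) = B b t e^{-bt}}.
#'
#' The defaults are chosen so that an isolated mass sits at a subthreshold
#' fixed point (`Ve` near 5 mV) with a weak noise-driven alpha-band resonance
#' near 8.8 Hz, while a mass embedded in the default healthy network receives
#' enough recurrent excitatory drive to cross into a collective, near-critical
#' alpha limit cycle. Network-level alpha power and phase locking therefore
#' depend on intact structural coupling and collapse as the connectome
#' degenerates.
#'
#' @param A,B excitatory/inhibitory synaptic gain (mV).
#' @param a,b excitatory/inhibitory rate constants (1/s).
#' @param C1 excitatory-to-inhibitory coupling constant (dimensionless).
#' @param C2 inhibitory-to-excitatory coupling constant (dimensionless).
#' @param q maximum spike density (1/s).
#' @param r sigmoid steepness (1/mV).
#' @param Vd1,Vd2 threshold potentials of the excitatory/inhibitory
#'   populations (mV); scalar or one value per node. Lowering a threshold
#'   raises excitability. Baseline is 7 mV for both.
#' @param P_mean,P_sd mean and s.d. of the Gaussian thalamic input
#'   pulse-density noise (1/s); draws are truncated at 0.
#' @return An object of class `mass_params` (a validated named list).
#' @examples
#' p <- mass_params()
#' p$Vd1
#' @export
mass_params <- function(A = 10, B = 15.556, a = 120, b = 70,
                        C1 = 10, C2 = 62, q = 5, r = 0.56,
                        Vd1 = 7, Vd2 = 7,
                        P_mean = 86.04, P_sd = 12) {
  for (nm in c("A", "B", "a", "b", "q", "r")) {
    assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  assert_scalar_num(C1, "C1"); assert_scalar_num(C2, "C2")
  if (C1 < 0 || C2 < 0) abort("`C1` and `C2` must be >= 0.")
  assert_scalar_num(P_mean, "P_mean"); assert_scalar_num(P_sd, "P_sd")
  if (P_sd < 0) abort("`P_sd` must be >= 0.")
  if (!is.numeric(Vd1) || !is.numeric(Vd2) || any(!is.finite(Vd1)) ||
      any(!is.finite(Vd2))) {
    abort("`Vd1` and `Vd2` must be finite numeric (scalar or per node).")
  }
  structure(list(A = A, B = B, a = a, b = b, C1 = C1, C2 = C2,
                 q = q, r = r, Vd1 = Vd1, Vd2 = Vd2,
                 P_mean = P_mean, P_sd = P_sd),
            class = "mass_params")
}

#' @export
print.mass_params <- function(x, ...) {
  cat("<mass_params>\n")
  cat(sprintf("  synapses: A=%g mV, a=%g /s | B=%g mV, b=%g /s\n",
              x$A, x$a, x$B, x$b))
  cat(sprintf("  coupling: C1=%g, C2=%g | sigmoid: q=%g /s, r=%g /mV\n",
              x$C1, x$C2, x$q, x$r))
  cat(sprintf("  thresholds: Vd1=%s, Vd2=%s mV | input: P ~ N(%g, %g) /s\n",
              paste(unique(x$Vd1), collapse = "/"),
              paste(unique(x$Vd2), collapse = "/"), x$P_mean, x$P_sd))
  invisible(x)
}

#' State of a single neural mass
#'
#' @param Ve,Vi average excitatory/inhibitory membrane potential (mV).
#' @param ze,zi first-derivative auxiliary states of the two second-order
#'   synaptic filters (mV/s).
#' @param params `mass_params` used to derive the pulse densities.
#' @return Object of class `mass_state` with fields `Ve`, `Vi`, `E`, `I`,
#'   `ze`, `zi`.
#' @export
mass_state <- function(Ve = 0, Vi = 0, ze = 0, zi = 0, params = mass_params()) {
  vals <- c(Ve = Ve, Vi = Vi, ze = ze, zi = zi)
  if (any(!is.finite(vals))) abort("all state fields must be finite.")
  structure(list(Ve = Ve, Vi = Vi,
                 E = sigmoid_transfer(Ve, params$Vd1[1], params$q, params$r),
                 I = sigmoid_transfer(Vi, params$Vd2[1], params$q, params$r),
                 ze = ze, zi = zi),
            class = "mass_state")
}

#' Sigmoid membrane-potential-to-spike-density transfer
#'
#' Logistic transfer \eqn{S(V) = q / (1 + e^{r (V_d - V)})}. Output lies in
#' (0, q), increases with the membrane potential and decreases with the
#' threshold: lowering `Vd` makes the population more excitable.
#'
#' @param Vm membrane potential (mV); vectorized.
#' @param Vd threshold potential (mV), the sigmoid midpoint.
#' @param q maximum spike density (1/s).
#' @param r sigmoid steepness (1/mV).
#' @return Spike density (1/s), same length as `Vm`.
#' @examples
#' sigmoid_transfer(7, Vd = 7)  # midpoint: q/2
#' @export
sigmoid_transfer <- function(Vm, Vd, q = 5, r = 0.56) {
  if (any(!is.finite(Vm)) || any(!is.finite(Vd))) {
    abort("`Vm` and `Vd` must be finite.")
  }
  assert_scalar_num(q, "q", positive = TRUE)
  assert_scalar_num(r, "r", positive = TRUE)
  q / (1 + exp(r * (Vd - Vm)))
}

# Exact one-step update of a critically damped second-order filter
# y'' = G*k*u - 2k y' - k^2 y under piecewise-constant drive u.
filter_step <- function(y, z, u, G, k, dt) {
  ed <- exp(-k * dt)
  yss <- (G / k) * u
  dy <- y - yss
  c(y = yss + ed * (1 + k * dt) * dy + ed * dt * z,
    z = -k^2 * dt * ed * dy + ed * (1 - k * dt) * z)
}

#' Advance the two synaptic impulse-response filters by one step
#'
#' Applies the exact matrix-exponential one-step map of both critically
#' damped second-order filters, treating the drives as constant over the
#' step. A constant drive converges to the filter DC gain `A/a` (resp.
#' `B/b`) times the drive; an impulse peaks at `t = 1/a` with height `A/e`.
#'
#' @param state a `mass_state`.
#' @param drive_e,drive_i pulse-density drive of the excitatory/inhibitory
#'   filter (1/s).
#' @param params `mass_params`.
#' @param dt time step (s); must satisfy `dt > 0` and be well below
#'   `1/max(a, b)` for the sampled drive to resolve the kernels.
#' @return Updated `mass_state`.
#' @export
impulse_response_step <- function(state, drive_e, drive_i, params, dt) {
  assert_scalar_num(dt, "dt", positive = TRUE)
  assert_scalar_num(drive_e, "drive_e"); assert_scalar_num(drive_i, "drive_i")
  e <- filter_step(state$Ve, state$ze, drive_e, params$A, params$a, dt)
  i <- filter_step(state$Vi, state$zi, drive_i, params$B, params$b, dt)
  if (any(!is.finite(c(e, i)))) {
    abort(sprintf(
      "filter update diverged (dt = %g with rate constants a = %g, b = %g).",
      dt, params$a, params$b))
  }
  state$Ve <- unname(e["y"]); state$ze <- unname(e["z"])
  state$Vi <- unname(i["y"]); state$zi <- unname(i["z"])
  state$E <- sigmoid_transfer(state$Ve, params$Vd1[1], params$q, params$r)
  state$I <- sigmoid_transfer(state$Vi, params$Vd2[1], params$q, params$r)
  state
}

#' One closed-loop integration step of a single neural mass
#'
#' Computes the pulse densities `E = S1(Ve)`, `I = S2(Vi)`, drives the
#' excitatory filter with thalamic noise plus external input minus `C2 * I`,
#' the inhibitory filter with `C1 * E`, and advances both filters.
#'
#' @param state a `mass_state`.
#' @param external external excitatory pulse density from other masses (1/s).
#' @param params `mass_params`.
#' @param dt time step (s).
#' @param rng_draw standard-normal noise sample; the realized thalamic input
#'   is `max(0, P_mean + P_sd * rng_draw)`.
#' @return Updated `mass_state`.
#' @export
step_mass <- function(state, external, params, dt, rng_draw = 0) {
  P <- max(0, params$P_mean + params$P_sd * rng_draw)
  E <- sigmoid_transfer(state$Ve, params$Vd1[1], params$q, params$r)
  I <- sigmoid_transfer(state$Vi, params$Vd2[1], params$q, params$r)
  out <- impulse_response_step(state,
                               drive_e = P + external - params$C2 * I,
                               drive_i = params$C1 * E,
                               params = params, dt = dt)
  out
}
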