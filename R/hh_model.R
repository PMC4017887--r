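# Classical Hodgkin-Huxley action-potential model.
# State: V (mV), m, n, h.  Time in ms, currents in uA/cm2.

.hh_state <- function(V, m, n, h) c(V = V, m = m, n = n, h = h)

#' Right-hand side of the classical Hodgkin-Huxley model
#'
#' Reference (plain R) implementation of the four time derivatives.
#' For genotype `"mutant"` the h-equation is slowed/sped by the
#' voltage-dependent factor \eqn{\tau_h^*(V)/\tau_h(V)}; with fold
#' change `f = 1` the right-hand side is identical to wild-type.
#'
#' @param state Named numeric vector `(V, m, n, h)`.
#' @param I_app Applied current (uA/cm2).
#' @param params [hh_parameters()].
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param f Mutant fold-change (default 3).
#' @param spec Optional explicit [mutant_tau_spec()].
#' @return Named vector of derivatives `(V, m, n, h)` per ms.
#' @export
hh_rhs <- function(state, I_app = 0, params = hh_parameters(),
                   genotype = "wild-type", f = 3, spec = NULL) {
  genotype <- .check_genotype(genotype)
  V <- state[["V"]]; m <- state[["m"]]; n <- state[["n"]]; h <- state[["h"]]
  rm <- rate_constants(V, "m"); rn <- rate_constants(V, "n")
  rh <- rate_constants(V, "h")
  I_Na <- params$gbar_Na * m^3 * h * (V - params$E_Na)
  I_K  <- params$gbar_K * n^4 * (V - params$E_K)
  I_l  <- params$g_l * (V - params$E_leak)
  dh <- rh$alpha * (1 - h) - rh$beta * h
  if (genotype == "mutant") {
    if (is.null(spec)) spec <- mutant_tau_spec(f = f, variant = "classical")
    dh <- dh / mutant_tau_factor(V, spec)
  }
  c(V = -(I_Na + I_K + I_l - I_app) / params$C_m,
    m = rm$alpha * (1 - m) - rm$beta * m,
    n = rn$alpha * (1 - n) - rn$beta * n,
    h = dh)
}

#' Resting state of the classical model
#'
#' The equilibrium is found by a root search on the steady-state
#' current-voltage relation (gates at \eqn{x_\infty(V)}); it does not
#' depend on the genotype because the mutant rescaling moves only
#' \eqn{\tau_h}, not \eqn{h_\infty}.
#'
#' @param I_app Applied current (uA/cm2).
#' @param params [hh_parameters()].
#' @param interval Voltage bracket for the root search (mV).
#' @return Named state vector `(V, m, n, h)` with right-hand-side norm
#'   below 1e-10.
#' @export
hh_rest <- function(I_app = 0, params = hh_parameters(),
                    interval = c(-90, 50)) {
  iv <- function(V) {
    m <- .xinf(V, "m"); n <- .xinf(V, "n"); h <- .xinf(V, "h")
    params$gbar_Na * m^3 * h * (V - params$E_Na) +
      params$gbar_K * n^4 * (V - params$E_K) +
      params$g_l * (V - params$E_leak) - I_app
  }
  V <- uniroot(iv, interval, tol = 1e-13)$root
  .hh_state(V, .xinf(V, "m"), .xinf(V, "n"), .xinf(V, "h"))
}

.hh_parms_vec <- function(params, genotype, f = 3, spec = NULL,
                          I_const = 0, pulse = NULL) {
  mp <- .mutant_parms(genotype, f, "classical", spec)
  pu <- if (is.null(pulse)) c(0, 0, 0) else
    c(pulse$amplitude, pulse$onset, pulse$onset + pulse$duration)
  c(params$C_m, params$gbar_Na, params$gbar_K, params$g_l,
    params$E_Na, params$E_K, params$E_leak,
    mp, I_const, pu)
}

#' Simulate the classical Hodgkin-Huxley model
#'
#' Integrates the model under a stimulus schedule (constant current
#' and/or rectangular pulse) with the compiled right-hand side and the
#' stiff-capable adaptive solver.
#'
#' @param schedule A `stimulus_schedule` with unit `"ms"` (or `NULL`
#'   for no stimulation).
#' @param t_end_ms Simulation horizon (ms).
#' @param dt_ms Output sampling interval (ms); default 0.05.
#' @param init Initial state; defaults to the resting state at the
#'   schedule's constant current 0.
#' @param params [hh_parameters()].
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param f Mutant fold-change.
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `time_ms`, `V_mV`, `m`, `n`, `h`,
#'   `I_app_uA_cm2`; gating bounds are asserted on every sample.
#' @export
simulate_hh <- function(schedule = NULL, t_end_ms = 100, dt_ms = 0.05,
                        init = NULL, params = hh_parameters(),
                        genotype = "wild-type", f = 3,
                        rtol = .default_rtol, atol = .default_atol) {
  genotype <- .check_genotype(genotype)
  if (is.null(schedule)) schedule <- make_constant_current(0, "ms")
  stopifnot(schedule$unit == "ms", is.null(schedule$pump),
            is.null(schedule$t_off))
  if (is.null(init)) init <- hh_rest(params = params)
  pv <- .hh_parms_vec(params, genotype, f,
                      I_const = schedule$I_const, pulse = schedule$pulse)
  out <- .integrate_segments(init, seq(0, t_end_ms, by = dt_ms), pv,
                             "hhsd_deriv_hh", "hhsd_init_hh",
                             nout = 1, outnames = "I_app",
                             breaks = .schedule_breaks(schedule),
                             rtol = rtol, atol = atol)
  trace <- data.frame(time_ms = out[, 1], V_mV = out[, 2], m = out[, 3],
                      n = out[, 4], h = out[, 5], I_app_uA_cm2 = out[, 6])
  .check_gating_bounds(trace, c("m", "n", "h"))
  attr(trace, "genotype") <- genotype
  attr(trace, "model") <- "hh"
  trace
}

#' Action-potential features of a classical-model trace
#'
#' @param trace A [simulate_hh()] trace.
#' @param schedule The schedule used (for the pulse offset).
#' @param threshold_mV Spike threshold (mV).
#' @return List with `spike_times_ms`, `time_to_peak_ms` (from pulse
#'   offset to the voltage maximum, `NA` without a pulse) and
#'   `plateau_ms` (mean time above 0 mV per spike).
#' @export
ap_features <- function(trace, schedule = NULL, threshold_mV = 0) {
  sp <- detect_spikes(trace$time_ms, trace$V_mV, threshold_mV,
                      refractory = 1)
  ttp <- NA_real_
  if (!is.null(schedule) && !is.null(schedule$pulse)) {
    off <- schedule$pulse$onset + schedule$pulse$duration
    post <- trace[trace$time_ms >= off, ]
    ttp <- post$time_ms[which.max(post$V_mV)] - off
  }
  above <- trace$V_mV > 0
  dt <- diff(trace$time_ms[1:2])
  plateau <- if (length(sp) > 0) sum(above) * dt / length(sp) else 0
  list(spike_times_ms = sp, time_to_peak_ms = ttp, plateau_ms = plateau)
}
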