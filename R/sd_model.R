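# Spreading depression model: Hodgkin-Huxley membrane with dynamic
# potassium concentrations, electroneutrality-derived sodium, Na/K
# pump and potassium bath coupling.
# State: V (mV), n, h, K_i, K_e (mM).  Time in ms internally; the
# user-facing trace and protocol arguments are in seconds.

#' Nernst reversal potential
#'
#' \eqn{E = (26.64/z)\,\ln(c_e/c_i)} mV, with the model's fixed
#' prefactor of 26.64 mV.
#'
#' @param z Ion valence (+1 for Na+/K+, -1 for Cl-).
#' @param c_e,c_i Extra-/intracellular concentrations (mM, > 0).
#' @return Reversal potential (mV).
#' @examples
#' nernst(1, 4, 130.99)   # potassium: -92.94 mV
#' nernst(1, 120, 27)     # sodium:     39.74 mV
#' @export
nernst <- function(z, c_e, c_i) {
  if (any(c_e <= 0) || any(c_i <= 0))
    stop("concentrations must be positive")
  26.64 / z * log(c_e / c_i)
}

#' Na/K-ATPase pump current
#'
#' \eqn{I_p = \rho\,(1+e^{(25-Na_i)/3})^{-1}(1+e^{5.5-K_e})^{-1}}:
#' sigmoidal in both substrates, bounded by \eqn{(0, \rho)} and
#' monotone increasing in intracellular sodium and extracellular
#' potassium.
#'
#' @param Na_i Intracellular sodium (mM).
#' @param K_e Extracellular potassium (mM).
#' @param rho Maximal pump current (uA/cm2, >= 0).
#' @return Pump current (uA/cm2).
#' @export
pump_current <- function(Na_i, K_e, rho) {
  stopifnot(all(rho >= 0))
  rho / ((1 + exp((25 - Na_i) / 3)) * (1 + exp(5.5 - K_e)))
}

# sodium concentrations and reversal potentials implied by the
# electroneutrality constraint
.sd_derived <- function(K_i, K_e, params) {
  Na_i <- params$Na_i0 - K_i + params$K_i0
  Na_e <- params$vol_ratio * (params$Na_i0 - Na_i) + params$Na_e0
  list(Na_i = Na_i, Na_e = Na_e,
       E_Na = nernst(1, Na_e, Na_i), E_K = nernst(1, K_e, K_i))
}

#' Right-hand side of the spreading depression model
#'
#' Reference (plain R) implementation.  The m-gate is adiabatic
#' (\eqn{m = m_\infty(V)}); n and h are dynamic with the shifted rate
#' functions and timescale factor \eqn{\phi}; sodium concentrations
#' are recomputed algebraically from electroneutrality at every
#' evaluation; the pump enters the sodium and potassium currents with
#' 3:2 stoichiometry.
#'
#' @param state Named numeric vector `(V, n, h, K_i, K_e)`.
#' @param pump_scale Pump scaling factor \eqn{s_p \in [0, 1]}.
#' @param K_bath Bath potassium (mM); defaults to the parameter value.
#' @param I_app Applied current (uA/cm2).
#' @param params [sd_parameters()].
#' @param genotype,f,spec Genotype and mutant gating specification
#'   (shifted variant).
#' @return Named vector of derivatives (per ms).
#' @export
sd_rhs <- function(state, pump_scale = 1, K_bath = NULL, I_app = 0,
                   params = sd_parameters(), genotype = "wild-type",
                   f = 3, spec = NULL) {
  genotype <- .check_genotype(genotype)
  stopifnot(pump_scale >= 0, pump_scale <= 1)
  if (is.null(K_bath)) K_bath <- params$K_bath
  V <- state[["V"]]; n <- state[["n"]]; h <- state[["h"]]
  K_i <- state[["K_i"]]; K_e <- state[["K_e"]]
  d <- .sd_derived(K_i, K_e, params)
  m <- .xinf(V, "m", "shifted")
  I_p <- pump_scale * pump_current(d$Na_i, K_e, params$rho)
  I_Na <- (params$g_Na_l + params$g_Na_g * m^3 * h) * (V - d$E_Na) +
    3 * I_p
  I_K <- (params$g_K_l + params$g_K_g * n^4) * (V - d$E_K) - 2 * I_p
  rn <- rate_constants(V, "n", "shifted")
  rh <- rate_constants(V, "h", "shifted")
  dh <- params$phi * (rh$alpha * (1 - h) - rh$beta * h)
  if (genotype == "mutant") {
    if (is.null(spec)) spec <- mutant_tau_spec(f = f, variant = "shifted")
    dh <- dh / mutant_tau_factor(V, spec)
  }
  c(V = -(I_Na + I_K - I_app) / params$C_m,
    n = params$phi * (rn$alpha * (1 - n) - rn$beta * n),
    h = dh,
    K_i = -params$conv_i * I_K,
    K_e = params$conv_e * I_K + params$F_diff * (K_bath - K_e))
}

.sd_cache <- new.env(parent = emptyenv())

#' Resting state of the spreading depression model
#'
#' Obtained by relaxing the unperturbed model for 200 s from the
#' reference concentrations and polishing with damped Newton steps on
#' the full right-hand side (finite-difference Jacobian).  The result
#' has right-hand-side norm below 1e-8 and sits at the reference
#' concentrations: at rest the bath flux vanishes (K_e equals K_bath)
#' and both membrane currents are zero.  The resting state does not
#' depend on the genotype.
#'
#' @param params [sd_parameters()].
#' @return Named state vector `(V, n, h, K_i, K_e)`.
#' @export
sd_rest <- function(params = sd_parameters()) {
  key <- paste(format(unlist(params), digits = 15), collapse = "|")
  if (!is.null(.sd_cache[[key]])) return(.sd_cache[[key]])
  y0 <- c(V = -68, n = .xinf(-68, "n", "shifted"),
          h = .xinf(-68, "h", "shifted"),
          K_i = params$K_i0, K_e = params$K_e0)
  pv <- .sd_parms_vec(params, "wild-type")
  out <- .integrate_segments(y0, c(0, 2e5), pv, "hhsd_deriv_sd",
                             "hhsd_init_sd", nout = 6,
                             outnames = .sd_outnames,
                             rtol = 1e-10, atol = 1e-12)
  y <- setNames(as.numeric(out[nrow(out), 2:6]), names(y0))
  rhs <- function(x) sd_rhs(setNames(x, names(y0)), params = params)
  y <- .newton_polish(rhs, y)
  if (max(abs(rhs(y))) > 1e-8)
    stop("spreading depression model failed to settle to rest")
  .sd_cache[[key]] <- y
  y
}

# a few damped Newton steps with a central finite-difference Jacobian
.newton_polish <- function(rhs, y, iter = 8, fd = 1e-7) {
  for (k in seq_len(iter)) {
    r <- rhs(y)
    if (max(abs(r)) < 1e-12) break
    J <- .fd_jacobian(rhs, y, fd)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    cand <- y - step
    if (max(abs(rhs(cand))) < max(abs(r))) y <- cand else break
  }
  y
}

.fd_jacobian <- function(rhs, y, fd = 1e-6) {
  nn <- length(y)
  J <- matrix(0, nn, nn)
  for (j in seq_len(nn)) {
    e <- rep(0, nn); e[j] <- fd
    J[, j] <- (rhs(y + e) - rhs(y - e)) / (2 * fd)
  }
  J
}

.sd_outnames <- c("Na_i", "Na_e", "E_Na", "E_K", "pump_scale", "I_p")

.sd_parms_vec <- function(params, genotype, f = 3, spec = NULL,
                          I_const = 0, pulse = NULL, pump = NULL,
                          K_bath = NULL) {
  mp <- .mutant_parms(genotype, f, "shifted", spec)
  pu <- if (is.null(pulse)) c(0, 0, 0) else
    c(pulse$amplitude, pulse$onset * 1e3,
      (pulse$onset + pulse$duration) * 1e3)          # s -> ms
  pk <- if (is.null(pump)) c(-1, 0, 0, 0, 1) else
    c(.pump_knots(pump) * 1e3, pump$floor)           # s -> ms
  if (is.null(K_bath)) K_bath <- params$K_bath
  c(params$C_m, params$g_Na_l, params$g_Na_g, params$g_K_l,
    params$g_K_g, params$conv_i, params$conv_e, params$rho,
    params$phi, params$F_diff, K_bath,
    params$Na_i0, params$Na_e0, params$K_i0, params$vol_ratio,
    mp, I_const, pu, pk)
}

#' Simulate the spreading depression model
#'
#' @param schedule A `stimulus_schedule` with unit `"s"` (pump
#'   interruption and/or applied current), or `NULL` for the
#'   unperturbed model.
#' @param t_end_s Simulation horizon (s).
#' @param dt_ms Output sampling interval (ms); default 2.
#' @param init Initial state; defaults to [sd_rest()].
#' @param params [sd_parameters()].
#' @param genotype,f Genotype and mutant fold-change.
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `time_s`, `V_mV`, `n`, `h`,
#'   `K_i_mM`, `K_e_mM`, `Na_i_mM`, `Na_e_mM`, `E_Na_mV`, `E_K_mV`,
#'   `pump_scale`; gating bounds asserted on every sample.
#' @export
simulate_sd <- function(schedule = NULL, t_end_s = 100, dt_ms = 2,
                        init = NULL, params = sd_parameters(),
                        genotype = "wild-type", f = 3,
                        rtol = .default_rtol, atol = .default_atol) {
  genotype <- .check_genotype(genotype)
  if (is.null(schedule)) schedule <- make_constant_current(0, "s")
  stopifnot(schedule$unit == "s", is.null(schedule$t_off))
  if (is.null(init)) init <- sd_rest(params)
  pv <- .sd_parms_vec(params, genotype, f,
                      I_const = schedule$I_const,
                      pulse = schedule$pulse, pump = schedule$pump,
                      K_bath = schedule$K_bath)
  out <- .integrate_segments(init, seq(0, t_end_s * 1e3, by = dt_ms),
                             pv, "hhsd_deriv_sd", "hhsd_init_sd",
                             nout = 6, outnames = .sd_outnames,
                             breaks = .schedule_breaks(schedule, 1e3),
                             rtol = rtol, atol = atol)
  trace <- data.frame(time_s = out[, 1] / 1e3, V_mV = out[, 2],
                      n = out[, 3], h = out[, 4],
                      K_i_mM = out[, 5], K_e_mM = out[, 6],
                      Na_i_mM = out[, 7], Na_e_mM = out[, 8],
                      E_Na_mV = out[, 9], E_K_mV = out[, 10],
                      pump_scale = out[, 11])
  .check_gating_bounds(trace, c("n", "h"))
  attr(trace, "genotype") <- genotype
  attr(trace, "model") <- "sd"
  trace
}

#' Run one pump-interruption experiment
#'
#' From the rested model, the maximal pump rate is ramped down to 20%
#' over 10 s, held for `hold_s`, ramped back over 5 s, and the outcome
#' is classified as full recovery or spreading depression (all-or-none
#' criterion, see [classify_outcome()]).
#'
#' @param hold_s Hold duration at the reduced pump rate (s).
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param params [sd_parameters()].
#' @param f Mutant fold-change.
#' @param schedule Optional custom pump schedule; by default
#'   [make_pump_interruption()] with the given `hold_s`.
#' @param t_post_s Horizon beyond the end of the up-ramp (s).
#' @param dt_ms Output sampling interval (ms).
#' @param ... Passed to [classify_outcome()].
#' @return List with elements `trace`, `outcome` (`"SD"` or
#'   `"recovered"`, with the per-criterion labels as attribute),
#'   `schedule` and `rest`.
#' @export
run_pump_interruption <- function(hold_s, genotype = "wild-type",
                                  params = sd_parameters(), f = 3,
                                  schedule = NULL, t_post_s = 45,
                                  dt_ms = 2, ...) {
  genotype <- .check_genotype(genotype)
  if (is.null(schedule)) schedule <- make_pump_interruption(hold_s)
  rest <- sd_rest(params)
  t_end <- .pump_knots(schedule$pump)[4] + t_post_s
  trace <- simulate_sd(schedule, t_end_s = t_end, dt_ms = dt_ms,
                       init = rest, params = params,
                       genotype = genotype, f = f)
  outcome <- classify_outcome(trace, schedule, rest[["V"]], ...)
  list(trace = trace, outcome = outcome, schedule = schedule,
       rest = rest)
}

#' Minimal non-tolerated pump-interruption duration
#'
#' Searches the 0.1 s grid of hold durations for the smallest window
#' whose outcome is spreading depression.  The outcome is all-or-none
#' and monotone in the hold duration, which the search exploits by
#' bisection over the grid; monotonicity is re-asserted on the two
#' grid points below the returned threshold.
#'
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param step_s Grid resolution (s); default 0.1.
#' @param lower_s,upper_s Search bracket (s).  An error is raised if no
#'   SD outcome is found at `upper_s` (cap 60 s by default).
#' @param params,f Model parameters and mutant fold-change.
#' @param dt_ms Sampling interval used for the classification runs.
#' @param verify_monotone Re-check the two grid points below the
#'   threshold (default TRUE).
#' @param ... Passed to [run_pump_interruption()].
#' @return List with `threshold_s`, the classified `outcomes` (named by
#'   hold duration) and the threshold run itself (`run`).
#' @export
find_sd_threshold <- function(genotype = "wild-type", step_s = 0.1,
                              lower_s = 0, upper_s = 30,
                              params = sd_parameters(), f = 3,
                              dt_ms = 5, verify_monotone = TRUE, ...) {
  stopifnot(step_s > 0, upper_s <= 60, upper_s > lower_s)
  outcomes <- c()
  probe <- function(hold) {
    r <- run_pump_interruption(hold, genotype, params, f,
                               dt_ms = dt_ms, ...)
    outcomes[sprintf("%.1f", hold)] <<- as.character(r$outcome)
    list(sd = as.character(r$outcome) == "SD", run = r)
  }
  # bisection in integer grid units so holds stay exactly on the grid
  lo <- round(lower_s / step_s)
  hi <- round(upper_s / step_s)
  top <- probe(round(hi * step_s, 10))
  if (!top$sd)
    stop(sprintf("no spreading depression up to a %.1f s hold", upper_s))
  run_hi <- top$run
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    p <- probe(round(mid * step_s, 10))
    if (p$sd) {
      hi <- mid
      run_hi <- p$run
    } else {
      lo <- mid
    }
  }
  if (verify_monotone && lo - 1 >= round(lower_s / step_s)) {
    below <- probe(round(max(lower_s, (lo - 1) * step_s), 10))
    if (below$sd)
      stop("outcome not monotone near the threshold")
  }
  list(threshold_s = round(hi * step_s, 10), outcomes = outcomes,
       run = run_hi)
}

#' Critical time window of a supra-threshold run
#'
#' The critical window opens when the pump-rate recovery (the up-ramp
#' from 20% back to 100%) starts and closes at the onset of the
#' excitation block, taken as the last detected spike before the
#' sustained depolarization.
#'
#' During gradient rundown the sodium reversal potential collapses and
#' the terminal spikes of the burst no longer overshoot 0 mV; the
#' block-onset detector therefore uses a lower spike threshold
#' (default -20 mV) than the general-purpose action-potential
#' criterion.
#'
#' @param trace A [simulate_sd()] trace of a run classified as SD.
#' @param schedule The pump-interruption schedule of the run.
#' @param threshold_mV Spike threshold for block-onset detection (mV);
#'   default -20.
#' @return Window duration (s).  Errors if the trace contains no
#'   excitation block (sub-threshold run).
#' @export
critical_window <- function(trace, schedule, threshold_mV = -20) {
  stopifnot(!is.null(schedule$pump))
  k <- .pump_knots(schedule$pump)
  sp <- detect_spikes(trace$time_s, trace$V_mV, threshold_mV,
                      refractory = 1e-3)
  if (length(sp) == 0)
    stop("no spikes in trace; cannot locate the excitation block")
  # block onset = last spike, valid only if depolarization is sustained
  tail_ek <- trace$E_K_mV[trace$time_s > max(sp) + 2]
  if (length(tail_ek) == 0 || !all(tail_ek[seq_len(min(100, length(tail_ek)))] > -60))
    stop("no excitation block: the run did not end in sustained depolarization")
  max(sp) - k[3]
}
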