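# Anoxic depolarization model: explicit intra-/extracellular Na+, K+
# and Cl- dynamics, glial potassium buffering and blood diffusion.
# State: V (mV), n, h, Na_i, Na_e, K_i, K_e, Cl_i, Cl_e (mM).
# Time base is seconds (the rate parameters are per second); the
# membrane and gating dynamics are per-ms and bridged explicitly.

#' Glial potassium buffering flux
#'
#' \eqn{I_g = G\,(1+e^{(18-K_e)/2.5})^{-1}}: sigmoidal in extracellular
#' potassium, bounded by \eqn{(0, G)} and monotone increasing.
#'
#' @param K_e Extracellular potassium (mM).
#' @param G Maximal buffering rate (mM/s, >= 0).
#' @return Buffering flux (mM/s).
#' @export
glial_buffering <- function(K_e, G) {
  stopifnot(all(G >= 0))
  G / (1 + exp((18 - K_e) / 2.5))
}

#' Potassium diffusion to the blood
#'
#' \eqn{I_d = \epsilon (K_e - k_\infty)}: linear, vanishing at the
#' blood concentration.
#'
#' @param K_e Extracellular potassium (mM).
#' @param eps Diffusion rate (1/s).
#' @param k_inf Blood potassium (mM).
#' @return Diffusive flux (mM/s).
#' @export
blood_diffusion <- function(K_e, eps, k_inf) {
  eps * (K_e - k_inf)
}

#' Right-hand side of the anoxia model
#'
#' Reference (plain R) implementation.  Membrane currents (uA/cm2) are
#' converted to concentration fluxes by the factor A/(VF) (mM/s per
#' uA/cm2); extracellular derivatives carry the volume ratio
#' \eqn{\beta}.  For the chloride ion (valence -1) an outward positive
#' membrane current is an inward chloride flux, so its concentration
#' derivatives carry the opposite sign to the cations.  When `switch_on
#' = FALSE` the pump, glial and diffusion terms are all zero.
#'
#' @param state Named vector
#'   `(V, n, h, Na_i, Na_e, K_i, K_e, Cl_i, Cl_e)`.
#' @param switch_on Logical; energy-dependent clearance active?
#' @param I_app Applied current (uA/cm2).
#' @param params [anoxia_parameters()].
#' @param genotype,f,spec Genotype and mutant gating specification
#'   (shifted variant).
#' @return Named vector of derivatives (per s).
#' @export
anoxia_rhs <- function(state, switch_on = TRUE, I_app = 0,
                       params = anoxia_parameters(),
                       genotype = "wild-type", f = 3, spec = NULL) {
  genotype <- .check_genotype(genotype)
  V <- state[["V"]]; n <- state[["n"]]; h <- state[["h"]]
  Na_i <- state[["Na_i"]]; Na_e <- state[["Na_e"]]
  K_i <- state[["K_i"]]; K_e <- state[["K_e"]]
  Cl_i <- state[["Cl_i"]]; Cl_e <- state[["Cl_e"]]
  E_Na <- nernst(1, Na_e, Na_i)
  E_K <- nernst(1, K_e, K_i)
  E_Cl <- nernst(-1, Cl_e, Cl_i)
  m <- .xinf(V, "m", "shifted")
  sw <- as.numeric(switch_on)
  I_p <- sw * pump_current(Na_i, K_e, params$rho)
  I_g <- sw * glial_buffering(K_e, params$G)
  I_d <- sw * blood_diffusion(K_e, params$eps, params$k_inf)
  I_Na <- (params$g_Na_l + params$g_Na_g * m^3 * h) * (V - E_Na) +
    3 * I_p
  I_K <- (params$g_K_l + params$g_K_g * n^4) * (V - E_K) - 2 * I_p
  I_Cl <- params$g_Cl_l * (V - E_Cl)
  rn <- rate_constants(V, "n", "shifted")
  rh <- rate_constants(V, "h", "shifted")
  dh <- 1e3 * params$phi * (rh$alpha * (1 - h) - rh$beta * h)
  if (genotype == "mutant") {
    if (is.null(spec)) spec <- mutant_tau_spec(f = f, variant = "shifted")
    dh <- dh / mutant_tau_factor(V, spec)
  }
  cv <- params$conv
  c(V = -1e3 * (I_Na + I_K + I_Cl - I_app) / params$C_m,
    n = 1e3 * params$phi * (rn$alpha * (1 - n) - rn$beta * n),
    h = dh,
    Na_i = -cv * I_Na, Na_e = params$beta * cv * I_Na,
    K_i = -cv * I_K,
    K_e = params$beta * cv * I_K - I_g - I_d,
    Cl_i = cv * I_Cl, Cl_e = -params$beta * cv * I_Cl)
}

.anoxia_outnames <- c("E_Na", "E_K", "E_Cl", "switch_on")

.anoxia_parms_vec <- function(params, genotype, f = 3, spec = NULL,
                              I_const = 0, pulse = NULL, t_off = NULL) {
  mp <- .mutant_parms(genotype, f, "shifted", spec)
  pu <- if (is.null(pulse)) c(0, 0, 0) else
    c(pulse$amplitude, pulse$onset, pulse$onset + pulse$duration)
  c(params$C_m, params$g_Na_l, params$g_Na_g, params$g_K_l,
    params$g_K_g, params$g_Cl_l, params$conv, params$beta, params$rho,
    params$phi, params$G, params$eps, params$k_inf,
    mp, I_const, pu, if (is.null(t_off)) -1 else t_off)
}

.anoxia_cache <- new.env(parent = emptyenv())

#' Resting state of the anoxia model
#'
#' Obtained by relaxing the unperturbed model from the reference
#' concentrations for 5000 s (the chloride equilibration time constant
#' is of the order of 100 s).  Total sodium and chloride
#' (\eqn{c_i + c_e/\beta}) are conserved along the relaxation; at rest
#' all three membrane currents vanish (in particular E_Cl equals the
#' resting potential) and glial buffering balances blood diffusion.
#' The derivative norm at the returned state is below 1e-6.
#'
#' @param params [anoxia_parameters()].
#' @return Named state vector.
#' @export
anoxia_rest <- function(params = anoxia_parameters()) {
  key <- paste(format(unlist(params), digits = 15), collapse = "|")
  if (!is.null(.anoxia_cache[[key]])) return(.anoxia_cache[[key]])
  y0 <- c(V = -68, n = .xinf(-68, "n", "shifted"),
          h = .xinf(-68, "h", "shifted"),
          Na_i = params$Na_i0, Na_e = params$Na_e0,
          K_i = params$K_i0, K_e = params$K_e0,
          Cl_i = params$Cl_i0, Cl_e = params$Cl_e0)
  pv <- .anoxia_parms_vec(params, "wild-type")
  out <- .integrate_segments(y0, c(0, 5000), pv, "hhsd_deriv_anoxia",
                             "hhsd_init_anoxia", nout = 4,
                             outnames = .anoxia_outnames,
                             rtol = 1e-10, atol = 1e-12)
  y <- setNames(as.numeric(out[nrow(out), 2:10]), names(y0))
  res <- max(abs(anoxia_rhs(y, params = params)))
  if (res > 1e-8)
    stop(sprintf("anoxia model failed to settle (residual %.3g)", res))
  .anoxia_cache[[key]] <- y
  y
}

#' Simulate the anoxia model
#'
#' @param schedule A `stimulus_schedule` with unit `"s"`; use
#'   [make_anoxia_switch()] for the total energy shut-off.
#' @param t_end_s Simulation horizon (s).
#' @param dt_ms Output sampling interval (ms); default 0.5.
#' @param init Initial state; defaults to [anoxia_rest()].
#' @param params [anoxia_parameters()].
#' @param genotype,f Genotype and mutant fold-change.
#' @param rtol,atol Solver tolerances.
#' @return Data frame with `time_s`, `V_mV`, `n`, `h`, the six ion
#'   concentrations (mM), three reversal potentials (mV) and the
#'   switch state.
#' @export
simulate_anoxia <- function(schedule = NULL, t_end_s = 60, dt_ms = 0.5,
                            init = NULL, params = anoxia_parameters(),
                            genotype = "wild-type", f = 3,
                            rtol = .default_rtol, atol = .default_atol) {
  genotype <- .check_genotype(genotype)
  if (is.null(schedule)) schedule <- make_constant_current(0, "s")
  stopifnot(schedule$unit == "s", is.null(schedule$pump))
  if (is.null(init)) init <- anoxia_rest(params)
  pv <- .anoxia_parms_vec(params, genotype, f,
                          I_const = schedule$I_const,
                          pulse = schedule$pulse,
                          t_off = schedule$t_off)
  out <- .integrate_segments(init, seq(0, t_end_s, by = dt_ms / 1e3),
                             pv, "hhsd_deriv_anoxia", "hhsd_init_anoxia",
                             nout = 4, outnames = .anoxia_outnames,
                             breaks = .schedule_breaks(schedule),
                             rtol = rtol, atol = atol)
  trace <- data.frame(time_s = out[, 1], V_mV = out[, 2], n = out[, 3],
                      h = out[, 4], Na_i_mM = out[, 5],
                      Na_e_mM = out[, 6], K_i_mM = out[, 7],
                      K_e_mM = out[, 8], Cl_i_mM = out[, 9],
                      Cl_e_mM = out[, 10], E_Na_mV = out[, 11],
                      E_K_mV = out[, 12], E_Cl_mV = out[, 13],
                      switch_on = out[, 14])
  .check_gating_bounds(trace, c("n", "h"))
  attr(trace, "genotype") <- genotype
  attr(trace, "model") <- "anoxia"
  trace
}

#' Total energy shut-off ("decapitation") experiment
#'
#' From rest, all pump, glial and diffusion terms are switched off at
#' `t_off_s`.  The membrane potential rises gradually for tens of
#' seconds, reaches the firing threshold, produces a terminal burst of
#' spiking, and enters the depolarization (excitation) block.
#'
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param params [anoxia_parameters()].
#' @param t_off_s Switch-off time (s); default 5.
#' @param t_end_s Simulation horizon (s); the run errors if no block is
#'   reached within it (default 120).
#' @param f Mutant fold-change.
#' @param dt_ms Output sampling interval (ms).
#' @param threshold_mV Spike threshold (mV).
#' @return List with `trace`, and `features`: `rise_s` (switch-off to
#'   first spike), `spiking_to_block_s` (first to last spike),
#'   `first_spike_s`, `block_onset_s`.
#' @export
run_decapitation <- function(genotype = "wild-type",
                             params = anoxia_parameters(),
                             t_off_s = 5, t_end_s = 120, f = 3,
                             dt_ms = 0.5, threshold_mV = 0) {
  genotype <- .check_genotype(genotype)
  schedule <- make_anoxia_switch(t_off_s)
  trace <- simulate_anoxia(schedule, t_end_s = t_end_s, dt_ms = dt_ms,
                           params = params, genotype = genotype, f = f)
  sp <- detect_spikes(trace$time_s, trace$V_mV, threshold_mV,
                      refractory = 1e-3)
  sp <- sp[sp >= t_off_s]
  if (length(sp) == 0)
    stop("no depolarization block reached within the horizon")
  last <- max(sp)
  if (last > t_end_s - 5)
    stop("spiking still ongoing at the end of the horizon; extend it")
  features <- list(rise_s = min(sp) - t_off_s,
                   spiking_to_block_s = last - min(sp),
                   first_spike_s = min(sp), block_onset_s = last)
  list(trace = trace, features = features)
}
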