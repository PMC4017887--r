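# Equilibrium continuation in the applied current for the classical
# model, Hopf-point detection and firing-rate curves.

#' Equilibrium of the classical model at a given applied current
#'
#' At any equilibrium the gates sit at \eqn{x_\infty(V)} (true for the
#' mutant as well: the tau rescaling does not move the steady state),
#' so the equilibrium reduces to a scalar root problem on the
#' steady-state current-voltage relation.
#'
#' @param I_app Applied current (uA/cm2).
#' @param genotype Kept for interface symmetry; the equilibrium
#'   location is genotype-independent.
#' @param params [hh_parameters()].
#' @return Named state `(V, m, n, h)` with right-hand-side norm below
#'   1e-10.
#' @export
find_equilibrium <- function(I_app, genotype = "wild-type",
                             params = hh_parameters()) {
  eq <- hh_rest(I_app, params)
  res <- max(abs(hh_rhs(eq, I_app, params, genotype)))
  if (res > 1e-10)
    stop(sprintf("equilibrium residual %.3g exceeds 1e-10", res))
  eq
}

#' Jacobian of the classical model at a state
#'
#' Central finite differences (step 1e-6 in each state variable) on
#' the reference right-hand side.
#'
#' @inheritParams hh_rhs
#' @return 4x4 Jacobian matrix (rows/cols V, m, n, h).
#' @export
hh_jacobian <- function(state, I_app = 0, params = hh_parameters(),
                        genotype = "wild-type", f = 3, spec = NULL) {
  rhs <- function(x) hh_rhs(setNames(x, names(state)), I_app, params,
                            genotype, f, spec)
  .fd_jacobian(rhs, state, fd = 1e-6)
}

# real part of the leading complex-conjugate eigenvalue pair
.lead_re <- function(I_app, genotype, params, f = 3, spec = NULL) {
  eq <- find_equilibrium(I_app, genotype, params)
  ev <- eigen(hh_jacobian(eq, I_app, params, genotype, f, spec),
              only.values = TRUE)$values
  cc <- ev[abs(Im(ev)) > 1e-9]
  if (length(cc) == 0) max(Re(ev)) else max(Re(cc))
}

#' Locate the Hopf bifurcations of the classical model
#'
#' Continues the equilibrium branch over a grid of applied currents,
#' tracks the real part of the leading complex eigenvalue pair of the
#' finite-difference Jacobian, and refines every sign change by
#' bisection.  The lower Hopf current (HB1) is the rheobase, the upper
#' one (HB2) the excitation block.
#'
#' @param I_range Current range to scan (uA/cm2); must bracket both
#'   eigenvalue sign changes.
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param params [hh_parameters()].
#' @param f Mutant fold-change.
#' @param dI Continuation step (uA/cm2); default 0.5.
#' @param refine_tol Bisection tolerance on the Hopf current; default
#'   1e-3.
#' @return List of class `"bifurcation_result"`: `branch` (data frame
#'   `I_app`, `V`, `lead_re`), `HB1`, `HB2` (uA/cm2), `rheobase`
#'   (= HB1) and `genotype`.
#' @export
scan_hopf <- function(I_range = c(0, 200), genotype = "wild-type",
                      params = hh_parameters(), f = 3, dI = 0.5,
                      refine_tol = 1e-3) {
  genotype <- .check_genotype(genotype)
  spec <- if (genotype == "mutant")
    mutant_tau_spec(f = f, variant = "classical") else NULL
  Is <- seq(I_range[1], I_range[2], by = dI)
  lead <- vapply(Is, .lead_re, 0, genotype = genotype, params = params,
                 f = f, spec = spec)
  Vs <- vapply(Is, function(I) find_equilibrium(I, genotype,
                                                params)[["V"]], 0)
  cross <- which(diff(sign(lead)) != 0)
  if (length(cross) < 2)
    stop("I_range does not bracket two eigenvalue sign changes")
  refine <- function(lo, hi) {
    s_lo <- sign(.lead_re(lo, genotype, params, f, spec))
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (sign(.lead_re(mid, genotype, params, f, spec)) == s_lo)
        lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }
  hopf <- vapply(cross, function(i) refine(Is[i], Is[i + 1]), 0)
  structure(list(branch = data.frame(I_app = Is, V = Vs,
                                     lead_re = lead),
                 HB1 = hopf[1], HB2 = hopf[length(hopf)],
                 rheobase = hopf[1], genotype = genotype),
            class = "bifurcation_result")
}

#' Firing rate at a constant applied current
#'
#' Simulates the model, discards the settling transient and divides
#' the spike count by the counting window.  Action potentials
#' overshoot 0 mV at low currents, but towards the supercritical
#' excitation block the oscillation shrinks onto a depolarized
#' plateau; cycles are therefore counted as upward crossings of the
#' midpoint of the settled waveform, and a settled peak-to-peak
#' amplitude below 5 mV counts as quiescence (rate 0).  Near the
#' subcritical lower Hopf point the attractor depends on the initial
#' condition (bistability); `from = "spiking"` starts from a
#' large-amplitude state instead of the equilibrium so both branches
#' of the hysteresis loop can be reported.
#'
#' @param I_app Constant applied current (uA/cm2).
#' @param genotype `"wild-type"` or `"mutant"`.
#' @param params,f Model parameters and mutant fold-change.
#' @param settle_ms Transient discarded before counting (ms).
#' @param window_ms Counting window (ms, >= 1000).
#' @param from `"equilibrium"` or `"spiking"` initial condition.
#' @return Firing rate (Hz); 0 if the settled attractor is the
#'   equilibrium.
#' @export
firing_rate <- function(I_app, genotype = "wild-type",
                        params = hh_parameters(), f = 3,
                        settle_ms = 500, window_ms = 1000,
                        from = c("equilibrium", "spiking")) {
  from <- match.arg(from)
  stopifnot(window_ms >= 1000)
  init <- if (from == "equilibrium") {
    eq <- find_equilibrium(I_app, genotype, params)
    # nudge off the equilibrium so that an unstable focus can develop
    # into the spiking attractor within the settling window
    eq[["V"]] <- eq[["V"]] + 1
    eq
  } else {
    # a state on the upstroke of an action potential
    .hh_state(-20, 0.6, 0.4, 0.5)
  }
  trace <- simulate_hh(make_constant_current(I_app, "ms"),
                       t_end_ms = settle_ms + window_ms, dt_ms = 0.05,
                       init = init, params = params,
                       genotype = genotype, f = f)
  w <- trace[trace$time_ms >= settle_ms, ]
  rng <- range(w$V_mV)
  if (diff(rng) < 5) return(0)
  sp <- detect_spikes(w$time_ms, w$V_mV, threshold_mV = mean(rng))
  1e3 * length(sp) / window_ms
}

#' Firing-rate curve over a grid of currents
#'
#' @param I_grid Currents (uA/cm2).
#' @inheritParams firing_rate
#' @return Data frame `I_app`, `F_Hz`, `genotype`.
#' @export
firing_rate_curve <- function(I_grid, genotype = "wild-type",
                              params = hh_parameters(), f = 3, ...) {
  F <- vapply(I_grid, firing_rate, 0, genotype = genotype,
              params = params, f = f, ...)
  data.frame(I_app = I_grid, F_Hz = F, genotype = genotype)
}

# peak-to-peak voltage amplitude of the settled attractor
.settled_amplitude <- function(I_app, genotype, params, f = 3,
                               from = "equilibrium", perturb = 0) {
  init <- find_equilibrium(I_app, genotype, params)
  if (from == "spiking") init <- .hh_state(-20, 0.6, 0.4, 0.5)
  init[["V"]] <- init[["V"]] + perturb
  trace <- simulate_hh(make_constant_current(I_app, "ms"),
                       t_end_ms = 900, dt_ms = 0.05, init = init,
                       params = params, genotype = genotype, f = f)
  w <- trace[trace$time_ms >= 600, ]
  diff(range(w$V_mV))
}

#' Classify the criticality of a Hopf point by simulation probes
#'
#' At a subcritical Hopf point a large-amplitude stable oscillation
#' coexists with the stable equilibrium just outside the unstable
#' region; at a supercritical point the stable oscillation just inside
#' shrinks continuously to zero amplitude.  The probe simulates the
#' settled attractor on both sides of the point and applies these
#' signatures; an ambiguous probe yields `"undetermined"`.
#'
#' @param hopf_I Hopf current (uA/cm2), from [scan_hopf()].
#' @param side `"lower"` (HB1) or `"upper"` (HB2).
#' @param genotype,params,f Model configuration.
#' @param delta Probe offsets (uA/cm2).
#' @return `"subcritical"`, `"supercritical"` or `"undetermined"`.
#' @export
classify_criticality <- function(hopf_I, side = c("lower", "upper"),
                                 genotype = "wild-type",
                                 params = hh_parameters(), f = 3,
                                 delta = c(0.5, 4)) {
  side <- match.arg(side)
  out_I <- if (side == "lower") hopf_I - delta[1] else hopf_I + delta[1]
  in1 <- if (side == "lower") hopf_I + delta[1] else hopf_I - delta[1]
  in2 <- if (side == "lower") hopf_I + delta[2] else hopf_I - delta[2]
  # outside the unstable region, seeded from a spiking state
  amp_out <- .settled_amplitude(out_I, genotype, params, f,
                                from = "spiking")
  # just inside, seeded near the (unstable) equilibrium
  amp_in1 <- .settled_amplitude(in1, genotype, params, f, perturb = 0.5)
  amp_in2 <- .settled_amplitude(in2, genotype, params, f, perturb = 0.5)
  if (amp_out > 40 && amp_in1 > 40)
    return("subcritical")
  if (amp_out < 5 && amp_in1 < amp_in2 && amp_in2 < 60)
    return("supercritical")
  "undetermined"
}
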