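# Simulated voltage-clamp measurement of the h-gate time constant,
# mirroring the tail-current protocol: hold, step, and read the time
# at which h crosses the 1/e point of its relaxation.

#' Voltage-clamp step protocol
#'
#' @param V_hold Holding potential (mV); default -120 (h fully
#'   deinactivated).
#' @param V_step Step potential (mV); default -10 (h inactivates).
#' @param hold_ms,step_ms Durations (ms, > 0).
#' @return List of class `"clamp_protocol"`.
#' @export
clamp_protocol <- function(V_hold = -120, V_step = -10, hold_ms = 50,
                           step_ms = 60) {
  stopifnot(hold_ms > 0, step_ms > 0)
  structure(list(V_hold = V_hold, V_step = V_step, hold_ms = hold_ms,
                 step_ms = step_ms),
            class = "clamp_protocol")
}

#' Measure the h-gate time constant under voltage clamp
#'
#' With the voltage clamped, only the scalar h-equation evolves: from
#' \eqn{h(0) = h_\infty(V_{hold})} at the moment of the step, h
#' relaxes toward \eqn{h_\infty(V_{step})}.  The measured time
#' constant is the time at which h crosses
#' \eqn{h_\infty(V_{step}) + (h(0) - h_\infty(V_{step}))/e}, i.e. the
#' intersection with the 1/e-line (inactivation) or (1-1/e)-line
#' (deinactivation).  For this linear relaxation the measurement
#' equals \eqn{\tau_h} (or \eqn{\tau_h^*}) evaluated at the step
#' potential.
#'
#' @param protocol A [clamp_protocol()].
#' @param kinetics A [gate_kinetics()] for the h-gate.
#' @param dt_ms Output sampling interval of the h-trajectory (ms).
#' @return List with `tau_measured_ms`, the target level `h_target`,
#'   and the clamped trajectory `trace` (columns `t_ms`, `h`).
#' @export
clamp_measure_tau <- function(protocol = clamp_protocol(),
                              kinetics = gate_kinetics("h"),
                              dt_ms = 0.01) {
  stopifnot(inherits(protocol, "clamp_protocol"),
            inherits(kinetics, "gate_kinetics"),
            kinetics$gate == "h")
  h0 <- gate_steady_and_tau(protocol$V_hold, kinetics)$x_inf
  st <- gate_steady_and_tau(protocol$V_step, kinetics)
  rhs <- function(t, y, p) {
    g <- gate_steady_and_tau(protocol$V_step, kinetics)
    list((g$x_inf - y) / g$tau)
  }
  times <- seq(0, protocol$step_ms, by = dt_ms)
  out <- deSolve::lsoda(c(h = h0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  h <- out[, 2]
  target <- st$x_inf + (h0 - st$x_inf) / exp(1)
  # h moves monotonically from h0 toward x_inf; find the crossing
  crossed <- if (h0 > st$x_inf) h <= target else h >= target
  if (!any(crossed))
    stop("h did not cross the 1/e point: use a longer step duration")
  i <- which(crossed)[1]
  t_cross <- if (i == 1) 0 else
    approx(h[c(i - 1, i)], out[c(i - 1, i), 1], xout = target)$y
  list(tau_measured_ms = t_cross, h_target = target,
       trace = data.frame(t_ms = out[, 1], h = h))
}

#' Inactivation/deinactivation time-constant ratios, mutant vs wild-type
#'
#' Runs the two step protocols (-120 to -10 mV: inactivation; -10 to
#' -120 mV: deinactivation) for both genotypes and reports the
#' mutant/wild-type ratios of the measured time constants.  By
#' construction of the gating defect the ratios approach f and 1/f.
#'
#' @param variant Rate-function variant.
#' @param f Mutant fold-change.
#' @return List with `inactivation_ratio`, `deinactivation_ratio` and
#'   the four measured taus (ms).
#' @export
clamp_tau_ratios <- function(variant = c("classical", "shifted"),
                             f = 3) {
  variant <- match.arg(variant)
  measure <- function(genotype, V_hold, V_step) {
    kin <- gate_kinetics("h", variant, genotype, f = f)
    clamp_measure_tau(clamp_protocol(V_hold, V_step),
                      kin)$tau_measured_ms
  }
  inact_wt <- measure("wild-type", -120, -10)
  inact_mu <- measure("mutant", -120, -10)
  deinact_wt <- measure("wild-type", -10, -120)
  deinact_mu <- measure("mutant", -10, -120)
  list(inactivation_ratio = inact_mu / inact_wt,
       deinactivation_ratio = deinact_mu / deinact_wt,
       tau_inact_wt_ms = inact_wt, tau_inact_mut_ms = inact_mu,
       tau_deinact_wt_ms = deinact_wt, tau_deinact_mut_ms = deinact_mu)
}
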