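#' Voltage-dependent opening and closing rates of the gating variables
#'
#' Hodgkin-Huxley rate functions \eqn{\alpha_x(V)}, \eqn{\beta_x(V)} for
#' the activation gates `m` (sodium), `n` (potassium) and the
#' inactivation gate `h` (sodium).  Two variants are provided: the
#' `"classical"` rates of the action-potential model and the `"shifted"`
#' rates used by the ion-concentration models (SD and anoxia).
#'
#' The expressions for \eqn{\alpha_m} and \eqn{\alpha_n} have a removable
#' singularity where the denominator \eqn{1 - e^{-x/10}} vanishes
#' (classical: V = -40 and -55 mV; shifted: V = -30 and -34 mV).  Within
#' `1e-7` mV of the singular point the analytic limit
#' \eqn{x/(1-e^{-x/10}) \to 10 + x/2} is used instead.
#'
#' @param V Membrane potential (mV).  May be a vector; must be finite.
#' @param gate One of `"m"`, `"n"`, `"h"`.
#' @param variant `"classical"` or `"shifted"`.
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @examples
#' rate_constants(-40, "m")$alpha   # exactly 1 (limit value)
#' rate_constants(-65, "h")$alpha   # 0.07
#' @export
rate_constants <- function(V, gate = c("m", "n", "h"),
                           variant = c("classical", "shifted")) {
  gate <- match.arg(gate)
  variant <- match.arg(variant)
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("'V' must be finite: invalid membrane state")
  s <- if (variant == "classical") c(m = 40, bm = 65, n = 55, bn = 65,
                                     ah = 65, bh = 35)
       else                        c(m = 30, bm = 55, n = 34, bn = 44,
                                     ah = 44, bh = 14)
  switch(gate,
    m = list(alpha = 0.1 * .xexp10(V + s[["m"]]),
             beta  = 4 * exp(-(V + s[["bm"]]) / 18)),
    n = list(alpha = 0.01 * .xexp10(V + s[["n"]]),
             beta  = 0.125 * exp(-(V + s[["bn"]]) / 80)),
    h = list(alpha = 0.07 * exp(-(V + s[["ah"]]) / 20),
             beta  = 1 / (1 + exp(-0.1 * (V + s[["bh"]])))))
}

# x/(1 - exp(-x/10)) with its limit near x = 0
.xexp10 <- function(x) {
  ifelse(abs(x) < 1e-7, 10 + x / 2, x / (1 - exp(-x / 10)))
}

#' Gate kinetics descriptor
#'
#' Bundles everything that determines the dynamics of one gating
#' variable: the rate-function variant, the timescale factor
#' \eqn{\phi} (1/ms; 1 for the classical model, 3 for the shifted
#' models), the genotype, and -- for the mutant h-gate -- the
#' time-constant rescaling specification.
#'
#' @param gate One of `"m"`, `"n"`, `"h"`.
#' @param variant `"classical"` or `"shifted"`.
#' @param genotype `"wild-type"` or `"mutant"`.  Only the h-gate time
#'   constant differs between genotypes.
#' @param phi Timescale factor (1/ms).  Defaults to 1 for the classical
#'   variant and 3 for the shifted variant.
#' @param f Fold-change of the mutant gating defect (default 3).
#' @param spec Optional [mutant_tau_spec()]; built from `f` and
#'   `variant` when omitted.
#' @return An object of class `"gate_kinetics"`.
#' @export
gate_kinetics <- function(gate = c("m", "n", "h"),
                          variant = c("classical", "shifted"),
                          genotype = c("wild-type", "mutant"),
                          phi = NULL, f = 3, spec = NULL) {
  gate <- match.arg(gate)
  variant <- match.arg(variant)
  genotype <- match.arg(genotype)
  if (is.null(phi)) phi <- if (variant == "classical") 1 else 3
  stopifnot(phi > 0)
  if (genotype == "mutant" && gate == "h" && is.null(spec))
    spec <- mutant_tau_spec(f = f, variant = variant)
  structure(list(gate = gate, variant = variant, genotype = genotype,
                 phi = phi, f = f, spec = spec),
            class = "gate_kinetics")
}

#' Steady state and time constant of a gating variable
#'
#' \eqn{x_\infty = \alpha/(\alpha+\beta)} and
#' \eqn{\tau_x = 1/(\phi(\alpha+\beta))}.  For the mutant h-gate the
#' time constant is additionally multiplied by the voltage-dependent
#' factor of [mutant_tau_factor()].
#'
#' @param V Membrane potential (mV); may be a vector.
#' @param kinetics A [gate_kinetics()] object.
#' @return List with components `x_inf` (in (0,1)) and `tau` (ms, > 0).
#' @export
gate_steady_and_tau <- function(V, kinetics) {
  stopifnot(inherits(kinetics, "gate_kinetics"))
  r <- rate_constants(V, kinetics$gate, kinetics$variant)
  tau <- 1 / (kinetics$phi * (r$alpha + r$beta))
  if (kinetics$gate == "h" && kinetics$genotype == "mutant")
    tau <- tau * mutant_tau_factor(V, kinetics$spec)
  list(x_inf = r$alpha / (r$alpha + r$beta), tau = tau)
}

# steady-state shorthand used throughout the model code
.xinf <- function(V, gate, variant = "classical") {
  r <- rate_constants(V, gate, variant)
  r$alpha / (r$alpha + r$beta)
}
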