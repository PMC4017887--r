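#' Parameters of the classical Hodgkin-Huxley model
#'
#' Membrane capacitance (uF/cm2), maximal and leak conductances
#' (mS/cm2) and fixed reversal potentials (mV) of the classical
#' action-potential model.
#'
#' @param C_m Membrane capacitance (uF/cm2).
#' @param gbar_Na,gbar_K Maximal gated conductances (mS/cm2).
#' @param g_l Leak conductance (mS/cm2).
#' @param E_Na,E_K,E_leak Reversal potentials (mV).
#' @return A named list of class `"hh_parameters"`.
#' @export
hh_parameters <- function(C_m = 1, gbar_Na = 120, gbar_K = 36, g_l = 0.3,
                          E_Na = 50, E_K = -77, E_leak = -54.402) {
  stopifnot(C_m > 0, gbar_Na > 0, gbar_K > 0, g_l > 0)
  structure(list(C_m = C_m, gbar_Na = gbar_Na, gbar_K = gbar_K, g_l = g_l,
                 E_Na = E_Na, E_K = E_K, E_leak = E_leak),
            class = "hh_parameters")
}

#' Parameters of the spreading depression model
#'
#' Conductances (mS/cm2), compartment geometry, Na/K pump strength,
#' bath coupling and reference ion concentrations of the
#' ion-concentration-resolving SD model.  Time unit is ms.
#'
#' The current-to-flux factor is *derived* from the membrane surface
#' and Faraday's constant rather than taken as a free parameter:
#' \deqn{\gamma = A_m / F,} and the per-compartment conversions used by
#' the ODEs are \eqn{\gamma/\omega_i} and \eqn{\gamma/\omega_e} in
#' mM/ms per uA/cm2.  The unit chain, with \eqn{A_m} in cm2 and
#' \eqn{\omega} in litres, is
#' `conv = A_m[cm2] * 1e-6[A/uA] / (F[C/mol] * omega[L])`
#' (mol L^-1 s^-1 per uA/cm2, numerically equal to mM/ms per uA/cm2
#' after the mM and ms rescalings cancel).  Both conversions are
#' exposed as `conv_i` and `conv_e` for inspection.
#'
#' @param C_m Membrane capacitance (uF/cm2).
#' @param g_Na_l,g_K_l Leak conductances (mS/cm2).
#' @param g_Na_g,g_K_g Maximal gated conductances (mS/cm2).
#' @param omega_i,omega_e Intra-/extracellular volumes (um3).
#' @param A_m Membrane surface (um2).
#' @param Faraday Faraday's constant (C/mol).
#' @param rho Maximal Na/K pump current (uA/cm2).
#' @param phi Gating timescale factor (1/ms).
#' @param F_diff Potassium bath coupling rate (1/ms).
#' @param K_bath Bath potassium concentration (mM).
#' @param Na_i0,Na_e0,K_i0,K_e0 Reference (physiological) intra- and
#'   extracellular sodium/potassium concentrations (mM), which also
#'   anchor the electroneutrality constraint.
#' @return A named list of class `"sd_parameters"`; includes the derived
#'   `gamma` (um2 mol/C), `conv_i`, `conv_e` (mM/ms per uA/cm2) and the
#'   volume ratio `vol_ratio`.
#' @export
sd_parameters <- function(C_m = 1, g_Na_l = 0.0175, g_Na_g = 100,
                          g_K_l = 0.05, g_K_g = 40,
                          omega_i = 2160, omega_e = 720, A_m = 922,
                          Faraday = 96485, rho = 5.25, phi = 3,
                          F_diff = 3.75e-5, K_bath = 4,
                          Na_i0 = 27, Na_e0 = 120, K_i0 = 130.99,
                          K_e0 = 4) {
  stopifnot(C_m > 0, omega_i > 0, omega_e > 0, A_m > 0, rho >= 0,
            phi > 0, F_diff >= 0,
            min(Na_i0, Na_e0, K_i0, K_e0, K_bath) > 0)
  # A_m [um2] -> cm2 is 1e-8; omega [um3] -> L is 1e-15
  conv <- function(omega) (A_m * 1e-8) * 1e-6 / (Faraday * omega * 1e-15)
  structure(list(C_m = C_m, g_Na_l = g_Na_l, g_Na_g = g_Na_g,
                 g_K_l = g_K_l, g_K_g = g_K_g,
                 omega_i = omega_i, omega_e = omega_e, A_m = A_m,
                 Faraday = Faraday, rho = rho, phi = phi,
                 F_diff = F_diff, K_bath = K_bath,
                 Na_i0 = Na_i0, Na_e0 = Na_e0, K_i0 = K_i0, K_e0 = K_e0,
                 gamma = A_m / Faraday,
                 conv_i = conv(omega_i), conv_e = conv(omega_e),
                 vol_ratio = omega_i / omega_e),
            class = "sd_parameters")
}

#' Parameters of the anoxic depolarization model
#'
#' Conductances (mS/cm2), ion-flux conversion, volume ratio, pump rate,
#' glial buffering and blood diffusion of the nine-variable anoxia
#' model.  Time unit is s; the membrane-current-to-concentration-flux
#' conversion `conv` is expressed in mM/s per uA/cm2 (the published
#' 0.044 figure; together with the pump rate of 28.1 uA/cm2 it gives
#' the conventional pump flux of about 1.24 mM/s).
#'
#' @param C_m Membrane capacitance (uF/cm2).
#' @param g_Na_l,g_K_l,g_Cl_l Leak conductances (mS/cm2).
#' @param g_Na_g,g_K_g Maximal gated conductances (mS/cm2).
#' @param conv Current-to-flux conversion A/(VF) (mM/s per uA/cm2).
#' @param beta Ratio of intra- to extracellular volume (dimensionless).
#' @param rho Maximal Na/K pump current (uA/cm2).
#' @param phi Gating timescale factor (1/ms).
#' @param G Maximal glial potassium buffering rate (mM/s).
#' @param eps Blood diffusion rate (1/s).
#' @param k_inf Blood potassium concentration (mM).
#' @param temperature Absolute temperature (K); recorded for
#'   completeness, the Nernst prefactor is the fixed 26.64 mV.
#' @param Na_i0,Na_e0,K_i0,K_e0 Initial sodium/potassium concentrations
#'   (mM).
#' @param Cl_i0,Cl_e0 Initial chloride concentrations (mM).  Not part of
#'   the published table; the defaults are the conventional values of
#'   the source seizure/anoxia models (E_Cl about -82 mV) and the
#'   resting state is obtained by relaxation, which drives E_Cl to the
#'   resting potential while conserving total chloride.
#' @return A named list of class `"anoxia_parameters"`.
#' @export
anoxia_parameters <- function(C_m = 1, g_Na_l = 0.0175, g_Na_g = 100,
                              g_K_l = 0.05, g_K_g = 40, g_Cl_l = 0.05,
                              conv = 0.044, beta = 2, rho = 28.1,
                              phi = 3, G = 66, eps = 1.3, k_inf = 4,
                              temperature = 310,
                              Na_i0 = 27, Na_e0 = 120, K_i0 = 130.99,
                              K_e0 = 4, Cl_i0 = 6, Cl_e0 = 130) {
  stopifnot(C_m > 0, conv > 0, beta > 0, rho >= 0, phi > 0, G >= 0,
            eps >= 0, min(Na_i0, Na_e0, K_i0, K_e0, Cl_i0, Cl_e0) > 0)
  structure(list(C_m = C_m, g_Na_l = g_Na_l, g_Na_g = g_Na_g,
                 g_K_l = g_K_l, g_K_g = g_K_g, g_Cl_l = g_Cl_l,
                 conv = conv, beta = beta, rho = rho, phi = phi,
                 G = G, eps = eps, k_inf = k_inf,
                 temperature = temperature,
                 Na_i0 = Na_i0, Na_e0 = Na_e0, K_i0 = K_i0, K_e0 = K_e0,
                 Cl_i0 = Cl_i0, Cl_e0 = Cl_e0),
            class = "anoxia_parameters")
}
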