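test_that("Nernst potentials reproduce the reference reversal potentials", {
  # exact to the four significant figures of the reference table
  expect_equal(nernst(1, 4, 130.99), -92.94, tolerance = 1.3e-4)
  expect_equal(nernst(1, 120, 27), 39.74, tolerance = 1.3e-4)
  expect_equal(nernst(1, 7.3, 7.3), 0)
  expect_equal(nernst(-1, 130, 6), -26.64 * log(130 / 6))
  expect_error(nernst(1, -1, 4), "positive")
  expect_error(nernst(1, 4, 0), "positive")
})

test_that("the pump current is bounded, half-activated and saturating as designed", {
  rho <- 5.25
  expect_equal(pump_current(25, 5.5, rho), rho / 4)
  expect_equal(pump_current(1e3, 1e3, rho), rho, tolerance = 1e-12)
  # independent direct-formula evaluation at the reference state
  expect_equal(pump_current(27, 4, rho),
               rho * (1 + exp((25 - 27) / 3))^-1 *
                 (1 + exp(5.5 - 4))^-1)
  # monotone in both substrates
  na <- seq(5, 45, 1)
  expect_true(all(diff(pump_current(na, 4, rho)) > 0))
  ke <- seq(1, 12, 0.25)
  expect_true(all(diff(pump_current(27, ke, rho)) > 0))
  expect_true(all(pump_current(na, 4, rho) > 0 &
                    pump_current(na, 4, rho) < rho))
})

test_that("potassium bookkeeping closes: transmembrane fluxes cancel in the totals", {
  p <- sd_parameters()
  set.seed(7)
  for (k in 1:20) {
    # K_i below ~91 mM would drive Na_e negative under the
    # electroneutrality constraint, so stay in the physical range
    st <- c(V = runif(1, -90, 20), n = runif(1), h = runif(1),
            K_i = runif(1, 100, 135), K_e = runif(1, 2, 40))
    d <- sd_rhs(st, pump_scale = runif(1), params = p)
    # d/dt(omega_i K_i + omega_e K_e) = omega_e * J_diff
    J_diff <- p$F_diff * (p$K_bath - st[["K_e"]])
    expect_equal(p$omega_i * d[["K_i"]] + p$omega_e * d[["K_e"]],
                 p$omega_e * J_diff, tolerance = 1e-12)
  }
})

test_that("the rested model sits at the reference state and stays there", {
  rest <- sd_rest()
  p <- sd_parameters()
  expect_lt(max(abs(sd_rhs(rest, params = p))), 1e-8)
  expect_equal(rest[["K_e"]], p$K_e0, tolerance = 1e-3)
  expect_equal(rest[["K_i"]], p$K_i0, tolerance = 0.05)
  tr <- simulate_sd(t_end_s = 20, dt_ms = 10)
  expect_lt(max(abs(tr$V_mV - rest[["V"]])), 1e-4)
})

test_that("electroneutrality identities hold exactly on simulated traces", {
  p <- sd_parameters()
  run <- sd_threshold_run_fine("wild-type")
  tr <- run$trace
  expect_equal(tr$Na_i_mM + tr$K_i_mM,
               rep(p$Na_i0 + p$K_i0, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$Na_e_mM,
               p$vol_ratio * (p$Na_i0 - tr$Na_i_mM) + p$Na_e0,
               tolerance = 1e-12)
  expect_true(all(tr$n >= 0 & tr$n <= 1 & tr$h >= 0 & tr$h <= 1))
  expect_true(all(tr$K_i_mM > 0 & tr$K_e_mM > 0 & tr$Na_i_mM > 0 &
                    tr$Na_e_mM > 0))
})

test_that("with no bath coupling the potassium pool is closed over 100 s", {
  p <- sd_parameters(F_diff = 0)
  rest <- sd_rest()   # rest of the coupled model; fine as an initial state
  tr <- simulate_sd(t_end_s = 100, dt_ms = 50, init = rest, params = p)
  total <- p$omega_i * tr$K_i_mM + p$omega_e * tr$K_e_mM
  expect_lt(max(abs(total - total[1])) / total[1], 1e-8)
})

test_that("compiled and reference SD dynamics agree through a pump dip", {
  sched <- make_pump_interruption(2, down_s = 2, up_s = 2, t0_s = 1)
  rest <- sd_rest()
  rhs_r <- function(t, y, pp) {
    s <- schedule_value(sched, t / 1e3)$pump_scale
    list(sd_rhs(y, pump_scale = s))
  }
  ref <- deSolve::lsoda(rest, seq(0, 8e3, 10), rhs_r, NULL,
                        rtol = 1e-10, atol = 1e-12)
  com <- simulate_sd(sched, t_end_s = 8, dt_ms = 10, init = rest,
                     rtol = 1e-10, atol = 1e-12)
  expect_equal(com$V_mV, unname(ref[, "V"]), tolerance = 1e-6)
  expect_equal(com$K_e_mM, unname(ref[, "K_e"]), tolerance = 1e-8)
})

test_that("pump interruption outcomes are all-or-none and monotone at the threshold", {
  thr <- sd_threshold_fixture("wild-type")
  expect_equal(as.character(
    run_pump_interruption(0, "wild-type")$outcome), "recovered")
  oc <- thr$outcomes
  holds <- as.numeric(names(oc))
  expect_true(all(oc[holds < thr$threshold_s] == "recovered"))
  expect_true(all(oc[holds >= thr$threshold_s] == "SD"))
  # both classification criteria agree on either side of the threshold
  for (hold in c(thr$threshold_s - 0.1, thr$threshold_s)) {
    out <- run_pump_interruption(hold, "wild-type")$outcome
    bc <- attr(out, "by_criterion")
    expect_equal(unname(bc["E_K"]), unname(bc["V_return"]))
  }
})

test_that("spreading depression shows gradient breakdown and slow recovery", {
  run <- sd_threshold_run_fine("wild-type")
  tr <- run$trace
  gap <- tr$E_Na_mV - tr$E_K_mV
  # reversal potentials converge toward each other during SD
  expect_lt(min(gap), 0.25 * gap[1])
  # and have not recovered to rest even 30 s after the stimulation end
  t3 <- max(hhsd:::.pump_knots(run$schedule$pump))
  late <- tr[tr$time_s > t3 + 30, ]
  expect_true(all(late$E_K_mV > -60))
})

test_that("the mutant loses its potassium gradient faster while spiking", {
  wt <- sd_threshold_run_fine("wild-type")
  mu <- sd_threshold_run_fine("mutant")
  slope <- function(run) {
    sp <- detect_spikes(run$trace$time_s, run$trace$V_mV, -20, 1e-3)
    w <- run$trace[run$trace$time_s >= min(sp) &
                     run$trace$time_s <= max(sp), ]
    unname(coef(lm(E_K_mV ~ time_s, w))[2])
  }
  expect_gt(slope(mu), 1.5 * slope(wt))
})

test_that("the critical window needs a supra-threshold run", {
  thr <- sd_threshold_fixture("wild-type")
  sub <- run_pump_interruption(thr$threshold_s - 0.2, "wild-type",
                               dt_ms = 1)
  expect_error(critical_window(sub$trace, sub$schedule),
               "block")
})
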