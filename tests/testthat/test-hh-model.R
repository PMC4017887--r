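test_that("the wild-type resting state is a stable equilibrium", {
  rest <- hh_rest()
  expect_lt(max(abs(hh_rhs(rest))), 1e-8)
  ev <- eigen(hh_jacobian(rest), only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
})

test_that("the right-hand side obeys zero-driving-force and input scaling", {
  p0 <- hh_parameters(g_l = 1e-12)   # (leak suppressed)
  st <- c(V = p0$E_Na, m = 1, n = 0, h = 1)
  d <- hh_rhs(st, I_app = 0, params = p0)
  # sodium at its reversal potential and no open K channels: no current
  expect_equal(unname(d[["V"]]), 0, tolerance = 1e-9)
  # an applied current enters as +I/C_m on top of the ionic terms
  rest <- hh_rest()
  d0 <- hh_rhs(rest, 0)
  d10 <- hh_rhs(rest, 10)
  expect_equal(d10[["V"]] - d0[["V"]], 10 / hh_parameters()$C_m)
  # one explicit-Euler oracle step agrees with the returned derivative
  dt <- 1e-6
  euler <- rest + dt * hh_rhs(rest, 10)
  tr <- simulate_hh(make_constant_current(10, "ms"), t_end_ms = dt,
                    dt_ms = dt, init = rest)
  got <- unlist(tr[nrow(tr), c("V_mV", "m", "n", "h")])
  expect_equal(unname(got), unname(euler), tolerance = 1e-8)
})

test_that("compiled and reference right-hand sides integrate identically", {
  for (g in c("wild-type", "mutant")) {
    rest <- hh_rest()
    rest[["V"]] <- rest[["V"]] + 10
    ref <- deSolve::lsoda(rest, seq(0, 25, 0.1),
                          function(t, y, p) list(hh_rhs(y, 8,
                                                        genotype = g)),
                          NULL, rtol = 1e-10, atol = 1e-12)
    com <- simulate_hh(make_constant_current(8, "ms"), 25, 0.1,
                       init = rest, genotype = g,
                       rtol = 1e-10, atol = 1e-12)
    expect_equal(com$V_mV, unname(ref[, "V"]), tolerance = 1e-6)
    expect_equal(com$h, unname(ref[, "h"]), tolerance = 1e-6)
  }
})

test_that("a fold change of one makes the mutant right-hand side wild-type", {
  set.seed(42)
  for (k in 1:25) {
    st <- c(V = runif(1, -90, 40), m = runif(1), n = runif(1),
            h = runif(1))
    expect_identical(hh_rhs(st, 7, genotype = "mutant",
                            spec = mutant_tau_spec(f = 1)),
                     hh_rhs(st, 7))
  }
})

test_that("the excitatory pulse produces one action potential with the genotype timing", {
  sched <- make_pulse(3, 3, 10)
  tr_wt <- simulate_hh(sched, t_end_ms = 40)
  tr_mu <- simulate_hh(sched, t_end_ms = 40, genotype = "mutant")
  f_wt <- ap_features(tr_wt, sched)
  f_mu <- ap_features(tr_mu, sched)
  expect_length(f_wt$spike_times_ms, 1)
  expect_length(f_mu$spike_times_ms, 1)
  # wild-type peaks about 3 ms after the pulse ends, the mutant well
  # before it (initialization makes the exact figures approximate)
  expect_equal(f_wt$time_to_peak_ms, 3, tolerance = 0.2)
  expect_lt(f_mu$time_to_peak_ms, 2.2)
  expect_lt(f_mu$time_to_peak_ms, f_wt$time_to_peak_ms - 0.5)
  # a zero-amplitude pulse leaves the membrane at rest
  tr0 <- simulate_hh(make_pulse(0, 3, 10), t_end_ms = 40)
  expect_lt(max(abs(tr0$V_mV - tr0$V_mV[1])), 1e-3)
  expect_length(ap_features(tr0)$spike_times_ms, 0)
})

test_that("tonic mutant action potentials carry a plateau", {
  sched <- make_constant_current(12, "ms")
  init <- hh_rest()
  init[["V"]] <- init[["V"]] + 1
  tr_wt <- simulate_hh(sched, t_end_ms = 400, init = init)
  tr_mu <- simulate_hh(sched, t_end_ms = 400, init = init,
                       genotype = "mutant")
  expect_gt(ap_features(tr_mu)$plateau_ms,
            ap_features(tr_wt)$plateau_ms)
})

test_that("gating stays in [0,1] and the integration is tolerance-robust", {
  sched <- make_pulse(3, 3, 10, I_const = 0)
  for (g in c("wild-type", "mutant")) {
    tr <- simulate_hh(sched, t_end_ms = 40, genotype = g)
    expect_true(all(tr$m >= 0 & tr$m <= 1))
    expect_true(all(tr$n >= 0 & tr$n <= 1))
    expect_true(all(tr$h >= 0 & tr$h <= 1))
    peak <- function(trace) trace$time_ms[which.max(trace$V_mV)]
    tr2 <- simulate_hh(sched, t_end_ms = 40, genotype = g,
                       rtol = .5e-8, atol = .5e-10)
    expect_equal(peak(tr2), peak(tr), tolerance = 0.01)
  }
})
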