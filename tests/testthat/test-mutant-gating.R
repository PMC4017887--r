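test_that("the tau_h maximum is located to within 0.01 mV of a dense grid scan", {
  for (variant in c("classical", "shifted")) {
    grid <- seq(-120, 20, by = 0.001)
    r <- rate_constants(grid, "h", variant)
    tau <- 1 / (r$alpha + r$beta)
    v_grid <- grid[which.max(tau)]
    # a single interior maximum
    expect_gt(v_grid, -120)
    expect_lt(v_grid, 20)
    vm <- locate_vmax(variant)
    expect_equal(vm, v_grid, tolerance = 0.01)
    # definition of a maximum
    tau_at <- function(V) 1 / sum(unlist(rate_constants(V, "h", variant)))
    expect_lt(tau_at(vm + 5), tau_at(vm))
    expect_lt(tau_at(vm - 5), tau_at(vm))
  }
  # the shifted rates are the classical ones moved by +21 mV in the
  # h equations, so the maxima differ by that shift
  expect_equal(locate_vmax("shifted") - locate_vmax("classical"), 21,
               tolerance = 0.05)
})

test_that("the mutant factor has the prescribed anchor, limits and monotonicity", {
  spec <- mutant_tau_spec(f = 3)
  expect_equal(spec$kappa1, 1.335)
  expect_equal(spec$kappa2, 1.665)
  expect_equal(mutant_tau_factor(spec$V_max, spec), spec$kappa2)
  expect_equal(mutant_tau_factor(1e4, spec), spec$kappa1 + spec$kappa2,
               tolerance = 1e-9)
  expect_equal(mutant_tau_factor(-1e4, spec),
               spec$kappa2 - spec$kappa1, tolerance = 1e-9)
  # the asymptotes are the f-fold changes: f and (rounded) 1/f
  expect_equal(mutant_tau_factor(1e4, spec), 3, tolerance = 1e-6)
  expect_equal(mutant_tau_factor(-1e4, spec), 1 / 3, tolerance = 0.01)
  V <- seq(-150, 60, by = 0.25)
  fac <- mutant_tau_factor(V, spec)
  expect_true(all(diff(fac) > 0))
  # bounded by the published coefficients (whose difference is the
  # rounded 1/f), to within the tanh saturation tolerance
  eps <- 1e-6
  expect_true(all(fac > spec$kappa2 - spec$kappa1 - eps &
                    fac < spec$kappa1 + spec$kappa2 + eps))
  expect_true(all(fac > 1 / 3 - 0.005 & fac < 3 + eps))
  # generic fold changes satisfy both constraints exactly
  for (f in c(1, 2, 4)) {
    sp <- mutant_tau_spec(f = f)
    expect_equal(sp$kappa1 + sp$kappa2, f)
    expect_equal(sp$kappa2 - sp$kappa1, 1 / f)
  }
  # f = 1 forces the factor to be identically one
  sp1 <- mutant_tau_spec(f = 1)
  expect_equal(mutant_tau_factor(V, sp1), rep(1, length(V)))
})

test_that("voltage-clamp steps measure tau_h at the step potential", {
  kin <- gate_kinetics("h", "classical")
  m <- clamp_measure_tau(clamp_protocol(-120, -10), kin)
  r <- rate_constants(-10, "h", "classical")
  expect_equal(m$tau_measured_ms, 1 / (r$alpha + r$beta),
               tolerance = 0.01)
  # a step too short to reach the 1/e point is a protocol error
  expect_error(
    clamp_measure_tau(clamp_protocol(-120, -10, step_ms = 0.01),
                      kin, dt_ms = 0.002),
    "longer")
})

test_that("mutant/wild-type clamp ratios realise the fold change", {
  for (variant in c("classical", "shifted")) {
    rat <- clamp_tau_ratios(variant)
    expect_equal(rat$inactivation_ratio, 3, tolerance = 0.1 / 3)
    expect_equal(rat$deinactivation_ratio, 1 / 3, tolerance = 0.03)
  }
})
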