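test_that("glial buffering and blood diffusion follow their formulas", {
  expect_equal(glial_buffering(18, 66), 33)
  expect_equal(glial_buffering(1e3, 66), 66, tolerance = 1e-12)
  # independent direct-formula evaluation at the reference state
  expect_equal(glial_buffering(4, 66), 66 / (1 + exp((18 - 4) / 2.5)))
  ke <- seq(1, 40, 0.5)
  expect_true(all(diff(glial_buffering(ke, 66)) > 0))
  expect_true(all(glial_buffering(ke, 66) > 0 &
                    glial_buffering(ke, 66) < 66))
  expect_equal(blood_diffusion(4, 1.3, 4), 0)
  expect_equal(blood_diffusion(5, 1.3, 4), 1.3)
  expect_equal(sign(blood_diffusion(ke, 1.3, 4)), sign(ke - 4))
})

test_that("sodium and chloride pools are conserved, potassium when switched off", {
  p <- anoxia_parameters()
  set.seed(11)
  for (sw in c(TRUE, FALSE)) {
    for (k in 1:10) {
      st <- c(V = runif(1, -90, 20), n = runif(1), h = runif(1),
              Na_i = runif(1, 10, 40), Na_e = runif(1, 90, 150),
              K_i = runif(1, 80, 140), K_e = runif(1, 2, 40),
              Cl_i = runif(1, 4, 30), Cl_e = runif(1, 90, 140))
      d <- anoxia_rhs(st, switch_on = sw, params = p)
      expect_equal(d[["Na_i"]] + d[["Na_e"]] / p$beta, 0,
                   tolerance = 1e-12)
      expect_equal(d[["Cl_i"]] + d[["Cl_e"]] / p$beta, 0,
                   tolerance = 1e-12)
      if (!sw)
        expect_equal(d[["K_i"]] + d[["K_e"]] / p$beta, 0,
                     tolerance = 1e-12)
    }
  }
})

test_that("the relaxed resting state balances all currents", {
  rest <- anoxia_rest()
  p <- anoxia_parameters()
  expect_lt(max(abs(anoxia_rhs(rest, params = p))), 1e-8)
  # chloride equilibrates to the resting potential
  expect_equal(nernst(-1, rest[["Cl_e"]], rest[["Cl_i"]]),
               rest[["V"]], tolerance = 1e-4)
  # glial uptake balances diffusion from the blood
  expect_equal(glial_buffering(rest[["K_e"]], p$G),
               -blood_diffusion(rest[["K_e"]], p$eps, p$k_inf),
               tolerance = 1e-8)
})

test_that("under physiological conditions the model spikes normally", {
  tr <- simulate_anoxia(make_pulse(10, 0.003, 1, unit = "s"),
                        t_end_s = 3, dt_ms = 0.2)
  expect_length(detect_spikes(tr$time_s, tr$V_mV, 0, 1e-3), 1)
  tr2 <- simulate_anoxia(make_constant_current(2, "s"), t_end_s = 5,
                         dt_ms = 0.2)
  sp <- detect_spikes(tr2$time_s, tr2$V_mV, 0, 1e-3)
  expect_gt(length(sp), 10)   # periodic firing
})

test_that("compiled and reference anoxia dynamics agree across the switch-off", {
  rest <- anoxia_rest()
  rhs_r <- function(t, y, pp) {
    list(anoxia_rhs(y, switch_on = t < 2))
  }
  ref <- deSolve::lsoda(rest, seq(0, 10, 0.02), rhs_r, NULL,
                        rtol = 1e-10, atol = 1e-12)
  com <- simulate_anoxia(make_anoxia_switch(2), t_end_s = 10,
                         dt_ms = 20, rtol = 1e-10, atol = 1e-12)
  expect_equal(com$V_mV, unname(ref[, "V"]), tolerance = 1e-5)
  expect_equal(com$K_e_mM, unname(ref[, "K_e"]), tolerance = 1e-7)
})

test_that("total energy failure runs through rise, burst and block", {
  wt <- decapitation_fixture("wild-type")
  mu <- decapitation_fixture("mutant")
  expect_gt(wt$features$rise_s, 5)
  # genotypes are indistinguishable until spiking starts
  expect_equal(mu$features$first_spike_s, wt$features$first_spike_s,
               tolerance = 0.01 * wt$features$rise_s)
  pre <- wt$trace$time_s < wt$features$first_spike_s - 0.5
  expect_lt(max(abs(wt$trace$V_mV[pre] - mu$trace$V_mV[pre])), 0.5)
  # once spiking, the mutant reaches the block about 2.5 times sooner
  expect_equal(wt$features$spiking_to_block_s /
                 mu$features$spiking_to_block_s, 2.5,
               tolerance = 0.15)
  # conservation along the full trajectory
  p <- anoxia_parameters()
  tot_na <- wt$trace$Na_i_mM + wt$trace$Na_e_mM / p$beta
  tot_cl <- wt$trace$Cl_i_mM + wt$trace$Cl_e_mM / p$beta
  expect_lt(max(abs(tot_na - tot_na[1])) / tot_na[1], 1e-7)
  expect_lt(max(abs(tot_cl - tot_cl[1])) / tot_cl[1], 1e-7)
  # after the switch-off potassium is closed too
  post <- wt$trace$time_s > 5.01
  tot_k <- wt$trace$K_i_mM[post] + wt$trace$K_e_mM[post] / p$beta
  expect_lt(max(abs(tot_k - tot_k[1])) / tot_k[1], 1e-7)
})
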