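test_that("pulse schedules are rectangular with the stated charge", {
  s <- make_pulse(3, 3, 10)
  t <- seq(0, 40, by = 0.01)
  v <- schedule_value(s, t)
  expect_true(all(v$I_app[t >= 10 & t < 13] == 3))
  expect_true(all(v$I_app[t < 10 | t >= 13] == 0))
  expect_equal(sum(v$I_app) * 0.01, 3 * 3, tolerance = 0.02)
  z <- schedule_value(make_pulse(0, 3, 10), t)
  expect_true(all(z$I_app == 0))
})

test_that("the pump-interruption ramp is continuous with an exact floor", {
  s <- make_pump_interruption(13.6)
  k <- hhsd:::.pump_knots(s$pump)
  expect_equal(k[4] - k[1], 28.6)   # 10 + 13.6 + 5
  t <- seq(0, 60, by = 0.005)
  v <- schedule_value(s, t)$pump_scale
  expect_equal(min(v), 0.2)
  expect_lt(max(abs(diff(v))), 1e-3)   # no jumps on a 5 ms grid
  # a zero hold gives a continuous V-shape
  v0 <- schedule_value(make_pump_interruption(0), t)$pump_scale
  expect_equal(min(v0), 0.2)
  expect_lt(max(abs(diff(v0))), 1e-3)
})

test_that("schedules compose additively and serialize through YAML", {
  a <- make_constant_current(2, "s")
  b <- make_pump_interruption(5)
  ab <- schedule_combine(a, b)
  expect_equal(ab$I_const, 2)
  expect_equal(ab$pump$hold, 5)
  expect_error(schedule_combine(b, make_pump_interruption(1)), "both")
  path <- tempfile(fileext = ".yaml")
  write_schedule_yaml(ab, path)
  rt <- read_schedule_yaml(path)
  expect_equal(schedule_value(rt, seq(0, 50, 0.1)),
               schedule_value(ab, seq(0, 50, 0.1)))
})

test_that("spike detection counts crossings and honours the refractory merge", {
  expect_length(detect_spikes(0:100, rep(-65, 101)), 0)
  t <- seq(0, 100, by = 0.1)
  v <- 20 * sin(2 * pi * t / 10) - 5   # 10 crossings, 10 ms apart
  expect_length(detect_spikes(t, v), 10)
  # two crossings 0.4 ms apart merge into one spike
  tt <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  vv <- c(-10, 10, -10, 10, -10, -10)
  expect_length(detect_spikes(tt, vv, refractory = 1), 1)
  expect_length(detect_spikes(tt, vv, refractory = 0.1), 2)
})

test_that("tonic spiking is regular and feature extraction is sampling-robust", {
  init <- hh_rest(); init[["V"]] <- init[["V"]] + 1
  tr <- simulate_hh(make_constant_current(12, "ms"), 1000, 0.05,
                    init = init)
  sp <- detect_spikes(tr$time_ms, tr$V_mV)
  isi <- diff(sp[sp > 300])
  expect_lt(stats::sd(isi) / mean(isi), 0.05)
  # halving the sampling rate must not change the spike count, and the
  # block onset of a threshold run moves by well under 10 ms
  half <- tr[seq(1, nrow(tr), by = 2), ]
  expect_length(detect_spikes(half$time_ms, half$V_mV), length(sp))
  run <- sd_threshold_run_fine("wild-type")
  on_full <- max(detect_spikes(run$trace$time_s, run$trace$V_mV,
                               -20, 1e-3))
  sub <- run$trace[seq(1, nrow(run$trace), by = 2), ]
  on_half <- max(detect_spikes(sub$time_s, sub$V_mV, -20, 1e-3))
  expect_lt(abs(on_full - on_half), 0.01)
})

test_that("outcome classification needs an adequate horizon and rests easy", {
  tr <- simulate_sd(t_end_s = 60, dt_ms = 10)
  sched <- make_pump_interruption(0, t0_s = 1)
  rest <- sd_rest()
  expect_equal(as.character(
    classify_outcome(tr, sched, rest[["V"]])), "recovered")
  short <- tr[tr$time_s < 20, ]
  expect_error(classify_outcome(short, sched, rest[["V"]]),
               "too short")
})
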