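#' Stimulus schedules
#'
#' A stimulus schedule bundles the time-dependent controls of an
#' experiment: the applied current \eqn{I_{app}(t)} (a constant plus an
#' optional rectangular pulse), the Na/K pump scaling factor
#' \eqn{s_p(t)} (a continuous piecewise-linear down-ramp/hold/up-ramp),
#' the energy switch-off time of the anoxia model, and the bath
#' potassium concentration.  Schedules compose additively in the
#' current terms and multiplicatively in the scaling terms, see
#' [schedule_combine()].
#'
#' @name stimulus_schedule
NULL

.new_schedule <- function(unit, I_const = 0, pulse = NULL, pump = NULL,
                          t_off = NULL, K_bath = NULL) {
  structure(list(unit = unit, I_const = I_const, pulse = pulse,
                 pump = pump, t_off = t_off, K_bath = K_bath),
            class = "stimulus_schedule")
}

#' Rectangular current pulse
#'
#' @param amplitude Pulse amplitude (uA/cm2).
#' @param duration Pulse duration (> 0, in `unit`).
#' @param onset Pulse onset time (in `unit`).
#' @param I_const Constant background current (uA/cm2).
#' @param unit Time unit of `duration`/`onset`: `"ms"` (action-potential
#'   model) or `"s"` (ion-concentration models).
#' @return A `stimulus_schedule`.
#' @examples
#' make_pulse(3, 3, 10)       # the 3 ms / 3 uA cm-2 excitatory pulse
#' @export
make_pulse <- function(amplitude, duration, onset, I_const = 0,
                       unit = c("ms", "s")) {
  unit <- match.arg(unit)
  stopifnot(duration > 0, onset >= 0)
  .new_schedule(unit, I_const = I_const,
                pulse = list(amplitude = amplitude, onset = onset,
                             duration = duration))
}

#' Constant applied current
#'
#' @param I_app Constant current (uA/cm2).
#' @inheritParams make_pulse
#' @export
make_constant_current <- function(I_app, unit = c("ms", "s")) {
  .new_schedule(match.arg(unit), I_const = I_app)
}

#' Pump-interruption schedule
#'
#' The maximal pump rate is linearly down-regulated to `floor` (20% of
#' its physiological value) within `down_s` seconds, held there for the
#' variable window `hold_s`, and linearly up-regulated back to 100%
#' within `up_s` seconds.  The scaling factor is continuous and its
#' minimum is exactly `floor`.
#'
#' @param hold_s Hold duration at the reduced rate (s, >= 0).
#' @param down_s Down-ramp duration (s); default 10.
#' @param up_s Up-ramp duration (s); default 5.
#' @param floor Reduced pump fraction in \[0, 1\]; default 0.2.
#' @param t0_s Time at which the down-ramp starts (s); default 20, so
#'   that traces show the resting state first.
#' @return A `stimulus_schedule` (unit `"s"`).
#' @export
make_pump_interruption <- function(hold_s, down_s = 10, up_s = 5,
                                   floor = 0.2, t0_s = 20) {
  stopifnot(hold_s >= 0, down_s > 0, up_s > 0, floor >= 0, floor <= 1,
            t0_s >= 0)
  .new_schedule("s",
                pump = list(t0 = t0_s, down = down_s, hold = hold_s,
                            up = up_s, floor = floor))
}

#' Total energy shut-off (anoxia) schedule
#'
#' Pump, glial buffering and blood diffusion terms are all set to zero
#' from `t_off_s` on.
#'
#' @param t_off_s Switch-off time (s, >= 0); default 5.
#' @export
make_anoxia_switch <- function(t_off_s = 5) {
  stopifnot(t_off_s >= 0)
  .new_schedule("s", t_off = t_off_s)
}

#' Combine two schedules
#'
#' Current terms add; the pump schedule, switch-off time and bath
#' potassium must be given by at most one operand.
#'
#' @param a,b `stimulus_schedule` objects with the same time unit.
#' @export
schedule_combine <- function(a, b) {
  stopifnot(inherits(a, "stimulus_schedule"),
            inherits(b, "stimulus_schedule"), a$unit == b$unit)
  pick1 <- function(x, y, what) {
    if (!is.null(x) && !is.null(y))
      stop(sprintf("both schedules define a %s", what))
    if (is.null(x)) y else x
  }
  .new_schedule(a$unit, I_const = a$I_const + b$I_const,
                pulse = pick1(a$pulse, b$pulse, "pulse"),
                pump = pick1(a$pump, b$pump, "pump schedule"),
                t_off = pick1(a$t_off, b$t_off, "switch-off time"),
                K_bath = pick1(a$K_bath, b$K_bath, "bath concentration"))
}

#' Evaluate a schedule's controls at given times
#'
#' @param schedule A `stimulus_schedule`.
#' @param t Times (in the schedule's unit).
#' @return Data frame with columns `t`, `I_app`, `pump_scale`,
#'   `switch_on`.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  I <- rep(schedule$I_const, length(t))
  if (!is.null(schedule$pulse)) {
    p <- schedule$pulse
    I <- I + p$amplitude * (t >= p$onset & t < p$onset + p$duration)
  }
  sp <- rep(1, length(t))
  if (!is.null(schedule$pump)) {
    k <- .pump_knots(schedule$pump)
    sp <- ifelse(t < k[1] | t >= k[4], 1,
          ifelse(t < k[2],
                 1 + (schedule$pump$floor - 1) * (t - k[1]) / (k[2] - k[1]),
          ifelse(t < k[3], schedule$pump$floor,
                 schedule$pump$floor +
                   (1 - schedule$pump$floor) * (t - k[3]) / (k[4] - k[3]))))
  }
  sw <- if (is.null(schedule$t_off)) rep(TRUE, length(t)) else
    t < schedule$t_off
  data.frame(t = t, I_app = I, pump_scale = sp, switch_on = sw)
}

# knot times (t0, t1, t2, t3) of the pump ramp, in the schedule's unit
.pump_knots <- function(pump) {
  t0 <- pump$t0
  c(t0, t0 + pump$down, t0 + pump$down + pump$hold,
    t0 + pump$down + pump$hold + pump$up)
}

# breakpoints at which integration is restarted
.schedule_breaks <- function(schedule, scale = 1) {
  b <- numeric()
  if (!is.null(schedule$pulse))
    b <- c(b, schedule$pulse$onset, schedule$pulse$onset +
             schedule$pulse$duration)
  if (!is.null(schedule$pump)) b <- c(b, .pump_knots(schedule$pump))
  if (!is.null(schedule$t_off)) b <- c(b, schedule$t_off)
  b * scale
}

#' Write / read a stimulus schedule as YAML
#'
#' @param schedule A `stimulus_schedule`.
#' @param path File path.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  yaml::write_yaml(unclass(schedule), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  .new_schedule(x$unit, I_const = x$I_const %||% 0, pulse = x$pulse,
                pump = x$pump, t_off = x$t_off, K_bath = x$K_bath)
}

#' Detect spikes in a voltage trace
#'
#' Spikes are upward crossings of the membrane potential through a
#' threshold (default 0 mV -- action potentials overshoot 0 mV), with
#' crossing times refined by linear interpolation and crossings closer
#' than the refractory window merged.
#'
#' @param time Sample times (any unit, strictly increasing).
#' @param V Membrane potential samples (mV).
#' @param threshold_mV Crossing threshold (mV); default 0.
#' @param refractory Merge window in the same unit as `time`; default 1
#'   (i.e. 1 ms for ms-sampled traces).
#' @return Numeric vector of spike times (possibly empty).
#' @export
detect_spikes <- function(time, V, threshold_mV = 0, refractory = 1) {
  stopifnot(length(time) == length(V))
  if (length(V) < 2) return(numeric())
  below <- V[-length(V)] < threshold_mV
  above <- V[-1] >= threshold_mV
  idx <- which(below & above)
  if (length(idx) == 0) return(numeric())
  frac <- (threshold_mV - V[idx]) / (V[idx + 1] - V[idx])
  tt <- time[idx] + frac * (time[idx + 1] - time[idx])
  if (length(tt) > 1) {
    keep <- c(TRUE, diff(tt) > refractory)
    tt <- tt[keep]
  }
  tt
}

#' Classify a pump-interruption run as recovered or spreading depression
#'
#' Two equivalent readings of the all-or-none criterion are computed:
#'
#' * `"E_K"`: the run is SD iff, after the up-ramp has completed, the
#'   potassium reversal potential stays above `EK_level_mV` for at
#'   least `EK_sustain_s` contiguous seconds (sustained gradient
#'   breakdown);
#' * `"V_return"`: the run is SD iff the membrane potential does not
#'   return to within `V_band_mV` of rest within `V_within_s` seconds
#'   of the stimulation end.
#'
#' The returned label follows the criterion selected by `criterion`
#' (default `"E_K"`); both labels are attached as the
#' `"by_criterion"` attribute so that agreement can be asserted.
#'
#' @param trace A trace from [simulate_sd()] (columns `time_s`, `V_mV`,
#'   `E_K_mV`).
#' @param schedule The pump-interruption schedule of the run.
#' @param V_rest_mV Resting potential of the model (mV).
#' @param criterion `"E_K"` or `"V_return"`.
#' @param EK_level_mV,EK_sustain_s,V_band_mV,V_within_s Criterion
#'   parameters (see above).
#' @return `"SD"` or `"recovered"`, with attribute `by_criterion`.
#' @export
classify_outcome <- function(trace, schedule, V_rest_mV,
                             criterion = c("E_K", "V_return"),
                             EK_level_mV = -60, EK_sustain_s = 5,
                             V_band_mV = 5, V_within_s = 15) {
  criterion <- match.arg(criterion)
  stopifnot(!is.null(schedule$pump))
  t3 <- .pump_knots(schedule$pump)[4]
  if (max(trace$time_s) < t3 + V_within_s + 5)
    stop("trace too short to classify: extend the simulation horizon")
  post <- trace[trace$time_s >= t3, , drop = FALSE]

  runs <- rle(post$E_K_mV > EK_level_mV)
  dt <- diff(post$time_s[1:2])
  sustained <- any(runs$lengths[runs$values] * dt >= EK_sustain_s)
  ek_label <- if (sustained) "SD" else "recovered"

  w <- post[post$time_s <= t3 + V_within_s, , drop = FALSE]
  returned <- any(abs(w$V_mV - V_rest_mV) < V_band_mV)
  v_label <- if (returned) "recovered" else "SD"

  out <- if (criterion == "E_K") ek_label else v_label
  attr(out, "by_criterion") <- c(E_K = ek_label, V_return = v_label)
  out
}
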