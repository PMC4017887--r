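# Shared integration core.
#
# All models are integrated with the stiff-capable adaptive solver
# (deSolve::lsoda) and compiled right-hand sides.  Schedules are
# piecewise smooth; the integration is restarted at every breakpoint
# (pulse edges, ramp knots, switch-off time) so the solver never steps
# across a discontinuity in the controls.

.default_rtol <- 1e-8
.default_atol <- 1e-10

.integrate_segments <- function(y0, times, parms, func, initfunc,
                                nout, outnames, breaks = numeric(),
                                rtol = .default_rtol,
                                atol = .default_atol) {
  t0 <- times[1]
  t1 <- times[length(times)]
  brk <- sort(unique(breaks[breaks > t0 & breaks < t1]))
  edges <- c(t0, brk, t1)
  y <- y0
  pieces <- vector("list", length(edges) - 1)
  eps <- max(abs(t1 - t0), 1) * 1e-10
  for (k in seq_len(length(edges) - 1)) {
    seg <- unique(c(edges[k],
                    times[times > edges[k] + eps &
                            times < edges[k + 1] - eps],
                    edges[k + 1]))
    o <- deSolve::lsoda(y, seg, func = func, parms = parms,
                        dllname = "hhsd", initfunc = initfunc,
                        nout = nout, outnames = outnames,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    t_last <- o[nrow(o), 1]
    if (t_last < edges[k + 1] - 1e-9)
      stop(sprintf("integrator failure: last valid time %.6g", t_last))
    y <- o[nrow(o), 1 + seq_along(y0)]
    pieces[[k]] <- if (k == 1) o else o[-1, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  class(out) <- "matrix"
  out
}

# assert the hard invariant on every stored sample
.check_gating_bounds <- function(trace, cols) {
  for (cl in cols) {
    x <- trace[[cl]]
    if (any(x < -1e-6 | x > 1 + 1e-6))
      stop(sprintf("gating variable '%s' left [0, 1]", cl))
  }
  invisible(TRUE)
}
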