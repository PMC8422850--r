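#' Index of the varying segment of a step protocol
#' @noRd
varying_index <- function(protocol) {
  for (i in seq_along(protocol$segments)) {
    s <- protocol$segments[[i]]
    if (length(s$level) > 1 || length(s$dur) > 1) return(i)
  }
  length(protocol$segments)
}

#' Absolute time window of the test pulse of one sweep
#'
#' The test pulse is the final command segment of the sweep: in
#' activation-style protocols it is the (level-varying) test step itself,
#' in inactivation and time-course protocols it is the fixed test step
#' following the varying prepulse. Times include the pre-pulse padding.
#'
#' @param protocol a [step_protocol()].
#' @param sweep sweep index.
#' @return numeric `c(start, end)` in ms.
#' @export
test_pulse_window <- function(protocol, sweep = 1L) {
  ti <- length(protocol$segments)
  durs <- c(protocol$pad, vapply(protocol$segments, function(x)
    if (length(x$dur) > 1) x$dur[sweep] else x$dur, numeric(1)))
  start <- sum(durs[seq_len(ti)])
  c(start, start + durs[ti + 1L])
}

#' Peak current within a window
#'
#' Maximum of the trace within `window` (outward currents positive). The
#' default window is the whole trace; the slow-transient recovery analysis
#' overrides it to 70-150 ms after test-pulse onset to avoid contamination
#' by the fast transient.
#'
#' @param trace a [ktrace()].
#' @param window `c(start, end)` in ms (absolute trace time), or NULL for
#'   the full trace.
#' @return peak value in the trace's units.
#' @export
peak_current <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "ktrace"))
  sel <- if (is.null(window)) rep(TRUE, length(trace$t))
         else trace$t >= window[1] & trace$t <= window[2]
  if (!any(sel)) stop("empty analysis window")
  max(trace$y[sel])
}

#' Peak current-voltage relation over a sweep set
#'
#' @param traces list of [ktrace()] objects (one per sweep) carrying sweep
#'   levels, e.g. from [run_voltage_clamp()].
#' @param window optional window passed to [peak_current()]; either a
#'   single `c(start, end)` or a function of the sweep index returning one.
#' @return object of class `iv_curve`: data.frame with columns `V` (the
#'   sweep level) and `peak` (pA).
#' @export
iv_curve <- function(traces, window = NULL) {
  peaks <- vapply(seq_along(traces), function(i) {
    w <- if (is.function(window)) window(i) else window
    peak_current(traces[[i]], w)
  }, numeric(1))
  V <- vapply(traces, `[[`, numeric(1), "level")
  structure(data.frame(V = V, peak = peaks), class = c("iv_curve", "data.frame"))
}

#' Fit a leak/capacitance template from averaged small test pulses
#'
#' Estimates the baseline current, the linear leak conductance and the
#' capacitive-transient shape from the averaged response to -5 mV test
#' pulses, for use by [offline_leak_subtract()].
#'
#' @param trace averaged template [ktrace()].
#' @param pulse_start,pulse_dur onset time and duration of the template
#'   pulse in ms.
#' @param dV template step size in mV (default -5).
#' @return object of class `leak_template`.
#' @export
leak_template <- function(trace, pulse_start, pulse_dur, dV = -5) {
  stopifnot(inherits(trace, "ktrace"), pulse_dur > 0)
  # a sample exactly on the step boundary still carries the pre-step level
  pre <- trace$t <= pulse_start
  plateau <- trace$t >= pulse_start + 0.75 * pulse_dur &
    trace$t <= pulse_start + pulse_dur
  if (!any(pre) || !any(plateau)) stop("template grid does not cover the pulse")
  baseline <- mean(trace$y[pre])
  g_leak <- (mean(trace$y[plateau]) - baseline) / dV
  inpulse <- which(trace$t > pulse_start & trace$t <= pulse_start + pulse_dur)
  s <- trace$t[inpulse] - pulse_start
  shape <- trace$y[inpulse] - baseline - g_leak * dV
  structure(list(baseline = baseline, g_leak = g_leak, dV = dV,
                 s = s, shape = shape, dt = trace$t[2] - trace$t[1]),
            class = "leak_template")
}

#' Offline leak and capacitive-transient subtraction
#'
#' Subtracts the appropriately scaled template response from a recorded
#' trace: for each command segment the template is scaled by
#' (step size)/(template step size), covering both the steady leak current
#' and the capacitive transient at each step edge. This emulates the
#' offline subtraction used for the long total-/slow-K+ protocols, for
#' which P/N subtraction is unfeasible.
#'
#' @param trace recorded [ktrace()].
#' @param template a [leak_template()] (or an averaged template trace plus
#'   `pulse_start`/`pulse_dur` arguments).
#' @param command command waveform for the sweep, as returned by
#'   [command_waveform()] (data.frame with `t`, `V` on the same grid).
#' @param holding holding potential the template pulses started from (mV).
#' @return leak-subtracted [ktrace()].
#' @export
offline_leak_subtract <- function(trace, template, command, holding = -70) {
  stopifnot(inherits(trace, "ktrace"), inherits(template, "leak_template"))
  if (nrow(command) != length(trace$t) ||
      max(abs(command$t - trace$t)) > 1e-6)
    stop("template/trace grid mismatch: command grid must match the trace")
  V <- command$V
  pred <- template$baseline + template$g_leak * (V - holding)
  jumps <- which(diff(V) != 0) + 1L
  for (j in jumps) {
    dV <- V[j] - V[j - 1]
    scale <- dV / template$dV
    n <- min(length(template$shape), length(V) - j + 1L)
    idx <- j:(j + n - 1L)
    pred[idx] <- pred[idx] + scale * template$shape[seq_len(n)]
  }
  out <- trace
  out$y <- trace$y - pred
  out
}

#' P/N online leak subtraction
#'
#' Standard P/-5-style correction: the baseline-corrected responses to
#' `|n|` scaled sub-pulses (amplitude -1/|n| of the main command, from the
#' holding potential) are summed and added to the baseline-corrected main
#' sweep, cancelling the linear (leak) component.
#'
#' @param trace main sweep [ktrace()].
#' @param subsweeps list of sub-sweep [ktrace()] objects on the same grid.
#' @param baseline_window `c(start, end)` in ms over which to measure each
#'   sweep's baseline (default the first 100 ms pre-pulse padding).
#' @return corrected [ktrace()].
#' @export
pn_subtract <- function(trace, subsweeps, baseline_window = c(0, 100)) {
  stopifnot(inherits(trace, "ktrace"), length(subsweeps) >= 1)
  base_of <- function(tr) {
    sel <- tr$t >= baseline_window[1] & tr$t <= baseline_window[2]
    mean(tr$y[sel])
  }
  y <- trace$y - base_of(trace)
  for (sub in subsweeps) {
    if (length(sub$t) != length(trace$t))
      stop("insufficient or misaligned subsweeps")
    y <- y + (sub$y - base_of(sub))
  }
  out <- trace
  out$y <- y
  out
}

#' Voltage-based subtraction to isolate the fast-transient current
#'
#' Pointwise A - B over aligned grids: protocol B's depolarized
#' conditioning (-30 mV) inactivates the fast transient, so the difference
#' isolates it from the residual component.
#'
#' @param traceA,traceB [ktrace()] objects on identical grids.
#' @return difference [ktrace()].
#' @export
voltage_subtraction_isolate <- function(traceA, traceB) {
  stopifnot(inherits(traceA, "ktrace"), inherits(traceB, "ktrace"))
  if (length(traceA$t) != length(traceB$t) ||
      max(abs(traceA$t - traceB$t)) > 1e-6)
    stop("grid mismatch between protocol A and B traces")
  out <- traceA
  out$y <- traceA$y - traceB$y
  out
}

#' Convert peak currents to normalized GHK conductance
#'
#' Divides each peak by the GHK driving force at the calculated K+ reversal
#' potential (-94 mV, the analysis constant; the model channels use -92 mV)
#' and normalizes to the maximum over sweeps, yielding a steady-state
#' activation/inactivation curve in [0, 1].
#'
#' @param iv an [iv_curve()] (columns `V`, `peak`). For inactivation
#'   protocols `V` is the prepulse potential but the test potential is
#'   fixed; pass `V_driving` to evaluate the driving force at the test
#'   potential instead.
#' @param Erev reversal potential in mV (default -94).
#' @param VT thermal voltage in mV (default 31 degree C value).
#' @param V_driving optional voltage(s) at which to evaluate the driving
#'   force (defaults to `iv$V`).
#' @return data.frame with columns `V` and `g_norm`.
#' @export
normalized_ghk_conductance <- function(iv, Erev = -94, VT = thermal_voltage(31),
                                       V_driving = NULL) {
  df <- driving_force("ghk", E = Erev, VT = VT)
  Vd <- if (is.null(V_driving)) iv$V else rep_len(V_driving, nrow(iv))
  d <- driving(df, Vd)
  keep <- abs(Vd - Erev) > 1e-9 & d != 0
  perm <- iv$peak[keep] / d[keep]
  if (all(perm == 0)) stop("all-zero peaks: cannot normalize")
  data.frame(V = iv$V[keep], g_norm = perm / max(perm))
}

#' Boltzmann fit of a normalized conductance curve
#'
#' Least-squares fit of g(V) = gmax / (1 + exp((V - V50)/k)) by
#' Gauss-Newton (`nls`, port algorithm) from three heuristic starts,
#' keeping the lowest-residual solution. With the signed-slope convention,
#' k < 0 for activation and k > 0 for inactivation curves.
#'
#' @param V voltages in mV (>= 4 points spanning the transition).
#' @param g normalized conductances.
#' @return object of class `boltzmann_fit` with fields `V50`, `k`, `gmax`,
#'   `residual` (sum of squares).
#' @export
fit_boltzmann <- function(V, g) {
  stopifnot(length(V) == length(g), length(V) >= 4)
  if (stats::sd(g) < 1e-12)
    stop("fit failure: degenerate (constant) conductance data")
  rising <- stats::cor(V, g) > 0
  gmax0 <- max(g)
  half <- gmax0 / 2
  V500 <- V[which.min(abs(g - half))]
  starts <- lapply(c(4, 8, 16), function(kk)
    list(V50 = V500, k = if (rising) -kk else kk, gmax = gmax0))
  best <- NULL
  dat <- data.frame(V = V, g = g)
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(g ~ gmax / (1 + exp((V - V50) / k)), data = dat, start = st,
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$residual) {
      cf <- stats::coef(fit)
      best <- list(V50 = unname(cf["V50"]), k = unname(cf["k"]),
                   gmax = unname(cf["gmax"]), residual = rss)
    }
  }
  if (is.null(best))
    stop("fit failure: Boltzmann fit did not converge from any start")
  structure(best, class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit V50 = %.2f mV, k = %.2f mV, gmax = %.3f, rss = %.3g>\n",
              x$V50, x$k, x$gmax, x$residual))
  invisible(x)
}

#' Single-exponential fit of a time-course curve
#'
#' Fits y(t) = a exp(-t/tau) + c with tau > 0 (port algorithm, multi-start),
#' as used for inactivation and recovery-from-inactivation time courses.
#'
#' @param durations times in ms (>= 4 points).
#' @param y normalized peak values.
#' @return object of class `exp_fit` with fields `tau` (ms), `amplitude`,
#'   `offset`, `residual`.
#' @export
fit_exponential <- function(durations, y) {
  stopifnot(length(durations) == length(y), length(durations) >= 4)
  if (stats::sd(y) < 1e-12) stop("degenerate fit: constant input")
  span <- diff(range(durations))
  c0 <- y[which.max(durations)]
  a0 <- y[which.min(durations)] - c0
  # data-driven tau start: log-linear regression on the decaying part
  resid0 <- y - c0
  use <- abs(resid0) > 0.05 * max(abs(resid0)) & sign(resid0) == sign(a0)
  tau_guess <- if (sum(use) >= 2) {
    sl <- stats::coef(stats::lm(log(abs(resid0[use])) ~ durations[use]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else span / 3
  } else span / 3
  dat <- data.frame(t = durations, y = y)
  best <- NULL
  for (tau0 in unique(c(tau_guess * c(1 / 3, 1, 3), span / 3))) {
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-t / tau) + c, data = dat,
                 start = list(a = a0, tau = tau0, c = c0),
                 algorithm = "port", lower = c(-Inf, 1e-9, -Inf),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$residual) {
      cf <- stats::coef(fit)
      best <- list(tau = unname(cf["tau"]), amplitude = unname(cf["a"]),
                   offset = unname(cf["c"]), residual = rss)
    }
  }
  if (is.null(best)) stop("fit failure: exponential fit did not converge")
  structure(best, class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit tau = %.1f ms, a = %.3f, c = %.3f, rss = %.3g>\n",
              x$tau, x$amplitude, x$offset, x$residual))
  invisible(x)
}
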