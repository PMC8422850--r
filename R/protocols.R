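#' Voltage-step protocol
#'
#' A piecewise-constant command waveform. Exactly one segment may vary
#' across sweeps, either in level (`level` a vector) or in duration
#' (`dur` a vector). Every protocol starts and ends with a padding segment
#' at the holding potential (100 ms by default) for baseline and offset
#' analysis.
#'
#' @param holding holding potential in mV (between-protocol level).
#' @param segments list of `list(level = , dur = )` entries; `level` in mV,
#'   `dur` in ms. One entry may carry a vector in exactly one of the fields.
#' @param label protocol name.
#' @param pad pre/post padding at the holding potential in ms.
#' @return an object of class `step_protocol`.
#' @export
step_protocol <- function(holding, segments, label = "", pad = 100) {
  nvar <- sum(vapply(segments, function(s)
    (length(s$level) > 1) + (length(s$dur) > 1), numeric(1)))
  if (nvar > 1) stop("at most one segment may vary across sweeps")
  stopifnot(all(vapply(segments, function(s)
    all(is.finite(s$level)) && all(is.finite(s$dur)) && all(s$dur >= 0),
    logical(1))))
  structure(list(holding = holding, segments = segments, label = label,
                 pad = pad),
            class = "step_protocol")
}

#' Number of sweeps in a step protocol
#' @param protocol a [step_protocol()] or [current_step_protocol()].
#' @return integer sweep count.
#' @export
n_sweeps <- function(protocol) {
  if (inherits(protocol, "current_step_protocol")) return(length(protocol$steps))
  max(vapply(protocol$segments, function(s)
    max(length(s$level), length(s$dur)), numeric(1)))
}

#' Per-sweep segment table
#'
#' Expands a [step_protocol()] into the concrete (level, duration) sequence
#' of one sweep, including the holding-level padding segments.
#'
#' @param protocol a [step_protocol()].
#' @param sweep sweep index (1-based).
#' @return data.frame with columns `level` (mV) and `dur` (ms).
#' @export
sweep_segments <- function(protocol, sweep) {
  stopifnot(inherits(protocol, "step_protocol"),
            sweep >= 1, sweep <= n_sweeps(protocol))
  rows <- lapply(protocol$segments, function(s) {
    lev <- if (length(s$level) > 1) s$level[sweep] else s$level
    dur <- if (length(s$dur) > 1) s$dur[sweep] else s$dur
    c(level = lev, dur = dur)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- rbind(c(level = protocol$holding, dur = protocol$pad), out,
               c(level = protocol$holding, dur = protocol$pad))
  out[out$dur > 0, , drop = FALSE]
}

#' Command waveform of one sweep
#'
#' @param protocol a [step_protocol()].
#' @param sweep sweep index.
#' @param dt sample interval in ms.
#' @return data.frame with columns `t` (ms) and `V` (mV); a sample falling
#'   exactly on a segment boundary takes the outgoing segment's level
#'   (steps take effect from the next sample).
#' @export
command_waveform <- function(protocol, sweep, dt = 0.05) {
  seg <- sweep_segments(protocol, sweep)
  edges <- cumsum(c(0, seg$dur))
  t <- seq(0, edges[length(edges)], by = dt)
  idx <- pmin(pmax(findInterval(t, edges, left.open = TRUE), 1), nrow(seg))
  data.frame(t = t, V = seg$level[idx])
}

#' Current-step protocol for current clamp
#'
#' @param steps applied current amplitudes in pA (relative to the holding
#'   current), one sweep per element.
#' @param duration pulse duration in ms (> 0).
#' @param pre,post pre- and post-pulse recording windows in ms.
#' @param baseline baseline applied current in pA (default 0).
#' @param label protocol name.
#' @return an object of class `current_step_protocol`.
#' @export
current_step_protocol <- function(steps, duration = 500, pre = 100, post = 500,
                                  baseline = 0, label = "") {
  stopifnot(duration > 0, pre >= 0, post >= 0, all(is.finite(steps)))
  structure(list(steps = steps, duration = duration, pre = pre, post = post,
                 baseline = baseline, label = label),
            class = "current_step_protocol")
}

#' Total K+ activation protocol
#'
#' Hold at -100 mV for 5 s to remove inactivation, then 1-s test pulses
#' from -70 to +40 mV in 10-mV increments (12 sweeps).
#' @return a [step_protocol()].
#' @export
total_activation <- function() {
  step_protocol(-70, list(
    list(level = -100, dur = 5000),
    list(level = seq(-70, 40, by = 10), dur = 1000)),
    label = "total_activation")
}

#' Total K+ inactivation protocol
#'
#' 10-s prepulses from -100 to -10 mV in 10-mV increments (10 sweeps),
#' then a 1-s test pulse at 0 mV.
#' @return a [step_protocol()].
#' @export
total_inactivation <- function() {
  step_protocol(-70, list(
    list(level = seq(-100, -10, by = 10), dur = 10000),
    list(level = 0, dur = 1000)),
    label = "total_inactivation")
}

#' Slow-transient K+ time-course protocols
#'
#' Duration-varying protocols for the rate of inactivation (hold -100 mV 5 s
#' to remove inactivation, conditioning at -10 mV for 0-8 s, test at 0 mV
#' for 1 s) and recovery from inactivation (hold -10 mV 10 s to inactivate,
#' recovery at -100 mV for 0-8 s, test at 0 mV for 1 s). The stated 0-8 s
#' ranges are discretized at 0, 50, 100, 250, 500, 1000, 2000, 4000, 8000 ms.
#'
#' @param durations conditioning-duration grid in ms.
#' @return list with elements `inactivation` and `recovery`, both
#'   [step_protocol()] objects.
#' @export
slow_time_course <- function(durations = c(0, 50, 100, 250, 500, 1000,
                                           2000, 4000, 8000)) {
  list(
    inactivation = step_protocol(-70, list(
      list(level = -100, dur = 5000),
      list(level = -10, dur = durations),
      list(level = 0, dur = 1000)),
      label = "slow_inactivation_rate"),
    recovery = step_protocol(-70, list(
      list(level = -10, dur = 10000),
      list(level = -100, dur = durations),
      list(level = 0, dur = 1000)),
      label = "slow_recovery"))
}

#' Fast-transient K+ protocols
#'
#' Builds the five fast-transient protocols: activation protocol A
#' (200-ms conditioning at -100 mV, 150-ms test pulses -70..+40 mV),
#' activation protocol B (identical but conditioning at -30 mV, which fully
#' inactivates the fast transient and isolates the residual component),
#' steady-state inactivation (200-ms prepulses -100..-20 mV, 150-ms test at
#' -10 mV), rate of inactivation (300 ms at -100 mV, conditioning at -30 mV
#' for 0-250 ms, 100-ms test at 0 mV) and recovery from inactivation
#' (300 ms at 0 mV, recovery at -100 mV for 0-250 ms, 100-ms test at 0 mV).
#' Duration grids discretize the stated 0-250 ms ranges.
#'
#' @param durations conditioning/recovery duration grid in ms.
#' @return named list of [step_protocol()] objects: `activationA`,
#'   `activationB`, `inactivation`, `inact_rate`, `recovery`.
#' @export
fast_protocols <- function(durations = c(0, 10, 25, 50, 100, 150, 200, 250)) {
  tests <- seq(-70, 40, by = 10)
  list(
    activationA = step_protocol(-70, list(
      list(level = -100, dur = 200),
      list(level = tests, dur = 150)),
      label = "fast_activation_A"),
    activationB = step_protocol(-70, list(
      list(level = -30, dur = 200),
      list(level = tests, dur = 150)),
      label = "fast_activation_B"),
    inactivation = step_protocol(-70, list(
      list(level = seq(-100, -20, by = 10), dur = 200),
      list(level = -10, dur = 150)),
      label = "fast_inactivation"),
    inact_rate = step_protocol(-70, list(
      list(level = -100, dur = 300),
      list(level = -30, dur = durations),
      list(level = 0, dur = 100)),
      label = "fast_inactivation_rate"),
    recovery = step_protocol(-70, list(
      list(level = 0, dur = 300),
      list(level = -100, dur = durations),
      list(level = 0, dur = 100)),
      label = "fast_recovery"))
}

#' F-I current-step protocol
#'
#' `experimental = TRUE` returns the slice-recording grid (depolarizing
#' 2-28 pA in 2-pA steps plus hyperpolarizing -25..-5 pA in 5-pA steps);
#' `FALSE` returns the simulation grid (-30..0 pA in 10-pA steps plus
#' 2-28 pA in 2-pA steps). Pulses are 500 ms.
#'
#' @param experimental logical.
#' @return a [current_step_protocol()].
#' @export
fi_protocol <- function(experimental = FALSE) {
  steps <- if (experimental)
    c(seq(-25, -5, by = 5), seq(2, 28, by = 2))
  else
    c(seq(-30, 0, by = 10), seq(2, 28, by = 2))
  current_step_protocol(steps = steps, duration = 500, pre = 100, post = 500,
                        label = if (experimental) "fi_experimental" else "fi_simulation")
}
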