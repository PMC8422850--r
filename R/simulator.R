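#' Sampled trace
#'
#' A uniformly sampled time series of clamp current (pA) or membrane
#' voltage (mV) for one sweep.
#'
#' @param t time grid in ms (uniform, strictly increasing).
#' @param y sampled values.
#' @param unit `"pA"` or `"mV"`.
#' @param sweep sweep index.
#' @param level value of the varying protocol dimension for this sweep
#'   (test level in mV, conditioning duration in ms, or applied current in
#'   pA), `NA` if not applicable.
#' @param label protocol label.
#' @return an object of class `ktrace`.
#' @export
ktrace <- function(t, y, unit = "pA", sweep = 1L, level = NA_real_, label = "") {
  stopifnot(length(t) == length(y), all(is.finite(t)))
  if (any(!is.finite(y))) stop("non-finite trace values")
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = t, y = y, unit = unit, sweep = as.integer(sweep),
                 level = level, label = label),
            class = "ktrace")
}

#' @export
print.ktrace <- function(x, ...) {
  cat(sprintf("<ktrace %s sweep %d, %d samples, %.1f ms, level = %s>\n",
              x$unit, x$sweep, length(x$t), max(x$t), format(x$level)))
  invisible(x)
}

#' @export
as.data.frame.ktrace <- function(x, ...) {
  data.frame(t_ms = x$t, value = x$y, sweep = x$sweep)
}

#' Varying-dimension value per sweep
#'
#' For a level-varying protocol this is the vector of test levels (mV); for
#' a duration-varying protocol the vector of durations (ms); for a
#' current-step protocol the applied currents (pA).
#'
#' @param protocol a [step_protocol()] or [current_step_protocol()].
#' @return numeric vector, one element per sweep.
#' @export
sweep_levels <- function(protocol) {
  if (inherits(protocol, "current_step_protocol")) return(protocol$steps)
  for (s in protocol$segments) {
    if (length(s$level) > 1) return(s$level)
    if (length(s$dur) > 1) return(s$dur)
  }
  rep(NA_real_, n_sweeps(protocol))
}

#' Keep only a subset of voltage-gated conductances
#'
#' Utility for simulating isolated current components: returns a copy of
#' the model containing only the named conductances (and optionally the
#' Markov Na+ channel). Leak and passive properties are untouched.
#'
#' @param model a [neuron_model()].
#' @param channels names of conductances to keep.
#' @param keep_nat keep the Markov Na+ channel (default FALSE).
#' @return a [neuron_model()].
#' @export
isolate_channels <- function(model, channels, keep_nat = FALSE) {
  unknown <- setdiff(channels, names(model$conductances))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  model$conductances <- model$conductances[channels]
  if (!keep_nat) model$nat <- NULL
  model
}

# Analytic gate trajectory over one constant-voltage segment.
# Returns values at times s (relative to segment start) and the end value.
relax_gate <- function(spec, V, x0, s, s_end) {
  inf <- steady_state(spec, V)
  tau <- time_constant(spec$tau, V)
  list(y = inf + (x0 - inf) * exp(-s / tau),
       end = inf + (x0 - inf) * exp(-s_end / tau))
}

# Analytic Markov (C, O) trajectory over one constant-voltage segment.
relax_markov <- function(spec, V, x0, s, s_end) {
  sys <- markov_system(spec, V)
  xss <- solve(sys$A, -sys$b)
  eg <- eigen(sys$A)
  cf <- solve(eg$vectors, x0 - xss)
  evo <- function(ss) {
    m <- eg$vectors %*% (cf * exp(eg$values %o% ss))
    Re(m)
  }
  traj <- evo(s)
  endv <- evo(s_end)
  xss <- Re(xss)
  list(C = xss[1] + traj[1, ], O = xss[2] + traj[2, ],
       Cend = xss[1] + endv[1, 1], Oend = xss[2] + endv[2, 1])
}

#' Simulated voltage-clamp experiment
#'
#' Runs a step protocol under an ideal clamp: the membrane voltage follows
#' the command exactly and the recorded trace is the summed ionic current
#' (outward positive). Within each constant-voltage segment the gate ODEs
#' and the Markov state equations are solved in closed form (exponential
#' relaxation / 2x2 matrix exponential), so the result is exact at every
#' sample regardless of `dt`, which only sets the output grid. No leak or
#' capacitive artifact is added (see [record_cell()] for the realistic
#' in-silico rig). States are initialized at steady state at the holding
#' potential.
#'
#' @param model a [neuron_model()].
#' @param protocol a [step_protocol()].
#' @param dt output sample interval in ms (default 0.05, i.e. 20 kHz).
#' @param include_leak add the Ohmic leak current to the recording.
#' @param decompose attach a per-channel current matrix to each trace
#'   (`attr(trace, "components")`).
#' @param sweeps subset of sweep indices (default all).
#' @return list of [ktrace()] objects, one per sweep, with the protocol
#'   stored in `attr(, "protocol")`.
#' @export
run_voltage_clamp <- function(model, protocol, dt = 0.05, include_leak = FALSE,
                              decompose = FALSE, sweeps = NULL) {
  stopifnot(inherits(model, "neuron_model"), inherits(protocol, "step_protocol"))
  if (is.null(sweeps)) sweeps <- seq_len(n_sweeps(protocol))
  levels <- sweep_levels(protocol)
  chan_names <- names(model$conductances)
  init <- steady_state_model(model, protocol$holding)
  out <- lapply(sweeps, function(sw) {
    seg <- sweep_segments(protocol, sw)
    edges <- cumsum(c(0, seg$dur))
    t <- seq(0, edges[length(edges)], by = dt)
    idx <- pmin(pmax(findInterval(t, edges, left.open = TRUE), 1), nrow(seg))
    y <- numeric(length(t))
    comp <- if (decompose)
      matrix(0, length(t), length(chan_names) + !is.null(model$nat),
             dimnames = list(NULL, c(chan_names, if (!is.null(model$nat)) "nat")))
    gates <- init$gates
    nat <- init$nat
    for (i in seq_len(nrow(seg))) {
      sel <- which(idx == i)
      V <- seg$level[i]
      s <- t[sel] - edges[i]
      s_end <- seg$dur[i]
      for (nm in chan_names) {
        cs <- model$conductances[[nm]]
        mg <- relax_gate(cs$m, V, gates[[nm]]$m, s, s_end)
        H <- if (length(cs$inactivation)) 0 else 1
        hend <- numeric(length(cs$inactivation))
        for (j in seq_along(cs$inactivation)) {
          e <- cs$inactivation[[j]]
          hg <- relax_gate(e$gate, V, gates[[nm]]$h[j], s, s_end)
          H <- H + e$weight * hg$y
          hend[j] <- hg$end
        }
        Ic <- cs$gbar * mg$y^cs$r * H * driving(cs$df, V)
        y[sel] <- y[sel] + Ic
        if (decompose) comp[sel, nm] <- Ic
        gates[[nm]]$m <- mg$end
        gates[[nm]]$h <- hend
      }
      if (!is.null(model$nat)) {
        mk <- relax_markov(model$nat, V, c(nat[["C"]], nat[["O"]]), s, s_end)
        Inat <- model$nat$gbar * mk$O^model$nat$open_exponent * (V - model$nat$E)
        y[sel] <- y[sel] + Inat
        if (decompose) comp[sel, "nat"] <- Inat
        nat <- c(C = mk$Cend, O = mk$Oend, I = 1 - mk$Cend - mk$Oend)
      }
      if (include_leak) y[sel] <- y[sel] + model$g_leak * (V - model$E_leak)
    }
    if (any(!is.finite(y)))
      stop("integration error: non-finite clamp current (sweep ", sw, ")")
    tr <- ktrace(t, y, unit = "pA", sweep = sw, level = levels[sw],
                 label = protocol$label)
    if (decompose) attr(tr, "components") <- comp
    tr
  })
  attr(out, "protocol") <- protocol
  out
}

# Resting potential: solve Ihold = steady-state total current. Subthreshold
# inward currents (NaP/CaT windows) can create additional depolarized
# equilibria, so scan for sign changes and take the root nearest `near`
# (the -70 mV baseline).
find_rest <- function(model, lower = -110, upper = -30, near = -70) {
  f <- function(v) model$Ihold - steady_state_current(model, v)
  grid <- seq(lower, upper, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  flips <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(flips))
    stop("could not locate resting potential in [", lower, ", ", upper, "] mV")
  roots <- vapply(flips, function(i)
    uniroot(f, grid[c(i, i + 1)], tol = 1e-10)$root, numeric(1))
  roots[which.min(abs(roots - near))]
}

#' Simulated current-clamp experiment
#'
#' Integrates Cm dV/dt = -sum(I_ion) + I_applied + Ihold from the model's
#' resting state for each current step of the protocol. Gates and Markov
#' states are advanced exactly at frozen voltage each sub-step; the voltage
#' uses a midpoint step (see `src/integrate.cpp`).
#'
#' @param model a [neuron_model()] (calibrate first for -70 mV / 1 GOhm
#'   baseline conditions).
#' @param protocol a [current_step_protocol()].
#' @param dt integration step in ms (default 0.01).
#' @param dt_out output sample interval in ms (default 0.05).
#' @return list of [ktrace()] objects (membrane voltage, mV) with the
#'   protocol in `attr(, "protocol")`.
#' @export
run_current_clamp <- function(model, protocol, dt = 0.01, dt_out = 0.05) {
  stopifnot(inherits(model, "neuron_model"),
            inherits(protocol, "current_step_protocol"))
  V0 <- find_rest(model)
  flat <- flatten_model(model)
  x0 <- state_vector(model, V0)
  t_total <- protocol$pre + protocol$duration + protocol$post
  out <- lapply(seq_along(protocol$steps), function(i) {
    I <- protocol$steps[i]
    breaks <- c(0, protocol$pre, protocol$pre + protocol$duration)
    levels <- c(protocol$baseline, protocol$baseline + I, protocol$baseline)
    res <- .cc_integrate_cpp(flat, x0, V0, t_total, dt, dt_out, breaks, levels)
    ktrace(res$t, res$V, unit = "mV", sweep = i, level = I,
           label = protocol$label)
  })
  attr(out, "protocol") <- protocol
  out
}

#' Clamp the membrane to an arbitrary voltage trajectory
#'
#' Replays a sampled voltage waveform under an ideal clamp and returns the
#' membrane current. Used to cross-check the current-clamp and
#' voltage-clamp code paths: clamping to a recorded current-clamp voltage
#' trace reproduces the applied-current time course (minus the capacitive
#' current Cm dV/dt).
#'
#' @param model a [neuron_model()].
#' @param t uniform time grid in ms.
#' @param V voltage samples in mV.
#' @param include_leak include the leak current (default TRUE).
#' @return a [ktrace()] of clamp current in pA.
#' @export
clamp_to_voltage <- function(model, t, V, include_leak = TRUE) {
  stopifnot(length(t) == length(V), length(t) > 1)
  dt <- t[2] - t[1]
  flat <- flatten_model(model)
  x0 <- state_vector(model, V[1])
  I <- .vc_replay_cpp(flat, x0, V, dt, include_leak)
  ktrace(t, I, unit = "pA", label = "vc_replay")
}

#' Write a set of traces as CSV plus a JSON sidecar
#'
#' @param traces list of [ktrace()] objects.
#' @param path output CSV path (columns t_ms, value, sweep); protocol and
#'   sweep metadata go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    unit = traces[[1]]$unit, label = traces[[1]]$label,
    levels = vapply(traces, `[[`, numeric(1), "level"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return list of [ktrace()] objects.
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- lapply(sort(unique(df$sweep)), function(sw) {
    d <- df[df$sweep == sw, ]
    ktrace(d$t_ms, d$value, unit = meta$unit, sweep = sw,
           level = meta$levels[sw], label = meta$label)
  })
  out
}
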