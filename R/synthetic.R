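#' Draw a synthetic cell
#'
#' Emulates cell-to-cell variability in whole-cell recordings: per-channel
#' maximal-conductance multipliers are lognormal with median 1, and passive
#' properties (Rs, Rinput, Cm, Ihold) are drawn around the recorded
#' population means, truncated to the study's inclusion criteria
#' (Rs < 20 MOhm, Rinput > 500 MOhm, Cm 8-30 pF, Ihold -60..10 pA).
#' Deterministic for a given seed.
#'
#' @param stage `"diestrus"` or `"proestrus"`.
#' @param seed RNG seed for this cell.
#' @param sdlog standard deviation of log-multipliers (default 0.25;
#'   0 gives multipliers exactly 1).
#' @return object of class `synthetic_cell` with fields `base` (the stage
#'   preset), `multipliers`, `passive`, `seed`.
#' @export
sample_cell <- function(stage = "diestrus", seed = 1, sdlog = 0.25) {
  base <- preset(stage)
  chans <- names(base$conductances)
  local_seed(seed, {
    mult <- setNames(rlnorm(length(chans), 0, sdlog), chans)
    draw_trunc <- function(mean, sd, lo, hi) {
      for (i in 1:1000) {
        x <- rnorm(1, mean, sd)
        if (x > lo && x < hi) return(x)
      }
      mean
    }
    passive <- list(
      Rs = draw_trunc(15.7, 2.0, 5, 20),        # MOhm
      Rinput = draw_trunc(980, 250, 500, 2500), # MOhm
      Cm = draw_trunc(17.62, 3.5, 8, 30),       # pF
      Ihold = draw_trunc(-20, 12, -60, 10))     # pA
    structure(list(base = base, multipliers = mult, passive = passive,
                   seed = seed),
              class = "synthetic_cell")
  })
}

#' Concrete model of a synthetic cell
#'
#' Applies the cell's gbar multipliers and passive properties (Cm, leak
#' conductance = 1/Rinput) to its base preset.
#'
#' @param cell a [sample_cell()].
#' @return a [neuron_model()].
#' @export
cell_model <- function(cell) {
  stopifnot(inherits(cell, "synthetic_cell"))
  m <- cell$base
  for (nm in names(m$conductances))
    m$conductances[[nm]]$gbar <- m$conductances[[nm]]$gbar * cell$multipliers[[nm]]
  m$Cm <- cell$passive$Cm
  m$g_leak <- 1000 / cell$passive$Rinput # MOhm -> nS
  m$E_leak <- -70
  m$label <- paste0(m$label, "_synthetic")
  m
}

add_artifacts <- function(y, command, g_leak, Ihold, Rs_GOhm, Cm, dt) {
  V <- command$V
  y <- y + g_leak * (V - command$V[1]) + Ihold
  jumps <- which(diff(V) != 0) + 1L
  tau <- Rs_GOhm * Cm # ms
  n <- length(V)
  for (j in jumps) {
    dV <- V[j] - V[j - 1]
    amp <- dV / Rs_GOhm # pA
    len <- min(n - j + 1L, ceiling(10 * tau / dt))
    s <- (seq_len(len) - 1L) * dt
    idx <- j:(j + len - 1L)
    y[idx] <- y[idx] + amp * exp(-s / tau)
  }
  y
}

#' Record a synthetic cell under a clamp protocol
#'
#' The in-silico rig: simulates the ideal clamp currents of the cell's
#' K+ channels (Na+/Ca2+/HCN blocked, as in the recording solutions), then
#' adds the linear leak current, the holding-current baseline, capacitive
#' transients at step edges (amplitude dV/Rs, decay tau = Rs*Cm) and
#' additive white Gaussian noise. Also emits the averaged -5 mV template
#' pulse needed for offline leak subtraction and, on request, the P/-5
#' sub-sweeps for online subtraction.
#'
#' @param cell a [sample_cell()].
#' @param protocol a [step_protocol()].
#' @param noise_sd additive noise standard deviation in pA (default 5).
#' @param artifacts add leak/baseline/capacitive artifacts (default TRUE).
#' @param seed RNG seed for the noise.
#' @param pn_subsweeps also generate the P/-5 sub-sweeps (default FALSE).
#' @param n_template number of -5 mV pulses averaged for the template
#'   (default 100; noise scales with 1/sqrt(n)).
#' @param dt sample interval in ms.
#' @param channels K+ components left unblocked (default all three;
#'   a subset emulates ideal pharmacological isolation).
#' @return list with `traces`, `template` (a [leak_template()]),
#'   `template_trace`, `subsweeps` (list per sweep or NULL), `commands`,
#'   and `truth` (ground-truth parameters for recovery tests).
#' @export
record_cell <- function(cell, protocol, noise_sd = 5, artifacts = TRUE,
                        seed = 1, pn_subsweeps = FALSE, n_template = 100,
                        dt = 0.05, channels = c("slow", "fast", "resid")) {
  stopifnot(inherits(cell, "synthetic_cell"))
  model <- cell_model(cell)
  kmod <- isolate_channels(model, intersect(channels,
                                            names(model$conductances)))
  ideal <- run_voltage_clamp(kmod, protocol, dt = dt)
  Rs_GOhm <- cell$passive$Rs / 1000
  g_leak <- model$g_leak
  commands <- lapply(seq_along(ideal), function(sw)
    command_waveform(protocol, sw, dt))
  local_seed(seed + 1000L * cell$seed, {
    traces <- lapply(seq_along(ideal), function(sw) {
      tr <- ideal[[sw]]
      y <- tr$y
      if (artifacts)
        y <- add_artifacts(y, commands[[sw]], g_leak, cell$passive$Ihold,
                           Rs_GOhm, cell$passive$Cm, dt)
      if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
      tr$y <- y
      tr
    })
    # averaged -5 mV, 20 ms template pulse from the holding potential
    tpl_prot <- step_protocol(protocol$holding,
                              list(list(level = protocol$holding - 5, dur = 20)),
                              label = "template", pad = 20)
    tpl_ideal <- run_voltage_clamp(kmod, tpl_prot, dt = dt)[[1]]
    tpl_cmd <- command_waveform(tpl_prot, 1, dt)
    ty <- tpl_ideal$y
    if (artifacts)
      ty <- add_artifacts(ty, tpl_cmd, g_leak, cell$passive$Ihold,
                          Rs_GOhm, cell$passive$Cm, dt)
    if (noise_sd > 0) ty <- ty + rnorm(length(ty), 0, noise_sd / sqrt(n_template))
    tpl_trace <- ktrace(tpl_ideal$t, ty, unit = "pA", label = "template")
    template <- leak_template(tpl_trace, pulse_start = 20, pulse_dur = 20,
                              dV = -5)
    subsweeps <- NULL
    if (pn_subsweeps) {
      subsweeps <- lapply(seq_along(ideal), function(sw) {
        cmd <- commands[[sw]]
        subV <- protocol$holding - (cmd$V - protocol$holding) / 5
        lapply(1:5, function(k) {
          I <- clamp_to_voltage(kmod, cmd$t, subV, include_leak = FALSE)
          y <- I$y
          if (artifacts)
            y <- add_artifacts(y, data.frame(t = cmd$t, V = subV), g_leak,
                               cell$passive$Ihold, Rs_GOhm, cell$passive$Cm, dt)
          if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
          ktrace(cmd$t, y, unit = "pA", sweep = sw, label = "pn_sub")
        })
      })
    }
    list(traces = traces, template = template, template_trace = tpl_trace,
         subsweeps = subsweeps, commands = commands,
         truth = list(multipliers = cell$multipliers, passive = cell$passive,
                      g_leak = g_leak))
  })
}

#' Drug condition: multiplicative per-component suppression
#'
#' Represents bath-applied channel blockers as per-component maximal-
#' conductance scaling in \[0, 1\] (no kinetic change): 20 mM TEA mainly
#' suppresses the slow-transient (and part of the residual) K+ current;
#' 5 mM 4-AP mainly the fast transient. Default factors are calibration
#' targets (see [calibrate_drug_factors()]), not measurements.
#'
#' @param name `"none"`, `"TEA"` or `"FourAP"`.
#' @param suppression named numeric factors in \[0, 1\]; defaults per name.
#' @return object of class `drug_condition`.
#' @export
drug_condition <- function(name = c("none", "TEA", "FourAP"),
                           suppression = NULL) {
  name <- match.arg(name)
  if (is.null(suppression))
    suppression <- switch(name,
      none = c(slow = 1, fast = 1, resid = 1),
      TEA = c(slow = 0.15, resid = 0.35, fast = 0.80),
      FourAP = c(fast = 0.10, slow = 0.85, resid = 0.95))
  if (any(suppression < 0 | suppression > 1))
    stop("suppression factors must lie in [0, 1]")
  structure(list(name = name, suppression = suppression),
            class = "drug_condition")
}

#' Apply a drug condition to a synthetic cell
#'
#' @param cell a [sample_cell()].
#' @param condition a [drug_condition()].
#' @return the cell with the named components' gbar multipliers scaled.
#' @export
apply_drug <- function(cell, condition) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(condition, "drug_condition"))
  unknown <- setdiff(names(condition$suppression), names(cell$multipliers))
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  for (nm in names(condition$suppression))
    cell$multipliers[[nm]] <- cell$multipliers[[nm]] * condition$suppression[[nm]]
  cell
}

peak_totalK_40 <- function(model, factors = NULL) {
  kmod <- isolate_channels(model, c("slow", "fast", "resid"))
  if (!is.null(factors))
    for (nm in names(factors))
      kmod$conductances[[nm]]$gbar <- kmod$conductances[[nm]]$gbar * factors[[nm]]
  prot <- total_activation()
  tr <- run_voltage_clamp(kmod, prot, sweeps = n_sweeps(prot))[[1]]
  peak_current(tr, test_pulse_window(prot, n_sweeps(prot)))
}

#' Calibrate drug suppression factors to the population peak ratio
#'
#' Scales a base factor set f0 along f(lambda) = 1 - lambda (1 - f0) so
#' that the noiseless peak total-K+ current at the +40 mV test pulse of the
#' stage preset, relative to the untreated peak, equals the published
#' population ratio (53.0% for 20 mM TEA, 76.1% for 5 mM 4-AP).
#' Deterministic (no sampling involved).
#'
#' @param stage stage preset to calibrate against (default diestrus).
#' @param name `"TEA"` or `"FourAP"`.
#' @param target target peak ratio (defaults: TEA 0.530, FourAP 0.761).
#' @return a calibrated [drug_condition()], with the achieved ratio in
#'   attribute `ratio`.
#' @export
calibrate_drug_factors <- function(stage = "diestrus",
                                   name = c("TEA", "FourAP"), target = NULL) {
  name <- match.arg(name)
  if (is.null(target)) target <- switch(name, TEA = 0.530, FourAP = 0.761)
  base <- drug_condition(name)$suppression
  model <- preset(stage)
  p0 <- peak_totalK_40(model)
  ratio_of <- function(lambda) {
    f <- pmax(1 - lambda * (1 - base), 0)
    peak_totalK_40(model, f) / p0
  }
  lam_max <- 1 / max(1 - base)
  r <- uniroot(function(l) ratio_of(l) - target, c(0, lam_max), tol = 1e-6)
  f <- pmax(1 - r$root * (1 - base), 0)
  cond <- drug_condition(name, suppression = f)
  attr(cond, "ratio") <- ratio_of(r$root)
  attr(cond, "lambda") <- r$root
  cond
}
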