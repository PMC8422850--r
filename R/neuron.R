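#' Single-compartment neuron model
#'
#' Assembles membrane capacitance, a named set of Hodgkin-Huxley
#' conductances, the Markov transient Na+ channel, an Ohmic leak and a
#' holding current into one model object.
#'
#' @param Cm membrane capacitance in pF (> 0).
#' @param conductances named list of [conductance_spec()] objects.
#' @param nat a [markov_nat_spec()] or `NULL` for models without transient Na+.
#' @param g_leak leak conductance in nS (>= 0).
#' @param E_leak leak reversal potential in mV.
#' @param Ihold holding current in pA.
#' @param label one of "diestrus", "proestrus", "hybrid", or free text.
#' @return an object of class `neuron_model`.
#' @export
neuron_model <- function(Cm, conductances = list(), nat = NULL,
                         g_leak = 0, E_leak = -70, Ihold = 0,
                         label = "custom") {
  stopifnot(is.finite(Cm), Cm > 0, is.finite(g_leak), g_leak >= 0,
            is.finite(E_leak), is.finite(Ihold))
  if (length(conductances)) {
    stopifnot(!is.null(names(conductances)), all(nzchar(names(conductances))))
    ok <- vapply(conductances, inherits, logical(1), "conductance_spec")
    if (!all(ok)) stop("all conductances must be conductance_spec objects")
  }
  if (!is.null(nat)) stopifnot(inherits(nat, "markov_nat_spec"))
  structure(list(Cm = Cm, conductances = conductances, nat = nat,
                 g_leak = g_leak, E_leak = E_leak, Ihold = Ihold,
                 label = label),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("<neuron_model:", x$label, ">\n")
  cat(sprintf("  Cm = %.2f pF, g_leak = %.4f nS (E_leak = %.1f mV), Ihold = %.3f pA\n",
              x$Cm, x$g_leak, x$E_leak, x$Ihold))
  for (nm in names(x$conductances)) {
    cs <- x$conductances[[nm]]
    cat(sprintf("  %-6s gbar = %6.2f nS  %-5s E = %6.1f mV  r = %d  n_h = %d\n",
                nm, cs$gbar, cs$df$law, cs$df$E, cs$r, length(cs$inactivation)))
  }
  if (!is.null(x$nat))
    cat(sprintf("  nat    gbar = %6.2f nS  markov E = %6.1f mV  O^%d\n",
                x$nat$gbar, x$nat$E, x$nat$open_exponent))
  invisible(x)
}

gate_from_json <- function(g) {
  tj <- g$tau
  tau <- switch(tj$form,
    constant = tau_spec("constant", fixed_value = tj$fixed_value),
    single_sigmoid = tau_spec("single_sigmoid", A = tj$A, B = tj$B, C = tj$C, D = tj$D),
    double_sigmoid = tau_spec("double_sigmoid", A = tj$A, B = tj$B, C = tj$C,
                              D = tj$D, E = tj$E, F = tj$F, G = tj$G),
    bell = tau_spec("bell", A = tj$A, B = tj$B, C = tj$C, D = tj$D,
                    E = tj$E, F = tj$F),
    stop("unknown tau form: ", tj$form))
  gating_spec(V50 = g$V50, K = g$K, tau = tau, sign_convention = g$sign)
}

#' Stage presets for the diestrous and proestrous models
#'
#' Builds the fully parameterized single-compartment model for the requested
#' estrous-cycle stage from the versioned preset files shipped with the
#' package (`inst/extdata/presets/`). The three K+ currents use GHK driving
#' with E = -92 mV; NaP, CaT, HCN and leak are Ohmic with
#' E = 50, 155, -19.9 and -70 mV; Cm = 17.62 pF; the Markov NaT channel
#' (gbar = 68.12 nS) is identical between stages.
#'
#' @param stage `"diestrus"` or `"proestrus"`.
#' @param ghk_prefactor GHK prefactor convention passed to [driving_force()].
#' @param open_exponent exponent on the NaT open state (default from preset).
#' @return a [neuron_model()].
#' @export
preset <- function(stage = c("diestrus", "proestrus"),
                   ghk_prefactor = c("V_over_VT", "mV"),
                   open_exponent = NULL) {
  stage <- match.arg(stage)
  ghk_prefactor <- match.arg(ghk_prefactor)
  key <- paste(stage, ghk_prefactor, open_exponent %||% "default", sep = "|")
  hit <- .preset_cache[[key]]
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "presets", paste0(stage, ".json"),
                      package = "kneuron", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  VT <- p$VT_mV
  chans <- lapply(names(p$channels), function(nm) {
    cj <- p$channels[[nm]]
    df <- driving_force(cj$law, E = cj$E_mV, VT = VT, ghk_prefactor = ghk_prefactor)
    inact <- lapply(cj$inactivation, function(h)
      list(gate = gate_from_json(h), weight = h$weight))
    conductance_spec(nm, gbar = cj$gbar_nS, df = df, m = gate_from_json(cj$m),
                     r = cj$r, inactivation = inact)
  })
  names(chans) <- names(p$channels)
  nj <- p$nat
  nat <- markov_nat_spec(
    gbar = nj$gbar_nS, E = nj$E_mV,
    alpha = rate_spec(nj$alpha$s, nj$alpha$k, nj$alpha$r),
    beta = rate_spec(nj$beta$s, nj$beta$k, nj$beta$r),
    r1 = rate_spec(nj$r1$s, nj$r1$k, nj$r1$r),
    r3 = rate_spec(nj$r3$s, nj$r3$k, nj$r3$r),
    open_exponent = if (is.null(open_exponent)) nj$open_exponent else open_exponent)
  out <- neuron_model(Cm = p$Cm_pF, conductances = chans, nat = nat,
                      g_leak = p$leak$g_nS, E_leak = p$leak$E_mV,
                      Ihold = p$Ihold_pA, label = p$label)
  .preset_cache[[key]] <- out
  out
}

.preset_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full steady-state gate/state assignment at a holding voltage
#'
#' HH gates are set to their Boltzmann steady states; the Markov Na+ states
#' are set to the null-space solution of the rate matrix, normalized to
#' C + O + I = 1. Used to initialize every simulation.
#'
#' @param model a [neuron_model()].
#' @param V holding voltage in mV.
#' @return list with per-channel `m` and `h` values and `nat = c(C, O, I)`.
#' @export
steady_state_model <- function(model, V) {
  stopifnot(inherits(model, "neuron_model"))
  gates <- lapply(model$conductances, function(cs) {
    list(m = steady_state(cs$m, V),
         h = vapply(cs$inactivation, function(e) steady_state(e$gate, V),
                    numeric(1)))
  })
  nat <- if (!is.null(model$nat)) markov_steady_state(model$nat, V) else NULL
  list(gates = gates, nat = nat)
}

#' Total membrane current at steady state
#'
#' Summed ionic current (outward positive) with all gates at steady state,
#' including leak. Useful for finding the resting potential and for setting
#' the holding current.
#'
#' @param model a [neuron_model()].
#' @param V membrane voltage in mV (vectorized).
#' @param include_leak include the leak current (default TRUE).
#' @return current in pA.
#' @export
steady_state_current <- function(model, V, include_leak = TRUE) {
  vapply(V, function(v) {
    st <- steady_state_model(model, v)
    I <- 0
    for (nm in names(model$conductances)) {
      cs <- model$conductances[[nm]]
      g <- st$gates[[nm]]
      I <- I + channel_current(cs, v, g$m, g$h)
    }
    if (!is.null(model$nat))
      I <- I + model$nat$gbar * st$nat[["O"]]^model$nat$open_exponent * (v - model$nat$E)
    if (include_leak) I <- I + model$g_leak * (v - model$E_leak)
    I
  }, numeric(1))
}

#' Measure input resistance from a small current step
#'
#' Runs a current-clamp simulation from the model's resting state and
#' reports the steady-state voltage deflection divided by the step
#' amplitude, as in whole-cell recordings.
#'
#' @param model a calibrated [neuron_model()].
#' @param I_step step amplitude in pA (default -5).
#' @param duration step duration in ms (default 500; deflection measured at
#'   the end of the step).
#' @param dt integration step in ms.
#' @return list with `Rin` (GOhm), `V_rest` (mV, just before the step) and
#'   `V_end` (mV, at the end of the step).
#' @export
measure_rin <- function(model, I_step = -5, duration = 500, dt = 0.01) {
  pre <- 100
  prot <- current_step_protocol(steps = I_step, duration = duration,
                                pre = pre, post = 50)
  tr <- run_current_clamp(model, prot, dt = dt)[[1]]
  i_base <- max(which(tr$t <= pre))
  i_end <- max(which(tr$t <= pre + duration))
  V_rest <- tr$y[i_base]; V_end <- tr$y[i_end]
  list(Rin = (V_end - V_rest) / I_step, V_rest = V_rest, V_end = V_end)
}

#' Calibrate leak conductance and holding current
#'
#' Adjusts `g_leak` and `Ihold` by fixed-point iteration so that (a) the
#' simulated resting potential before a pulse is within 50 uV of `V_target`
#' and (b) the input resistance measured from a small hyperpolarizing step
#' (-5 pA, 500 ms) equals `Rin_target` within 0.5% (internal tolerance
#' 10 uV / 0.1%). The holding current is set to the total steady-state
#' ionic current at `V_target`; the leak conductance absorbs the difference
#' between the measured and target input conductance.
#'
#' @param model a [neuron_model()].
#' @param V_target target resting potential in mV (default -70).
#' @param Rin_target target input resistance in GOhm (default 1).
#' @param max_iter maximum fixed-point iterations.
#' @param dt integration step in ms for the measurement simulations.
#' @return the calibrated model, with attributes `Rin` and `V_rest` holding
#'   the final measured values.
#' @export
calibrate <- function(model, V_target = -70, Rin_target = 1,
                      max_iter = 25, dt = 0.01) {
  stopifnot(inherits(model, "neuron_model"))
  for (it in seq_len(max_iter)) {
    model$Ihold <- steady_state_current(model, V_target)
    meas <- measure_rin(model, dt = dt)
    ok_V <- abs(meas$V_rest - V_target) < 0.01
    ok_R <- abs(meas$Rin - Rin_target) / Rin_target < 1e-3
    if (ok_V && ok_R) {
      attr(model, "Rin") <- meas$Rin
      attr(model, "V_rest") <- meas$V_rest
      return(model)
    }
    g_new <- model$g_leak + (1 / Rin_target - 1 / meas$Rin)
    if (!is.finite(g_new) || g_new < 0)
      stop("calibration failure: no feasible g_leak >= 0 for Rin_target = ",
           Rin_target, " GOhm")
    model$g_leak <- g_new
  }
  stop("calibration failure: did not converge in ", max_iter, " iterations")
}

#' Build a hybrid model by swapping conductances between stages
#'
#' Replaces the named conductances of `base` with the donor's versions
#' (maximal conductance and kinetics), as in the in-silico conductance
#' substitution experiments. The result is labelled "hybrid" and, by
#' default, re-calibrated so that resting potential and input resistance
#' match across all hybrids.
#'
#' @param base,donor [neuron_model()] objects with matching channel names.
#' @param channels character vector of channel names to take from the donor
#'   (may be empty).
#' @param recalibrate re-run [calibrate()] on the hybrid (default TRUE).
#' @param ... passed to [calibrate()].
#' @return a [neuron_model()].
#' @export
swap_conductances <- function(base, donor, channels = character(0),
                              recalibrate = TRUE, ...) {
  stopifnot(inherits(base, "neuron_model"), inherits(donor, "neuron_model"))
  unknown <- setdiff(channels, intersect(names(base$conductances),
                                         names(donor$conductances)))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  out <- base
  for (nm in channels) out$conductances[[nm]] <- donor$conductances[[nm]]
  if (length(channels)) out$label <- "hybrid"
  if (recalibrate) out <- calibrate(out, ...)
  out
}

# ---- flat numeric encoding shared with the C++ integrator ----

gate_vec <- function(g) {
  t <- g$tau
  form <- match(t$form, c("constant", "single_sigmoid", "double_sigmoid", "bell"))
  c(g$V50, g$K, as.numeric(g$sign_convention == "V_plus_V50"), form,
    if (is.null(t$fixed_value)) 0 else t$fixed_value,
    t$A, t$B, t$C, t$D, t$E, t$F, t$G)
}

flatten_model <- function(model) {
  chans <- lapply(model$conductances, function(cs) {
    h <- if (length(cs$inactivation))
      t(vapply(cs$inactivation, function(e) gate_vec(e$gate), numeric(12)))
    else matrix(0, 0, 12)
    w <- vapply(cs$inactivation, `[[`, numeric(1), "weight")
    list(gbar = cs$gbar, law = as.integer(cs$df$law == "ghk"), E = cs$df$E,
         VT = cs$df$VT, pref_mV = as.integer(cs$df$ghk_prefactor == "mV"),
         r = cs$r, m = gate_vec(cs$m), h = h, w = as.numeric(w))
  })
  nat <- if (is.null(model$nat)) NULL else {
    n <- model$nat
    list(gbar = n$gbar, E = n$E, expo = n$open_exponent,
         s = c(n$alpha$s, n$beta$s, n$r1$s, n$r3$s),
         k = c(n$alpha$k, n$beta$k, n$r1$k, n$r3$k),
         r = c(n$alpha$r, n$beta$r, n$r1$r, n$r3$r))
  }
  list(Cm = model$Cm, g_leak = model$g_leak, E_leak = model$E_leak,
       Ihold = model$Ihold, channels = unname(chans), nat = nat)
}

state_vector <- function(model, V) {
  st <- steady_state_model(model, V)
  x <- numeric(0)
  for (nm in names(model$conductances)) {
    g <- st$gates[[nm]]
    x <- c(x, g$m, g$h)
  }
  if (!is.null(model$nat)) x <- c(x, st$nat[["C"]], st$nat[["O"]])
  x
}
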