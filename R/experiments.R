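#' Recover steady-state parameters from simulated voltage clamp
#'
#' Runs the isolated-component clamp protocols for one stage and pushes the
#' simulated traces through the same analysis chain used for recordings
#' (peak extraction, GHK permeability conversion at -94 mV, Boltzmann /
#' exponential fits). Components are simulated in isolation, as in the
#' model-fitting workflow; the fast transient is isolated by the A - B
#' voltage subtraction and the residual from protocol B.
#'
#' @param stage `"diestrus"` or `"proestrus"`.
#' @param dt sample interval in ms.
#' @return data.frame with columns `component`, `measure`
#'   (`activation`/`inactivation`/`recovery_tau`), `V50`, `k`, `tau`.
#' @export
reproduce_vc_panels <- function(stage = "diestrus", dt = 0.05) {
  model <- preset(stage)
  rows <- list()
  add <- function(component, measure, V50 = NA, k = NA, tau = NA)
    rows[[length(rows) + 1]] <<- data.frame(
      component = component, measure = measure, V50 = V50, k = k, tau = tau)

  # slow transient: 1-s activation / 10-s prepulse inactivation
  slow <- isolate_channels(model, "slow")
  act <- total_activation()
  trs <- run_voltage_clamp(slow, act, dt = dt)
  g <- normalized_ghk_conductance(
    iv_curve(trs, function(i) test_pulse_window(act, i)))
  f <- fit_boltzmann(g$V, g$g_norm)
  add("slow", "activation", f$V50, f$k)

  inact <- total_inactivation()
  trs <- run_voltage_clamp(slow, inact, dt = dt)
  g <- normalized_ghk_conductance(
    iv_curve(trs, function(i) test_pulse_window(inact, i)), V_driving = 0)
  f <- fit_boltzmann(g$V, g$g_norm)
  add("slow", "inactivation", f$V50, f$k)

  # slow recovery from inactivation: 70-150 ms peak window rule
  rec <- slow_time_course()$recovery
  trs <- run_voltage_clamp(slow, rec, dt = dt)
  peaks <- vapply(seq_along(trs), function(i) {
    w <- test_pulse_window(rec, i)
    peak_current(trs[[i]], c(w[1] + 70, w[1] + 150))
  }, numeric(1))
  durs <- sweep_levels(rec)
  ef <- fit_exponential(durs, peaks / max(peaks))
  add("slow", "recovery_tau", tau = ef$tau)

  # fast transient: A - B subtraction, 150-ms tests
  fp <- fast_protocols()
  fast <- isolate_channels(model, "fast")
  trsA <- run_voltage_clamp(fast, fp$activationA, dt = dt)
  trsB <- run_voltage_clamp(fast, fp$activationB, dt = dt)
  iso <- lapply(seq_along(trsA), function(i)
    voltage_subtraction_isolate(trsA[[i]], trsB[[i]]))
  g <- normalized_ghk_conductance(
    iv_curve(iso, function(i) test_pulse_window(fp$activationA, i)))
  f <- fit_boltzmann(g$V, g$g_norm)
  add("fast", "activation", f$V50, f$k)

  trs <- run_voltage_clamp(fast, fp$inactivation, dt = dt)
  g <- normalized_ghk_conductance(
    iv_curve(trs, function(i) test_pulse_window(fp$inactivation, i)),
    V_driving = -10)
  f <- fit_boltzmann(g$V, g$g_norm)
  add("fast", "inactivation", f$V50, f$k)

  # residual: protocol B isolates it (fast inactivated by -30 mV hold)
  resid <- isolate_channels(model, "resid")
  trs <- run_voltage_clamp(resid, fp$activationB, dt = dt)
  g <- normalized_ghk_conductance(
    iv_curve(trs, function(i) test_pulse_window(fp$activationB, i)))
  f <- fit_boltzmann(g$V, g$g_norm)
  add("resid", "activation", f$V50, f$k)

  out <- do.call(rbind, rows)
  out$stage <- stage
  out
}

hybrid_specs <- function() {
  list(
    di_full = list(base = "diestrus", channels = character(0)),
    pro_full = list(base = "proestrus", channels = character(0)),
    di_proK = list(base = "diestrus", channels = c("slow", "fast", "resid")),
    di_proSlow = list(base = "diestrus", channels = "slow"),
    di_proFast = list(base = "diestrus", channels = "fast"),
    di_proResid = list(base = "diestrus", channels = "resid"),
    di_proCaT = list(base = "diestrus", channels = "cat"),
    di_proNaP = list(base = "diestrus", channels = "nap"),
    di_proH = list(base = "diestrus", channels = "hcn"),
    di_proInward = list(base = "diestrus", channels = c("cat", "nap", "hcn")))
}

#' Conductance-swap simulation suite
#'
#' Builds the full set of diestrous-based hybrid models (single and grouped
#' K+ and subthreshold-inward substitutions from the proestrous model),
#' re-calibrates each to -70 mV / 1 GOhm, runs the F-I protocol, and counts
#' rebound spikes after the -30 pA step.
#'
#' @param dt integration step in ms.
#' @param hybrids optional subset of hybrid names (see source for the set).
#' @return list with `summary` (data.frame: hybrid, rheobase_pA,
#'   rebound_spikes, total_spikes, Rin, V_rest) and `fi` (named list of
#'   [fi_curve()] objects).
#' @export
swap_suite <- function(dt = 0.01, hybrids = NULL) {
  specs <- hybrid_specs()
  if (!is.null(hybrids)) specs <- specs[hybrids]
  di <- preset("diestrus"); pro <- preset("proestrus")
  prot <- fi_protocol(experimental = FALSE)
  fis <- list(); rows <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    base <- if (sp$base == "diestrus") di else pro
    donor <- if (sp$base == "diestrus") pro else di
    mod <- if (length(sp$channels))
      swap_conductances(base, donor, sp$channels, dt = dt)
    else calibrate(base, dt = dt)
    trs <- run_current_clamp(mod, prot, dt = dt)
    fi <- fi_curve(trs, prot)
    fis[[nm]] <- fi
    i30 <- which(prot$steps == -30)
    reb <- if (length(i30))
      rebound_spikes(trs[[i30]], prot$pre + prot$duration) else NA_integer_
    rows[[nm]] <- data.frame(
      hybrid = nm, rheobase_pA = rheobase(fi),
      rebound_spikes = reb, total_spikes = sum(fi$n_spikes),
      Rin = attr(mod, "Rin"), V_rest = attr(mod, "V_rest"))
  }
  list(summary = do.call(rbind, rows), fi = fis)
}

#' Rheobase action-potential comparison between stages
#'
#' Extracts the rheobase spike of the calibrated diestrous and proestrous
#' models and reports threshold (rate of rise > 2 V/s) and amplitude
#' (threshold to peak).
#'
#' @param dt integration step in ms.
#' @return data.frame with columns `stage`, `rheobase_pA`, `threshold_mV`,
#'   `amplitude_mV`, `peak_mV` (NA with a message if a stage never fires).
#' @export
rheobase_ap_comparison <- function(dt = 0.01) {
  prot <- fi_protocol(experimental = FALSE)
  rows <- lapply(c("diestrus", "proestrus"), function(stage) {
    mod <- calibrate(preset(stage), dt = dt)
    trs <- run_current_clamp(mod, prot, dt = dt)
    fi <- fi_curve(trs, prot)
    rb <- rheobase(fi)
    if (is.na(rb))
      return(data.frame(stage = stage, rheobase_pA = NA_real_,
                        threshold_mV = NA_real_, amplitude_mV = NA_real_,
                        peak_mV = NA_real_))
    tr <- trs[[which(prot$steps == rb)]]
    spk <- detect_spikes(tr, c(prot$pre, prot$pre + prot$duration))
    thr <- ap_threshold(tr, spk[1])
    pk <- max(tr$y[tr$t >= spk[1] - 1 & tr$t <= spk[1] + 1])
    data.frame(stage = stage, rheobase_pA = rb, threshold_mV = thr,
               amplitude_mV = pk - thr, peak_mV = pk)
  })
  do.call(rbind, rows)
}
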