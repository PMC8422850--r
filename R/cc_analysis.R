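#' Detect action potentials in a voltage trace
#'
#' Local maxima whose peak is depolarized relative to -10 mV, separated by
#' at least `min_separation` ms (the larger peak wins within a conflict).
#'
#' @param trace voltage [ktrace()].
#' @param window optional `c(start, end)` in ms restricting the search.
#' @param threshold peak criterion in mV (default -10).
#' @param min_separation minimum inter-spike separation in ms (default 2).
#' @return numeric vector of spike peak times in ms (possibly empty).
#' @export
detect_spikes <- function(trace, window = NULL, threshold = -10,
                          min_separation = 2) {
  stopifnot(inherits(trace, "ktrace"))
  t <- trace$t; y <- trace$y
  n <- length(y)
  if (n < 3) return(numeric(0))
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max & y > threshold)
  if (!is.null(window)) idx <- idx[t[idx] > window[1] & t[idx] <= window[2]]
  if (length(idx) > 1) {
    keep <- order(y[idx], decreasing = TRUE)
    chosen <- integer(0)
    for (i in idx[keep]) {
      if (!length(chosen) || all(abs(t[i] - t[chosen]) >= min_separation))
        chosen <- c(chosen, i)
    }
    idx <- sort(chosen)
  }
  t[idx]
}

#' Action-potential threshold
#'
#' Membrane voltage at the first sample, within `lookback` ms preceding the
#' spike peak, where the rate of rise (central difference) exceeds
#' 2 V/s (= 2 mV/ms).
#'
#' @param trace voltage [ktrace()].
#' @param spike_time peak time in ms (from [detect_spikes()]).
#' @param dvdt_crit threshold criterion in mV/ms (default 2).
#' @param lookback search window before the peak in ms (default 10).
#' @return threshold voltage in mV.
#' @export
ap_threshold <- function(trace, spike_time, dvdt_crit = 2, lookback = 10) {
  t <- trace$t; y <- trace$y
  n <- length(y)
  dt <- t[2] - t[1]
  dvdt <- c(NA, (y[3:n] - y[1:(n - 2)]) / (2 * dt), NA)
  ipk <- which.min(abs(t - spike_time))
  sel <- which(t >= spike_time - lookback & t <= spike_time)
  sel <- sel[!is.na(dvdt[sel])]
  cross <- sel[dvdt[sel] > dvdt_crit]
  if (!length(cross))
    stop("no threshold: dV/dt never exceeds ", dvdt_crit, " mV/ms before the peak")
  y[cross[1]]
}

#' Firing-current (F-I) curve
#'
#' Counts spikes within the stimulus window of each sweep and reports the
#' rheobase, the smallest depolarizing step that evokes at least one spike.
#'
#' @param traces list of voltage [ktrace()] objects, one per current step
#'   (levels carry the step amplitudes), e.g. from [run_current_clamp()].
#' @param protocol the [current_step_protocol()] used (defaults to the one
#'   attached to `traces`).
#' @return object of class `fi_curve`: data.frame with columns `I_pA` and
#'   `n_spikes`, and attribute `rheobase` (pA, or NA if no depolarizing
#'   step fires).
#' @export
fi_curve <- function(traces, protocol = attr(traces, "protocol")) {
  stopifnot(!is.null(protocol))
  win <- c(protocol$pre, protocol$pre + protocol$duration)
  I <- vapply(traces, `[[`, numeric(1), "level")
  counts <- vapply(traces, function(tr) length(detect_spikes(tr, win)), numeric(1))
  out <- data.frame(I_pA = I, n_spikes = as.integer(counts))
  firing <- out$I_pA > 0 & out$n_spikes >= 1
  attr(out, "rheobase") <- if (any(firing)) min(out$I_pA[firing]) else NA_real_
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Rheobase of an F-I curve
#' @param fi an [fi_curve()].
#' @return rheobase in pA (NA if none).
#' @export
rheobase <- function(fi) attr(fi, "rheobase")

#' Count rebound spikes after stimulus offset
#'
#' Spikes in the interval (offset, offset + window] following release from
#' a hyperpolarizing step (postinhibitory rebound).
#'
#' @param trace voltage [ktrace()].
#' @param offset_time stimulus offset in ms.
#' @param window analysis window after offset in ms (default 500).
#' @return integer spike count.
#' @export
rebound_spikes <- function(trace, offset_time, window = 500) {
  length(detect_spikes(trace, c(offset_time, offset_time + window)))
}
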