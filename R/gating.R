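#' Thermal voltage kT/q
#'
#' Boltzmann constant times absolute temperature over the elementary charge,
#' in millivolts. At the 31 degree C bath temperature used for slice
#' recordings this is 26.21 mV; the voltage-clamp analysis reversal potential
#' was computed at room temperature (~21 degree C).
#'
#' @param temp_celsius temperature in degrees Celsius.
#' @return thermal voltage in mV.
#' @export
#' @examples
#' thermal_voltage(31) # ~26.21 mV
thermal_voltage <- function(temp_celsius = 31) {
  8.617333262e-2 * (temp_celsius + 273.15)
}

#' Nernst equilibrium potential
#'
#' @param c_in,c_out internal and external ion concentrations (same units).
#' @param temp_celsius temperature in degrees Celsius.
#' @param z ionic valence.
#' @return equilibrium potential in mV.
#' @export
#' @examples
#' nernst(145, 3.5, temp_celsius = 21) # K+ reversal, ~ -94 mV
nernst <- function(c_in, c_out, temp_celsius = 21, z = 1) {
  stopifnot(c_in > 0, c_out > 0, z != 0)
  thermal_voltage(temp_celsius) / z * log(c_out / c_in)
}

#' Voltage-dependent time constant specification
#'
#' Four functional forms cover every gate in the models:
#' \describe{
#'   \item{constant}{tau(V) = fixed_value}
#'   \item{single_sigmoid}{tau(V) = A + B / (1 + exp((V - C)/D))}
#'   \item{double_sigmoid}{tau(V) = A + (B / (1 + exp((V - C)/D))) *
#'     (E / (1 + exp((V - F)/G)))}
#'   \item{bell}{tau(V) = E / (exp((A + V)/B) + exp((C + V)/D)) + F
#'     (persistent-Na inactivation)}
#' }
#' The spec is validated to give a strictly positive time constant over
#' the physiological range -120..+60 mV.
#'
#' @param form one of "constant", "single_sigmoid", "double_sigmoid", "bell".
#' @param fixed_value time constant in ms (constant form only).
#' @param A,B,C,D,E,F,G parameters (ms and mV as applicable).
#' @return an object of class `tau_spec`.
#' @export
tau_spec <- function(form = c("constant", "single_sigmoid", "double_sigmoid", "bell"),
                     fixed_value = NULL,
                     A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_,
                     E = NA_real_, F = NA_real_, G = NA_real_) {
  form <- match.arg(form)
  spec <- structure(
    list(form = form, fixed_value = fixed_value,
         A = A, B = B, C = C, D = D, E = E, F = F, G = G),
    class = "tau_spec")
  if (form == "constant") {
    if (is.null(fixed_value) || !is.finite(fixed_value) || fixed_value <= 0)
      stop("invalid tau_spec: constant form needs a positive fixed_value")
  } else {
    vals <- time_constant(spec, seq(-120, 60, by = 0.5))
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("invalid tau_spec: non-positive time constant on [-120, 60] mV")
  }
  spec
}

#' Evaluate a voltage-dependent time constant
#'
#' @param spec a [tau_spec()].
#' @param V membrane voltage in mV (vectorized).
#' @return time constant(s) in ms.
#' @export
time_constant <- function(spec, V) {
  stopifnot(inherits(spec, "tau_spec"))
  out <- switch(spec$form,
    constant = rep(spec$fixed_value, length(V)),
    single_sigmoid = spec$A + spec$B / (1 + exp((V - spec$C) / spec$D)),
    double_sigmoid = spec$A +
      (spec$B / (1 + exp((V - spec$C) / spec$D))) *
      (spec$E / (1 + exp((V - spec$F) / spec$G))),
    bell = spec$E / (exp((spec$A + V) / spec$B) + exp((spec$C + V) / spec$D)) + spec$F
  )
  if (any(!is.finite(out)) || any(out <= 0))
    stop("invalid tau_spec: non-positive or non-finite time constant at V = ",
         paste(V[!is.finite(out) | out <= 0][1]))
  out
}

#' Gating variable specification (Boltzmann steady state)
#'
#' Steady state is 1 / (1 + exp(x / K)) with x = (V - V50) under the
#' `"V_minus_V50"` convention or x = (V + V50) under `"V_plus_V50"`.
#' With this convention K < 0 gives an activation curve (increasing with
#' depolarization) and K > 0 an inactivation curve. The persistent-Na gates
#' are tabulated with positive half-voltages and use the `"V_plus_V50"`
#' convention (half-activation at -V50).
#'
#' @param V50 half-activation/inactivation voltage parameter (mV).
#' @param K slope factor (mV, signed, non-zero).
#' @param sign_convention `"V_minus_V50"` (default) or `"V_plus_V50"`.
#' @param tau a [tau_spec()] giving the voltage-dependent time constant.
#' @return an object of class `gating_spec`.
#' @export
gating_spec <- function(V50, K, tau,
                        sign_convention = c("V_minus_V50", "V_plus_V50")) {
  sign_convention <- match.arg(sign_convention)
  if (!is.finite(K) || K == 0) stop("invalid gating_spec: K must be non-zero")
  stopifnot(is.finite(V50), inherits(tau, "tau_spec"))
  structure(list(V50 = V50, K = K, sign_convention = sign_convention, tau = tau),
            class = "gating_spec")
}

#' Steady-state value of a gating variable
#'
#' @param spec a [gating_spec()].
#' @param V membrane voltage in mV (vectorized).
#' @return steady-state open fraction in (0, 1).
#' @export
steady_state <- function(spec, V) {
  stopifnot(inherits(spec, "gating_spec"))
  x <- if (spec$sign_convention == "V_plus_V50") V + spec$V50 else V - spec$V50
  1 / (1 + exp(x / spec$K))
}

#' Driving-force specification
#'
#' Ohmic driving is (V - E). GHK driving follows the Goldman-Hodgkin-Katz
#' current equation,
#' `(V/VT) * (exp((V - E)/VT) - 1) / (exp(V/VT) - 1)`,
#' with the removable singularity at V = 0 evaluated in the limit
#' (`expm1(-E/VT)`). Both laws are exactly zero at V = E and agree in sign
#' everywhere. The dimensionless-prefactor (V/VT) reading of the GHK
#' equation is the default because it composes with nS-scale maximal
#' conductances to give physiological pA-scale currents; the mV-prefactor
#' variant (driving = V * (...)) is available via `ghk_prefactor = "mV"`.
#'
#' @param law `"ohmic"` or `"ghk"`.
#' @param E reversal potential in mV.
#' @param VT thermal voltage kT/q in mV (default 26.21, i.e. 31 degree C).
#' @param ghk_prefactor `"V_over_VT"` (default) or `"mV"`.
#' @return an object of class `driving_force`.
#' @export
driving_force <- function(law = c("ohmic", "ghk"), E, VT = thermal_voltage(31),
                          ghk_prefactor = c("V_over_VT", "mV")) {
  law <- match.arg(law)
  ghk_prefactor <- match.arg(ghk_prefactor)
  stopifnot(is.finite(E), is.finite(VT), VT > 0)
  structure(list(law = law, E = E, VT = VT, ghk_prefactor = ghk_prefactor),
            class = "driving_force")
}

#' Evaluate a driving force
#'
#' @param df a [driving_force()].
#' @param V membrane voltage in mV (vectorized).
#' @return driving force such that gbar (nS) x gates x driving = current (pA),
#'   outward positive.
#' @export
driving <- function(df, V) {
  stopifnot(inherits(df, "driving_force"))
  if (df$law == "ohmic") return(V - df$E)
  VT <- df$VT
  num <- expm1((V - df$E) / VT)
  den <- expm1(V / VT)
  pref <- if (df$ghk_prefactor == "mV") V else V / VT
  out <- pref * num / den
  # V -> 0 limit: num -> expm1(-E/VT), den ~ V/VT
  small <- abs(V) < 1e-9
  if (any(small)) {
    lim <- expm1(-df$E / VT)
    if (df$ghk_prefactor == "mV") lim <- VT * lim
    out[small] <- lim
  }
  out
}

#' Ionic current through one conductance
#'
#' I = gbar * m^r * H * driving(V), where H is the (possibly composite)
#' inactivation term, a weighted sum over the channel's inactivation gates.
#' Outward current is positive.
#'
#' @param cs a [conductance_spec()].
#' @param V membrane voltage in mV.
#' @param m activation gate value in \[0, 1\].
#' @param h numeric vector of inactivation gate values (one per inactivation
#'   gate in `cs`; ignored if the channel does not inactivate).
#' @return current in pA.
#' @export
channel_current <- function(cs, V, m, h = numeric(0)) {
  stopifnot(inherits(cs, "conductance_spec"))
  if (any(m < 0 | m > 1)) stop("gate values must lie in [0, 1]")
  H <- 1
  if (length(cs$inactivation)) {
    if (length(h) != length(cs$inactivation))
      stop("need one h value per inactivation gate")
    if (any(h < 0 | h > 1)) stop("gate values must lie in [0, 1]")
    H <- sum(vapply(seq_along(h), function(i) cs$inactivation[[i]]$weight * h[i],
                    numeric(1)))
  }
  cs$gbar * m^cs$r * H * driving(cs$df, V)
}

#' Conductance (channel) specification
#'
#' One voltage-gated channel: maximal conductance, driving-force law,
#' activation gate with exponent r, and zero or more inactivation gates,
#' each a (gating_spec, weight) pair. Weights must sum to 1 when any
#' inactivation gate is present (the fast-transient K+ current uses two
#' inactivation gates with fixed time constants sharing one steady state).
#'
#' @param name channel identifier.
#' @param gbar maximal conductance in nS (>= 0).
#' @param df a [driving_force()].
#' @param m activation [gating_spec()].
#' @param r integer activation exponent (>= 1).
#' @param inactivation list of `list(gate = gating_spec, weight = w)` entries;
#'   empty for non-inactivating channels such as HCN.
#' @return an object of class `conductance_spec`.
#' @export
conductance_spec <- function(name, gbar, df, m, r = 1L, inactivation = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(gbar), gbar >= 0, r >= 1,
            inherits(df, "driving_force"), inherits(m, "gating_spec"))
  if (length(inactivation)) {
    ok <- vapply(inactivation, function(e)
      inherits(e$gate, "gating_spec") && is.finite(e$weight) && e$weight >= 0,
      logical(1))
    if (!all(ok)) stop("each inactivation entry needs a gating_spec and a weight")
    w <- vapply(inactivation, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-9) stop("inactivation weights must sum to 1")
  }
  structure(list(name = name, gbar = gbar, df = df, m = m, r = as.integer(r),
                 inactivation = inactivation),
            class = "conductance_spec")
}
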