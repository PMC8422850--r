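#' Transition-rate specification for the Markov Na+ channel
#'
#' Each rate is a falling sigmoid of voltage, rate(V) = r / (1 + exp((V + s)/k)),
#' in ms^-1. With k < 0 the rate grows with depolarization.
#'
#' @param s half-voltage offset (mV).
#' @param k slope (mV, signed, non-zero).
#' @param r maximal rate (ms^-1, >= 0).
#' @return an object of class `rate_spec`.
#' @export
rate_spec <- function(s, k, r) {
  if (!is.finite(k) || k == 0) stop("invalid rate_spec: k must be non-zero")
  stopifnot(is.finite(s), is.finite(r), r >= 0)
  structure(list(s = s, k = k, r = r), class = "rate_spec")
}

eval_rate <- function(rs, V) rs$r / (1 + exp((V + rs$s) / rs$k))

#' Three-state Markov transient Na+ channel specification
#'
#' States closed (C), open (O), inactivated (I) with transitions
#' C -> O at alpha(V), O -> C at beta(V), O -> I at r1(V), I -> C at r3(V),
#' and I = 1 - C - O by conservation. The current is
#' I_NaT = gbar * O^open_exponent * (V - E).
#'
#' @param gbar maximal conductance (nS).
#' @param E reversal potential (mV).
#' @param alpha,beta,r1,r3 [rate_spec()] objects.
#' @param open_exponent integer exponent on the open-state occupancy
#'   (default 3, as printed; configurable to 1).
#' @return an object of class `markov_nat_spec`.
#' @export
markov_nat_spec <- function(gbar, E, alpha, beta, r1, r3, open_exponent = 3L) {
  stopifnot(is.finite(gbar), gbar >= 0, is.finite(E), open_exponent >= 1,
            inherits(alpha, "rate_spec"), inherits(beta, "rate_spec"),
            inherits(r1, "rate_spec"), inherits(r3, "rate_spec"))
  structure(list(gbar = gbar, E = E, alpha = alpha, beta = beta,
                 r1 = r1, r3 = r3, open_exponent = as.integer(open_exponent)),
            class = "markov_nat_spec")
}

#' Voltage-dependent transition rates of the Markov Na+ channel
#'
#' @param spec a [markov_nat_spec()].
#' @param V membrane voltage in mV.
#' @return named list with elements `alpha`, `beta`, `r1`, `r3` (ms^-1).
#' @export
markov_rates <- function(spec, V) {
  stopifnot(inherits(spec, "markov_nat_spec"))
  list(alpha = eval_rate(spec$alpha, V), beta = eval_rate(spec$beta, V),
       r1 = eval_rate(spec$r1, V), r3 = eval_rate(spec$r3, V))
}

# Reduced 2-state linear system in x = (C, O):
#   dC/dt = -(alpha + r3) C + (beta - r3) O + r3
#   dO/dt = alpha C - (beta + r1) O
markov_system <- function(spec, V) {
  rt <- markov_rates(spec, V)
  A <- matrix(c(-(rt$alpha + rt$r3), rt$alpha,
                rt$beta - rt$r3, -(rt$beta + rt$r1)), 2, 2)
  list(A = A, b = c(rt$r3, 0))
}

#' Steady-state occupancies of the Markov Na+ channel
#'
#' Solves the null space of the rate matrix at fixed voltage, normalized to
#' C + O + I = 1.
#'
#' @param spec a [markov_nat_spec()].
#' @param V membrane voltage in mV (scalar).
#' @return named numeric vector `c(C = , O = , I = )`.
#' @export
markov_steady_state <- function(spec, V) {
  sys <- markov_system(spec, V)
  x <- tryCatch(solve(sys$A, -sys$b),
                error = function(e) stop("numerical degeneracy: singular Markov rate matrix at V = ", V))
  C <- x[1]; O <- x[2]
  c(C = C, O = O, I = 1 - C - O)
}

# Advance (C, O) exactly over dt at frozen voltage: x(dt) = xss + expm(A dt) (x0 - xss)
markov_advance <- function(spec, V, x0, dt) {
  sys <- markov_system(spec, V)
  xss <- solve(sys$A, -sys$b)
  xss + expm2x2(sys$A, dt) %*% (x0 - xss)
}

# 2x2 matrix exponential expm(A t), robust to complex eigenvalues.
expm2x2 <- function(A, t) {
  mu <- (A[1, 1] + A[2, 2]) / 2
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  q2 <- mu * mu - detA
  if (q2 > 1e-24) {
    q <- sqrt(q2)
    ch <- cosh(q * t); sh <- sinh(q * t) / q
  } else if (q2 < -1e-24) {
    w <- sqrt(-q2)
    ch <- cos(w * t); sh <- sin(w * t) / w
  } else {
    ch <- 1; sh <- t
  }
  exp(mu * t) * (ch * diag(2) + sh * (A - mu * diag(2)))
}
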