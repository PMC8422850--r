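# gating module: steady states, time constants, driving forces, currents

test_that("steady_state midpoints, limits and conventions", {
  g <- simple_gate(-20, -8)
  expect_equal(steady_state(g, -20), 0.5)
  # diestrus slow activation: K < 0 means activation rises with V
  slow_m <- gating_spec(-1.70, -7.73, const_tau(1.4))
  expect_equal(steady_state(slow_m, 1e6), 1.0)
  expect_equal(steady_state(slow_m, -1e6), 0.0)
  # NaP convention: x = (V + V50), half-activation at -V50
  nap_m <- gating_spec(50.45, -3.72, const_tau(0.4),
                       sign_convention = "V_plus_V50")
  expect_equal(steady_state(nap_m, -50.45), 0.5)
  expect_error(gating_spec(-20, 0, const_tau(1)), "K must be non-zero")
})

test_that("steady_state is monotone and bounded for all preset gates", {
  V <- seq(-120, 60, by = 1)
  for (stage in c("diestrus", "proestrus")) {
    model <- preset(stage)
    for (cs in model$conductances) {
      gates <- c(list(cs$m), lapply(cs$inactivation, `[[`, "gate"))
      for (g in gates) {
        y <- steady_state(g, V)
        expect_true(all(y > 0 & y < 1))
        d <- diff(y)
        if (g$K < 0) expect_true(all(d >= 0)) else expect_true(all(d <= 0))
      }
    }
  }
})

test_that("time_constant forms evaluate correctly", {
  # fast m: B = 0 forces tau = A at every V
  fast_m <- tau_spec("single_sigmoid", A = 0.53, B = 0, C = -8.68, D = 7.88)
  expect_equal(time_constant(fast_m, c(-100, -20, 40)), rep(0.53, 3))
  # NaP h bell at the symmetric point V = -A: E/2 + F
  bell <- tau_spec("bell", A = 67.30, B = -27.50, C = 67.30, D = 27.50,
                   E = 4650.15, F = 62.48)
  expect_equal(time_constant(bell, -67.30), 4650.15 / 2 + 62.48, tolerance = 1e-12)
  # diestrus slow m double sigmoid at V = 0: direct hand evaluation
  sm <- tau_spec("double_sigmoid", A = 1.40, B = 1.54, C = 15.81, D = -0.27,
                 E = 8.67, F = 2.89, G = 8.50)
  hand <- 1.40 + (1.54 / (1 + exp((0 - 15.81) / -0.27))) *
    (8.67 / (1 + exp((0 - 2.89) / 8.50)))
  expect_equal(time_constant(sm, 0), hand, tolerance = 1e-12)
  expect_error(tau_spec("constant", fixed_value = -1), "positive")
  expect_error(tau_spec("single_sigmoid", A = -5, B = 0.1, C = 0, D = 5),
               "non-positive")
})

test_that("time_constant > 0 on [-120, 60] for every preset gate", {
  V <- seq(-120, 60, by = 0.5)
  for (stage in c("diestrus", "proestrus")) {
    model <- preset(stage)
    for (cs in model$conductances) {
      gates <- c(list(cs$m), lapply(cs$inactivation, `[[`, "gate"))
      for (g in gates) expect_true(all(time_constant(g$tau, V) > 0))
    }
  }
})

test_that("driving forces: zero at reversal, limits, linearization", {
  ghk <- driving_force("ghk", E = -92, VT = 26.21)
  ohm <- driving_force("ohmic", E = -70)
  expect_equal(driving(ghk, -92), 0)
  expect_equal(driving(ohm, -69), 1)
  # V -> 0 removable singularity equals evaluation at +/- 1e-6 mV
  lim <- driving(ghk, 0)
  expect_equal(lim, expm1(92 / 26.21), tolerance = 1e-12)
  expect_equal(driving(ghk, 1e-6), lim, tolerance = 1e-6)
  expect_equal(driving(ghk, -1e-6), lim, tolerance = 1e-6)
  # mV-prefactor variant is VT times larger
  ghk_mv <- driving_force("ghk", E = -92, VT = 26.21, ghk_prefactor = "mV")
  expect_equal(driving(ghk_mv, 0), 26.21 * lim, tolerance = 1e-12)
  # sign agreement with ohmic everywhere, zero only at E
  V <- seq(-120, 60, by = 0.25)
  gd <- driving(ghk, V)
  od <- V - (-92)
  expect_true(all(sign(gd) == sign(od)))
  expect_true(all(abs(gd[abs(V + 92) > 1e-9]) > 0))
  # near-linear for |V - E| << VT
  eps <- c(-0.5, -0.1, 0.1, 0.5)
  slope <- driving(ghk, -92 + eps) / eps
  expect_lt(max(abs(slope / slope[1] - 1)), 0.02)
})

test_that("channel_current composes gbar, gates and driving force", {
  di <- preset("diestrus")
  resid <- di$conductances$resid
  V <- 40
  m <- steady_state(resid$m, V)
  h <- steady_state(resid$inactivation[[1]]$gate, V)
  I <- channel_current(resid, V, m, h)
  # oracle: independent re-composition of the three factor functions
  oracle <- 29.7 *
    (1 / (1 + exp((V + 5.54) / -8.85))) *
    (1 / (1 + exp((V + 39.16) / 11.29))) *
    (V / 26.21) * expm1((V + 92) / 26.21) / expm1(V / 26.21)
  expect_equal(I, oracle, tolerance = 1e-12)
  expect_equal(channel_current(resid, -92, 0.5, 0.5), 0)
  expect_equal(channel_current(resid, 40, 0, 1), 0)
  expect_error(channel_current(resid, 40, 1.5, 1), "\\[0, 1\\]")
})

test_that("conductance_spec validates inactivation weights", {
  df <- driving_force("ohmic", E = -70)
  expect_error(
    conductance_spec("x", 1, df, simple_gate(-20, -8),
                     inactivation = list(list(gate = simple_gate(-50, 7),
                                              weight = 0.7))),
    "sum to 1")
})
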