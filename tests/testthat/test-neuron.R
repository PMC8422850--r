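# neuron module: presets, Markov channel, steady states, calibration, swaps

test_that("presets carry the published parameter sets", {
  di <- preset("diestrus")
  pro <- preset("proestrus")
  gb <- function(m) vapply(m$conductances, `[[`, numeric(1), "gbar")
  expect_equal(unname(gb(di)), c(37.4, 36.9, 29.7, 0.14, 1.60, 0.11))
  expect_equal(unname(gb(pro)), c(42.0, 45.7, 32.9, 0.20, 2.0, 0.64))
  expect_equal(di$nat$gbar, 68.12)
  expect_equal(pro$nat$gbar, 68.12)
  expect_equal(di$Cm, 17.62)
  expect_equal(di$g_leak, 1.06)
  expect_equal(pro$g_leak, 0.88)
  # K channels GHK at -92; inward channels Ohmic at printed reversals
  for (nm in c("slow", "fast", "resid")) {
    expect_equal(di$conductances[[nm]]$df$law, "ghk")
    expect_equal(di$conductances[[nm]]$df$E, -92)
  }
  expect_equal(di$conductances$nap$df$E, 50)
  expect_equal(di$conductances$cat$df$E, 155)
  expect_equal(di$conductances$hcn$df$E, -19.9)
  expect_equal(di$E_leak, -70)
  expect_equal(di$conductances$cat$r, 2L)
  expect_length(di$conductances$hcn$inactivation, 0)
  expect_length(di$conductances$fast$inactivation, 2)
  # fast activation kinetics shared between stages, slow kinetics differ
  expect_equal(pro$conductances$fast$m$V50, di$conductances$fast$m$V50)
  expect_false(pro$conductances$slow$m$V50 == di$conductances$slow$m$V50)
})

test_that("markov_rates match the sigmoid rate law", {
  nat <- preset("diestrus")$nat
  r <- markov_rates(nat, -65.24)
  expect_equal(r$alpha, 38.40 / 2, tolerance = 1e-12) # midpoint of alpha
  expect_equal(markov_rates(nat, 1e6)$beta, 0)        # k > 0 limit
  r100 <- markov_rates(nat, -100)
  expect_equal(r100$r3, 0.014 / (1 + exp((-100 + 12.68) / 3.08)),
               tolerance = 1e-12)
})

test_that("markov steady state solves the null space and matches relaxation", {
  nat <- preset("diestrus")$nat
  for (V in c(-100, -70, -40, 0)) {
    ss <- markov_steady_state(nat, V)
    expect_equal(sum(ss), 1, tolerance = 1e-12)
    expect_true(all(ss >= 0 & ss <= 1))
    # null space: derivatives vanish
    rt <- markov_rates(nat, V)
    dC <- rt$beta * ss[["O"]] + rt$r3 * ss[["I"]] - rt$alpha * ss[["C"]]
    dO <- rt$alpha * ss[["C"]] - (rt$beta + rt$r1) * ss[["O"]]
    expect_lt(abs(dC) + abs(dO), 1e-12)
  }
  # oracle: dense implicit-Euler time stepping from a different start
  V <- -70
  rt <- markov_rates(nat, V)
  A <- matrix(c(-(rt$alpha + rt$r3), rt$alpha,
                rt$beta - rt$r3, -(rt$beta + rt$r1)), 2, 2)
  b <- c(rt$r3, 0)
  x <- c(C = 0.2, O = 0.5)
  h <- 0.01
  M <- solve(diag(2) - h * A)
  for (i in seq_len(200000)) x <- M %*% (x + h * b) # 2 s of relaxation
  ss <- markov_steady_state(nat, V)
  expect_lt(max(abs(x - ss[c("C", "O")])), 1e-6)
})

test_that("steady_state_model is a fixed point of the gate ODEs", {
  di <- preset("diestrus")
  st <- steady_state_model(di, -70)
  for (nm in names(di$conductances)) {
    cs <- di$conductances[[nm]]
    expect_equal(st$gates[[nm]]$m, steady_state(cs$m, -70))
    for (j in seq_along(cs$inactivation))
      expect_equal(st$gates[[nm]]$h[j],
                   steady_state(cs$inactivation[[j]]$gate, -70))
  }
  expect_equal(sum(st$nat), 1, tolerance = 1e-12)
})

test_that("calibration: passive cell is exact, presets converge, idempotent", {
  pm <- passive_model(g = 1.0, E = -70)
  cal <- calibrate(pm)
  expect_equal(cal$g_leak, 1.0, tolerance = 1e-6)
  expect_equal(cal$Ihold, 0, tolerance = 1e-9)
  di <- calibrate(preset("diestrus"))
  expect_lt(abs(attr(di, "V_rest") + 70), 0.05)       # within 50 uV
  expect_lt(abs(attr(di, "Rin") - 1), 0.005)          # within 0.5%
  di2 <- calibrate(di)
  expect_lt(abs(di2$g_leak - di$g_leak) / di$g_leak, 1e-3)
  expect_lt(abs(di2$Ihold - di$Ihold) / max(abs(di$Ihold), 1e-6), 1e-3)
})

test_that("with all voltage-gated gbar zero, Rin = 1/g_leak", {
  m <- preset("diestrus")
  for (nm in names(m$conductances)) m$conductances[[nm]]$gbar <- 0
  m$nat$gbar <- 0
  m$g_leak <- 2.0
  meas <- measure_rin(m)
  expect_equal(meas$Rin, 0.5, tolerance = 1e-4)
})

test_that("swap_conductances: empty swap, involution, field replacement", {
  di <- preset("diestrus"); pro <- preset("proestrus")
  expect_identical(swap_conductances(di, pro, character(0), recalibrate = FALSE),
                   di)
  all_ch <- names(di$conductances)
  hybrid <- swap_conductances(di, pro, all_ch, recalibrate = FALSE)
  back <- swap_conductances(hybrid, di, all_ch, recalibrate = FALSE)
  expect_equal(back$conductances, di$conductances)
  kswap <- swap_conductances(di, pro, c("slow", "fast", "resid"),
                             recalibrate = FALSE)
  expect_equal(kswap$conductances$slow$gbar, 42.0)
  expect_equal(kswap$conductances$fast$gbar, 45.7)
  expect_equal(kswap$conductances$resid$gbar, 32.9)
  expect_equal(kswap$conductances$cat$gbar, 1.60)
  expect_equal(kswap$conductances$nap$gbar, 0.14)
  expect_equal(kswap$label, "hybrid")
  expect_error(swap_conductances(di, pro, "nope"), "unknown channel")
})
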