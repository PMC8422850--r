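# simulator module: ideal clamp, integration accuracy, code-path agreement

test_that("all-zero conductances give zero clamp current", {
  m <- preset("diestrus")
  for (nm in names(m$conductances)) m$conductances[[nm]]$gbar <- 0
  m$nat$gbar <- 0
  trs <- run_voltage_clamp(m, mini_activation())
  for (tr in trs) expect_true(all(tr$y == 0))
})

test_that("voltage-clamp currents converge to the analytic steady state", {
  m <- toy_k_model()
  p <- step_protocol(-70, list(list(level = 0, dur = 2000)), pad = 10)
  tr <- run_voltage_clamp(m, p)[[1]]
  cs <- m$conductances$toyk
  I_inf <- channel_current(cs, 0, steady_state(cs$m, 0),
                           steady_state(cs$inactivation[[1]]$gate, 0))
  # last sample of the 0 mV segment (the trace ends with holding padding)
  i_end <- max(which(tr$t <= 10 + 2000))
  expect_equal(tr$y[i_end], I_inf, tolerance = 1e-6)
})

test_that("halving dt leaves voltage-clamp peaks essentially unchanged", {
  slow <- isolate_channels(preset("diestrus"), "slow")
  p <- mini_activation(levels = 40)
  w <- test_pulse_window(p, 1)
  pk1 <- peak_current(run_voltage_clamp(slow, p, dt = 0.05)[[1]], w)
  pk2 <- peak_current(run_voltage_clamp(slow, p, dt = 0.025)[[1]], w)
  expect_lt(abs(pk2 - pk1) / pk1, 0.001)
})

test_that("analytic clamp agrees with a dense explicit-Euler oracle", {
  slow <- isolate_channels(preset("diestrus"), "slow")
  p <- step_protocol(-70, list(list(level = -100, dur = 200),
                               list(level = 40, dur = 300)), pad = 50)
  w <- test_pulse_window(p, 1)
  pk <- peak_current(run_voltage_clamp(slow, p)[[1]], w)
  # independent code path: forward Euler on the gate ODEs at 2 us
  cs <- slow$conductances$slow
  hg <- cs$inactivation[[1]]$gate
  dtE <- 0.002
  tE <- seq(0, 600, by = dtE)
  VE <- ifelse(tE <= 50, -70, ifelse(tE <= 250, -100, ifelse(tE <= 550, 40, -70)))
  m <- steady_state(cs$m, -70); h <- steady_state(hg, -70)
  pkO <- -Inf
  minf_tab <- steady_state(cs$m, c(-70, -100, 40))
  tm_tab <- time_constant(cs$m$tau, c(-70, -100, 40))
  hinf_tab <- steady_state(hg, c(-70, -100, 40))
  th_tab <- time_constant(hg$tau, c(-70, -100, 40))
  vi <- ifelse(VE == -70, 1L, ifelse(VE == -100, 2L, 3L))
  drv_tab <- driving(cs$df, c(-70, -100, 40))
  for (i in seq_along(tE)) {
    k <- vi[i]
    I <- cs$gbar * m * h * drv_tab[k]
    if (tE[i] > w[1] && tE[i] <= w[2] && I > pkO) pkO <- I
    m <- m + dtE * (minf_tab[k] - m) / tm_tab[k]
    h <- h + dtE * (hinf_tab[k] - h) / th_tab[k]
  }
  expect_lt(abs(pk - pkO) / pkO, 0.005)
})

test_that("passive cell gives the closed-form RC response", {
  g <- 1.2; Cm <- 17.62
  m <- passive_model(g = g, Cm = Cm)
  prot <- current_step_protocol(steps = -5, duration = 500, pre = 50, post = 50)
  tr <- run_current_clamp(m, prot)[[1]]
  tau <- Cm / g              # ms
  dV <- -5 / g               # mV steady deflection
  sel <- tr$t > 50 & tr$t <= 550
  pred <- -70 + dV * (1 - exp(-(tr$t[sel] - 50) / tau))
  expect_lt(max(abs(tr$y[sel] - pred)), 0.01)
  expect_equal(tr$y[length(tr$y)] < -70, TRUE)
})

test_that("calibrated model holds -70 mV within 50 uV for 1 s at zero input", {
  di <- calibrate(preset("diestrus"))
  prot <- current_step_protocol(steps = 0, duration = 800, pre = 100, post = 100)
  tr <- run_current_clamp(di, prot)[[1]]
  expect_lt(max(abs(tr$y + 70)), 0.05)
})

test_that("clamping to a current-clamp trajectory recovers the applied current", {
  di <- calibrate(preset("diestrus"))
  prot <- current_step_protocol(steps = 6, duration = 300, pre = 50, post = 100)
  dt <- 0.005
  tr <- run_current_clamp(di, prot, dt = dt, dt_out = dt)[[1]]
  rep <- clamp_to_voltage(di, tr$t, tr$y, include_leak = TRUE)
  n <- length(tr$t)
  dvdt <- (tr$y[3:n] - tr$y[1:(n - 2)]) / (2 * dt)
  Iapp <- di$Cm * dvdt + rep$y[2:(n - 1)] - di$Ihold
  sel <- tr$t[2:(n - 1)] > 55 & tr$t[2:(n - 1)] < 345
  expect_lt(stats::median(abs(Iapp[sel] - 6)), 0.01)
})

test_that("Markov occupancies stay conserved and bounded along a clamp", {
  nat <- preset("diestrus")$nat
  x <- markov_steady_state(nat, -70)[c("C", "O")]
  for (V in c(-100, -40, 0, 20, -70)) {
    for (i in 1:50) {
      x <- kneuron:::markov_advance(nat, V, x, 0.05)
      expect_true(all(x >= -1e-12 & x <= 1 + 1e-12))
    }
  }
  # relax_markov trajectory matches step-by-step advance
  p <- step_protocol(-70, list(list(level = -30, dur = 10)), pad = 5)
  natmod <- neuron_model(Cm = 17.62, nat = nat, g_leak = 0, label = "natonly")
  tr <- run_voltage_clamp(natmod, p, dt = 0.05)
  expect_true(all(is.finite(tr[[1]]$y)))
})

test_that("trace CSV round trip preserves data and metadata", {
  trs <- run_voltage_clamp(toy_k_model(), mini_activation())
  path <- tempfile(fileext = ".csv")
  write_traces(trs, path)
  back <- read_traces(path)
  expect_length(back, length(trs))
  expect_equal(back[[2]]$y, trs[[2]]$y, tolerance = 1e-12)
  expect_equal(back[[2]]$level, trs[[2]]$level)
  unlink(c(path, paste0(path, ".json")))
})

test_that("integration errors carry informative messages", {
  expect_error(ktrace(1:3, c(1, NA, 3)), "non-finite")
})
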