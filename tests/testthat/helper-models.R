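# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

const_tau <- function(ms) tau_spec("constant", fixed_value = ms)

simple_gate <- function(V50, K, tau_ms = 1) gating_spec(V50, K, const_tau(tau_ms))

passive_model <- function(g = 1, E = -70, Cm = 17.62, Ihold = 0) {
  neuron_model(Cm = Cm, conductances = list(), nat = NULL,
               g_leak = g, E_leak = E, Ihold = Ihold, label = "passive")
}

# One GHK K+-like channel with activation + single inactivation gate.
toy_k_model <- function(gbar = 10, Cm = 17.62) {
  cs <- conductance_spec(
    "toyk", gbar = gbar, df = driving_force("ghk", E = -92),
    m = simple_gate(-20, -8, 2),
    inactivation = list(list(gate = simple_gate(-50, 7, 50), weight = 1)))
  neuron_model(Cm = Cm, conductances = list(toyk = cs), g_leak = 0,
               label = "toyk")
}

# A short activation-style protocol (cheap to simulate).
mini_activation <- function(levels = c(-40, 0, 40), test_ms = 200,
                            cond_ms = 200) {
  step_protocol(-70, list(
    list(level = -100, dur = cond_ms),
    list(level = levels, dur = test_ms)),
    label = "mini_activation", pad = 50)
}

# Synthetic voltage trace with Gaussian bumps as "spikes".
bump_trace <- function(spike_times, amplitudes, baseline = -65,
                       t_max = 1000, dt = 0.05, width = 1) {
  t <- seq(0, t_max, by = dt)
  y <- rep(baseline, length(t))
  for (i in seq_along(spike_times))
    y <- y + (amplitudes[i] - baseline) * exp(-(t - spike_times[i])^2 / (2 * width^2))
  ktrace(t, y, unit = "mV")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}

local_seed_test <- function(seed, expr) kneuron:::local_seed(seed, expr)
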