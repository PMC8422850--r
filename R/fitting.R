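#' Sum-of-squares error between simulated and target traces
#'
#' Equal weighting across all samples of all sweeps; grids must be aligned.
#'
#' @param sim,target lists of [ktrace()] objects (same sweep count and
#'   grids), or single traces.
#' @param window optional `c(start, end)` in ms restricting the comparison.
#' @return scalar sum of squared differences (pA^2).
#' @export
sse_traces <- function(sim, target, window = NULL) {
  if (inherits(sim, "ktrace")) sim <- list(sim)
  if (inherits(target, "ktrace")) target <- list(target)
  if (length(sim) != length(target)) stop("grid mismatch: sweep counts differ")
  tot <- 0
  for (i in seq_along(sim)) {
    a <- sim[[i]]; b <- target[[i]]
    if (length(a$t) != length(b$t) || max(abs(a$t - b$t)) > 1e-6)
      stop("grid mismatch in sweep ", i)
    sel <- if (is.null(window)) TRUE else a$t >= window[1] & a$t <= window[2]
    tot <- tot + sum((a$y[sel] - b$y[sel])^2)
  }
  tot
}

#' Objective for maximal-conductance optimization
#'
#' Builds a fast SSE objective in the free maximal conductances for a
#' voltage-clamp fit. Because every gate's kinetics are independent of
#' gbar, each channel's clamp current scales linearly with its gbar; the
#' per-channel unit responses are precomputed once and candidate models are
#' evaluated as linear combinations — exactly equal to re-simulating, at a
#' fraction of the cost. Kinetic parameters (V50, k, tau) are never touched.
#'
#' By default the error is evaluated over the first 250 ms of the test
#' pulse of each sweep (late-trace error is dominated by slow-inactivation
#' mismatch); pass `window = NULL` for full-trace weighting.
#'
#' @param model a [neuron_model()] containing the free channels.
#' @param protocol the [step_protocol()] defining the target sweeps.
#' @param target list of target [ktrace()] objects (one per sweep).
#' @param channels names of the free-gbar channels (default: all).
#' @param window `c(start, end)` relative to test-pulse onset in ms, or
#'   NULL for the whole trace. Default `c(0, 250)`.
#' @param dt sample interval in ms.
#' @return list with `fn(gbar)` (the objective), `gbar0` (the model's
#'   values), `channels`, and `n_obs`.
#' @export
gbar_objective <- function(model, protocol, target, channels = NULL,
                           window = c(0, 250), dt = 0.05) {
  if (is.null(channels)) channels <- names(model$conductances)
  stopifnot(all(channels %in% names(model$conductances)))
  nsw <- n_sweeps(protocol)
  stopifnot(length(target) == nsw)
  sel_of <- function(tr, sw) {
    if (is.null(window)) rep(TRUE, length(tr$t))
    else {
      w <- test_pulse_window(protocol, sw)
      tr$t >= w[1] + window[1] & tr$t <= min(w[1] + window[2], w[2])
    }
  }
  basis <- lapply(channels, function(nm) {
    iso <- isolate_channels(model, nm)
    trs <- run_voltage_clamp(iso, protocol, dt = dt)
    g0 <- model$conductances[[nm]]$gbar
    if (g0 <= 0) stop("basis channel ", nm, " has gbar = 0; cannot scale")
    unlist(lapply(seq_len(nsw), function(sw) trs[[sw]]$y[sel_of(trs[[sw]], sw)])) / g0
  })
  B <- do.call(cbind, basis)
  yt <- unlist(lapply(seq_len(nsw), function(sw)
    target[[sw]]$y[sel_of(target[[sw]], sw)]))
  if (nrow(B) != length(yt)) stop("grid mismatch between basis and target")
  list(fn = function(gbar) {
    stopifnot(length(gbar) == length(channels))
    sum((as.vector(B %*% gbar) - yt)^2)
  },
  gbar0 = vapply(channels, function(nm) model$conductances[[nm]]$gbar, numeric(1)),
  channels = channels, n_obs = length(yt))
}

#' Particle swarm optimization of maximal conductances
#'
#' Canonical global-best PSO with reflecting bounds. Deterministic under a
#' fixed seed; the global-best SSE history is non-increasing by
#' construction. Hyperparameters follow common practice (inertia 0.729,
#' cognitive/social 1.49); they and the bounds are configurable.
#'
#' @param objective function mapping a gbar vector to a scalar SSE (e.g.
#'   `gbar_objective(...)$fn`).
#' @param lower,upper bounds on each parameter (default `[0, 3 x init]`
#'   when `init` is given).
#' @param init optional center for the default bounds / first particle.
#' @param swarm number of particles (>= 1).
#' @param iters iteration count (>= 0; 0 returns the best initial particle).
#' @param seed RNG seed.
#' @param inertia,cognitive,social PSO coefficients.
#' @return list with `gbar` (best parameters), `sse` (its objective),
#'   `sse_initial` (best initial particle), `history` (global best per
#'   iteration, length `iters`), `seed`.
#' @export
pso_gbar <- function(objective, lower = NULL, upper = NULL, init = NULL,
                     swarm = 30, iters = 200, seed = 1,
                     inertia = 0.729, cognitive = 1.49, social = 1.49) {
  if (swarm < 1) stop("zero-size swarm")
  if (is.null(lower)) {
    if (is.null(init)) stop("need either bounds or init")
    lower <- rep(0, length(init))
  }
  if (is.null(upper)) {
    if (is.null(init)) stop("need either bounds or init")
    upper <- 3 * init
  }
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  run <- local_seed(seed, {
    X <- matrix(runif(swarm * d, lower, upper), nrow = swarm, byrow = TRUE)
    if (!is.null(init)) X[1, ] <- pmin(pmax(init, lower), upper)
    Vel <- matrix(runif(swarm * d, -(upper - lower), upper - lower),
                  nrow = swarm, byrow = TRUE) * 0.1
    fX <- apply(X, 1, objective)
    Pb <- X; fPb <- fX
    gi <- which.min(fPb)
    gbest <- Pb[gi, ]; fg <- fPb[gi]
    sse_initial <- fg
    history <- numeric(iters)
    for (it in seq_len(iters)) {
      r1 <- matrix(runif(swarm * d), swarm, d)
      r2 <- matrix(runif(swarm * d), swarm, d)
      Vel <- inertia * Vel + cognitive * r1 * (Pb - X) +
        social * r2 * matrix(gbest, swarm, d, byrow = TRUE) - social * r2 * X
      X <- X + Vel
      for (j in seq_len(d)) { # reflect at bounds
        lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
        X[lo, j] <- 2 * lower[j] - X[lo, j]; Vel[lo, j] <- -Vel[lo, j]
        X[hi, j] <- 2 * upper[j] - X[hi, j]; Vel[hi, j] <- -Vel[hi, j]
        X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
      }
      fX <- apply(X, 1, objective)
      better <- fX < fPb
      Pb[better, ] <- X[better, , drop = FALSE]; fPb[better] <- fX[better]
      gi <- which.min(fPb)
      if (fPb[gi] < fg) { fg <- fPb[gi]; gbest <- Pb[gi, ] }
      history[it] <- fg
    }
    list(gbar = gbest, sse = fg, sse_initial = sse_initial,
         history = history)
  })
  run$seed <- seed
  run
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
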