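# Independent oracles used by the tests. These are deliberately written as
# straight transcriptions of the defining formulas / brute-force procedures,
# sharing no code with the package implementation.

# Squid-axon rate expressions, plain form (no singularity guard; callers
# avoid the singular potentials or supply the limit themselves).
oracle_rates <- function(V) {
  list(
    alpha_m = 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10)),
    beta_m  = 4 * exp(-(V + 65) / 18),
    alpha_h = 0.07 * exp(-(V + 65) / 20),
    beta_h  = 1 / (1 + exp(-(V + 35) / 10)),
    alpha_n = 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10)),
    beta_n  = 0.125 * exp(-(V + 65) / 80)
  )
}

# One forward-Euler step of a 3-compartment sealed-end chain, hand-rolled.
oracle_three_node_step <- function(V, m, h, n, p, gax, Ctot, Ist, dt) {
  r <- oracle_rates(V)
  INa <- p$gNa * m^3 * h * (V - p$ENa)
  IK <- p$gK * n^4 * (V - p$EK)
  IL <- p$gL * (V - p$EL)
  Iax <- c(gax * (V[2] - V[1]),
           gax * (V[1] - V[2]) + gax * (V[3] - V[2]),
           gax * (V[2] - V[3]))
  Vn <- V + dt * (Ist + Iax - INa - IK - IL) / Ctot
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  list(V = Vn,
       m = clamp01(m + dt * (r$alpha_m * (1 - m) - r$beta_m * m)),
       h = clamp01(h + dt * (r$alpha_h * (1 - h) - r$beta_h * h)),
       n = clamp01(n + dt * (r$alpha_n * (1 - n) - r$beta_n * n)))
}

# Brute-force spike detector: rle segmentation of the suprathreshold mask,
# argmax within each accepted run. Runs that begin at the first sample have
# no upward crossing and are skipped, matching the crossing definition.
oracle_detect_spikes <- function(v, dt, threshold = 0, refractory = 2) {
  r <- rle(v > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  times <- numeric(0)
  peaks <- numeric(0)
  last <- -Inf
  for (k in which(r$values)) {
    s <- starts[k]
    if (s == 1L) next
    t_cross <- (s - 1L) * dt
    if (t_cross - last < refractory) next
    last <- t_cross
    seg <- s:ends[k]
    pk <- seg[which.max(v[seg])]
    times <- c(times, (pk - 1L) * dt)
    peaks <- c(peaks, v[pk])
  }
  list(times = times, peaks = peaks)
}

# Random action-potential-like trace: unimodal Gaussian bumps on a resting
# baseline, bump onsets separated by more than the default refractory window.
random_ap_trace <- function(dur = 200, dt = 0.1, max_bumps = 12) {
  t <- seq(0, dur, by = dt)
  v <- rep(-65, length(t))
  centers <- sort(runif(max_bumps, 5, dur - 5))
  centers <- centers[c(TRUE, diff(centers) > 5)]
  amps <- runif(length(centers), 40, 110)
  for (i in seq_along(centers))
    v <- pmax(v, -65 + amps[i] * exp(-((t - centers[i]) / 1.2)^2))
  v
}

# Exhaustive Mann-Whitney: enumerate every assignment of the pooled values
# to the first sample and compute the exact two-sided p of the observed U.
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(a, b)
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided t-tail by numeric integration of the t density.
oracle_p_from_t <- function(t, df) {
  if (t == 0) return(1)
  2 * integrate(function(x) stats::dt(x, df), abs(t), Inf,
                rel.tol = 1e-10)$value
}

# Quick cohort regeneration with a different seed but shared configuration.
reseed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}
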