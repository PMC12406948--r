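# Independent oracles used across the suite. They deliberately avoid the
# package's integration and FFT paths: equilibrium curves come from a dense
# trapezoid quadrature of the raw Langevin formula, dynamics from a
# fixed-step classical RK4 integrator at high oversampling, and harmonic
# coefficients from direct Fourier sums.

# Langevin via the raw closed form; the leading linear term stands in below
# 1e-5 where coth - 1/x cancels catastrophically in doubles
oracle_langevin <- function(xi) {
  ifelse(abs(xi) < 1e-5, xi / 3, 1 / tanh(xi) - 1 / xi)
}

# size-averaged equilibrium moment by trapezoid quadrature on ln d
oracle_equilibrium <- function(B, preset, iron_mass, temperature,
                               n_grid = 4001L) {
  kB <- 1.380649e-23
  msat <- preset$M_s * iron_mass / (0.7236 * 5170)
  if (preset$sigma_d == 0) {
    mp <- preset$M_s * pi / 6 * preset$d_med^3
    return(msat * oracle_langevin(mp * B / (kB * temperature)))
  }
  mu <- log(preset$d_med); s <- preset$sigma_d
  x <- seq(mu - 5 * s, mu + 5 * s, length.out = n_grid)
  d <- exp(x)
  w <- dnorm(x, mu, s) * d^3
  w <- w / sum(w)
  mp <- preset$M_s * pi / 6 * d^3
  vapply(B, function(b) {
    if (b == 0) return(0)
    msat * sum(w * oracle_langevin(mp * b / (kB * temperature)))
  }, numeric(1))
}

# fixed-step RK4 integration of dm/dt = (m_eq(B(t)) - m)/tau at
# `oversample` substeps per acquired sample; returns samples on the
# acquisition grid after discarding `n_transient` whole periods.
oracle_rk4_simulate <- function(config, preset, iron_mass,
                                oversample = 100L, n_transient = 20L) {
  tau <- preset$tau
  stopifnot(tau > 0)
  spp_f <- config$samples_per_period * oversample
  # equilibrium forcing on the half-step grid of one period
  jj <- seq_len(2L * spp_f) - 1L
  Bhalf <- config$B_ex * sin(pi * jj / spp_f)
  ghalf <- oracle_equilibrium(Bhalf, preset, iron_mass, config$temperature)
  h <- 1 / (config$f_ex * spp_f)
  total <- (n_transient + config$n_periods) * spp_f
  m <- ghalf[1]
  out <- numeric(config$n_periods * config$samples_per_period)
  oi <- 0L
  for (k in seq_len(total) - 1L) {
    i0 <- (2L * k) %% (2L * spp_f) + 1L
    g0 <- ghalf[i0]
    gh <- ghalf[(i0 %% (2L * spp_f)) + 1L]
    g1 <- ghalf[((i0 + 1L) %% (2L * spp_f)) + 1L]
    k1 <- (g0 - m) / tau
    k2 <- (gh - (m + h / 2 * k1)) / tau
    k3 <- (gh - (m + h / 2 * k2)) / tau
    k4 <- (g1 - (m + h * k3)) / tau
    if (k >= n_transient * spp_f && k %% oversample == 0L) {
      oi <- oi + 1L
      out[oi] <- m
    }
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

# direct Fourier sine/cosine sums at harmonic n (no FFT); returns the
# amplitude and the raw phase against sin(n w t)
oracle_fourier <- function(x, n, samples_per_period) {
  N <- length(x)
  j <- seq_len(N) - 1L
  arg <- 2 * pi * n * j / samples_per_period
  bs <- 2 / N * sum(x * sin(arg))
  bc <- 2 / N * sum(x * cos(arg))
  list(amplitude = sqrt(bs^2 + bc^2),
       phase_deg = atan2(bc, bs) * 180 / pi)
}
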