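test_that("langevin is odd, bounded, and matches the closed form", {
  expect_identical(langevin(0), 0)
  # high-precision value of coth(1) - 1
  expect_equal(langevin(1), 0.3130352855, tolerance = 1e-9)
  expect_equal(langevin(-1), -langevin(1))
  xi <- c(-50, -3, -0.5, -1e-3, 1e-3, 0.5, 3, 50)
  expect_equal(langevin(xi), -langevin(-xi))
  expect_true(all(abs(langevin(xi)) < 1))
  # series branch continuous across the switch at 1e-4
  # (closed form carries ~1e-8 relative cancellation error at this scale)
  lo <- langevin(1e-4 * (1 - 1e-9))
  hi <- langevin(1e-4 * (1 + 1e-9))
  expect_equal(lo, hi, tolerance = 1e-6)
})

test_that("equilibrium moment is odd, monotone, saturating, and matches a quadrature oracle", {
  cfg <- test_config()
  p <- particle_preset("mono", "physical", d_med = 5e-9, sigma_d = 0,
                       M_s = 3e5, tau = 0)
  expect_identical(equilibrium_moment(0, p, 1e-9, cfg), 0)
  B <- seq(-50e-3, 50e-3, length.out = 41)
  m <- equilibrium_moment(B, p, 1e-9, cfg)
  expect_equal(m, -rev(m))
  expect_true(all(diff(m) > 0))
  # single-size worked value: xi = M_s (pi/6) d^3 B / (kB T) = 0.11852
  kB <- 1.380649e-23
  xi <- 3e5 * pi / 6 * (5e-9)^3 * 25e-3 / (kB * 300)
  expect_equal(xi, 0.1185, tolerance = 1e-3)
  msat <- 3e5 * 1e-9 / (0.7236 * 5170)
  expect_equal(equilibrium_moment(25e-3, p, 1e-9, cfg) / msat,
               langevin(xi), tolerance = 1e-12)
  expect_equal(langevin(xi), 0.0394, tolerance = 2e-3)
  # Langevin limit: deep saturation within 2 percent
  mp <- 3e5 * pi / 6 * (5e-9)^3
  B_big <- 50 * kB * 300 / mp
  expect_equal(equilibrium_moment(B_big, p, 1e-9, cfg), msat,
               tolerance = 0.02)
  # polydisperse case against an independent trapezoid quadrature
  pp <- particle_preset("poly", "physical", d_med = 10e-9, sigma_d = 0.3,
                        M_s = 3e5, tau = 0)
  Bv <- c(5e-3, 15e-3, 25e-3)
  expect_equal(equilibrium_moment(Bv, pp, 2e-9, cfg),
               oracle_equilibrium(Bv, pp, 2e-9, 300), tolerance = 1e-5)
  expect_error(particle_preset("bad", "physical", d_med = 0, sigma_d = 0,
                               M_s = 3e5, tau = 0))
})

test_that("tau = 0 simulation equals the sampled equilibrium response with zero phase", {
  cfg <- test_config()
  p <- particle_preset("eq", "physical", d_med = 15e-9, sigma_d = 0.2,
                       M_s = 3e5, tau = 0)
  sig <- simulate_physical(cfg, p, 1e-9)
  B <- drive_field_samples(cfg)
  expect_equal(sig$samples, equilibrium_moment(B, p, 1e-9, cfg),
               tolerance = 1e-12)
  spec <- extract_harmonics(sig)
  expect_true(all(abs(spec$phi_n) < 0.1))
})

test_that("simulated moment is exactly proportional to iron mass and odd under half-period shift", {
  cfg <- test_config()
  p <- particle_preset("lin", "physical", d_med = 12e-9, sigma_d = 0.2,
                       M_s = 3e5, tau = 1e-6)
  s1 <- simulate_physical(cfg, p, 1e-9)
  s2 <- simulate_physical(cfg, p, 2e-9)
  expect_equal(s2$samples, 2 * s1$samples, tolerance = 1e-12)
  # half-period antisymmetry in steady state => even harmonics vanish
  half <- cfg$samples_per_period / 2
  shifted <- c(s1$samples[-seq_len(half)], s1$samples[seq_len(half)])
  expect_equal(shifted, -s1$samples, tolerance = 1e-6)
  X <- abs(fft(s1$samples))
  a3_bin <- 3 * cfg$n_periods + 1
  even_bins <- seq(2, 8, by = 2) * cfg$n_periods + 1
  expect_true(all(X[even_bins] / X[a3_bin] < 1e-6))
})

test_that("phase lag grows monotonically with relaxation time", {
  cfg <- test_config()
  taus <- c(0, 2e-7, 5e-7, 1e-6, 2e-6, 5e-6)
  phi3 <- vapply(taus, function(tau) {
    p <- particle_preset("t", "physical", d_med = 12e-9, sigma_d = 0.2,
                         M_s = 3e5, tau = tau)
    extract_harmonics(simulate_physical(cfg, p, 1e-9))$phi_n[1]
  }, numeric(1))
  expect_true(all(diff(abs(phi3)) > 0))
  expect_true(all(phi3[-1] < 0))
})

test_that("excessive relaxation time triggers the transient-budget error", {
  cfg <- test_config()
  p <- particle_preset("slow", "physical", d_med = 12e-9, sigma_d = 0.2,
                       M_s = 3e5, tau = 0.0041)  # > 100 periods at 25 kHz
  expect_error(simulate_physical(cfg, p, 1e-9), "transient")
})

test_that("noisy simulation is reproducible under a fixed seed", {
  cfg <- test_config()
  p <- particle_preset("n", "physical", d_med = 12e-9, sigma_d = 0.2,
                       M_s = 3e5, tau = 1e-6)
  a <- simulate_physical(cfg, p, 1e-9, noise_sd = 1e-11, seed = 7)
  b <- simulate_physical(cfg, p, 1e-9, noise_sd = 1e-11, seed = 7)
  d <- simulate_physical(cfg, p, 1e-9, noise_sd = 1e-11, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, d$samples))
})

test_that("template synthesis round-trips through the analyzer", {
  cfg <- test_config()
  for (nm in c("vsop", "endorem", "mcp_resovist")) {
    pre <- test_presets()[[nm]]
    spec <- extract_harmonics(synthesize_template(cfg, pre, 1e-10))
    expect_equal(spec$A_n / spec$A_n[1], unname(pre$template_amps),
                 tolerance = 1e-3)
    expect_equal(spec$phi_n, unname(pre$template_phases), tolerance = 0.1)
  }
  # single-tone identity
  single <- particle_preset("tone", "template",
                            template_amps = c("3" = 1),
                            template_phases = c("3" = 0))
  spec <- extract_harmonics(synthesize_template(cfg, single, 1e-10))
  expect_equal(spec$A_n[1], 1e-10, tolerance = 1e-12)
  expect_true(all(spec$A_n[-1] <= pmax(spec$noise_floor_n[-1], 1e-22)))
  expect_error(particle_preset("even", "template",
                               template_amps = c("3" = 1, "4" = 0.5),
                               template_phases = c("3" = 0, "4" = 0)))
})

test_that("contaminant hysteron lags, encloses area, and matches direct Fourier sums", {
  cfg <- test_config()
  # closed loop with coercivity: large third-harmonic lag
  pre <- contaminant_preset(1e-9, 10e-3, 2e-3)
  sig <- simulate_contaminant(cfg, pre)
  spec <- extract_harmonics(sig)
  expect_gt(abs(spec$phi_n[1]), 10)
  # loop area: integral m dB over one period is nonzero
  B <- drive_field_samples(cfg)
  spp <- cfg$samples_per_period
  one <- seq_len(spp)
  area <- sum(sig$samples[one] * (B[c(one[-1], 1)] - B[one]))
  expect_gt(abs(area), 0)
  # independent Fourier sums agree with the FFT analyzer (amplitudes and
  # raw phase differences between orders)
  for (n in c(3, 5, 7)) {
    of <- oracle_fourier(sig$samples, n, spp)
    i <- match(n, spec$orders)
    expect_equal(spec$A_n[i], of$amplitude, tolerance = 1e-10)
  }
  # zero coercivity: branches coincide, anhysteretic, no lag
  pre0 <- contaminant_preset(1e-9, 0, 2e-3)
  spec0 <- extract_harmonics(simulate_contaminant(cfg, pre0))
  expect_true(all(abs(spec0$phi_n) < 0.1))
  # determinism without jitter
  s1 <- simulate_contaminant(cfg, pre, seed = 1)
  s2 <- simulate_contaminant(cfg, pre, seed = 99)
  expect_identical(s1$samples, s2$samples)
  # coercivity at/above the drive amplitude is rejected
  expect_error(simulate_contaminant(cfg, contaminant_preset(1e-9, 25e-3, 2e-3)),
               "B_ex")
})

test_that("blank fixture has the documented mean and spread; random blanks obey the no-noise limit", {
  b <- generate_blanks()
  expect_length(b$a3_values, 20L)
  expect_true(all(b$a3_values >= 0))
  expect_equal(mean(b$a3_values), 1.4e-11, tolerance = 1e-12)
  expect_equal(sd(b$a3_values), 0.2e-11, tolerance = 1e-12)
  expect_error(generate_blanks(n = 10), "20")
  expect_error(generate_blanks("random", n = 1), "2")
  # pure-noise blanks with the noise switched off analyze to exactly zero
  b0 <- generate_blanks("random", n = 5, noise_sd = 0, background_a3 = 0)
  expect_equal(b0$a3_values, rep(0, 5), tolerance = 1e-25)
  # with the default background + noise model, blank statistics sit near
  # the fixture's mean and spread
  br <- generate_blanks("random", n = 20, seed = 3)
  expect_equal(mean(br$a3_values), 1.4e-11, tolerance = 0.1)
  expect_equal(sd(br$a3_values), 0.2e-11, tolerance = 0.5)
})

test_that("study generator honours counts, ground truth, and determinism", {
  design <- study_design(groups = data.frame(treatment = "EuVSOP",
                                             model = "healthy_WT"),
                         n_per_cell = 8L, seed = 11)
  st <- generate_study(design)
  expect_equal(nrow(st$records), 48L)  # 1 group x 6 organs x 8
  st2 <- generate_study(design)
  expect_identical(st$records$truth_fe_kg, st2$records$truth_fe_kg)
  expect_identical(st$records$signal[[17]]$samples,
                   st2$records$signal[[17]]$samples)
  # PBS carries no tracer iron
  dp <- study_design(groups = data.frame(treatment = "PBS",
                                         model = "healthy_WT"),
                     n_per_cell = 2L, seed = 5)
  sp <- generate_study(dp)
  expect_true(all(sp$records$truth_fe_kg == 0))
  # uncontaminated PBS records analyze below the detection limit
  dp0 <- study_design(groups = data.frame(treatment = "PBS",
                                          model = "healthy_WT"),
                      contamination_prob = c(COL = 0, KID = 0, SIT = 0,
                                             CAE = 0, LIV = 0, SPL = 0),
                      n_per_cell = 2L, seed = 5)
  sp0 <- analyze_records(generate_study(dp0)$records)
  lod <- compute_lod(generate_blanks())
  expect_true(all(sp0$A3 < lod$lod))
  # over-committed biodistribution is rejected
  expect_error(study_design(biodistribution_fractions = c(LIV = 0.9,
                                                          SPL = 0.2)),
               "sum")
})
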