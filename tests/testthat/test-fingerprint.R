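test_that("fingerprint features are the (A5/A3, phi3) pair with A5 censoring", {
  vsop_like <- make_spectrum(A_n = c(1e-10, 1e-11), phi_n = c(-2, -2))
  f <- extract_features(vsop_like)
  expect_equal(f$r53, 0.10)
  expect_equal(f$phi3, -2)
  expect_false(f$r53_censored)
  multicore <- make_spectrum(A_n = c(1e-10, 3e-11), phi_n = c(-30, -34))
  f2 <- extract_features(multicore)
  expect_equal(f2$r53, 0.30)
  expect_equal(f2$phi3, -30)
  # A5 under its floor: ratio becomes the floor-based upper bound
  dim5 <- make_spectrum(A_n = c(1e-10, 1e-12), phi_n = c(-2, 0))
  f3 <- extract_features(dim5, lod5 = 2e-12)
  expect_true(f3$r53_censored)
  expect_equal(f3$r53, 0.02)
  expect_error(extract_features(make_spectrum(c(0, 0), c(0, 0))), "A3")
})

test_that("features are invariant under amplitude scaling (dilution invariance)", {
  s <- make_spectrum(A_n = c(2e-10, 3e-11), phi_n = c(-5, -7))
  for (k in c(0.1, 1, 25)) {
    sk <- s
    sk$A_n <- k * s$A_n
    fk <- extract_features(sk)
    expect_equal(fk$r53, 3 / 20)
    expect_equal(fk$phi3, -5)
  }
})

test_that("region fitting returns the Gaussian ellipse with chi-square threshold", {
  # chi-square(2) quantile at 0.99
  pts <- data.frame(r53 = c(0.08, 0.12, 0.10, 0.10),
                    phi3 = c(-2, -2, -1, -3))
  region <- fit_region(pts, quantile = 0.99)
  expect_equal(region$md2_threshold, 9.210, tolerance = 1e-3)
  expect_equal(unname(region$centroid), c(0.10, -2))
  expect_equal(region$n_reference, 4L)
  # collinear or too-few points are singular
  expect_error(fit_region(data.frame(r53 = c(0.1, 0.2), phi3 = c(-2, -3))),
               "3")
  expect_error(fit_region(data.frame(r53 = c(0.1, 0.2, 0.3),
                                     phi3 = c(-2, -2, -2))), "singular")
  # censored points never enter the fit
  pts$r53_censored <- c(FALSE, FALSE, FALSE, TRUE)
  r2 <- fit_region(pts)
  expect_equal(r2$n_reference, 3L)
})

test_that("classification gates on LOD first, then the Mahalanobis ellipse", {
  set.seed(21)
  ref <- data.frame(r53 = rnorm(50, 0.10, 0.012), phi3 = rnorm(50, -2, 1))
  region <- fit_region(ref, quantile = 0.99)
  lod <- compute_lod(generate_blanks())
  at_centroid <- make_spectrum(A_n = c(1e-9, 1e-9 * region$centroid[["r53"]]),
                               phi_n = c(region$centroid[["phi3"]], 0))
  expect_equal(classify(at_centroid, region, lod), "target_MNP")
  # a multicore-like signature lies far outside the small-tracer region
  mc <- make_spectrum(A_n = c(1e-9, 3e-10), phi_n = c(-30, -34))
  expect_equal(classify(mc, region, lod), "contaminated")
  # LOD precedence: whatever the features, half-LOD reads below_LOD
  weak <- make_spectrum(A_n = c(0.5 * lod$lod, 0.1 * lod$lod),
                        phi_n = c(-30, -34))
  expect_equal(classify(weak, region, lod), "below_LOD")
})

test_that("fresh tracer replicates are accepted at close to the nominal coverage", {
  cfg <- test_config()
  pre <- test_presets()$vsop
  scatter <- c(r53 = 0.012, phi3_deg = 1.0)
  ref <- generate_reference_features(n = 500, tracer_preset = pre,
                                     config = cfg, scatter = scatter,
                                     seed = 100)
  region <- fit_region(ref, quantile = 0.95)
  lod <- compute_lod(generate_blanks())
  fresh <- generate_reference_features(n = 400, tracer_preset = pre,
                                       config = cfg, scatter = scatter,
                                       seed = 200)
  md2 <- stats::mahalanobis(cbind(fresh$r53, fresh$phi3), region$centroid,
                            region$covariance)
  accepted <- sum(md2 <= region$md2_threshold)
  # 99 percent binomial band around q = 0.95 for n = 400
  bounds <- qbinom(c(0.005, 0.995), 400, 0.95)
  expect_gte(accepted, bounds[1])
  expect_lte(accepted, bounds[2])
})

test_that("contaminant-only records above LOD are rejected under the dietary prior", {
  cfg <- test_config()
  lod <- compute_lod(generate_blanks())
  region <- fit_region(generate_reference_features(n = 100, seed = 7),
                       quantile = 0.99)
  noise <- default_noise_sd(cfg)
  labels <- vapply(1:100, function(i) {
    pre <- sample_contaminant_preset(seed = i, label = "reject")
    sig <- simulate_contaminant(cfg, pre, sample_id = sprintf("c%03d", i))
    set.seed(substream_seed(1000 + i, "rejnoise"))
    x <- sig$samples + rnorm(length(sig$samples), 0, noise)
    spec <- extract_harmonics(mps_signal(x, cfg, sig$sample_id))
    if (spec$A_n[1] < lod$lod) return(NA_character_)
    classify(spec, region, lod, lod5 = lod_noise_only(noise, cfg))
  }, character(1))
  labels <- labels[!is.na(labels)]
  expect_gte(length(labels), 50)
  expect_gte(mean(labels == "contaminated"), 0.95)
})

test_that("mixtures move monotonically away from the tracer region", {
  cfg <- test_config()
  pre <- test_presets()$vsop
  region <- fit_region(generate_reference_features(n = 100, seed = 7),
                       quantile = 0.99)
  lod <- compute_lod(generate_blanks())
  tracer <- synthesize_template(cfg, pre, a3_moment = 2e-9)$samples
  cont <- simulate_contaminant(cfg, contaminant_preset(1e-9, 10e-3, 2e-3))$samples
  fracs <- c(0, 0.02, 0.05, 0.1, 0.2, 0.4, 1)
  md2 <- vapply(fracs, function(f) {
    spec <- extract_harmonics(mps_signal((1 - f) * tracer + f * cont, cfg,
                                         "mix"))
    ft <- extract_features(spec)
    stats::mahalanobis(cbind(ft$r53, ft$phi3), region$centroid,
                       region$covariance)[1]
  }, numeric(1))
  expect_true(all(diff(md2) > 0))
  # vanishing contaminant fraction converges to a tracer call
  expect_lte(md2[1], region$md2_threshold)
})

test_that("corrected quantification tallies exclusions and respects the LOD gate", {
  cfg <- test_config()
  pre <- test_presets()$vsop
  lod <- compute_lod(generate_blanks())
  region <- fit_region(generate_reference_features(n = 100, seed = 7),
                       quantile = 0.99)
  cal <- calibrate(extract_harmonics(
    synthesize_template(cfg, pre, a3_moment = 1e-8)), 1e-8 / pre$specific_a3_per_kg)
  noise <- default_noise_sd(cfg)
  # 10 colon records, 5 of them carrying a contaminant signal
  build <- function(i, contaminated) {
    m <- synthesize_template(cfg, pre, a3_moment = 5e-10)$samples
    if (contaminated)
      m <- m + simulate_contaminant(
        cfg, contaminant_preset(1e-9, 12e-3, 3e-3))$samples
    set.seed(substream_seed(i, "ten"))
    mps_signal(m + rnorm(length(m), 0, noise), cfg, sprintf("col%02d", i))
  }
  recs <- data.frame(id = sprintf("col%02d", 1:10), treatment = "PBS",
                     model = "healthy_WT", organ = "COL",
                     tissue_mass_g = 0.25)
  recs$signal <- lapply(1:10, function(i) build(i, i <= 5))
  out <- correct_quantification(analyze_records(recs), region, cal, lod,
                                lod5 = lod_noise_only(noise, cfg))
  expect_equal(out$exclusions$n_excluded, 5L)
  expect_equal(out$exclusions$n_total, 10L)
  expect_true(all(is.na(out$records$fe_mass_kg[out$records$label ==
                                                 "contaminated"])))
  # all-below-LOD input: nothing quantified, nothing contaminated
  recs0 <- recs
  recs0$signal <- lapply(1:10, function(i) {
    set.seed(substream_seed(i, "blankrec"))
    mps_signal(rnorm(cfg$samples_per_period * cfg$n_periods, 0, noise),
               cfg, sprintf("b%02d", i))
  })
  out0 <- correct_quantification(analyze_records(recs0), region, cal, lod)
  expect_true(all(out0$records$label == "below_LOD"))
  expect_equal(out0$exclusions$n_excluded, 0L)
  expect_true(all(is.na(out0$records$fe_mass_kg)))
})

test_that("pure tracer records at ten times the LOD are essentially always accepted", {
  cfg <- test_config()
  pre <- test_presets()$vsop
  lod <- compute_lod(generate_blanks())
  region <- fit_region(generate_reference_features(n = 100, seed = 7),
                       quantile = 0.99)
  noise <- default_noise_sd(cfg)
  lod5 <- lod_noise_only(noise, cfg)
  labels <- vapply(1:100, function(i) {
    m <- synthesize_template(cfg, pre, a3_moment = 10 * lod$lod)$samples
    set.seed(substream_seed(i, "power"))
    spec <- extract_harmonics(mps_signal(m + rnorm(length(m), 0, noise),
                                         cfg, "p"))
    classify(spec, region, lod, lod5 = lod5)
  }, character(1))
  expect_gte(mean(labels == "target_MNP"), 0.99)
})
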