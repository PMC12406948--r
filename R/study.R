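#' Organ-panel study design
#'
#' Describes a synthetic biodistribution experiment: treatment groups
#' (vehicle `PBS` vs tracer `EuVSOP`) crossed with disease models, an organ
#' panel, the injected iron dose, the fraction of the dose each organ
#' retains, and per-organ contamination probabilities for dietary magnetic
#' material. Defaults emulate an intravenous small-tracer study 90 min after
#' injection: clearance dominated by liver and spleen (mononuclear phagocyte
#' system), small fractions in kidney and intestinal tissue, and dietary
#' contamination confined to intestinal organs, feces and food.
#'
#' @param groups data frame with columns `treatment`
#'   (`"PBS"`/`"EuVSOP"`) and `model`
#'   (`"healthy_WT"`, `"DSS"`, `"Rag1_transfer"`).
#' @param organs character vector from `COL, KID, SIT, CAE, LIV, SPL,
#'   FEC_COL, FEC_CAE, FOOD`.
#' @param n_per_cell specimens per group x organ cell.
#' @param dose_mol_per_kg injected iron in mol per kg body weight.
#' @param body_mass_kg animal body mass in kg.
#' @param biodistribution_fractions named fractions of the injected dose per
#'   organ; must be non-negative and sum to at most 1.
#' @param contamination_prob named per-organ probabilities in `[0, 1]`.
#' @param tissue_mass_g named list of `c(mean, sd)` tissue masses in g.
#' @param fe_jitter_sdlog lognormal spread of per-animal organ uptake.
#' @param fingerprint_scatter named vector `c(r53, phi3_deg)`: standard
#'   deviations of the per-specimen tracer-signature scatter (environmental
#'   variability of the fingerprint).
#' @param seed integer master seed.
#' @return an object of class `study_design`.
#' @export
study_design <- function(
    groups = data.frame(treatment = c("PBS", "EuVSOP"),
                        model = c("healthy_WT", "healthy_WT")),
    organs = c("COL", "KID", "SIT", "CAE", "LIV", "SPL"),
    n_per_cell = 8L,
    dose_mol_per_kg = 0.03e-3,
    body_mass_kg = 0.020,
    biodistribution_fractions = c(LIV = 0.55, SPL = 0.12, COL = 0.03,
                                  KID = 0.03, SIT = 0.04, CAE = 0.03,
                                  FEC_COL = 0.005, FEC_CAE = 0.005,
                                  FOOD = 0),
    contamination_prob = c(COL = 0.5, CAE = 0.3, SIT = 0.3, KID = 0,
                           LIV = 0, SPL = 0, FEC_COL = 1, FEC_CAE = 1,
                           FOOD = 1),
    tissue_mass_g = list(COL = c(0.25, 0.05), KID = c(0.30, 0.05),
                         SIT = c(0.60, 0.10), CAE = c(0.30, 0.08),
                         LIV = c(1.00, 0.15), SPL = c(0.08, 0.015),
                         FEC_COL = c(0.10, 0.03), FEC_CAE = c(0.15, 0.04),
                         FOOD = c(0.50, 0.05)),
    fe_jitter_sdlog = 0.3,
    fingerprint_scatter = c(r53 = 0.012, phi3_deg = 1.0),
    seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("treatment", "model") %in% names(groups)),
            all(groups$treatment %in% c("PBS", "EuVSOP")),
            all(organs %in% c("COL", "KID", "SIT", "CAE", "LIV", "SPL",
                              "FEC_COL", "FEC_CAE", "FOOD")),
            n_per_cell >= 1, dose_mol_per_kg >= 0, body_mass_kg > 0,
            all(biodistribution_fractions >= 0),
            all(contamination_prob >= 0 & contamination_prob <= 1),
            fe_jitter_sdlog >= 0)
  if (sum(biodistribution_fractions) > 1)
    stop("biodistribution fractions sum to more than 1")
  structure(list(groups = groups, organs = organs,
                 n_per_cell = as.integer(n_per_cell),
                 dose_mol_per_kg = dose_mol_per_kg,
                 body_mass_kg = body_mass_kg,
                 biodistribution_fractions = biodistribution_fractions,
                 contamination_prob = contamination_prob,
                 tissue_mass_g = tissue_mass_g,
                 fe_jitter_sdlog = fe_jitter_sdlog,
                 fingerprint_scatter = fingerprint_scatter,
                 seed = as.integer(seed)),
            class = "study_design")
}

## template preset with per-specimen scatter applied: shifts the A5/A3 of
## the template and all phases coherently
perturb_template <- function(preset, d_r53, d_phi_deg) {
  amps <- preset$template_amps
  r53 <- max(amps[["5"]] + d_r53, 1e-4)
  amps[["5"]] <- min(r53, 1)
  # keep the non-increasing amplitude ladder intact
  for (k in seq_along(amps)[-1])
    amps[[k]] <- min(amps[[k]], amps[[k - 1]])
  phases <- preset$template_phases + d_phi_deg
  particle_preset(preset$name, "template", template_amps = amps,
                  template_phases = phases,
                  specific_a3_per_kg = preset$specific_a3_per_kg)
}

#' Generate a synthetic biodistribution study with ground truth
#'
#' Produces one time-domain measurement per specimen. For tracer-treated
#' animals each organ receives `dose * body mass * fraction * molar mass of
#' iron` kilograms of tracer iron, lognormally jittered per specimen; the
#' tracer signal is synthesized from the (per-specimen perturbed) tracer
#' template at `iron mass * specific moment`. Contaminated specimens (drawn
#' per organ with `contamination_prob`) additionally carry a hysteretic
#' contaminant signal with jittered loop parameters. White instrument noise
#' is added to every measurement. All ground truth (tracer iron, contaminant
#' flag) is retained; all randomness flows from the design seed via named
#' substreams, so regeneration is bit-reproducible.
#'
#' @param design a [study_design()].
#' @param tracer_preset template-mode [particle_preset()] of the tracer.
#' @param contaminant a [contaminant_preset()].
#' @param config an [excitation_config()].
#' @param noise_sd per-sample instrument noise in A m^2.
#' @return list of class `study_dataset`: `records` (data frame with a
#'   `signal` list-column and truth columns `truth_fe_kg`,
#'   `truth_contaminated`), plus the generating `design`, `config` and the
#'   ground-truth `specific_a3_per_kg`.
#' @export
generate_study <- function(design,
                           tracer_preset = load_presets()$vsop,
                           contaminant = load_presets()$contaminant_diet,
                           config = excitation_config(),
                           noise_sd = default_noise_sd(config)) {
  stopifnot(inherits(design, "study_design"),
            inherits(tracer_preset, "particle_preset"),
            tracer_preset$mode == "template",
            inherits(contaminant, "contaminant_preset"))
  spec_a3 <- tracer_preset$specific_a3_per_kg
  if (is.null(spec_a3))
    stop("tracer preset lacks specific_a3_per_kg ground truth")
  fe_total <- design$dose_mol_per_kg * design$body_mass_kg * .M_FE
  rows <- list()
  signals <- list()
  idx <- 0L
  for (g in seq_len(nrow(design$groups))) {
    treatment <- design$groups$treatment[g]
    model <- design$groups$model[g]
    for (organ in design$organs) {
      frac <- design$biodistribution_fractions[[organ]] %||% 0
      p_cont <- design$contamination_prob[[organ]] %||% 0
      tm <- design$tissue_mass_g[[organ]] %||% c(0.3, 0.05)
      for (r in seq_len(design$n_per_cell)) {
        idx <- idx + 1L
        id <- sprintf("%s_%s_%s_%02d", treatment, model, organ, r)
        set.seed(substream_seed(design$seed, paste0("record:", id)))
        mass_g <- max(stats::rnorm(1, tm[1], tm[2]), 0.01)
        contaminated <- stats::runif(1) < p_cont
        fe_kg <- 0
        if (treatment == "EuVSOP" && frac > 0)
          fe_kg <- fe_total * frac *
            exp(stats::rnorm(1, 0, design$fe_jitter_sdlog))
        d_r53 <- stats::rnorm(1, 0, design$fingerprint_scatter[["r53"]])
        d_phi <- stats::rnorm(1, 0, design$fingerprint_scatter[["phi3_deg"]])
        m <- numeric(n_samples(config))
        if (fe_kg > 0) {
          pre <- perturb_template(tracer_preset, d_r53, d_phi)
          m <- m + synthesize_template(config, pre,
                                       a3_moment = fe_kg * spec_a3)$samples
        }
        if (contaminated) {
          m <- m + simulate_contaminant(config, contaminant,
                                        seed = design$seed,
                                        sample_id = id)$samples
        }
        if (noise_sd > 0)
          m <- m + stats::rnorm(length(m), 0, noise_sd)
        signals[[idx]] <- mps_signal(m, config, id)
        rows[[idx]] <- data.frame(
          id = id, treatment = treatment, model = model, organ = organ,
          tissue_mass_g = mass_g, truth_fe_kg = fe_kg,
          truth_contaminated = contaminated)
      }
    }
  }
  records <- do.call(rbind, rows)
  records$signal <- signals
  structure(list(records = records, design = design, config = config,
                 specific_a3_per_kg = spec_a3,
                 noise_sd = noise_sd),
            class = "study_dataset")
}

#' Generate reference fingerprint features for region fitting
#'
#' Emulates a reference measurement campaign of the pure tracer under
#' varying environment (pH, ionic strength, cellular uptake): `n` replicates
#' of the tracer template, each perturbed by the same per-specimen scatter
#' law used in [generate_study()], measured at a comfortable amplitude with
#' instrument noise, analyzed, and reduced to fingerprint features.
#'
#' @param n number of reference measurements.
#' @param tracer_preset template-mode tracer preset.
#' @param config an [excitation_config()].
#' @param scatter named vector `c(r53, phi3_deg)` of scatter SDs.
#' @param a3_ref synthesis amplitude in A m^2.
#' @param noise_sd per-sample noise in A m^2.
#' @param lod5 A5 detection limit passed to [extract_features()].
#' @param seed integer master seed.
#' @return data frame with columns `r53`, `phi3`, `r53_censored`.
#' @export
generate_reference_features <- function(
    n = 100L, tracer_preset = load_presets()$vsop,
    config = excitation_config(),
    scatter = c(r53 = 0.012, phi3_deg = 1.0),
    a3_ref = 2e-9, noise_sd = default_noise_sd(config),
    lod5 = 2e-11, seed = 1L) {
  feats <- lapply(seq_len(n), function(i) {
    id <- sprintf("ref_%03d", i)
    set.seed(substream_seed(seed, paste0("reference:", id)))
    d_r53 <- stats::rnorm(1, 0, scatter[["r53"]])
    d_phi <- stats::rnorm(1, 0, scatter[["phi3_deg"]])
    pre <- perturb_template(tracer_preset, d_r53, d_phi)
    m <- synthesize_template(config, pre, a3_moment = a3_ref)$samples
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    extract_features(extract_harmonics(mps_signal(m, config, id)),
                     lod5 = lod5)
  })
  features_frame(feats)
}

#' Draw a contaminant preset from the dietary prior
#'
#' The dietary contaminant population is modeled by the packaged
#' `contaminant_diet` preset's jitter: coercivity uniform over 5-20 mT,
#' switching width uniform over 1-5 mT, lognormal moment spread. This helper
#' resolves the jitter once and returns the frozen single-measurement
#' preset, which is convenient for studying classifier power over the prior.
#'
#' @param seed integer seed.
#' @param base the jittered base preset.
#' @param label substream label.
#' @return a [contaminant_preset()] with zero jitter.
#' @export
sample_contaminant_preset <- function(seed, base = load_presets()$contaminant_diet,
                                      label = "prior") {
  set.seed(substream_seed(seed, paste0("contaminant_prior:", label)))
  jit <- base$jitter
  m_c <- base$m_c * exp(stats::rnorm(1, 0, jit[["m_c"]]))
  B_c <- max(base$B_c + stats::runif(1, -jit[["B_c"]], jit[["B_c"]]), 0)
  B_w <- max(base$B_w + stats::runif(1, -jit[["B_w"]], jit[["B_w"]]), 1e-4)
  contaminant_preset(m_c, B_c, B_w)
}
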