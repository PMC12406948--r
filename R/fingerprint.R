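#' Concentration-independent fingerprint features
#'
#' The pair \eqn{(A_5/A_3, \phi_3)} characterizes the spectral *shape* of a
#' measurement and is invariant to the amount of material: scaling every
#' amplitude leaves both coordinates unchanged. Small fast-relaxing tracers
#' sit at low ratio and near-zero phase; multicore systems and hysteretic
#' contaminants sit at higher ratios and larger lags. When A5 does not rise
#' above its detection floor the ratio is only an upper bound; it is
#' returned with `r53_censored = TRUE` and the floor-based bound as value.
#'
#' @param spectrum an `mps_spectrum` containing orders 3 and 5.
#' @param lod5 detection limit for A5 in A m^2 (defaults to 0: censor on the
#'   in-spectrum noise floor only).
#' @return list with `r53`, `phi3` (degrees), `r53_censored`.
#' @export
extract_features <- function(spectrum, lod5 = 0) {
  stopifnot(inherits(spectrum, "mps_spectrum"))
  a3 <- spectrum_amp(spectrum, 3L)
  a5 <- spectrum_amp(spectrum, 5L)
  if (is.na(a3) || a3 <= 0) stop("A3 must be positive to form A5/A3")
  if (is.na(a5)) stop("spectrum does not contain order 5")
  floor5 <- max(lod5, spectrum$noise_floor_n[match(5L, spectrum$orders)])
  if (a5 < floor5) {
    list(r53 = floor5 / a3, phi3 = spectrum_phase(spectrum, 3L),
         r53_censored = TRUE)
  } else {
    list(r53 = a5 / a3, phi3 = spectrum_phase(spectrum, 3L),
         r53_censored = FALSE)
  }
}

#' Fit the tracer acceptance region in the (A5/A3, phi3) plane
#'
#' The tracer's reference range — an ellipse in the fingerprint plane
#' spanning preparation and environmental variability (pH, ionic strength,
#' cellular uptake) — is formalized as a Gaussian acceptance region: the
#' centroid and sample covariance of reference features define a Mahalanobis
#' metric, and the boundary is the chi-square quantile with 2 degrees of
#' freedom at the requested coverage (default 0.99, i.e. squared-distance
#' threshold 9.21).
#'
#' Censored reference ratios never enter the fit (they would bias the
#' covariance toward the censoring floor).
#'
#' @param reference_features list of feature lists from
#'   [extract_features()], or a data frame with columns `r53`, `phi3`
#'   (optionally `r53_censored`).
#' @param quantile nominal coverage in (0, 1).
#' @return an object of class `mps_region`: `centroid` (named vector),
#'   `covariance` (2x2), `md2_threshold`, `quantile`, `n_reference`.
#' @export
fit_region <- function(reference_features, quantile = 0.99) {
  stopifnot(quantile > 0, quantile < 1)
  df <- features_frame(reference_features)
  df <- df[!df$r53_censored, , drop = FALSE]
  if (nrow(df) < 3)
    stop("at least 3 non-censored reference points are required")
  X <- cbind(r53 = df$r53, phi3 = df$phi3)
  centroid <- colMeans(X)
  covariance <- stats::cov(X)
  if (!all(is.finite(covariance)) || det(covariance) <= 0 ||
      rcond(covariance) < 1e-12)
    stop("reference features are collinear or duplicated; ",
         "covariance is singular")
  structure(list(centroid = centroid, covariance = covariance,
                 md2_threshold = stats::qchisq(quantile, df = 2),
                 quantile = quantile, n_reference = nrow(df)),
            class = "mps_region")
}

#' @export
print.mps_region <- function(x, ...) {
  cat(sprintf(
    "fingerprint region: centroid (A5/A3 = %.3f, phi3 = %.2f deg), coverage %.2f (md2 <= %.3f), n_ref = %d\n",
    x$centroid[["r53"]], x$centroid[["phi3"]], x$quantile, x$md2_threshold,
    x$n_reference))
  invisible(x)
}

features_frame <- function(feats) {
  if (is.data.frame(feats)) {
    if (is.null(feats$r53_censored)) feats$r53_censored <- FALSE
    return(feats[, c("r53", "phi3", "r53_censored")])
  }
  do.call(rbind, lapply(feats, function(f)
    data.frame(r53 = f$r53, phi3 = f$phi3,
               r53_censored = isTRUE(f$r53_censored))))
}

## squared Mahalanobis distance of feature points to the region centroid
region_md2 <- function(region, r53, phi3) {
  stats::mahalanobis(cbind(r53, phi3), region$centroid, region$covariance)
}

#' Classify one measurement: below LOD, tracer, or contaminated
#'
#' Three-way decision with LOD precedence: a measurement whose A3 falls
#' below the limit of detection carries no interpretable shape information
#' and is labeled `below_LOD`; otherwise its fingerprint features are tested
#' against the tracer region — inside (squared Mahalanobis distance within
#' the threshold) is `target_MNP`, outside is `contaminated`.
#'
#' @param spectrum an `mps_spectrum`.
#' @param region an `mps_region`.
#' @param lod an `mps_lod`.
#' @param lod5 detection limit used for A5 censoring. The same mu + 3 sigma
#'   rule applies per harmonic; order 5 carries no background feedthrough,
#'   so its limit is lower than the n = 3 LOD (see [lod_noise_only()]).
#'   Defaults conservatively to `lod$lod`.
#' @return a character label: `"below_LOD"`, `"target_MNP"` or
#'   `"contaminated"`.
#' @export
classify <- function(spectrum, region, lod, lod5 = lod$lod) {
  stopifnot(inherits(region, "mps_region"), inherits(lod, "mps_lod"))
  a3 <- spectrum_amp(spectrum, 3L)
  if (a3 < lod$lod) return("below_LOD")
  f <- extract_features(spectrum, lod5 = lod5)
  md2 <- region_md2(region, f$r53, f$phi3)
  if (md2 <= region$md2_threshold) "target_MNP" else "contaminated"
}

#' Corrected quantification: classify, exclude contamination, quantify
#'
#' Applies the full correction to an analyzed record table: every record is
#' classified ([classify()]); iron is quantified only for `target_MNP`
#' records; contaminated records are excluded from quantification and
#' tallied per organ and group, mirroring the "x out of n excluded"
#' bookkeeping of a corrected biodistribution report.
#'
#' @param records a record data frame carrying a `spectrum` list-column (see
#'   [analyze_records()]).
#' @param region an `mps_region`.
#' @param cal an `mps_calibration`.
#' @param lod an `mps_lod`.
#' @param lod5 detection limit for A5 censoring (see [classify()]).
#' @return list with `records` (input plus `r53`, `phi3_deg`,
#'   `r53_censored`, `label`, `fe_mass_kg`, `fe_upper_bound_kg`,
#'   `excluded_reason`) and `exclusions` (per treatment-model-organ counts
#'   `n_excluded`, `n_total`).
#' @export
correct_quantification <- function(records, region, cal, lod,
                                   lod5 = lod$lod) {
  stopifnot(is.data.frame(records))
  if (is.null(records$spectrum))
    stop("records carry no spectra; run analyze_records() first")
  n <- nrow(records)
  records$r53 <- NA_real_
  records$phi3_deg <- NA_real_
  records$r53_censored <- NA
  records$label <- character(n)
  records$fe_mass_kg <- NA_real_
  records$fe_upper_bound_kg <- NA_real_
  records$excluded_reason <- NA_character_
  for (i in seq_len(n)) {
    spec <- records$spectrum[[i]]
    lab <- classify(spec, region, lod, lod5 = lod5)
    records$label[i] <- lab
    if (lab != "below_LOD") {
      f <- extract_features(spec, lod5 = lod5)
      records$r53[i] <- f$r53
      records$phi3_deg[i] <- f$phi3
      records$r53_censored[i] <- f$r53_censored
    }
    q <- quantify_iron(spec, cal, lod)
    records$fe_upper_bound_kg[i] <- q$upper_bound_kg
    if (lab == "target_MNP") {
      records$fe_mass_kg[i] <- q$fe_mass_kg
    } else {
      records$excluded_reason[i] <-
        if (lab == "below_LOD") "below_LOD" else "contaminated_fingerprint"
    }
  }
  key <- interaction(records$treatment, records$model, records$organ,
                     drop = TRUE)
  exclusions <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(treatment = g$treatment[1], model = g$model[1],
               organ = g$organ[1],
               n_excluded = sum(g$label == "contaminated"),
               n_total = nrow(g))
  }))
  rownames(exclusions) <- NULL
  list(records = records, exclusions = exclusions)
}

#' Attach harmonic spectra to a study record table
#'
#' Runs [extract_harmonics()] on every record's time signal and stores the
#' spectrum plus its A3 alongside the record.
#'
#' @param records record data frame with a `signal` list-column of
#'   [mps_signal()] objects (see [generate_study()]).
#' @param n_max highest harmonic order to analyze.
#' @return the records with added `spectrum` list-column and `A3` column.
#' @export
analyze_records <- function(records, n_max = NULL) {
  stopifnot(is.data.frame(records), !is.null(records$signal))
  specs <- lapply(records$signal, function(s)
    extract_harmonics(s, n_max = if (is.null(n_max)) s$config$n_max_harmonic
                      else n_max))
  records$spectrum <- specs
  records$A3 <- vapply(specs, spectrum_amp, numeric(1), 3L)
  records
}
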