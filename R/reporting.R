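#' Group-level descriptive statistics of a classified record table
#'
#' One summary row per grouping cell (default: treatment x model x organ).
#' Counts partition every record into below-LOD, contaminated and
#' quantified; the descriptive statistics (mean, unadjusted SD, median,
#' quartiles by linear interpolation, whiskers, outliers) are computed on
#' the *quantified* records only — censored values are counted, never
#' imputed. Statistics are reported for the third-harmonic moment `A3`
#' (A m^2) and, when present, for iron per tissue mass (`fe_per_g`).
#'
#' Whisker conventions (box statistics are identical across modes):
#' * `percentile_5_95` — whiskers at the 5th and 95th percentiles;
#' * `sd` — whiskers at mean +/- one standard deviation;
#' * `iqr_1_5` — Tukey whiskers at quartile -/+ 1.5 IQR.
#'
#' @param records classified record data frame (see
#'   [correct_quantification()]).
#' @param grouping character vector of grouping columns.
#' @param whisker_mode one of `"percentile_5_95"`, `"sd"`, `"iqr_1_5"`.
#' @return data frame, one row per group, with count, A3 and `fe_per_g`
#'   summary columns; `outliers_a3` is a list-column of values outside the
#'   whiskers.
#' @export
summarize_groups <- function(records,
                             grouping = c("treatment", "model", "organ"),
                             whisker_mode = c("percentile_5_95", "sd",
                                              "iqr_1_5")) {
  whisker_mode <- match.arg(whisker_mode)
  stopifnot(is.data.frame(records), all(grouping %in% names(records)),
            !is.null(records$label))
  key <- interaction(records[grouping], drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    q <- g[g$label == "target_MNP", , drop = FALSE]
    row <- g[1, grouping, drop = FALSE]
    row$n_total <- nrow(g)
    row$n_below_lod <- sum(g$label == "below_LOD")
    row$n_contaminated <- sum(g$label == "contaminated")
    row$n_quantified <- nrow(q)
    a3 <- q$A3
    st <- describe_values(a3, whisker_mode)
    names(st) <- paste0(names(st), "_a3")
    row <- cbind(row, st)
    row$outliers_a3 <- I(list(
      a3[a3 < st$whisker_low_a3 | a3 > st$whisker_high_a3]))
    if (!is.null(q$fe_per_g)) {
      st2 <- describe_values(q$fe_per_g * 1e9, whisker_mode)  # kg/g -> ug/g
      names(st2) <- paste0(names(st2), "_fe_ug_per_g")
      row <- cbind(row, st2)
    }
    row$whisker_mode <- whisker_mode
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## descriptive block used for each reported variable; linear-interpolation
## (type 7) quantiles match the boxplot convention
describe_values <- function(x, whisker_mode) {
  if (length(x) == 0)
    return(data.frame(mean = NA_real_, sd = NA_real_, median = NA_real_,
                      q1 = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
                      whisker_high = NA_real_))
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  wh <- switch(whisker_mode,
    percentile_5_95 = stats::quantile(x, c(0.05, 0.95), type = 7,
                                      names = FALSE),
    sd = c(m - s, m + s),
    iqr_1_5 = c(qs[1] - 1.5 * (qs[3] - qs[1]),
                qs[3] + 1.5 * (qs[3] - qs[1])))
  data.frame(mean = m, sd = s, median = qs[2], q1 = qs[1], q3 = qs[3],
             whisker_low = wh[1], whisker_high = wh[2])
}

#' Normalize quantified iron to tissue mass
#'
#' Adds `fe_per_g` (kg iron per g tissue) to each record:
#' `fe_mass_kg / tissue_mass_g` for quantified records and the normalized
#' censoring bound `fe_upper_bound_kg / tissue_mass_g` as
#' `fe_per_g_upper_bound` for all records, so censored records keep their
#' censored status with a mass-normalized bound.
#'
#' @param records classified record data frame with `tissue_mass_g`.
#' @return the records with `fe_per_g` and `fe_per_g_upper_bound` columns.
#' @export
normalize_per_tissue_mass <- function(records) {
  stopifnot(is.data.frame(records), !is.null(records$tissue_mass_g))
  if (any(records$tissue_mass_g <= 0))
    stop("tissue masses must be positive")
  records$fe_per_g <- records$fe_mass_kg / records$tissue_mass_g
  records$fe_per_g_upper_bound <-
    records$fe_upper_bound_kg / records$tissue_mass_g
  records
}

#' Plot-ready fingerprint scatter and region boundaries
#'
#' Builds the data behind an (A5/A3, phi3) fingerprint plot: one scatter row
#' per record with features (below-LOD records carry none and are reported
#' in the legend counts only), plus a sampled boundary polyline per region —
#' the ellipse of constant squared Mahalanobis distance equal to the
#' region's threshold.
#'
#' @param records classified record data frame.
#' @param regions an `mps_region` or list of them.
#' @param n_boundary points per boundary polyline.
#' @return list with `points` (columns `id`, `group`, `label`, `r53`,
#'   `phi3`), `boundaries` (columns `region`, `r53`, `phi3`) and
#'   `legend_counts` (records per label).
#' @export
export_fingerprint_plot_data <- function(records, regions,
                                         n_boundary = 181L) {
  stopifnot(is.data.frame(records))
  if (inherits(regions, "mps_region")) regions <- list(regions)
  has_f <- !is.na(records$r53)
  points <- data.frame(
    id = records$id[has_f],
    group = paste(records$treatment[has_f], records$model[has_f],
                  records$organ[has_f], sep = "/"),
    label = records$label[has_f],
    r53 = records$r53[has_f],
    phi3 = records$phi3_deg[has_f])
  if (is.null(names(regions)))
    names(regions) <- paste0("region_", seq_along(regions))
  boundaries <- do.call(rbind, lapply(names(regions), function(nm) {
    rg <- regions[[nm]]
    theta <- seq(0, 2 * pi, length.out = n_boundary)
    L <- chol(rg$covariance)  # upper triangular, t(L) %*% L = cov
    circ <- rbind(cos(theta), sin(theta)) * sqrt(rg$md2_threshold)
    xy <- t(t(L) %*% circ) + matrix(rg$centroid, n_boundary, 2, byrow = TRUE)
    data.frame(region = nm, r53 = xy[, 1], phi3 = xy[, 2])
  }))
  legend_counts <- as.data.frame(table(label = records$label),
                                 responseName = "n")
  list(points = points, boundaries = boundaries,
       legend_counts = legend_counts)
}

#' Quick fingerprint plot
#'
#' Thin optional wrapper around [export_fingerprint_plot_data()] using
#' ggplot2 (suggested dependency): scatter of record fingerprints colored by
#' label with region boundary ellipses.
#'
#' @inheritParams export_fingerprint_plot_data
#' @return a ggplot object.
#' @export
plot_fingerprint <- function(records, regions) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_fingerprint() needs the ggplot2 package")
  pd <- export_fingerprint_plot_data(records, regions)
  ggplot2::ggplot(pd$points, ggplot2::aes(x = .data$r53, y = .data$phi3)) +
    ggplot2::geom_path(data = pd$boundaries,
                       ggplot2::aes(group = .data$region),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8) +
    ggplot2::labs(x = expression(A[5] / A[3]),
                  y = expression(phi[3] ~ "(deg)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
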