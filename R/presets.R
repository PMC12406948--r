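#' Particle presets: physical and template modes
#'
#' A particle preset describes the magnetic response of one MNP system in
#' one of two ways:
#'
#' * **physical** — a lognormal core-size distribution (median diameter
#'   `d_med` in m, lognormal shape `sigma_d`), core saturation magnetization
#'   `M_s` (A/m) and a single effective Debye relaxation time `tau` (s).
#'   Signals are produced by integrating the relaxation dynamics of the
#'   size-averaged Langevin equilibrium response.
#' * **template** — a spectral template: relative odd-harmonic amplitudes
#'   (`template_amps`, with \eqn{A_3 \equiv 1}) and phases in degrees
#'   (`template_phases`, negative = lag). Template synthesis round-trips
#'   exactly through the analyzer and anchors the spectral signatures of
#'   named tracers (VSOP-like, Endorem-like, multicore).
#'
#' Template presets additionally carry `specific_a3_per_kg`, the
#' third-harmonic moment per kg of iron (A m^2 / kg), used by the study
#' generator as the ground-truth calibration constant.
#'
#' @param name preset name.
#' @param mode `"physical"` or `"template"`.
#' @param d_med,sigma_d,M_s,tau physical-mode fields (see above).
#' @param template_amps named numeric vector, names are odd orders >= 3,
#'   `template_amps["3"]` must be 1 and amplitudes non-increasing in order.
#' @param template_phases named numeric vector of phases in degrees for the
#'   same orders.
#' @param specific_a3_per_kg A3 moment per kg iron (template mode).
#' @return an object of class `particle_preset`.
#' @export
particle_preset <- function(name, mode = c("physical", "template"),
                            d_med = NULL, sigma_d = NULL, M_s = NULL,
                            tau = NULL, template_amps = NULL,
                            template_phases = NULL,
                            specific_a3_per_kg = NULL) {
  mode <- match.arg(mode)
  if (mode == "physical") {
    stopifnot(is.numeric(d_med), d_med > 0, is.numeric(sigma_d), sigma_d >= 0,
              is.numeric(M_s), M_s > 0, is.numeric(tau), tau >= 0)
  } else {
    orders <- as.integer(names(template_amps))
    if (any(is.na(orders)) || any(orders %% 2 == 0) || any(orders < 3))
      stop("template orders must be odd integers >= 3")
    if (is.null(names(template_phases)) ||
        !identical(sort(orders), sort(as.integer(names(template_phases)))))
      stop("template_amps and template_phases must cover the same orders")
    o <- order(orders)
    template_amps <- template_amps[o]
    template_phases <- template_phases[as.character(orders[o])]
    if (abs(template_amps[["3"]] - 1) > 1e-12)
      stop("template amplitude at order 3 must be 1 (A3 reference)")
    if (any(template_amps <= 0) || any(template_amps > 1))
      stop("relative template amplitudes must lie in (0, 1]")
    if (any(diff(template_amps) > 1e-12))
      stop("relative template amplitudes must be non-increasing in order")
  }
  structure(list(name = name, mode = mode, d_med = d_med, sigma_d = sigma_d,
                 M_s = M_s, tau = tau, template_amps = template_amps,
                 template_phases = template_phases,
                 specific_a3_per_kg = specific_a3_per_kg),
            class = "particle_preset")
}

#' @export
print.particle_preset <- function(x, ...) {
  if (x$mode == "physical") {
    cat(sprintf(
      "particle preset '%s' (physical): d_med = %.3g nm, sigma_d = %.3g, M_s = %.3g A/m, tau = %.3g s\n",
      x$name, x$d_med * 1e9, x$sigma_d, x$M_s, x$tau))
  } else {
    cat(sprintf("particle preset '%s' (template): A_n/A_3 = {%s}, phi_n = {%s} deg\n",
                x$name,
                paste(sprintf("%d: %.3g", as.integer(names(x$template_amps)),
                              x$template_amps), collapse = ", "),
                paste(sprintf("%d: %.3g", as.integer(names(x$template_phases)),
                              x$template_phases), collapse = ", ")))
  }
  invisible(x)
}

#' Hysteretic contaminant preset
#'
#' Dietary magnetic contamination is modeled as a smooth rectangular
#' hysteron: ascending branch \eqn{m = m_c \tanh((B - B_c)/B_w)}, descending
#' branch \eqn{m = m_c \tanh((B + B_c)/B_w)}, the branch selected by the sign
#' of \eqn{dB/dt}. `jitter` gives per-measurement uniform half-widths for
#' `(m_c, B_c, B_w)` (absolute for the fields, relative log-scale for `m_c`)
#' so that a population of contaminated specimens shows the broad fingerprint
#' scatter seen in dietary iron.
#'
#' @param m_c saturation moment in A m^2.
#' @param B_c coercivity in T.
#' @param B_w switching smoothness in T.
#' @param jitter named list/vector with elements `m_c` (lognormal sd of the
#'   moment), `B_c` and `B_w` (uniform half-widths in T); all default 0.
#' @return an object of class `contaminant_preset`.
#' @export
contaminant_preset <- function(m_c, B_c, B_w,
                               jitter = c(m_c = 0, B_c = 0, B_w = 0)) {
  stopifnot(m_c > 0, B_c >= 0, B_w > 0)
  jit <- c(m_c = 0, B_c = 0, B_w = 0)
  jit[names(jitter)] <- unlist(jitter)
  structure(list(m_c = m_c, B_c = B_c, B_w = B_w, jitter = jit),
            class = "contaminant_preset")
}

#' Load the packaged preset registry
#'
#' The registry (a YAML file under `inst/extdata/`) ships template presets
#' for the named tracer systems and the default dietary-contaminant hysteron:
#'
#' * `vsop` — steep harmonic decay, A5/A3 = 0.10, phases near -2 deg;
#' * `endorem` — intermediate, A5/A3 = 0.20, phases near -10 deg;
#' * `mcp_resovist` — flat multicore spectrum, A5/A3 = 0.30, phases near
#'   -30 deg;
#' * `vsop_physical` — a representative small-core physical preset;
#' * `contaminant_diet` — hysteron with broad coercivity/smoothness jitter.
#'
#' @param path optional path to an alternative registry file.
#' @return a named list of `particle_preset` / `contaminant_preset` objects.
#' @examples
#' presets <- load_presets()
#' presets$vsop
#' @export
load_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "mpsquant",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    if (identical(p$kind, "contaminant")) {
      contaminant_preset(m_c = p$m_c_am2, B_c = p$b_c_t, B_w = p$b_w_t,
                         jitter = c(m_c = p$jitter$m_c_rel %||% 0,
                                    B_c = p$jitter$b_c_t %||% 0,
                                    B_w = p$jitter$b_w_t %||% 0))
    } else if (identical(p$mode, "template")) {
      particle_preset(nm, "template",
                      template_amps = unlist(p$template_amps),
                      template_phases = unlist(p$template_phases_deg),
                      specific_a3_per_kg = p$specific_a3_am2_per_kg)
    } else {
      particle_preset(nm, "physical", d_med = p$d_med_m,
                      sigma_d = p$sigma_d, M_s = p$m_s_a_per_m,
                      tau = p$tau_s)
    }
  })
  names(out) <- names(raw)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
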