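## Sign of the n-th Fourier sine coefficient of an ideal lag-free saturable
## response m(t) = g(B_ex sin wt), g odd and saturating. For such responses
## the odd sine coefficients alternate: +, -, +, ... for n = 1, 3, 5, ...
## Computed once numerically from a deeply saturated tanh drive and cached;
## this is the phase reference that makes a lag-free measurement read 0 deg.
.eq_sign_cache <- new.env(parent = emptyenv())

equilibrium_phase_sign <- function(n) {
  key <- as.character(n)
  if (!is.null(.eq_sign_cache[[key]])) return(.eq_sign_cache[[key]])
  spp <- 4096L
  j <- seq_len(spp) - 1L
  g <- tanh(5 * sin(2 * pi * j / spp))
  b_n <- 2 / spp * sum(g * sin(2 * pi * n * j / spp))
  s <- if (b_n >= 0) 1 else -1
  .eq_sign_cache[[key]] <- s
  s
}

#' Extract the odd-harmonic amplitude and phase spectrum
#'
#' Fourier analysis of a coherently sampled measurement. Because the
#' acquisition contains an integer number of drive periods, harmonic `n`
#' falls exactly on DFT bin `n * n_periods` and a rectangular window is
#' leakage-free. For each odd order `n` from 3 to `n_max`:
#'
#' * amplitude \eqn{A_n = 2 |c_n| / N} (A m^2), where \eqn{c_n} is the DFT
#'   coefficient at the harmonic bin;
#' * raw phase \eqn{\theta_n} measured against the drive reference
#'   \eqn{\sin(2\pi n f_{ex} t)};
#' * reported phase \eqn{\phi_n = wrap(\theta_n - \theta_n^{eq})}, where
#'   \eqn{\theta_n^{eq} \in \{0°, 180°\}} is the phase of an ideal lag-free
#'   saturable response. An equilibrium (zero-relaxation) measurement
#'   therefore reads exactly 0 deg at every order, and relaxation lag reads
#'   negative — the instrument's negative-lag convention.
#'
#' Voltage-mode signals are de-converted to moment units before reporting
#' (amplitude at order `n` divided by \eqn{2\pi n f_{ex}}, phase rotated by
#' +90 deg). The fundamental (`n = 1`) is suppressed in hardware by
#' high-pass filtering and the gradiometric pick-up and is never reported.
#'
#' @param signal an [mps_signal()].
#' @param n_max highest (odd) harmonic order to report.
#' @return an object of class `mps_spectrum`: list with `orders`, `A_n`,
#'   `phi_n` (degrees in (-180, 180]), `noise_floor_n`, `sample_id`,
#'   `config`.
#' @examples
#' cfg <- excitation_config()
#' sig <- synthesize_template(cfg, load_presets()$vsop, a3_moment = 1e-10)
#' spec <- extract_harmonics(sig)
#' spec$A_n[2] / spec$A_n[1]  # A5/A3 = 0.10
#' @export
extract_harmonics <- function(signal, n_max = signal$config$n_max_harmonic) {
  stopifnot(inherits(signal, "mps_signal"))
  config <- signal$config
  if (n_max %% 2 == 0) stop("n_max must be odd")
  if (n_max * config$f_ex > config$sample_rate / 2)
    stop("harmonic ", n_max, " is above Nyquist for this acquisition")
  N <- length(signal$samples)
  if (N %% config$samples_per_period != 0)
    stop("signal does not contain an integer number of periods")
  orders <- seq(3L, n_max, by = 2L)
  X <- stats::fft(signal$samples)
  bins <- orders * config$n_periods  # 0-based bin index
  c_n <- X[bins + 1L]
  A_n <- 2 * Mod(c_n) / N
  # x = A sin(n w t + theta) has DFT coefficient (N/2) A e^{i(theta - 90deg)}
  theta <- Arg(c_n) * 180 / pi + 90
  if (signal$voltage_mode) {
    A_n <- A_n / (2 * pi * orders * config$f_ex)
    theta <- theta + 90
  }
  eq_sign <- vapply(orders, equilibrium_phase_sign, numeric(1))
  theta_eq <- ifelse(eq_sign > 0, 0, 180)
  phi_n <- wrap_deg(theta - theta_eq)
  floors <- noise_floor_from_fft(X, N, config, orders,
                                 voltage = signal$voltage_mode)
  structure(list(orders = orders, A_n = A_n, phi_n = phi_n,
                 noise_floor_n = floors, sample_id = signal$sample_id,
                 config = config),
            class = "mps_spectrum")
}

#' @export
print.mps_spectrum <- function(x, ...) {
  cat(sprintf("MPS spectrum '%s':\n", x$sample_id))
  print(data.frame(n = x$orders, A_n = signif(x$A_n, 4),
                   phi_n_deg = round(x$phi_n, 2),
                   noise_floor = signif(x$noise_floor_n, 3)),
        row.names = FALSE)
  invisible(x)
}

## per-order noise floor: median amplitude of non-harmonic bins in a window
## around each harmonic bin (harmonic bins themselves excluded).
noise_floor_from_fft <- function(X, N, config, orders, voltage = FALSE) {
  np <- config$n_periods
  amps <- 2 * Mod(X) / N
  vapply(orders, function(n) {
    centre <- n * np
    if (np == 1L) {
      warning("n_periods = 1: no non-harmonic bins near order ", n,
              "; falling back to the global non-harmonic median")
      cand <- setdiff(seq(2L, N %/% 2), orders)
      fl <- stats::median(amps[cand + 1L])
    } else {
      win <- (centre - np + 1L):(centre + np - 1L)
      win <- setdiff(win, seq(0L, N, by = np))  # drop harmonic bins
      win <- win[win >= 1 & win <= N %/% 2]
      fl <- stats::median(amps[win + 1L])
    }
    if (voltage) fl <- fl / (2 * pi * n * config$f_ex)
    fl
  }, numeric(1))
}

#' Noise floor per harmonic order
#'
#' Convenience wrapper returning only the per-order noise floors of
#' [extract_harmonics()]: the median amplitude of the non-harmonic DFT bins
#' in a window around each harmonic bin, in the same amplitude units as
#' `A_n`. Harmonics whose amplitude does not rise above these floors are
#' treated as unobserved (e.g. when censoring the A5/A3 ratio).
#'
#' @inheritParams extract_harmonics
#' @return numeric vector of per-order floors in A m^2.
#' @export
estimate_noise_floor <- function(signal, n_max = signal$config$n_max_harmonic) {
  extract_harmonics(signal, n_max)$noise_floor_n
}

#' Average spectra as phasors
#'
#' Complex (phasor) mean per harmonic order: amplitudes and phases are
#' combined as \eqn{\bar z_n = mean(A_n e^{i\phi_n})}; the averaged spectrum
#' has \eqn{A_n = |\bar z_n|}, \eqn{\phi_n = \arg \bar z_n}. Identical
#' inputs average to themselves; incoherent phases reduce amplitude, as in
#' the instrument's on-board averaging.
#'
#' @param spectra a list of `mps_spectrum` objects sharing orders and
#'   acquisition settings.
#' @return an `mps_spectrum`.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) == 0) stop("cannot average an empty list of spectra")
  stopifnot(all(vapply(spectra, inherits, logical(1), "mps_spectrum")))
  orders <- spectra[[1]]$orders
  for (s in spectra)
    if (!identical(s$orders, orders))
      stop("spectra have mismatched harmonic orders")
  Z <- vapply(spectra, function(s) s$A_n * exp(1i * s$phi_n * pi / 180),
              complex(length(orders)))
  Z <- matrix(Z, nrow = length(orders))
  zbar <- rowMeans(Z)
  floors <- rowMeans(matrix(
    vapply(spectra, `[[`, numeric(length(orders)), "noise_floor_n"),
    nrow = length(orders)))
  structure(list(orders = orders, A_n = Mod(zbar),
                 phi_n = wrap_deg(Arg(zbar) * 180 / pi),
                 noise_floor_n = floors,
                 sample_id = paste0("mean_of_", length(spectra)),
                 config = spectra[[1]]$config),
            class = "mps_spectrum")
}

#' Amplitude or phase of a spectrum at one harmonic order
#'
#' @param spectrum an `mps_spectrum`.
#' @param n harmonic order.
#' @return the amplitude in A m^2 (or phase in degrees); `NA` when the
#'   order is not present.
#' @export
spectrum_amp <- function(spectrum, n) {
  i <- match(n, spectrum$orders)
  if (is.na(i)) NA_real_ else spectrum$A_n[i]
}

#' @rdname spectrum_amp
#' @export
spectrum_phase <- function(spectrum, n) {
  i <- match(n, spectrum$orders)
  if (is.na(i)) NA_real_ else spectrum$phi_n[i]
}

#' Spectra as a long data frame
#'
#' @param spectra a list of `mps_spectrum` objects (or a single one).
#' @return data frame with columns `sample_id`, `n`, `A_n`, `phi_n_deg`,
#'   `noise_floor_n`.
#' @export
spectra_table <- function(spectra) {
  if (inherits(spectra, "mps_spectrum")) spectra <- list(spectra)
  do.call(rbind, lapply(spectra, function(s) {
    data.frame(sample_id = s$sample_id, n = s$orders, A_n = s$A_n,
               phi_n_deg = s$phi_n, noise_floor_n = s$noise_floor_n)
  }))
}
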