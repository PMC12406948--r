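#' Excitation and acquisition settings
#'
#' Describes the sinusoidal drive field and the coherent acquisition used by
#' the spectrometer model. The defaults mirror a commercial magnetic particle
#' spectrometer driven at 25 kHz with a 25 mT amplitude; acquisition is
#' coherent (an integer number of samples per drive period) so that every
#' harmonic falls on an exact Fourier bin and a rectangular window is
#' leakage-free.
#'
#' @param f_ex excitation frequency in Hz.
#' @param B_ex excitation amplitude in T.
#' @param samples_per_period integer samples acquired per drive period.
#' @param n_periods integer number of periods acquired.
#' @param temperature sample temperature in K.
#' @param n_max_harmonic highest harmonic order the analyzer will report;
#'   used to check the Nyquist condition.
#' @return an object of class `excitation_config`.
#' @examples
#' cfg <- excitation_config()
#' cfg$sample_rate  # 1.6 MHz
#' @export
excitation_config <- function(f_ex = 25e3, B_ex = 25e-3,
                              samples_per_period = 64L, n_periods = 16L,
                              temperature = 300, n_max_harmonic = 9L) {
  stopifnot(f_ex > 0, B_ex > 0, temperature > 0,
            samples_per_period == round(samples_per_period),
            n_periods >= 1, n_periods == round(n_periods))
  samples_per_period <- as.integer(samples_per_period)
  n_periods <- as.integer(n_periods)
  if (samples_per_period < 2L * n_max_harmonic)
    stop("samples_per_period violates Nyquist for harmonic ", n_max_harmonic)
  structure(list(
    f_ex = f_ex, B_ex = B_ex,
    sample_rate = f_ex * samples_per_period,
    samples_per_period = samples_per_period,
    n_periods = n_periods,
    temperature = temperature,
    n_max_harmonic = as.integer(n_max_harmonic)
  ), class = "excitation_config")
}

#' @export
print.excitation_config <- function(x, ...) {
  cat(sprintf(
    "MPS excitation: f_ex = %g kHz, B_ex = %g mT, %d samples/period x %d periods, T = %g K\n",
    x$f_ex / 1e3, x$B_ex * 1e3, x$samples_per_period, x$n_periods,
    x$temperature))
  invisible(x)
}

n_samples <- function(config) config$samples_per_period * config$n_periods

## drive field over the acquisition grid (or an oversampled grid)
drive_field <- function(config, oversample = 1L, periods = config$n_periods) {
  spp <- config$samples_per_period * oversample
  j <- seq_len(spp * periods) - 1L
  config$B_ex * sin(2 * pi * j / spp)
}

#' Drive field over the acquisition grid
#'
#' @param config an [excitation_config()].
#' @return numeric vector of `B(t)` in T at every acquired sample.
#' @export
drive_field_samples <- function(config) drive_field(config, 1L)

#' Construct a time-domain MPS signal object
#'
#' A `mps_signal` holds one measurement: the sampled magnetic moment (A m^2)
#' or, with `voltage_mode = TRUE`, the induced-voltage-like moment rate
#' (A m^2 / s, proportional to -dm/dt), together with the acquisition
#' settings under which it was recorded.
#'
#' @param samples numeric vector of samples; length must equal
#'   `samples_per_period * n_periods` of `config`.
#' @param config an [excitation_config()].
#' @param sample_id identifier carried through analysis and exports.
#' @param voltage_mode logical; `TRUE` when `samples` is -dm/dt.
#' @return an object of class `mps_signal`.
#' @export
mps_signal <- function(samples, config, sample_id = "sample",
                       voltage_mode = FALSE) {
  stopifnot(inherits(config, "excitation_config"), is.numeric(samples))
  if (length(samples) != n_samples(config))
    stop("signal length ", length(samples), " does not equal ",
         "samples_per_period * n_periods = ", n_samples(config))
  structure(list(samples = as.numeric(samples),
                 dt = 1 / config$sample_rate,
                 voltage_mode = isTRUE(voltage_mode),
                 sample_id = as.character(sample_id),
                 config = config),
            class = "mps_signal")
}

#' @export
print.mps_signal <- function(x, ...) {
  cat(sprintf("MPS signal '%s': %d samples (%s), dt = %.3g s\n",
              x$sample_id, length(x$samples),
              if (x$voltage_mode) "voltage mode, A m^2/s" else "moment, A m^2",
              x$dt))
  invisible(x)
}

#' Convert a moment signal to its induced-voltage representation
#'
#' The pick-up coil senses \eqn{u(t) \propto -dm/dt}. For a coherent periodic
#' acquisition the derivative is computed spectrally (exact for band-limited
#' periodic signals), so converting and de-converting in the analyzer is an
#' identity.
#'
#' @param signal a moment-mode [mps_signal()].
#' @return an [mps_signal()] with `voltage_mode = TRUE`.
#' @export
voltage_from_moment <- function(signal) {
  stopifnot(inherits(signal, "mps_signal"))
  if (signal$voltage_mode) stop("signal is already in voltage mode")
  x <- signal$samples
  N <- length(x)
  k <- c(0:(N / 2), -(N / 2 - 1):-1)  # N is even by construction
  omega <- 2 * pi * k / (N * signal$dt)
  X <- stats::fft(x)
  X[N / 2 + 1] <- 0  # drop the unmatched Nyquist bin before differentiating
  dm <- Re(stats::fft(X * 1i * omega, inverse = TRUE)) / N
  mps_signal(-dm, signal$config, signal$sample_id, voltage_mode = TRUE)
}
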