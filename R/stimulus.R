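#' Zero-mean low-pass-filtered white-noise current
#'
#' Gaussian white noise passed through a first-order low-pass filter with
#' the requested corner (-3 dB) frequency, then rescaled so the realized
#' standard deviation equals the request exactly. Reproducible from the
#' R RNG state (`set.seed()`).
#'
#' @param sd_nA target standard deviation of the current (nA).
#' @param corner_kHz corner frequency of the low-pass filter (kHz); must be
#'   below the Nyquist frequency 1/(2 dt).
#' @param dt time step (ms).
#' @param duration_ms duration (ms).
#' @return numeric vector of length `round(duration_ms / dt)` (nA).
#' @examples
#' set.seed(1)
#' i <- make_filtered_noise(0.01, 1, 0.005, 1000)
#' sd(i)  # 0.01 by construction
#' @export
make_filtered_noise <- function(sd_nA, corner_kHz, dt, duration_ms) {
  n <- round(duration_ms / dt)
  stopifnot(n > 1)
  if (corner_kHz >= 1 / (2 * dt))
    stop("corner frequency must be below the Nyquist frequency 1/(2 dt)")
  w <- stats::rnorm(n)
  a <- exp(-2 * pi * corner_kHz * dt)
  x <- stats::filter(w * (1 - a), a, method = "recursive")
  x <- as.numeric(x)
  x * sd_nA / stats::sd(x)
}

#' Stimulus protocols
#'
#' Constructors for the two stimulus protocols: a rectangular suprathreshold
#' pulse and the zero-mean filtered white-noise current, both injected at a
#' single site (fraction of axon length; 0 = proximal end).
#'
#' @param amplitude_nA pulse amplitude (nA).
#' @param duration_ms pulse/noise duration (ms).
#' @param onset_ms onset time (ms); before onset no current is injected.
#' @param site injection site as a fraction of axon length.
#' @return an object of class `stimulus`.
#' @export
stim_pulse <- function(amplitude_nA, duration_ms = 0.5, onset_ms = 5,
                       site = 0) {
  structure(list(kind = "single_pulse", amplitude_nA = amplitude_nA,
                 duration_ms = duration_ms, onset_ms = onset_ms, site = site),
            class = "stimulus")
}

#' @rdname stim_pulse
#' @param sd_nA noise standard deviation (nA).
#' @param corner_kHz corner frequency (kHz).
#' @export
stim_noise <- function(sd_nA = 0.01, corner_kHz = 1, duration_ms,
                       onset_ms = 20, site = 0) {
  structure(list(kind = "filtered_white_noise", sd_nA = sd_nA,
                 corner_kHz = corner_kHz, duration_ms = duration_ms,
                 onset_ms = onset_ms, site = site),
            class = "stimulus")
}

# Internal: realize a stimulus as a per-step current vector (nA). Noise
# realizations consume the R RNG stream.
stimulus_vector <- function(stim, dt, n_steps) {
  i <- numeric(n_steps)
  k0 <- round(stim$onset_ms / dt)
  if (stim$kind == "single_pulse") {
    k1 <- min(k0 + round(stim$duration_ms / dt), n_steps)
    if (k1 > k0) i[(k0 + 1):k1] <- stim$amplitude_nA
  } else if (stim$kind == "filtered_white_noise") {
    k1 <- min(k0 + round(stim$duration_ms / dt), n_steps)
    if (k1 > k0)
      i[(k0 + 1):k1] <- make_filtered_noise(stim$sd_nA, stim$corner_kHz, dt,
                                            (k1 - k0) * dt)[seq_len(k1 - k0)]
  } else stop("unknown stimulus kind: ", stim$kind)
  i
}
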