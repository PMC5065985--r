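# Complex Morlet (Gabor) transform and instantaneous phase on a decimated
# analysis grid (default every 5th sample: 20 ms at 250 Hz).

#' Morlet analysis parameters
#'
#' The mother wavelet is the analytic Morlet
#' `w(t, f) = (sigma^2 * pi)^(-1/4) * exp(-t^2 / (2 sigma^2)) * exp(2i pi f t)`,
#' a Gaussian envelope of SD `sigma` seconds around central frequency `f`.
#' By default `sigma` follows a constant-cycles rule `sigma = n_cycles /
#' (2 pi f)`; passing `sigma` switches to a fixed envelope for all frequencies.
#'
#' @param freqs Ascending analysis frequencies in Hz (default 0.125--20 Hz in
#'   0.125-Hz steps; the 2--20 Hz step-2 frequencies of interest are a subset).
#' @param n_cycles Cycles of the constant-cycles rule (ignored if `sigma` set).
#' @param sigma Optional fixed Gaussian-envelope SD in seconds.
#' @param time_step Decimation step in samples (5 at 250 Hz gives a 20-ms grid).
#' @return A `morlet_params` list.
#' @export
morlet_params <- function(freqs = seq(0.125, 20, by = 0.125), n_cycles = 5,
                          sigma = NULL, time_step = 5L) {
  if (any(freqs <= 0)) stop("analysis frequencies must be positive", call. = FALSE)
  if (is.unsorted(freqs)) stop("`freqs` must be ascending", call. = FALSE)
  time_step <- stopifnot_scalar_count(time_step, "time_step")
  if (!is.null(sigma) && sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (is.null(sigma) && n_cycles <= 0) stop("`n_cycles` must be positive", call. = FALSE)
  structure(list(freqs = as.numeric(freqs), n_cycles = n_cycles,
                 sigma = sigma, time_step = time_step),
            class = "morlet_params")
}

morlet_sigma <- function(params) {
  if (!is.null(params$sigma)) rep(params$sigma, length(params$freqs))
  else params$n_cycles / (2 * pi * params$freqs)
}

#' Complex Morlet wavelet transform
#'
#' Convolves every channel with the unit-energy analytic Morlet at each
#' frequency (zero-padded FFT convolution, kernel truncated at +/- 4 sigma) and
#' evaluates the result every `time_step` samples. Grid points whose wavelet
#' support extends beyond the signal are flagged in the `valid` attribute
#' (frequencies x grid points).
#'
#' @param rec A [segmented_recording()].
#' @param params A [morlet_params()] (frequencies must stay below Nyquist).
#' @return Complex array channels x frequencies x grid points with attributes
#'   `freqs`, `fs_phase`, `valid`, `time_step`.
#' @export
morlet_transform <- function(rec, params = morlet_params()) {
  stopifnot(inherits(rec, "segmented_recording"))
  fs <- rec$fs
  if (max(params$freqs) >= fs / 2) {
    stop("max analysis frequency must be below Nyquist (fs/2)", call. = FALSE)
  }
  x <- rec$data
  n <- ncol(x)
  sig <- morlet_sigma(params)
  half <- ceiling(4 * sig * fs)
  if (2L * max(half) + 1L > n) {
    stop("signal shorter than the widest wavelet support", call. = FALSE)
  }
  step <- params$time_step
  idx <- seq(1L, n, by = step)
  np <- length(idx)            # floor((n - 1) / step) + 1
  nfft <- nextn(n + 2L * max(half) + 1L, 2)
  X <- mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))

  out <- array(NA_complex_, dim = c(nrow(x), length(params$freqs), np),
               dimnames = list(rec$labels, NULL, NULL))
  valid <- matrix(TRUE, length(params$freqs), np)
  for (k in seq_along(params$freqs)) {
    f <- params$freqs[k]
    s <- sig[k]
    h <- half[k]
    tt <- (-h:h) / fs
    kern <- (s^2 * pi)^(-1 / 4) * exp(-tt^2 / (2 * s^2)) * exp(2i * pi * f * tt) / fs
    kpad <- complex(length.out = nfft)
    kpad[1:(h + 1L)] <- kern[(h + 1L):(2L * h + 1L)]   # lags 0..h
    if (h > 0L) kpad[(nfft - h + 1L):nfft] <- kern[1:h] # lags -h..-1
    conv <- mvfft(X * fft(kpad), inverse = TRUE)[seq_len(n), , drop = FALSE] / nfft
    out[, k, ] <- t(conv[idx, , drop = FALSE])
    valid[k, ] <- idx > h & idx <= n - h
  }
  structure(out, freqs = params$freqs, fs_phase = fs / step,
            time_step = step, valid = valid, class = "morlet_coefficients")
}

#' Instantaneous phase from Morlet coefficients
#'
#' Element-wise complex argument wrapped to `(-pi, pi]`. Zero-magnitude
#' coefficients have no defined argument; they are emitted as phase 0 and
#' flagged in the `zero_coefficients` attribute.
#'
#' @param coeffs Output of [morlet_transform()].
#' @return A `phase_tensor`: numeric array channels x frequencies x grid points
#'   with attributes `freqs`, `fs_phase`, `valid`.
#' @export
instantaneous_phase <- function(coeffs) {
  if (any(!is.finite(coeffs))) stop("non-finite wavelet coefficients", call. = FALSE)
  ph <- Arg(coeffs)             # already in (-pi, pi]
  zero <- Mod(coeffs) == 0
  ph[zero] <- 0
  structure(array(ph, dim = dim(coeffs), dimnames = dimnames(coeffs)),
            freqs = attr(coeffs, "freqs"), fs_phase = attr(coeffs, "fs_phase"),
            valid = attr(coeffs, "valid"),
            zero_coefficients = any(zero),
            class = "phase_tensor")
}

#' Morlet phases of a recording in one call
#'
#' @inheritParams morlet_transform
#' @return A `phase_tensor`; see [instantaneous_phase()].
#' @export
extract_phases <- function(rec, params = morlet_params()) {
  instantaneous_phase(morlet_transform(rec, params))
}
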