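# n:m generalized phase differences, PSI, ternary in-phase coding with
# period-based cleaning, and windowed coupling indices (PCI/NCI/ACI/ICI).

#' Generalized n:m phase difference between two (channel, frequency) nodes
#'
#' `dphi(t) = n * phase_i(f_m, t) - m * phase_j(f_n, t)` wrapped to
#' `(-pi, pi]`, where `n * f_m == m * f_n`. For within-frequency coupling
#' (`f_m == f_n`) the ratio is 1:1.
#'
#' @param phases A `phase_tensor` from [extract_phases()].
#' @param pair List or vector `(channel_i, freq_i, channel_j, freq_j)`.
#' @param ratio Optional integer pair `c(n, m)`; derived from the frequencies
#'   when omitted. Must satisfy `n * freq_i == m * freq_j`.
#' @return A `phase_diff_series`: list with `values` (radians per grid point),
#'   `pair`, `ratio`, `fs_phase`, and a per-point `valid` flag.
#' @export
generalized_phase_difference <- function(phases, pair, ratio = NULL) {
  stopifnot(inherits(phases, "phase_tensor"))
  pair <- as.list(pair)
  names(pair) <- c("channel_i", "freq_i", "channel_j", "freq_j")
  freqs <- attr(phases, "freqs")
  fi <- as.numeric(pair$freq_i); fj <- as.numeric(pair$freq_j)
  ki <- which(abs(freqs - fi) < 1e-9)
  kj <- which(abs(freqs - fj) < 1e-9)
  if (length(ki) != 1L || length(kj) != 1L) {
    stop("pair frequencies must be on the analysis grid", call. = FALSE)
  }
  ci <- match(as.character(pair$channel_i), dimnames(phases)[[1L]])
  cj <- match(as.character(pair$channel_j), dimnames(phases)[[1L]])
  if (is.na(ci) || is.na(cj)) stop("unknown channel label", call. = FALSE)
  if (is.null(ratio)) {
    ratio <- nm_ratio(fi, fj)
  } else {
    ratio <- c(n = as.numeric(ratio[[1L]]), m = as.numeric(ratio[[2L]]))
    if (any(ratio < 1) || any(ratio != round(ratio)) ||
        abs(ratio[["n"]] * fi - ratio[["m"]] * fj) > 1e-9) {
      stop("`ratio` must be positive integers with n * freq_i == m * freq_j",
           call. = FALSE)
    }
  }
  v <- wrap_phase(ratio[["n"]] * phases[ci, ki, ] - ratio[["m"]] * phases[cj, kj, ])
  vmask <- attr(phases, "valid")
  structure(list(values = as.numeric(v), pair = pair, ratio = ratio,
                 fs_phase = attr(phases, "fs_phase"),
                 valid = vmask[ki, ] & vmask[kj, ]),
            class = "phase_diff_series")
}

#' Phase synchronization index
#'
#' Modulus of the time-averaged unit phasor `exp(1i * dphi)`: 1 for a
#' perfectly stable phase difference at any angle (including anti-phase),
#' near 0 for uniformly dispersed differences.
#'
#' @param diff A [generalized_phase_difference()] result (or numeric radians).
#' @param window Optional integer indices restricting the average.
#' @return PSI in `[0, 1]`.
#' @export
psi <- function(diff, window = NULL) {
  v <- if (inherits(diff, "phase_diff_series")) diff$values else as.numeric(diff)
  if (!is.null(window)) v <- v[window]
  if (length(v) == 0L) stop("empty window", call. = FALSE)
  Mod(mean(exp(1i * v)))
}

#' Ternary in-phase coding of a phase-difference series
#'
#' Codes each grid point `+1` if the wrapped difference lies in the open
#' interval `(0, pi/4)` (source leads), `-1` if in `(-pi/4, 0)` (source lags),
#' and `0` otherwise (non-synchronization). Boundary values (exactly 0 or
#' `+/- pi/4`) code 0.
#'
#' @param diff A [generalized_phase_difference()] result or numeric radians.
#' @param boundary Half-width of the in-phase range (radians).
#' @return A `ternary_code`: list with integer `codes`, `boundary`,
#'   `fs_phase`, and the pair frequencies used for cleaning defaults.
#' @export
ternary_code <- function(diff, boundary = pi / 4) {
  if (inherits(diff, "phase_diff_series")) {
    v <- diff$values
    fs_phase <- diff$fs_phase
    freqs <- c(diff$pair$freq_i, diff$pair$freq_j)
  } else {
    v <- as.numeric(diff)
    fs_phase <- NA_real_
    freqs <- NULL
  }
  codes <- (v > 0 & v < boundary) - (v > -boundary & v < 0)
  structure(list(codes = as.integer(codes), boundary = boundary,
                 fs_phase = fs_phase, freqs = freqs),
            class = "ternary_code")
}

clean_period_seconds <- function(freqs, policy = c("max", "min", "mean")) {
  policy <- match.arg(policy)
  periods <- 1 / freqs
  switch(policy, max = max(periods), min = min(periods), mean = mean(periods))
}

#' Remove accidental synchronization runs from a ternary code
#'
#' Every maximal run of consecutive nonzero codes whose duration is strictly
#' shorter than `period` seconds is recoded to 0; longer runs are unchanged.
#' This removes chance lock-ins shorter than one oscillation cycle.
#'
#' @param code A [ternary_code()] (or integer vector, then `fs_phase` is
#'   required).
#' @param period Minimum run duration in seconds; defaults to the longer
#'   period of the pair's two frequencies.
#' @param fs_phase Sampling rate of the code sequence in Hz.
#' @return A cleaned `ternary_code`.
#' @export
clean_code <- function(code, period = NULL, fs_phase = NULL) {
  if (!inherits(code, "ternary_code")) {
    if (is.null(fs_phase)) stop("`fs_phase` required for raw codes", call. = FALSE)
    code <- structure(list(codes = as.integer(code), boundary = pi / 4,
                           fs_phase = fs_phase, freqs = NULL),
                      class = "ternary_code")
  }
  fs_phase <- fs_phase %||% code$fs_phase
  if (is.null(period)) {
    if (is.null(code$freqs)) stop("`period` required when pair frequencies unknown",
                                  call. = FALSE)
    period <- clean_period_seconds(code$freqs)
  }
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  dt <- 1 / fs_phase
  if (period < dt) {
    warning("cleaning period shorter than one phase sample; no-op")
    return(code)
  }
  code$codes <- clean_codes_vec(code$codes, period, fs_phase)
  code
}

# run-length cleaning on a plain integer vector
clean_codes_vec <- function(codes, period, fs_phase) {
  r <- rle(codes != 0L)
  drop <- r$values & (r$lengths / fs_phase < period)
  if (any(drop)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(drop)) codes[starts[k]:ends[k]] <- 0L
  }
  codes
}

ici_formula <- function(pci, aci) {
  ifelse(aci > 0, ((pci + aci) / (2 * aci)) * pci, 0)
}

#' Windowed coupling indices from a ternary code
#'
#' `PCI`/`NCI` are the fractions of window points coded `+1` / `-1`; `ACI =
#' PCI + NCI`; the Integrative Coupling Index is `ICI = ((PCI + ACI) /
#' (2 ACI)) * PCI` (0 when `ACI = 0`). ICI is 1 when every point is locked in
#' the positive range and tends to 0 when all locked points are negative,
#' which is what makes it a directed measure.
#'
#' @param code A [ternary_code()] (cleaned or raw) or integer vector.
#' @param window Optional integer indices (default: whole sequence).
#' @return List with `pci`, `nci`, `aci`, `ici`.
#' @export
coupling_indices <- function(code, window = NULL) {
  v <- if (inherits(code, "ternary_code")) code$codes else as.integer(code)
  if (!is.null(window)) v <- v[window]
  if (length(v) == 0L) stop("empty window", call. = FALSE)
  pci <- mean(v == 1L)
  nci <- mean(v == -1L)
  aci <- pci + nci
  list(pci = pci, nci = nci, aci = aci, ici = ici_formula(pci, aci))
}

#' Sliding-window coupling indices for many node pairs
#'
#' For every (channel, frequency) pair the generalized phase difference is
#' computed on the phase grid, ternary-coded, cleaned on the full segment, and
#' summarized in every fully contained window of `window_ms` width advanced by
#' `step_ms` (defaults 2000/100 ms: 100-point windows stepped by 5 on the
#' 20-ms grid, i.e. 81 windows on a 10-s segment). Windows overlapping
#' edge-invalid grid points are kept but flagged in `$window_valid`.
#'
#' @param phases A `phase_tensor` from [extract_phases()].
#' @param pairs Data frame with columns `channel_i`, `freq_i`, `channel_j`,
#'   `freq_j` (one row per directed source -> destination pair; the reverse
#'   direction is returned alongside).
#' @param window_ms,step_ms Window width and step in milliseconds.
#' @param clean Apply run-length cleaning before windowing?
#' @param clean_period Period policy for cross-frequency pairs: longest
#'   (`"max"`, default), shortest, or mean of the two cycle lengths.
#' @return A `coupling_windows` object: `pairs` (with n:m ratios), matrices
#'   `psi`, `pci`, `nci`, `aci`, `ici`, `ici_rev` (pairs x windows),
#'   `window_onset_s`, `window_valid`, plus grid metadata.
#' @export
sliding_window_coupling <- function(phases, pairs, window_ms = 2000,
                                    step_ms = 100, clean = TRUE,
                                    clean_period = c("max", "min", "mean")) {
  stopifnot(inherits(phases, "phase_tensor"))
  clean_period <- match.arg(clean_period)
  pairs <- as.data.frame(pairs)
  need <- c("channel_i", "freq_i", "channel_j", "freq_j")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  fs_phase <- attr(phases, "fs_phase")
  freqs <- attr(phases, "freqs")
  labels <- dimnames(phases)[[1L]]
  C <- dim(phases)[1L]
  nt <- dim(phases)[3L]
  wlen <- as.integer(round(window_ms / 1000 * fs_phase))
  wstep <- as.integer(round(step_ms / 1000 * fs_phase))
  if (wlen > nt) stop("window longer than segment", call. = FALSE)
  if (wlen < 1L || wstep < 1L) stop("window/step too small for phase grid", call. = FALSE)
  nwin <- (nt - wlen) %/% wstep + 1L
  starts <- (seq_len(nwin) - 1L) * wstep + 1L

  fidx <- function(f) {
    k <- vapply(f, function(z) {
      w <- which(abs(freqs - z) < 1e-9)
      if (length(w) != 1L) NA_integer_ else w
    }, integer(1))
    if (anyNA(k)) stop("pair frequencies must be on the analysis grid", call. = FALSE)
    k
  }
  ki <- fidx(pairs$freq_i); kj <- fidx(pairs$freq_j)
  ci <- match(as.character(pairs$channel_i), labels)
  cj <- match(as.character(pairs$channel_j), labels)
  if (anyNA(ci) || anyNA(cj)) stop("unknown channel label in `pairs`", call. = FALSE)

  nm <- t(mapply(nm_ratio, pairs$freq_i, pairs$freq_j))
  pairs$n <- nm[, "n"]; pairs$m <- nm[, "m"]

  pm <- matrix(phases, nrow = C * length(freqs))  # row = ch + (freq - 1) * C
  ri <- ci + (ki - 1L) * C
  rj <- cj + (kj - 1L) * C
  dphi <- wrap_phase(pairs$n * pm[ri, , drop = FALSE] -
                     pairs$m * pm[rj, , drop = FALSE])

  cd <- (dphi > 0 & dphi < pi / 4) - (dphi > -pi / 4 & dphi < 0)
  if (clean) {
    periods <- vapply(seq_len(nrow(pairs)), function(p) {
      clean_period_seconds(c(pairs$freq_i[p], pairs$freq_j[p]), clean_period)
    }, numeric(1))
    for (p in seq_len(nrow(pairs))) {
      if (periods[p] >= 1 / fs_phase) {
        cd[p, ] <- clean_codes_vec(as.integer(cd[p, ]), periods[p], fs_phase)
      }
    }
  }

  # window sums via indicator matrix (grid points x windows)
  wind <- matrix(0, nt, nwin)
  for (w in seq_len(nwin)) wind[starts[w]:(starts[w] + wlen - 1L), w] <- 1
  pci <- ((cd == 1L) %*% wind) / wlen
  nci <- ((cd == -1L) %*% wind) / wlen
  aci <- pci + nci
  psi_m <- Mod(exp(1i * dphi) %*% wind) / wlen

  vmask <- attr(phases, "valid")
  pair_invalid <- (!vmask[ki, , drop = FALSE]) | (!vmask[kj, , drop = FALSE])
  window_valid <- (pair_invalid %*% wind) == 0

  structure(list(pairs = pairs,
                 psi = psi_m, pci = pci, nci = nci, aci = aci,
                 ici = ici_formula(pci, aci), ici_rev = ici_formula(nci, aci),
                 window_start_idx = starts,
                 window_onset_s = (starts - 1L) / fs_phase,
                 window_valid = window_valid,
                 n_windows = nwin, window_ms = window_ms, step_ms = step_ms,
                 fs_phase = fs_phase, cleaned = clean),
            class = "coupling_windows")
}

#' @export
print.coupling_windows <- function(x, ...) {
  cat(sprintf("<coupling_windows> %d pairs x %d windows (%g/%g ms)%s\n",
              nrow(x$pairs), x$n_windows, x$window_ms, x$step_ms,
              if (x$cleaned) ", cleaned" else ""))
  invisible(x)
}

#' Long-format coupling table
#'
#' One row per directed pair and window, both directions included
#' (the reverse direction swaps PCI and NCI and mirrors ICI).
#'
#' @param x A `coupling_windows` object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with window_index, src/dst channel and frequency, and
#'   the five indices.
#' @export
as.data.frame.coupling_windows <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  np <- nrow(x$pairs); nw <- x$n_windows
  fwd <- data.frame(
    window_index = rep(seq_len(nw), each = np),
    src_channel = rep(x$pairs$channel_i, nw), src_freq = rep(x$pairs$freq_i, nw),
    dst_channel = rep(x$pairs$channel_j, nw), dst_freq = rep(x$pairs$freq_j, nw),
    psi = as.vector(x$psi), pci = as.vector(x$pci), nci = as.vector(x$nci),
    aci = as.vector(x$aci), ici = as.vector(x$ici))
  rev <- data.frame(
    window_index = fwd$window_index,
    src_channel = fwd$dst_channel, src_freq = fwd$dst_freq,
    dst_channel = fwd$src_channel, dst_freq = fwd$src_freq,
    psi = fwd$psi, pci = fwd$nci, nci = fwd$pci,
    aci = fwd$aci, ici = as.vector(x$ici_rev))
  rbind(fwd, rev)
}
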