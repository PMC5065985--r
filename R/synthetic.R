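# Synthetic coupled-oscillator recordings and oddball-style event schedules.
# Everything is seeded so downstream stages are testable without external data.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate an oddball-style stimulus schedule
#'
#' Onset times are a cumulative sum of inter-stimulus intervals (ISIs) drawn
#' iid uniform on `isi_bounds`; stimulus classes are iid Bernoulli draws with
#' deviant probability `p_deviant`. The defaults mirror a classic auditory
#' oddball design: ISIs uniform on 1.2--1.5 s, 80% standards / 20% deviants.
#'
#' @param n_events Number of stimuli.
#' @param isi_bounds Length-2 numeric, lower/upper ISI bound in seconds.
#' @param p_deviant Probability that an event is a deviant.
#' @param seed Optional integer seed; fixed seed gives identical schedules.
#' @param t0 Onset of the first stimulus in seconds from segment start.
#' @return A `stimulus_schedule`: list with `onsets` (seconds, strictly
#'   increasing), `classes` (factor standard/deviant), `isi_bounds`, `n_events`.
#' @export
gen_stimulus_schedule <- function(n_events, isi_bounds = c(1.2, 1.5),
                                  p_deviant = 0.2, seed = NULL, t0 = 0) {
  stopifnot_scalar_count(n_events, "n_events")
  if (length(isi_bounds) != 2L || isi_bounds[1] > isi_bounds[2]) {
    stop("`isi_bounds` must be an ordered pair of seconds", call. = FALSE)
  }
  if (p_deviant < 0 || p_deviant > 1) stop("`p_deviant` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    isis <- runif(n_events - 1L, isi_bounds[1], isi_bounds[2])
    onsets <- t0 + cumsum(c(0, isis))
    classes <- ifelse(runif(n_events) < p_deviant, "deviant", "standard")
  })
  structure(
    list(onsets = onsets,
         classes = factor(classes, levels = c("standard", "deviant")),
         isi_bounds = as.numeric(isi_bounds),
         n_events = as.integer(n_events)),
    class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d events, %d deviant; onsets %.2f..%.2f s\n",
              x$n_events, sum(x$classes == "deviant"),
              min(x$onsets), max(x$onsets)))
  invisible(x)
}

#' Specify one oscillator on one channel
#'
#' An oscillator is a (possibly phase-diffusing) sinusoid; `coupled_to` slaves
#' its phase to a driver oscillator so that `n * phase(self) - m * phase(driver)
#' = lag` up to wrapped jitter, planting n:m phase coupling by construction.
#'
#' @param channel Channel label.
#' @param frequency Oscillation frequency in Hz (must be below Nyquist).
#' @param amplitude Peak amplitude (arbitrary units).
#' @param initial_phase Initial phase in radians.
#' @param coupled_to Optional list `(channel, frequency, n, m, lag, jitter)`
#'   naming the driver oscillator; `jitter` is the SD (radians) of smoothed
#'   wrapped-Gaussian noise on the lag -- the coupling-strength knob.
#' @param snr Ratio of oscillator power to additive Gaussian noise power;
#'   `Inf` = noiseless, `0` = the oscillator is replaced by noise of equal power.
#' @param phase_diffusion Phase random-walk rate in rad/sqrt(s) (0 = rigid).
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(channel, frequency, amplitude = 1,
                            initial_phase = 0, coupled_to = NULL,
                            snr = Inf, phase_diffusion = 0) {
  if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  if (snr < 0) stop("`snr` must be >= 0", call. = FALSE)
  if (!is.null(coupled_to)) {
    need <- c("channel", "frequency")
    if (!all(need %in% names(coupled_to))) {
      stop("`coupled_to` needs at least `channel` and `frequency`", call. = FALSE)
    }
    coupled_to$lag <- coupled_to$lag %||% 0
    coupled_to$jitter <- coupled_to$jitter %||% 0
    if (is.null(coupled_to$n) || is.null(coupled_to$m)) {
      nm <- nm_ratio(frequency, coupled_to$frequency)
      coupled_to$n <- nm[["n"]]
      coupled_to$m <- nm[["m"]]
    }
    if (coupled_to$n < 1 || coupled_to$m < 1 ||
        coupled_to$n != round(coupled_to$n) || coupled_to$m != round(coupled_to$m)) {
      stop("`n` and `m` must be positive integers", call. = FALSE)
    }
  }
  structure(list(channel = as.character(channel), frequency = frequency,
                 amplitude = amplitude, initial_phase = initial_phase,
                 coupled_to = coupled_to, snr = snr,
                 phase_diffusion = phase_diffusion),
            class = "oscillator_spec")
}

#' Construct a segmented multichannel recording
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param labels Unique channel labels (default rownames or Ch1..ChN).
#' @param schedule Optional [gen_stimulus_schedule()] result.
#' @return A `segmented_recording` with fields `data`, `fs`, `labels`,
#'   `duration`, `schedule`.
#' @export
segmented_recording <- function(data, fs, labels = NULL, schedule = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  labels <- labels %||% rownames(data) %||% paste0("Ch", seq_len(nrow(data)))
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != nrow(data)) stop("one label per channel required", call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 duration = ncol(data) / fs, schedule = schedule),
            class = "segmented_recording")
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat(sprintf("<segmented_recording> %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$duration,
              if (!is.null(x$schedule)) sprintf(", %d events", x$schedule$n_events) else ""))
  invisible(x)
}

# AR(1)-smoothed Gaussian noise with stationary SD `sd` and time constant
# `tau` seconds; slow enough to survive wavelet filtering.
smoothed_noise <- function(n, sd, fs, tau = 0.05) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-1 / (fs * tau))
  w <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(w, rho, method = "recursive")) +
    rnorm(1, 0, sd) * rho^(seq_len(n))
}

#' Generate a recording from coupled-oscillator specifications
#'
#' Each channel is the sum of its oscillators plus additive white Gaussian
#' noise at the per-oscillator SNR. An oscillator with `coupled_to = (B, f, n,
#' m, lag, jitter)` has its phase set to `(m * phase_B + lag + eps) / n`, so
#' the generalized phase difference `n * phase_self - m * phase_B` equals
#' `lag + eps` with `eps` the wrapped jitter noise.
#'
#' @param specs List of [oscillator_spec()] objects.
#' @param fs Sampling rate in Hz.
#' @param duration Segment duration in seconds.
#' @param seed Optional integer seed.
#' @param schedule Optional schedule to attach to the recording.
#' @return A [segmented_recording()].
#' @export
gen_coupled_oscillators <- function(specs, fs = 250, duration = 10,
                                    seed = NULL, schedule = NULL) {
  if (inherits(specs, "oscillator_spec")) specs <- list(specs)
  freqs <- vapply(specs, `[[`, numeric(1), "frequency")
  if (any(freqs >= fs / 2)) {
    stop("oscillator frequency at or above Nyquist (fs/2)", call. = FALSE)
  }
  ns <- round(fs * duration)
  tt <- (seq_len(ns) - 1) / fs
  channels <- unique(vapply(specs, `[[`, character(1), "channel"))

  with_seed(seed, {
    # resolve phases in dependency order (driver before slave)
    key <- function(ch, f) paste(ch, format(f), sep = "@")
    keys <- vapply(specs, function(s) key(s$channel, s$frequency), character(1))
    phases <- vector("list", length(specs))
    names(phases) <- keys
    done <- rep(FALSE, length(specs))
    for (pass in seq_len(length(specs) + 1L)) {
      for (i in seq_along(specs)) {
        if (done[i]) next
        s <- specs[[i]]
        if (is.null(s$coupled_to)) {
          drift <- if (s$phase_diffusion > 0) {
            cumsum(rnorm(ns, 0, s$phase_diffusion / sqrt(fs)))
          } else 0
          phases[[i]] <- 2 * pi * s$frequency * tt + s$initial_phase + drift
          done[i] <- TRUE
        } else {
          dk <- key(s$coupled_to$channel, s$coupled_to$frequency)
          j <- match(dk, keys)
          if (is.na(j)) stop("driver oscillator not found: ", dk, call. = FALSE)
          if (!done[j]) next
          eps <- smoothed_noise(ns, s$coupled_to$jitter, fs)
          phases[[i]] <- (s$coupled_to$m * phases[[j]] + s$coupled_to$lag + eps) /
            s$coupled_to$n
          done[i] <- TRUE
        }
      }
      if (all(done)) break
    }
    if (!all(done)) stop("circular `coupled_to` dependencies", call. = FALSE)

    data <- matrix(0, nrow = length(channels), ncol = ns,
                   dimnames = list(channels, NULL))
    noise_var <- stats::setNames(numeric(length(channels)), channels)
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      p_osc <- s$amplitude^2 / 2
      if (s$snr > 0) {
        data[s$channel, ] <- data[s$channel, ] + s$amplitude * cos(phases[[i]])
        if (is.finite(s$snr)) noise_var[s$channel] <- noise_var[s$channel] + p_osc / s$snr
      } else {
        noise_var[s$channel] <- noise_var[s$channel] + p_osc
      }
    }
    for (ch in channels) {
      if (noise_var[ch] > 0) data[ch, ] <- data[ch, ] + rnorm(ns, 0, sqrt(noise_var[ch]))
    }
  })
  segmented_recording(data, fs, channels, schedule = schedule)
}

#' Generate an event-modulated recording with class-specific coupling
#'
#' Plants stimulus-related network dynamics: the segment is divided into ISIs
#' by the schedule onsets (the last ISI extends to the segment end), non-
#' reference channels are assigned round-robin to ISI classes, and a channel
#' phase-locks to the reference channel (lag near `pi/8`, the center of the
#' positive in-phase range) only while its own ISI class is active.
#'
#' Outside its active ISI a channel free-runs at a channel-specific frequency
#' detuning (`detune_step * channel_rank` Hz above the reference), so every
#' pairwise phase difference sweeps linearly through the circle: its in-phase
#' duty cycle is a deterministic value below the 0.26 connectivity threshold
#' in every window, which is what makes the `effect_size = 0` null carry no
#' decodable class (or time) structure. `effect_size` scales the phase-lag
#' dynamics inside the active ISI: the detuning drift and jitter are
#' multiplied by `1 - effect_size` and the wrapped lag error is pulled to zero
#' at rate `effect_size * lock_rate`, so `effect_size = 1` gives rigid locking
#' and intermediate values progressively noisier lags.
#'
#' @param schedule A [gen_stimulus_schedule()] result; must fit in `duration`.
#' @param base List of [oscillator_spec()]s, one per channel; the first is the
#'   reference/driver channel and sets the carrier frequency.
#' @param effect_size Coupling boost in `[0, 1]`.
#' @param fs,duration Sampling rate (Hz) and segment length (s).
#' @param seed Optional integer seed.
#' @param lag Planted phase lag in radians (driver leads); alternate channels
#'   use `lag +/- lag/2` so co-active channels are mutually offset.
#' @param detune_step Detuning increment in Hz; channel rank r is detuned by
#'   `detune_step * ceiling(r/2) * (-1)^r`, so all pairwise relative detunings
#'   are at least `detune_step` while the detunings themselves stay within
#'   `+/- detune_step * n/2` of the carrier. Keeping the minimum relative
#'   detuning at or above ~0.45 Hz bounds the free-running in-phase duty
#'   cycle of a 2-s window safely below the 0.26 threshold.
#' @param jitter Phase random-walk rate in rad/sqrt(s) added to the
#'   free-running drift.
#' @param lock_rate Exponential pull-in rate (1/s) of the lag error during the
#'   active ISI at `effect_size = 1`.
#' @return A [segmented_recording()] with the schedule attached.
#' @export
gen_event_modulated_recording <- function(schedule, base, effect_size,
                                          fs = 250, duration = 10, seed = NULL,
                                          lag = pi / 8, detune_step = 0.45,
                                          jitter = 0.15, lock_rate = 40) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (effect_size < 0 || effect_size > 1) {
    stop("`effect_size` must be in [0, 1]", call. = FALSE)
  }
  if (max(schedule$onsets) >= duration) {
    stop("schedule extends beyond segment duration", call. = FALSE)
  }
  if (length(base) < 2L) stop("need a reference channel plus >= 1 target", call. = FALSE)
  freqs <- vapply(base, `[[`, numeric(1), "frequency")
  if (any(freqs >= fs / 2)) stop("oscillator frequency at or above Nyquist (fs/2)",
                                 call. = FALSE)
  ns <- round(fs * duration)
  dt <- 1 / fs
  tt <- (seq_len(ns) - 1) * dt
  K <- schedule$n_events
  isi_of_t <- pmin(pmax(findInterval(tt, schedule$onsets), 1L), K)

  ref <- base[[1L]]
  channels <- vapply(base, `[[`, character(1), "channel")
  if (anyDuplicated(channels)) stop("one oscillator per channel expected", call. = FALSE)

  with_seed(seed, {
    phi_ref <- 2 * pi * ref$frequency * tt + ref$initial_phase
    data <- matrix(0, nrow = length(base), ncol = ns,
                   dimnames = list(channels, NULL))
    data[1L, ] <- ref$amplitude * cos(phi_ref)
    nv <- numeric(length(base))
    if (is.finite(ref$snr) && ref$snr > 0) nv[1L] <- ref$amplitude^2 / 2 / ref$snr
    for (ci in seq_along(base)[-1L]) {
      s <- base[[ci]]
      rank <- ci - 1L
      klass <- ((ci - 2L) %% K) + 1L
      lag_c <- lag + (if (rank %% 2L == 0L) lag / 2 else -lag / 2)
      detune <- detune_step * ceiling(rank / 2) * (-1)^rank
      drift_rate <- 2 * pi * detune * dt
      noise <- rnorm(ns, 0, jitter * sqrt(dt))
      free <- 1 - effect_size * (isi_of_t == klass)
      pull <- effect_size * lock_rate * dt * (isi_of_t == klass)
      # lag error: drifts/jitters while free, pulled (mod 2pi) to 0 when locked
      eps <- numeric(ns)
      e <- runif(1, -pi, pi)
      for (k in seq_len(ns)) {
        e <- e + (drift_rate + noise[k]) * free[k] - pull[k] * wrap_phase(e)
        eps[k] <- e
      }
      phi <- phi_ref - lag_c + eps       # dphi(ref -> c) = lag_c - eps
      data[ci, ] <- s$amplitude * cos(phi)
      if (is.finite(s$snr) && s$snr > 0) nv[ci] <- s$amplitude^2 / 2 / s$snr
    }
    for (ci in seq_along(base)) {
      if (nv[ci] > 0) data[ci, ] <- data[ci, ] + rnorm(ns, 0, sqrt(nv[ci]))
    }
  })
  segmented_recording(data, fs, channels, schedule = schedule)
}

#' Write / read a recording as delimited text plus JSON sidecar
#'
#' The matrix is stored samples x channels with a header row of channel labels;
#' the sidecar (`<file>.json`) records the sampling rate. A schedule, when
#' present, is stored as two-column TSV `<file>.events.tsv` (onset_s, class).
#'
#' @param rec A [segmented_recording()].
#' @param file Path of the TSV to write (sidecars are derived from it).
#' @return `write_recording` returns `file` invisibly; `read_recording`
#'   returns a [segmented_recording()].
#' @export
write_recording <- function(rec, file) {
  stopifnot(inherits(rec, "segmented_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$labels
  write.table(m, file, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, n_channels = length(rec$labels),
                            duration = rec$duration),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(rec$schedule)) {
    write.table(data.frame(onset_s = rec$schedule$onsets,
                           class = as.character(rec$schedule$classes)),
                paste0(file, ".events.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_recording
#' @export
read_recording <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(file, sep = "\t", header = TRUE, check.names = FALSE))
  sched <- NULL
  ev_file <- paste0(file, ".events.tsv")
  if (file.exists(ev_file)) {
    ev <- read.table(ev_file, sep = "\t", header = TRUE)
    sched <- structure(list(onsets = ev$onset_s,
                            classes = factor(ev$class, levels = c("standard", "deviant")),
                            isi_bounds = range(diff(ev$onset_s)),
                            n_events = nrow(ev)),
                       class = "stimulus_schedule")
  }
  segmented_recording(t(m), fs = side$fs, labels = colnames(m), schedule = sched)
}
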