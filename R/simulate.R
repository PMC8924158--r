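# Synthetic multichannel EEG with the statistical structure the analysis
# pipeline assumes: a steady-state syllable-rate response, a word-rate
# component that ramps in with structured-stream exposure (the learning
# curve), condition-dependent test-word ERPs, spatially mixed 1/f
# background, white sensor noise, and occasional high-amplitude artifacts.
#
# All randomness derives from `config$seed` through fixed per-component
# child seeds, so zeroing one component's amplitude never changes another
# component's draws: the simulation is exactly linear in its components.

#' Simulation configuration
#'
#' Defaults describe a plausible neonatal frequency-tagging session:
#' syllable-evoked responses of a few microvolts, a weaker word-rate
#' component that becomes effective after about two minutes of structured
#' exposure, an early (0-0.4 s) ERP component larger for ABx than BCx test
#' words, pink background plus white sensor noise, and about one
#' high-amplitude artifact per minute.
#'
#' @param sampling_rate Hz (default 250).
#' @param syllable_response Kernel of the per-syllable evoked response:
#'   `amplitude` (uV), damped-sinusoid `freq` (Hz), `decay` (s, time
#'   constant), `duration` (s), `latency` (s).
#' @param word_rate_amplitude uV; amplitude of the kernel locked to word
#'   onsets inside structured streams (0 disables the component).
#' @param learning_onset_s Cumulative structured-stream exposure (s) at
#'   which the word-rate component reaches half amplitude (default 120).
#' @param learning_width_s Width of the sigmoidal ramp (s).
#' @param erp_effect Early test-word component: `amplitude_abx` and
#'   `amplitude_bcx` (uV) over `window` (s, relative to test-word onset),
#'   plus an optional late component `late_amplitude_abx/_bcx` over
#'   `late_window`.
#' @param noise `pink_scale` (uV SD per source), `exponent` (1/f^a slope),
#'   `n_sources`, `white_scale` (uV SD per channel).
#' @param artifact `rate_per_min` Poisson rate and `amplitude` (uV) of
#'   boxcar/spike excursions.
#' @param seed Master integer seed (noise, artifacts).
#' @param topo_seed Seed for the stimulus-locked component topographies.
#'   Held fixed across a cohort's subjects (default 1) so that evoked
#'   topographies are consistent at the group level, while `seed` varies
#'   the background noise per subject.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sampling_rate = 250,
                              syllable_response = list(amplitude = 4,
                                                       freq = 6,
                                                       decay = 0.06,
                                                       duration = 0.4,
                                                       latency = 0.04),
                              word_rate_amplitude = 2,
                              learning_onset_s = 120,
                              learning_width_s = 20,
                              erp_effect = list(amplitude_abx = 2,
                                                amplitude_bcx = 0,
                                                window = c(0, 0.4),
                                                late_amplitude_abx = 0,
                                                late_amplitude_bcx = 0,
                                                late_window = c(0.8, 1.6)),
                              noise = list(pink_scale = 3,
                                           exponent = 1,
                                           n_sources = 8,
                                           white_scale = 1),
                              artifact = list(rate_per_min = 1,
                                              amplitude = 500),
                              seed = 0L, topo_seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate,
              syllable_response = syllable_response,
              word_rate_amplitude = word_rate_amplitude,
              learning_onset_s = learning_onset_s,
              learning_width_s = learning_width_s,
              erp_effect = erp_effect,
              noise = noise, artifact = artifact, seed = as.integer(seed),
              topo_seed = as.integer(topo_seed))
  amps <- c(syllable_response$amplitude, word_rate_amplitude,
            erp_effect$amplitude_abx, erp_effect$amplitude_bcx,
            erp_effect$late_amplitude_abx, erp_effect$late_amplitude_bcx,
            noise$pink_scale, noise$white_scale, artifact$amplitude)
  if (any(amps < 0)) stopf("all amplitudes must be >= 0")
  if (learning_onset_s < 0) stopf("learning_onset_s must be >= 0")
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  structure(cfg, class = "simulation_config")
}

# Damped sinusoid evoked kernel sampled at `rate`.
.evoked_kernel <- function(rate, amplitude, freq, decay, duration,
                           latency = 0) {
  t <- seq(0, duration, by = 1 / rate)
  u <- t - latency
  k <- ifelse(u >= 0, sin(2 * pi * freq * u) * exp(-u / decay), 0)
  amplitude * k
}

# Raised-cosine bump spanning `window` (s), used for ERP components.
.bump_kernel <- function(rate, amplitude, window) {
  len <- window[2] - window[1]
  t <- seq(0, len, by = 1 / rate)
  pre <- numeric(max(0L, round(window[1] * rate)))
  c(pre, amplitude * 0.5 * (1 - cos(2 * pi * t / len)))
}

# Dipolar channel topography: projection of electrode positions onto a
# random unit vector, normalized to unit maximum absolute weight.
.dipolar_topography <- function(montage, seed) {
  u <- with_seed(seed, stats::rnorm(3))
  u <- u / sqrt(sum(u^2))
  w <- drop(montage$positions %*% u) / montage$head_radius
  w / max(abs(w))
}

#' 1/f^a Gaussian noise
#'
#' Spectrally shaped Gaussian noise with power spectral density
#' proportional to f^-exponent, unit standard deviation.
#'
#' @param n Number of samples.
#' @param rate Sampling rate (Hz).
#' @param exponent Spectral exponent a.
#' @return Numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, rate, exponent) {
  m <- fast_len(n)                     # pad to an FFT-friendly length
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * rate / m
  shape <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

# Add kernel responses at event samples (impulse-train convolution by
# zero-padded FFT).
.impulse_response <- function(n, samples, amplitudes, kernel) {
  m <- fast_len(n + length(kernel))
  src <- numeric(m)
  keep <- samples >= 1L & samples <= n
  for (j in which(keep)) {
    src[samples[j]] <- src[samples[j]] + amplitudes[j]
  }
  K <- stats::fft(c(kernel, numeric(m - length(kernel))))
  out <- Re(stats::fft(stats::fft(src) * K, inverse = TRUE)) / m
  out[seq_len(n)]
}

#' Simulate a multichannel EEG recording for a session
#'
#' Builds the recording as a sum of deterministic stimulus-locked
#' components and stochastic background terms (see the package vignette
#' for the signal model). Deterministic given `config$seed`.
#'
#' @param schedule A [build_session_schedule()] object.
#' @param montage A [make_montage()] object.
#' @param config A [simulation_config()].
#' @param keep_components Keep the per-component channel-by-sample
#'   matrices in the result (memory-heavy; for testing).
#' @return An `eeg_recording`: `data` (channels x samples matrix, uV),
#'   `rate`, `events` (schedule events with `sample` column), `segments`,
#'   `montage`, `config`, and optionally `components`.
#' @export
simulate_recording <- function(schedule, montage, config = simulation_config(),
                               keep_components = FALSE) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(montage, "montage"),
            inherits(config, "simulation_config"))
  rate <- config$sampling_rate
  n <- as.integer(ceiling(schedule$total_duration * rate))
  n_ch <- length(montage$channels)
  ev <- schedule$events
  ev$sample <- as.integer(round(ev$onset_s * rate)) + 1L
  seed <- config$seed
  comp <- list()

  # (a) syllable-evoked response at every syllable onset (streams + tests)
  sr <- config$syllable_response
  if (sr$amplitude > 0) {
    kern <- .evoked_kernel(rate, sr$amplitude, sr$freq, sr$decay,
                           sr$duration, sr$latency)
    src <- .impulse_response(n, ev$sample, rep(1, nrow(ev)), kern)
    topo <- .dipolar_topography(montage, derive_seed(config$topo_seed, 11L))
    comp$syllable <- outer(topo, src)
  }

  # (b) word-rate component: word onsets inside structured streams, gated
  # by a sigmoid in cumulative structured exposure
  if (config$word_rate_amplitude > 0) {
    won <- ev[ev$segment_kind == "StructuredStream" & ev$position == 1L, ]
    segs <- schedule$segments
    str_segs <- segs[segs$kind == "StructuredStream", , drop = FALSE]
    cum_before <- c(0, cumsum(str_segs$duration))[seq_len(nrow(str_segs))]
    seg_of <- findInterval(won$onset_s, str_segs$start)
    exposure <- cum_before[seg_of] + (won$onset_s - str_segs$start[seg_of])
    gate <- 1 / (1 + exp(-(exposure - config$learning_onset_s) /
                           config$learning_width_s))
    kern <- .evoked_kernel(rate, config$word_rate_amplitude, freq = 2,
                           decay = 0.15, duration = 0.6, latency = 0.08)
    src <- .impulse_response(n, won$sample, gate, kern)
    topo <- .dipolar_topography(montage, derive_seed(config$topo_seed, 12L))
    comp$word_rate <- outer(topo, src)
  }

  # (c) condition-dependent test-word ERP components
  ef <- config$erp_effect
  te <- ev[ev$segment_kind == "TestBlock" & ev$position == 1L, ]
  if (nrow(te) && (ef$amplitude_abx > 0 || ef$amplitude_bcx > 0 ||
                   ef$late_amplitude_abx > 0 || ef$late_amplitude_bcx > 0)) {
    abx <- te$condition %in% c("Word", "EdgeWord")
    topo <- .dipolar_topography(montage, derive_seed(config$topo_seed, 13L))
    src <- numeric(n)
    if (ef$amplitude_abx > 0 || ef$amplitude_bcx > 0) {
      kern <- .bump_kernel(rate, 1, ef$window)
      amp <- ifelse(abx, ef$amplitude_abx, ef$amplitude_bcx)
      src <- src + .impulse_response(n, te$sample, amp, kern)
    }
    if (ef$late_amplitude_abx > 0 || ef$late_amplitude_bcx > 0) {
      kern <- .bump_kernel(rate, 1, ef$late_window)
      amp <- ifelse(abx, ef$late_amplitude_abx, ef$late_amplitude_bcx)
      src <- src + .impulse_response(n, te$sample, amp, kern)
    }
    comp$erp <- outer(topo, src)
  }

  # (d) 1/f background: independent sources mixed by dipolar topographies
  if (config$noise$pink_scale > 0) {
    ns <- config$noise$n_sources
    pink <- matrix(0, n_ch, n)
    for (s in seq_len(ns)) {
      topo <- .dipolar_topography(montage, derive_seed(seed, 100L + s))
      srcn <- with_seed(derive_seed(seed, 200L + s),
                        one_over_f_noise(n, rate, config$noise$exponent))
      pink <- pink + outer(topo, config$noise$pink_scale * srcn)
    }
    comp$pink <- pink
  }

  # (e) white sensor noise, independent per channel
  if (config$noise$white_scale > 0) {
    comp$white <- with_seed(derive_seed(seed, 30L),
                            matrix(stats::rnorm(n_ch * n,
                                                sd = config$noise$white_scale),
                                   n_ch, n))
  }

  # (f) artifact excursions at Poisson times: half the events are boxcar
  # steps (~0.5 s), half single-sample-group spikes, on a random subset of
  # channels
  if (config$artifact$rate_per_min > 0 && config$artifact$amplitude > 0) {
    comp$artifact <- with_seed(derive_seed(seed, 40L), {
      art <- matrix(0, n_ch, n)
      n_art <- stats::rpois(1, config$artifact$rate_per_min *
                              schedule$total_duration / 60)
      if (n_art > 0) {
        for (a in seq_len(n_art)) {
          t0 <- sample.int(n, 1L)
          chans <- sample.int(n_ch, max(1L, round(n_ch * 0.3)))
          amp <- config$artifact$amplitude * sample(c(-1, 1), 1L)
          if (stats::runif(1) < 0.5) {
            len <- round(0.5 * rate)
          } else {
            len <- round(0.04 * rate)
          }
          idx <- t0:min(n, t0 + len - 1L)
          art[chans, idx] <- art[chans, idx] + amp
        }
      }
      art
    })
  }

  data <- matrix(0, n_ch, n)
  for (cm in comp) data <- data + cm
  rownames(data) <- montage$channels
  structure(list(data = data, rate = rate, events = ev,
                 segments = schedule$segments, montage = montage,
                 config = config,
                 components = if (keep_components) comp else NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}
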