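# Shared preprocessing: zero-phase filtering, FFT resampling, epoching,
# artifact rejection, referencing, normalization, baseline correction.
#
# Filtering is performed in the frequency domain: the spectrum is
# multiplied by a zero-phase Butterworth-magnitude response. At the
# default order 12 the attenuation one octave outside the band is about
# 6 * order ~ 72 dB (>= the 20 dB contract), a 50 Hz tone outside a
# 0.1-40 Hz band keeps < 10% of its RMS, phase lag is exactly zero, and
# DC is removed. Resampling is FFT-based (band-limited sinc
# interpolation), hence inherently anti-aliased.

.butter_magnitude <- function(f, low = NULL, high = NULL, order = 12) {
  h <- rep(1, length(f))
  if (!is.null(high)) h <- h / sqrt(1 + (f / high)^(2 * order))
  if (!is.null(low)) {
    hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (low / pmax(f, 1e-300))^(2 * order)))
    h <- h * hp
  }
  h
}

.fft_filter <- function(data, rate, low = NULL, high = NULL, order = 12) {
  n <- ncol(data)
  m <- fast_len(n)                     # zero-pad to an FFT-friendly length
  f <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * rate / m
  h <- .butter_magnitude(f, low, high, order)
  pad <- cbind(data, matrix(0, nrow(data), m - n))
  X <- stats::mvfft(t(pad))
  out <- t(Re(stats::mvfft(X * h, inverse = TRUE)) / m)
  out <- out[, seq_len(n), drop = FALSE]
  rownames(out) <- rownames(data)
  out
}

#' Zero-phase band-pass filter
#'
#' @param recording An `eeg_recording`.
#' @param low,high Band edges in Hz (`0 < low < high < rate/2`).
#' @param order Butterworth-magnitude order (default 12, ~72 dB one
#'   octave out).
#' @return The filtered recording; a `filter` entry is appended to its
#'   processing log.
#' @export
bandpass <- function(recording, low, high, order = 12) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low >= high ||
      high >= recording$rate / 2) {
    stopf("invalid band [%s, %s] for rate %g Hz", low, high, recording$rate)
  }
  recording$data <- .fft_filter(recording$data, recording$rate, low, high,
                                order)
  recording$log <- c(recording$log,
                     sprintf("bandpass %g-%g Hz (order %d)", low, high, order))
  recording
}

#' Zero-phase high-pass filter
#'
#' @inheritParams bandpass
#' @param low Cutoff in Hz.
#' @export
highpass <- function(recording, low, order = 12) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.numeric(low) || low <= 0 || low >= recording$rate / 2) {
    stopf("invalid high-pass cutoff %s for rate %g Hz", low, recording$rate)
  }
  recording$data <- .fft_filter(recording$data, recording$rate, low = low,
                                order = order)
  recording$log <- c(recording$log,
                     sprintf("highpass %g Hz (order %d)", low, order))
  recording
}

# FFT (band-limited) resampling of the columns-of-t(data) to m samples.
.fft_resample_core <- function(data, m) {
  n <- ncol(data)
  if (m == n) return(data)
  X <- stats::mvfft(t(data))                 # n x ch
  Y <- matrix(0 + 0i, m, ncol(X))
  nh <- min(n, m) %/% 2
  Y[seq_len(nh + 1L), ] <- X[seq_len(nh + 1L), ]
  if (nh >= 1) {
    Y[(m - nh + 2L):m, ] <- X[(n - nh + 2L):n, ]
  }
  if (min(n, m) %% 2 == 0) {
    # split/merge the shared Nyquist coefficient to keep symmetry
    if (m > n) {
      Y[nh + 1L, ] <- X[nh + 1L, ] / 2
      Y[m - nh + 1L, ] <- X[nh + 1L, ] / 2
    } else {
      Y[nh + 1L, ] <- X[nh + 1L, ] + X[n - nh + 1L, ]
    }
  }
  t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
}

# Rational-rate resampling with zero padding to a fast FFT length that
# keeps the new length integral: pad to a multiple of the reduced-ratio
# denominator, resample the padded block, trim to round(n * p / q).
.fft_resample_mat <- function(data, new_rate, old_rate) {
  n <- ncol(data)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  # reduce the ratio over a common grid (rates may be non-integer)
  sc <- 1e6
  p <- round(new_rate * sc); q <- round(old_rate * sc)
  d <- g(p, q); p <- p / d; q <- q / d
  L <- fast_len(n, mult = q)
  M <- as.integer(L * p / q)
  pad <- cbind(data, matrix(0, nrow(data), L - n))
  out <- .fft_resample_core(pad, M)
  out <- out[, seq_len(as.integer(round(n * p / q))), drop = FALSE]
  rownames(out) <- rownames(data)
  out
}

#' Resample a recording
#'
#' Band-limited FFT resampling; event sample indices are recomputed from
#' their onsets in seconds. Resampling 250 -> 300 Hz gives an integer 225
#' samples per 0.75 s triplet.
#'
#' @param recording An `eeg_recording`.
#' @param new_rate Target rate in Hz.
#' @return The resampled recording.
#' @export
resample <- function(recording, new_rate) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.numeric(new_rate) || new_rate <= 0) stopf("new_rate must be > 0")
  if (new_rate == recording$rate) return(recording)
  recording$data <- .fft_resample_mat(recording$data, new_rate,
                                      recording$rate)
  recording$rate <- new_rate
  if (!is.null(recording$events)) {
    recording$events$sample <-
      as.integer(round(recording$events$onset_s * new_rate)) + 1L
  }
  recording$log <- c(recording$log, sprintf("resample to %g Hz", new_rate))
  recording
}

#' Cut a recording into fixed-length epochs
#'
#' Each epoch spans `[onset + tmin, onset + tmax)`. Epochs exceeding the
#' data bounds are dropped with a warning.
#'
#' @param recording An `eeg_recording`.
#' @param onsets Onsets in seconds (recording time).
#' @param tmin,tmax Epoch window relative to onset (s), `tmin < tmax`.
#' @param metadata Optional data frame (one row per onset) carried along.
#' @return An `epoch_set`: `data` (epochs x channels x samples), `rate`,
#'   `tmin`, `onsets`, `metadata`, `channels`.
#' @export
epoch <- function(recording, onsets, tmin, tmax, metadata = NULL) {
  stopifnot(inherits(recording, "eeg_recording"), tmin < tmax)
  n <- ncol(recording$data)
  rate <- recording$rate
  n_samp <- as.integer(round((tmax - tmin) * rate))
  starts <- as.integer(round((onsets + tmin) * rate)) + 1L
  ok <- starts >= 1L & (starts + n_samp - 1L) <= n
  if (!all(ok)) {
    warning(sprintf("%d epoch(s) exceed data bounds and were dropped",
                    sum(!ok)), call. = FALSE)
  }
  if (!any(ok)) stopf("no valid epochs")
  starts <- starts[ok]
  arr <- array(0, dim = c(length(starts), nrow(recording$data), n_samp))
  for (e in seq_along(starts)) {
    arr[e, , ] <- recording$data[, starts[e]:(starts[e] + n_samp - 1L)]
  }
  md <- if (is.null(metadata)) {
    data.frame(onset_s = onsets[ok])
  } else {
    cbind(data.frame(onset_s = onsets[ok]),
          metadata[ok, , drop = FALSE])
  }
  rownames(md) <- NULL
  structure(list(data = arr, rate = rate, tmin = tmin,
                 onsets = onsets[ok], metadata = md,
                 channels = rownames(recording$data),
                 log = c(recording$log,
                         sprintf("epoch [%g, %g] s, %d epochs",
                                 tmin, tmax, length(starts)))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Epoch times relative to onset
#'
#' @param epochs An `epoch_set`.
#' @return Numeric vector of per-sample times (s).
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$rate
}

.subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$onsets <- epochs$onsets[keep]
  epochs$metadata <- epochs$metadata[keep, , drop = FALSE]
  rownames(epochs$metadata) <- NULL
  epochs
}

#' Peak-to-peak artifact rejection
#'
#' An epoch is removed iff any channel's peak-to-peak amplitude exceeds
#' the threshold. A stand-in for full artifact-correction pipelines,
#' sufficient because the simulator's artifacts are controlled.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Peak-to-peak threshold in uV (default 400).
#' @return The pruned `epoch_set`; `rejected` holds the logical mask,
#'   `retention` the retained fraction. Order is preserved.
#' @export
reject_epochs <- function(epochs, threshold = 400) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("threshold must be > 0")
  }
  p2p <- apply(epochs$data, c(1L, 2L), function(v) max(v) - min(v))
  bad <- apply(p2p > threshold, 1L, any)
  if (all(bad)) {
    stopf(paste0("all %d epochs exceed the %g uV threshold; ",
                 "consider raising it"), length(bad), threshold)
  }
  out <- .subset_epochs(epochs, !bad)
  out$rejected <- bad
  out$retention <- mean(!bad)
  out$log <- c(epochs$log,
               sprintf("reject p2p > %g uV: kept %d/%d (%.0f%%)",
                       threshold, sum(!bad), length(bad),
                       100 * mean(!bad)))
  out
}

#' Average reference
#'
#' Subtracts the across-channel mean at every sample of every epoch.
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  for (e in seq_len(d[1])) {
    x <- epochs$data[e, , ]
    epochs$data[e, , ] <- sweep(x, 2L, colMeans(x))
  }
  epochs$log <- c(epochs$log, "average reference")
  epochs
}

#' Per-epoch normalization
#'
#' Divides each epoch by its standard deviation pooled over channels and
#' samples (one scalar per epoch), preserving topography shape.
#'
#' @param epochs An `epoch_set`.
#' @return The normalized `epoch_set`.
#' @export
normalize_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  for (e in seq_len(d[1])) {
    s <- stats::sd(as.vector(epochs$data[e, , ]))
    if (!is.finite(s) || s == 0) stopf("epoch %d has zero variance", e)
    epochs$data[e, , ] <- epochs$data[e, , ] / s
  }
  epochs$log <- c(epochs$log, "normalize (pooled SD = 1)")
  epochs
}

#' Baseline correction
#'
#' Subtracts, per channel, the mean over a baseline window. `window` may
#' be a single `c(start, end)` (s, epoch time) or an epochs x 2 matrix of
#' per-epoch windows.
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window(s) in epoch time (s).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  tt <- epoch_times(epochs)
  if (is.null(dim(window))) {
    window <- matrix(rep(window, each = d[1]), ncol = 2L)
  }
  for (e in seq_len(d[1])) {
    sel <- tt >= window[e, 1] & tt <= window[e, 2]
    if (!any(sel)) stopf("baseline window of epoch %d is empty", e)
    x <- epochs$data[e, , ]
    epochs$data[e, , ] <- x - rowMeans(x[, sel, drop = FALSE])
  }
  epochs$log <- c(epochs$log, "baseline correction")
  epochs
}

#' Entrainment preprocessing pipeline
#'
#' Band-pass 0.1-40 Hz, resample to 300 Hz (225 samples per triplet),
#' high-pass 0.2 Hz, cut consecutive 0.75 s epochs from the start of each
#' resting/random/structured segment, and reject artifacted epochs. Steps
#' and retention are recorded in the `log`.
#'
#' @param recording An `eeg_recording` with `segments`.
#' @param reject_threshold Peak-to-peak threshold in uV.
#' @return An `epoch_set` with metadata `segment_kind`, `block`,
#'   `segment_index`.
#' @export
preprocess_entrainment <- function(recording, reject_threshold = 400) {
  rec <- bandpass(recording, 0.1, 40)
  rec <- resample(rec, 300)
  rec <- highpass(rec, 0.2)
  segs <- rec$segments
  segs <- segs[segs$kind %in% c("RestingState", "RandomStream",
                                "StructuredStream"), , drop = FALSE]
  onsets <- list(); meta <- list()
  for (i in seq_len(nrow(segs))) {
    k <- floor(segs$duration[i] / WORD_DURATION + 1e-9)
    on <- segs$start[i] + (seq_len(k) - 1L) * WORD_DURATION
    onsets[[i]] <- on
    meta[[i]] <- data.frame(segment_kind = segs$kind[i],
                            block = segs$block[i],
                            segment_index = i)[rep(1L, k), , drop = FALSE]
  }
  ep <- epoch(rec, unlist(onsets), 0, WORD_DURATION,
              metadata = do.call(rbind, meta))
  reject_epochs(ep, reject_threshold)
}

#' ERP preprocessing pipeline
#'
#' Band-pass 0.5-20 Hz, epoch [-1.50, 3.25] s around test-word onsets,
#' reject artifacted epochs, average-reference, normalize, and baseline
#' correct. The default baseline of a trial is the silent interval from
#' 2.25 s after the previous test word's onset up to the current onset
#' (`baseline = "previous"`); the first trial of a block uses [-0.25, 0]
#' s. `baseline = "fixed"` selects the alternative reading, a 2.25 s-long
#' window ending at onset (clipped to the epoch).
#'
#' @param recording An `eeg_recording`.
#' @param reject_threshold Peak-to-peak threshold in uV (applied before
#'   normalization).
#' @param baseline `"previous"` or `"fixed"`.
#' @return An `epoch_set` with metadata `condition`, `block`, `trial`.
#' @export
preprocess_erp <- function(recording, reject_threshold = 400,
                           baseline = c("previous", "fixed")) {
  baseline <- match.arg(baseline)
  rec <- bandpass(recording, 0.5, 20)
  ev <- rec$events
  te <- ev[ev$segment_kind == "TestBlock" & ev$position == 1L, , drop = FALSE]
  if (!nrow(te)) stopf("recording has no test-word events")
  ep <- epoch(rec, te$onset_s, -1.5, 3.25,
              metadata = te[, c("condition", "block", "trial")])
  ep <- reject_epochs(ep, reject_threshold)
  ep <- average_reference(ep)
  ep <- normalize_epochs(ep)
  md <- ep$metadata
  if (baseline == "previous") {
    win <- matrix(0, nrow(md), 2L)
    for (e in seq_len(nrow(md))) {
      prev <- te$onset_s[te$block == md$block[e] & te$trial < md$trial[e]]
      if (length(prev)) {
        win[e, 1] <- max(prev) + 2.25 - md$onset_s[e]
        win[e, 1] <- max(win[e, 1], -1.5)
      } else {
        win[e, 1] <- -0.25              # first word of a block
      }
      win[e, 2] <- 0
    }
  } else {
    win <- matrix(rep(c(-1.5, 0), each = nrow(md)), ncol = 2L)
  }
  baseline_correct(ep, win)
}
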