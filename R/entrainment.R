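# Steady-state (frequency-tagging) quantification: reshaping to long
# epochs, DSS denoising, evoked power, inter-trial coherence, SNR against
# local noise estimates, per-condition analysis and the sliding-window
# learning curve.
#
# With 7.5 s epochs the spectral resolution is 1/7.5 Hz, so the word rate
# (1/0.75 s = 1.333... Hz) and the syllable rate (4 Hz) fall exactly on
# bins 10 and 30 (0-based); a rectangular window (no taper) is therefore
# leakage-free at the target frequencies.

#' Reshape 0.75 s epochs into long epochs
#'
#' Groups consecutive retained epochs, in chronological order, into
#' non-overlapping long epochs of `n_per` triplets (default 10 -> 7.5 s,
#' 30 syllables); leftovers are discarded. Because every short epoch
#' starts at a triplet boundary, the steady-state phase is preserved.
#'
#' @param epochs An `epoch_set` of 0.75 s epochs.
#' @param n_per Short epochs per long epoch.
#' @return An `epoch_set` of long epochs; metadata keeps the first short
#'   epoch's fields plus `n_short`.
#' @export
reshape_to_long_epochs <- function(epochs, n_per = 10L) {
  stopifnot(inherits(epochs, "epoch_set"), is_count(n_per))
  d <- dim(epochs$data)
  n_groups <- d[1] %/% n_per
  if (n_groups < 1L) {
    stopf("need at least %d retained epochs to form one long epoch (have %d)",
          n_per, d[1])
  }
  arr <- array(0, dim = c(n_groups, d[2], d[3] * n_per))
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * n_per + 1L):(g * n_per)
    arr[g, , ] <- do.call(cbind, lapply(idx, function(e) epochs$data[e, , ]))
  }
  first <- ((seq_len(n_groups) - 1L) * n_per) + 1L
  md <- epochs$metadata[first, , drop = FALSE]
  md$n_short <- n_per
  rownames(md) <- NULL
  structure(list(data = arr, rate = epochs$rate, tmin = 0,
                 onsets = epochs$onsets[first], metadata = md,
                 channels = epochs$channels,
                 log = c(epochs$log,
                         sprintf("reshape: %d x %d -> %d long epochs",
                                 d[1], n_per, n_groups))),
            class = "epoch_set")
}

#' Denoising source separation (DSS)
#'
#' Builds a spatial filter in two stages: PCA on the total covariance of
#' all trials (keep `n_pca` components, whiten), then PCA on the
#' covariance of the trial-averaged data in the whitened space (keep
#' `n_dss` components, ranked by evoked reproducibility). Data are
#' projected onto the retained components and back to channel space, so
#' units and topographies are preserved; trial count is unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param n_pca Components kept by the first PCA (default 30).
#' @param n_dss Components kept by the bias-rotation stage (default 6).
#' @return The denoised `epoch_set`; attribute `dss` holds the `todss`
#'   matrix and the bias eigenvalue spectrum.
#' @export
dss_denoise <- function(epochs, n_pca = 30L, n_dss = 6L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ch <- d[2]
  if (!(n_ch >= n_pca && n_pca >= n_dss)) {
    stopf("need channels (%d) >= n_pca (%d) >= n_dss (%d)",
          n_ch, n_pca, n_dss)
  }
  # total covariance over all trials (channels x pooled-samples view)
  X2 <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), n_ch, d[3] * d[1])
  c0 <- tcrossprod(X2) / (d[1] * d[3])
  eg <- eigen(c0, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  if (sum(eg$values > tol) < n_pca) {
    stopf(paste0("covariance rank (%d) below n_pca (%d); ",
                 "use a smaller n_pca"), sum(eg$values > tol), n_pca)
  }
  keep <- seq_len(n_pca)
  whiten <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), n_pca)
  color <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), n_pca)
  # bias: covariance of the trial average, in whitened space
  avg <- colMeans(epochs$data, dims = 1L)
  yb <- crossprod(whiten, avg)
  c1 <- tcrossprod(yb) / d[3]
  eg2 <- eigen(c1, symmetric = TRUE)
  rot <- eg2$vectors[, seq_len(n_dss), drop = FALSE]
  # channel-space projector: whiten -> rotate -> truncate -> invert
  proj <- color %*% rot %*% crossprod(rot, t(whiten))
  epochs$data <- aperm(array(proj %*% X2, c(n_ch, d[3], d[1])),
                       c(3L, 1L, 2L))
  epochs$log <- c(epochs$log,
                  sprintf("DSS: %d PCA, %d DSS components", n_pca, n_dss))
  attr(epochs, "dss") <- list(todss = whiten %*% rot,
                              bias_eigenvalues = eg2$values)
  epochs
}

# Batched FFT over all (trial, channel) series: samples x (trial *
# channel) matrix, one mvfft call.
.epoch_fft_mat <- function(epochs) {
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), d[3], d[1] * d[2])
  stats::mvfft(X) / d[3]
}

.fft_freqs <- function(n, rate) (seq_len(n) - 1L) * rate / n

#' Evoked power spectrum
#'
#' Power spectrum of the trial-averaged response: phase-locked activity
#' survives averaging, induced activity cancels.
#'
#' @param epochs An `epoch_set`.
#' @return Channels x bins matrix of power (amplitude^2 of the mean
#'   response), with attribute `freqs` (Hz).
#' @export
evoked_power <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  avg <- colMeans(epochs$data, dims = 1L)
  S <- t(stats::mvfft(t(avg))) / d[3]
  p <- Mod(S)^2
  rownames(p) <- epochs$channels
  attr(p, "freqs") <- .fft_freqs(d[3], epochs$rate)
  p
}

#' Inter-trial coherence
#'
#' `ITC(f) = |1/N * sum_i exp(i phi(f, i))|`: the magnitude of the mean
#' unit phasor across the N trials, between 0 (random phases) and 1
#' (perfect phase locking).
#'
#' @param epochs An `epoch_set` with at least 2 trials.
#' @return Channels x bins matrix in \[0, 1\], attribute `freqs`.
#' @export
itc <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 2L) stopf("ITC requires at least 2 trials")
  F <- .epoch_fft_mat(epochs)
  # unit phasors; zero-amplitude bins contribute 0 (0 / xmin)
  U <- F / pmax(Mod(F), .Machine$double.xmin)
  # sum over trials: columns are trial-major per channel
  group <- kronecker(diag(d[2]), rep(1, d[1]))
  Z <- U %*% group                     # bins x channels
  # clamp out float roundoff: |mean phasor| is mathematically in [0, 1]
  v <- pmin(pmax(t(Mod(Z)) / d[1], 0), 1)
  rownames(v) <- epochs$channels
  attr(v, "freqs") <- .fft_freqs(d[3], epochs$rate)
  v
}

# Index of the bin holding `target` Hz; must be an exact bin center.
.bin_at <- function(freqs, target) {
  df <- freqs[2] - freqs[1]
  idx <- which.min(abs(freqs - target))
  if (abs(freqs[idx] - target) > df * 1e-3) {
    stopf("%g Hz is not a bin center (resolution %g Hz)", target, df)
  }
  idx
}

.adjacent_bins <- function(freqs, target, n_side = 6L) {
  idx <- .bin_at(freqs, target)
  adj <- c((idx - n_side):(idx - 1L), (idx + 1L):(idx + n_side))
  if (any(adj < 2L) || any(adj > length(freqs) %/% 2 + 1L)) {
    stopf("need %d valid bins on each side of %g Hz", n_side, target)
  }
  list(target = idx, adjacent = adj)
}

#' Power SNR against a local power-law noise floor
#'
#' Fits `log P = a + b log f` by OLS on the 12 bins adjacent to the
#' target (6 per side, 0.8 Hz at 7.5 s resolution; the target bin is
#' excluded), then scores the target's log-power excess over the fit in
#' units of the residual standard deviation. Because OLS residuals have
#' zero mean on the fit bins, this equals the published
#' `(log P - mean(P_noise)) / std(P_noise)` form. Zero under pure noise.
#'
#' @param power Channels x bins matrix from [evoked_power()].
#' @param target_freq Hz (must be a bin center).
#' @return Named numeric vector, one z-like score per channel.
#' @export
snr_power <- function(power, target_freq) {
  freqs <- attr(power, "freqs")
  if (is.null(freqs)) stopf("power matrix lacks a freqs attribute")
  bins <- .adjacent_bins(freqs, target_freq)
  used <- power[, c(bins$adjacent, bins$target), drop = FALSE]
  if (any(used <= 0)) {
    stopf("nonpositive power at a bin used by the SNR fit")
  }
  lp <- log(power[, bins$adjacent, drop = FALSE])
  A <- cbind(1, log(freqs[bins$adjacent]))
  coef <- solve(crossprod(A), crossprod(A, t(lp)))       # 2 x channels
  fitted <- A %*% coef
  resid <- t(lp) - fitted
  s <- apply(resid, 2L, stats::sd)
  pred_t <- drop(c(1, log(freqs[bins$target])) %*% coef)
  excess <- log(power[, bins$target]) - pred_t - colMeans(resid)
  # a spectrum lying exactly on a power law has zero residual SD; the
  # score is 0 there (no excess) rather than 0/0
  degenerate <- s < 1e-10
  score <- ifelse(degenerate,
                  ifelse(abs(excess) < 1e-8, 0, sign(excess) * Inf),
                  excess / s)
  stats::setNames(score, rownames(power))
}

#' ITC SNR against adjacent bins
#'
#' Z-score of the target-bin ITC against the mean and standard deviation
#' of the 12 adjacent bins (no power-law fit).
#'
#' @param itc_mat Channels x bins matrix from [itc()].
#' @param target_freq Hz (bin center).
#' @return Named numeric vector per channel.
#' @export
snr_itc <- function(itc_mat, target_freq) {
  freqs <- attr(itc_mat, "freqs")
  if (is.null(freqs)) stopf("itc matrix lacks a freqs attribute")
  bins <- .adjacent_bins(freqs, target_freq)
  adj <- itc_mat[, bins$adjacent, drop = FALSE]
  s <- apply(adj, 1L, stats::sd)
  if (any(s == 0)) {
    stopf("zero variance across adjacent ITC bins")
  }
  score <- (itc_mat[, bins$target] - rowMeans(adj)) / s
  stats::setNames(score, rownames(itc_mat))
}

.condition_kinds <- c(RestingState = "RestingState",
                      Random = "RandomStream",
                      Structured = "StructuredStream")

#' Per-condition entrainment analysis
#'
#' Full chain for one condition: entrainment preprocessing, selection of
#' the condition's 0.75 s epochs (Structured pools the long and the eight
#' short streams; Random pools the two random segments), reshaping to
#' 7.5 s, average reference and per-epoch normalization, optional DSS,
#' then evoked power, ITC and SNR at the word and syllable rates.
#'
#' @param recording An `eeg_recording`.
#' @param condition `"RestingState"`, `"Random"` or `"Structured"`.
#' @param reject_threshold uV.
#' @param n_pca,n_dss DSS dimensions; `use_dss = FALSE` skips DSS.
#' @param epochs Optionally, a precomputed [preprocess_entrainment()]
#'   result (saves refiltering when looping over conditions).
#' @param min_segments Minimum usable 0.75 s segments (default 6); below
#'   it an error of class `entrainr_excluded` is thrown.
#' @return A `spectral_result`: `freqs`, `power`, `itc` (channels x
#'   bins), `snr_power`, `snr_itc` (channels x 2 rate columns),
#'   `n_trials`, `condition`, plus intermediate `epochs`.
#' @export
condition_entrainment <- function(recording,
                                  condition = c("RestingState", "Random",
                                                "Structured"),
                                  reject_threshold = 400,
                                  n_pca = 30L, n_dss = 6L, use_dss = TRUE,
                                  epochs = NULL, min_segments = 6L) {
  condition <- match.arg(condition)
  if (is.null(epochs)) {
    epochs <- preprocess_entrainment(recording, reject_threshold)
  }
  sel <- epochs$metadata$segment_kind == .condition_kinds[[condition]]
  if (sum(sel) < min_segments) {
    stop(structure(class = c("entrainr_excluded", "error", "condition"),
                   list(message = sprintf(
                     "only %d usable segments for %s (need >= %d): subject excluded",
                     sum(sel), condition, min_segments),
                     call = NULL)))
  }
  ep <- .subset_epochs(epochs, sel)
  long <- reshape_to_long_epochs(ep, 10L)
  long <- normalize_epochs(average_reference(long))
  if (use_dss) {
    # average referencing costs one rank
    long <- dss_denoise(long, min(n_pca, dim(long$data)[2] - 1L), n_dss)
  }
  .spectral_result(long, condition)
}

.spectral_result <- function(long, label) {
  p <- evoked_power(long)
  ic <- itc(long)
  res <- list(freqs = attr(p, "freqs"),
              power = p, itc = ic,
              snr_power = cbind(word = snr_power(p, WORD_RATE),
                                syllable = snr_power(p, SYLLABLE_RATE)),
              snr_itc = cbind(word = snr_itc(ic, WORD_RATE),
                              syllable = snr_itc(ic, SYLLABLE_RATE)),
              n_trials = dim(long$data)[1],
              condition = label,
              epochs = long)
  class(res) <- "spectral_result"
  res
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> %s: %d trials, %d channels; mean SNR(power) word %.2f / syl %.2f\n",
              x$condition, x$n_trials, nrow(x$power),
              mean(x$snr_power[, "word"]), mean(x$snr_power[, "syllable"])))
  invisible(x)
}

#' Sliding-window entrainment time course
#'
#' Concatenates the retained 0.75 s stream epochs chronologically
#' (resting, random and structured segments; test-word periods are never
#' epoched) and repeats the per-condition analysis in windows of
#' `window_s` advanced by `step_s`. Each window is labeled by its central
#' time on the concatenated timeline, so the first full 120 s window is
#' centered at 60 s.
#'
#' @param recording An `eeg_recording`.
#' @param window_s,step_s Window length and step (s); defaults 120 / 1.5.
#' @param reject_threshold uV.
#' @param n_pca,n_dss,use_dss DSS settings; the filter is refit per
#'   window.
#' @param epochs Optional precomputed [preprocess_entrainment()] result.
#' @return A `sliding_result`: data frame `summary` (center_s, rate,
#'   mean_snr_power, mean_snr_itc) and arrays `snr_power`, `snr_itc`
#'   (windows x channels x 2 rates), plus `centers`.
#' @export
sliding_entrainment <- function(recording, window_s = 120, step_s = 1.5,
                                reject_threshold = 400,
                                n_pca = 30L, n_dss = 6L, use_dss = TRUE,
                                epochs = NULL) {
  if (is.null(epochs)) {
    epochs <- preprocess_entrainment(recording, reject_threshold)
  }
  n_ep <- dim(epochs$data)[1]
  per_win <- as.integer(round(window_s / WORD_DURATION))
  step_ep <- max(1L, as.integer(round(step_s / WORD_DURATION)))
  if (per_win < 10L) stopf("window shorter than one long epoch; skipped")
  starts <- seq(1L, n_ep - per_win + 1L, by = step_ep)
  n_ch <- dim(epochs$data)[2]
  snr_p <- array(NA_real_, dim = c(length(starts), n_ch, 2L),
                 dimnames = list(NULL, epochs$channels,
                                 c("word", "syllable")))
  snr_i <- snr_p
  centers <- (starts - 1L) * WORD_DURATION + window_s / 2
  for (w in seq_along(starts)) {
    ep <- .subset_epochs(epochs, starts[w]:(starts[w] + per_win - 1L))
    long <- reshape_to_long_epochs(ep, 10L)
    long <- normalize_epochs(average_reference(long))
    if (use_dss) {
      long <- dss_denoise(long, min(n_pca, dim(long$data)[2] - 1L), n_dss)
    }
    res <- .spectral_result(long, sprintf("window@%.1fs", centers[w]))
    snr_p[w, , ] <- res$snr_power
    snr_i[w, , ] <- res$snr_itc
  }
  summary <- data.frame(
    center_s = rep(centers, 2L),
    rate = rep(c("word", "syllable"), each = length(centers)),
    mean_snr_power = c(rowMeans(snr_p[, , 1L, drop = FALSE]),
                       rowMeans(snr_p[, , 2L, drop = FALSE])),
    mean_snr_itc = c(rowMeans(snr_i[, , 1L, drop = FALSE]),
                     rowMeans(snr_i[, , 2L, drop = FALSE])))
  structure(list(summary = summary, snr_power = snr_p, snr_itc = snr_i,
                 centers = centers, window_s = window_s, step_s = step_s),
            class = "sliding_result")
}

#' Write a spectral result as a TSV table
#'
#' @param result A `spectral_result`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_spectral_tsv <- function(result, path) {
  stopifnot(inherits(result, "spectral_result"))
  ch <- rownames(result$power)
  df <- data.frame(
    channel = rep(ch, 2L),
    rate = rep(c("word", "syllable"), each = length(ch)),
    frequency = rep(c(WORD_RATE, SYLLABLE_RATE), each = length(ch)),
    power = c(result$power[, .bin_at(result$freqs, WORD_RATE)],
              result$power[, .bin_at(result$freqs, SYLLABLE_RATE)]),
    itc = c(result$itc[, .bin_at(result$freqs, WORD_RATE)],
            result$itc[, .bin_at(result$freqs, SYLLABLE_RATE)]),
    snr_power = c(result$snr_power[, "word"], result$snr_power[, "syllable"]),
    snr_itc = c(result$snr_itc[, "word"], result$snr_itc[, "syllable"]),
    condition = result$condition)
  write_tsv(df, path)
}
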