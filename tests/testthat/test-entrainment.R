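# Reshaping, DSS, evoked power, ITC, SNR, and bin alignment.

test_that("reshaping groups consecutive epochs and preserves phase", {
  arr <- array(with_seed(1, rnorm(240 * 2 * 15)), c(240, 2, 15))
  ep <- fix_epoch_set(arr, 20)
  long <- reshape_to_long_epochs(ep, 10L)
  expect_equal(dim(long$data), c(24L, 2L, 150L))
  expect_equal(long$data[1, 1, 1:15], arr[1, 1, ])
  expect_equal(long$data[1, 1, 16:30], arr[2, 1, ])
  # 25 short epochs -> 2 long, 5 discarded
  ep25 <- fix_epoch_set(arr[1:25, , , drop = FALSE], 20)
  expect_equal(dim(reshape_to_long_epochs(ep25, 10L)$data)[1], 2L)
  expect_error(reshape_to_long_epochs(
    fix_epoch_set(arr[1:5, , , drop = FALSE], 20)), "at least 10")
})

test_that("word and syllable rates are exact leakage-free bin centers", {
  # 0.75 s epochs of a 4/3 Hz sinusoid at 300 Hz, reshaped to 7.5 s
  rate <- 300
  t_short <- (0:(225 - 1)) / rate
  n_short <- 40
  arr <- array(0, c(n_short, 1, 225))
  for (e in seq_len(n_short)) {
    # continuous phase across consecutive short epochs
    arr[e, 1, ] <- sin(2 * pi * (4 / 3) * (t_short + (e - 1) * 0.75))
  }
  long <- reshape_to_long_epochs(fix_epoch_set(arr, rate), 10L)
  p <- evoked_power(long)
  freqs <- attr(p, "freqs")
  expect_equal(freqs[2] - freqs[1], 1 / 7.5)
  expect_equal(which.max(p[1, 1:1125]), 10L + 1L)    # bin 10 (0-based)
  expect_gt(p[1, 11] / sum(p[1, 2:1125]), 0.99)      # no leakage
  # 4 Hz lands on bin 30
  arr4 <- array(0, c(2, 1, 2250))
  arr4[1, 1, ] <- arr4[2, 1, ] <- sin(2 * pi * 4 * ((0:2249) / rate))
  p4 <- evoked_power(fix_epoch_set(arr4, rate))
  expect_equal(which.max(p4[1, 1:1125]), 30L + 1L)
})

test_that("evoked power follows phase relationships across trials", {
  rate <- 30
  t <- (0:(rate - 1)) / rate
  tone <- cos(2 * pi * 4 * t)
  # single trial: all power at the 4 Hz bin (plus its conjugate)
  p1 <- evoked_power(fix_epoch_set(array(tone, c(1, 1, rate)), rate))
  expect_equal(which.max(p1[1, 1:15]), 5L)
  expect_gt(p1[1, 5] / sum(p1[1, 2:15]), 0.999)
  # two trials in antiphase: evoked power cancels exactly
  arr <- array(0, c(2, 1, rate))
  arr[1, 1, ] <- tone; arr[2, 1, ] <- -tone
  p2 <- evoked_power(fix_epoch_set(arr, rate))
  expect_lt(p2[1, 5], 1e-28)
  # many random-phase trials: evoked power at the tone bin shrinks
  n <- 400
  arr3 <- array(0, c(n, 1, rate))
  ph <- with_seed(4, runif(n, 0, 2 * pi))
  for (e in seq_len(n)) arr3[e, 1, ] <- cos(2 * pi * 4 * t + ph[e])
  p3 <- evoked_power(fix_epoch_set(arr3, rate))
  expect_lt(p3[1, 5], 0.01 * p1[1, 5])
})

test_that("ITC is 1 for identical trials, ~0 for uniform phases, sqrt(pi)/(2 sqrt(N)) on average", {
  rate <- 30
  t <- (0:(rate - 1)) / rate
  arr <- array(rep(sin(2 * pi * 4 * t) + 0.5 * cos(2 * pi * 7 * t), each = 8),
               c(8, 1, rate))
  for (e in 1:8) arr[e, 1, ] <- sin(2 * pi * 4 * t) + 0.5 * cos(2 * pi * 7 * t)
  v <- itc(fix_epoch_set(arr, rate))
  expect_equal(unname(v[1, 5]), 1)
  expect_equal(unname(v[1, 8]), 1)
  expect_true(all(v >= 0 & v <= 1))
  # uniform phases: ITC -> 0 as N grows
  n <- 1000
  arr2 <- array(0, c(n, 1, rate))
  ph <- with_seed(5, runif(n, 0, 2 * pi))
  for (e in seq_len(n)) arr2[e, 1, ] <- cos(2 * pi * 4 * t + ph[e])
  expect_lt(itc(fix_epoch_set(arr2, rate))[1, 5], 0.07)
  # E[ITC] for N random phases ~ sqrt(pi)/(2 sqrt(N)): Monte-Carlo check
  n_tr <- 16; n_rep <- 300
  vals <- numeric(n_rep)
  with_seed(6, {
    for (r in seq_len(n_rep)) {
      phr <- runif(n_tr, 0, 2 * pi)
      vals[r] <- Mod(mean(exp(1i * phr)))
    }
  })
  expect_lt(abs(mean(vals) - sqrt(pi) / (2 * sqrt(n_tr))), 0.02)
  expect_error(itc(fix_epoch_set(array(0, c(1, 1, 10)), 10)), "2 trials")
})

test_that("evoked_power and itc match the brute-force DFT oracle", {
  arr <- array(with_seed(7, rnorm(8 * 3 * 16)), c(8, 3, 16))
  ep <- fix_epoch_set(arr, 16)
  o <- oracle_spectra(arr)
  p <- evoked_power(ep)
  v <- itc(ep)
  expect_lt(max(abs(unclass(p) - o$power)), 1e-10)
  expect_lt(max(abs(unclass(v) - o$itc)), 1e-10)
})

test_that("snr_power scores the target bin against a power-law floor", {
  # spectrum exactly on a power law: score ~ 0
  rate <- 300
  freqs <- (0:2249) * rate / 2250
  pw <- matrix(0, 2, 2250)
  pw[1, ] <- c(1, freqs[-1]^-1.3)
  pw[2, ] <- c(1, 2 * freqs[-1]^-0.7)
  attr(pw, "freqs") <- freqs
  s0 <- snr_power(pw, 4 / 3)
  expect_lt(max(abs(s0)), 1e-6)
  # 10x excess at the target: large positive score
  pw10 <- pw
  pw10[, 11] <- pw10[, 11] * 10
  attr(pw10, "freqs") <- freqs
  expect_true(all(snr_power(pw10, 4 / 3) > 5))
  # nonpositive power is rejected
  pwbad <- pw; pwbad[1, 11] <- 0
  attr(pwbad, "freqs") <- freqs
  expect_error(snr_power(pwbad, 4 / 3), "nonpositive")
  # off-bin target and spectrum-edge targets are rejected
  expect_error(snr_power(pw, 1.11), "bin center")
  expect_error(snr_power(pw, freqs[3]), "valid bins")
})

test_that("snr_itc z-scores the target bin against its neighbors", {
  freqs <- (0:149) / 7.5
  v <- matrix(0.3, 1, 150)
  attr(v, "freqs") <- freqs
  expect_error(snr_itc(v, 4 / 3), "zero variance")    # flat neighbors
  v2 <- v + matrix(with_seed(8, rnorm(150, sd = 0.01)), 1)
  attr(v2, "freqs") <- freqs
  v3 <- v2; v3[1, 11] <- 0.9
  attr(v3, "freqs") <- freqs
  z <- snr_itc(v3, 4 / 3)
  adj <- v3[1, c(5:10, 12:17)]
  expect_equal(unname(z), (0.9 - mean(adj)) / sd(adj))
  expect_gt(z, 10)
})

test_that("null SNR scores center on zero (full calibration in acceptance suite)", {
  # signal-free epochs (white noise only), scaled down: 8 channels,
  # 12 long epochs, 40 replicate subjects at 40 Hz; the SD ~ 1 (+-0.3)
  # criterion runs at 400 replicates in test-acceptance.R
  scores_p <- scores_i <- c()
  with_seed(10, {
    for (r in 1:40) {
      arr <- array(rnorm(12 * 8 * 300), c(12, 8, 300))
      ep <- fix_epoch_set(arr, 40)
      p <- evoked_power(ep)
      scores_p <- c(scores_p, snr_power(p, 4))
      scores_i <- c(scores_i, snr_itc(itc(ep), 4))
    }
  })
  expect_lt(abs(mean(scores_p)), 0.15)
  expect_lt(abs(mean(scores_i)), 0.15)
  expect_lt(abs(sd(scores_i) - 1), 0.3)
})

test_that("DSS preserves low-rank reproducible signal exactly", {
  # identical trials with rank-2 spatial structure; bias covariance spans
  # the signal, so projection + back-projection is the identity
  rate <- 20
  t <- (0:(rate * 2 - 1)) / rate
  mix <- matrix(with_seed(11, rnorm(12)), 6, 2)
  src <- rbind(sin(2 * pi * 2 * t), cos(2 * pi * 3 * t))
  trial <- mix %*% src
  arr <- array(0, c(5, 6, length(t)))
  for (e in 1:5) arr[e, , ] <- trial
  ep <- fix_epoch_set(arr, rate)
  den <- dss_denoise(ep, n_pca = 2, n_dss = 2)
  expect_lt(max(abs(den$data - ep$data)), 1e-8)
  expect_error(dss_denoise(ep, n_pca = 5, n_dss = 2), "rank")
  expect_error(dss_denoise(ep, n_pca = 2, n_dss = 3), "n_pca")
})

test_that("DSS attenuates unreproducible noise and raises evoked SNR", {
  rate <- 40
  t <- (0:(rate * 7.5 - 1)) / rate
  n_tr <- 20; n_ch <- 10
  topo <- seq(-1, 1, length.out = n_ch)
  sig <- outer(topo, sin(2 * pi * 4 * t))
  with_seed(12, {
    noise_only <- array(rnorm(n_tr * n_ch * length(t)),
                        c(n_tr, n_ch, length(t)))
    noisy <- noise_only
    for (e in seq_len(n_tr)) noisy[e, , ] <- noisy[e, , ] + sig
  })
  # pure noise: evoked power can only go down
  ep_n <- fix_epoch_set(noise_only, rate)
  den_n <- dss_denoise(ep_n, n_pca = 10, n_dss = 3)
  expect_lt(sum(evoked_power(den_n)), sum(evoked_power(ep_n)))
  # signal + noise: SNR at 4 Hz strictly larger after DSS
  ep_s <- fix_epoch_set(noisy, rate)
  den_s <- dss_denoise(ep_s, n_pca = 10, n_dss = 3)
  snr_before <- mean(snr_power(evoked_power(ep_s), 4))
  snr_after <- mean(snr_power(evoked_power(den_s), 4))
  expect_gt(snr_after, snr_before)
})

test_that("condition_entrainment enforces the exclusion threshold", {
  rec <- fix_recording(seed = 21, n_ch = 8, sampling_rate = 100)
  ep <- preprocess_entrainment(rec)
  # artificially starve a condition
  few <- ep
  keep <- ep$metadata$segment_kind != "RestingState" |
    seq_len(nrow(ep$metadata)) <= 5
  few$data <- few$data[keep, , , drop = FALSE]
  few$metadata <- few$metadata[keep, , drop = FALSE]
  expect_error(condition_entrainment(rec, "RestingState", epochs = few,
                                     n_pca = 7, n_dss = 4),
               class = "entrainr_excluded")
})

test_that("sliding windows are labeled by center time and track onset", {
  # synthetic short-epoch stream: 4 Hz always; 4/3 Hz appears at 240 s
  rate <- 40
  n_ep <- 400                        # 300 s of concatenated epochs
  spe <- as.integer(rate * 0.75)
  onset_s <- 240
  arr <- array(with_seed(13, rnorm(n_ep * 4 * spe, sd = 0.2)),
               c(n_ep, 4, spe))
  gain <- c(1, 0.5, -0.5, -1)       # survives average referencing
  for (e in seq_len(n_ep)) {
    tt <- ((e - 1) * spe + seq_len(spe) - 1) / rate
    arr[e, , ] <- arr[e, , ] + outer(gain, sin(2 * pi * 4 * tt))
    if ((e - 1) * 0.75 >= onset_s) {
      arr[e, , ] <- arr[e, , ] + outer(gain, sin(2 * pi * (4 / 3) * tt))
    }
  }
  ep <- fix_epoch_set(arr, rate)
  ep$metadata$segment_kind <- "StructuredStream"
  sl <- sliding_entrainment(NULL, window_s = 120, step_s = 7.5,
                            use_dss = FALSE, epochs = ep)
  expect_equal(sl$centers[1], 60)
  expect_equal(diff(sl$centers)[1], 7.5)
  word_snr <- rowMeans(sl$snr_power[, , "word"])
  syl_snr <- rowMeans(sl$snr_power[, , "syllable"])
  # syllable rate significant in every window; word rate only once the
  # window overlaps the post-onset data, within one step of prediction
  expect_true(all(syl_snr > 3))
  first_sig <- sl$centers[which(word_snr > 3)[1]]
  predicted <- sl$centers[which(sl$centers + 60 > onset_s)[1]]
  expect_lte(abs(first_sig - predicted), 7.5)
  expect_true(all(word_snr[sl$centers + 60 <= onset_s] < 3))
})
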