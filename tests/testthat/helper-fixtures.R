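# Shared fixtures and independent oracles. Everything is generated in
# code; sizes are deliberately small so the full suite stays within a
# desk-scale budget (stated per test where a paper-scale quantity is
# exercised at reduced size).

fix_lexicon <- function(list_id = "A") build_lexicon(list_id)

fix_montage <- function(n = 16L, seed = 1L) make_montage(n, 6, seed = seed)

# A quiet, fast simulation configuration for pipeline tests.
fix_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    noise = list(pink_scale = 2, exponent = 1, n_sources = 4,
                 white_scale = 0.5),
    artifact = list(rate_per_min = 0.5, amplitude = 500),
    seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

fix_recording <- function(seed = 1L, n_ch = 16L, ...) {
  sch <- build_session_schedule(fix_lexicon(), seed = seed)
  simulate_recording(sch, fix_montage(n_ch), fix_sim_config(seed, ...))
}

# Hand-build an epoch_set from an epochs x channels x samples array.
fix_epoch_set <- function(arr, rate, tmin = 0, metadata = NULL) {
  structure(list(data = arr, rate = rate, tmin = tmin,
                 onsets = seq_len(dim(arr)[1]) - 1,
                 metadata = if (is.null(metadata))
                   data.frame(onset_s = seq_len(dim(arr)[1]) - 1)
                 else metadata,
                 channels = sprintf("E%03d", seq_len(dim(arr)[2])),
                 log = character()),
            class = "epoch_set")
}

# ---- independent oracles --------------------------------------------

# Direct O(n^2) discrete Fourier transform.
oracle_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# Evoked power and ITC computed from first principles with oracle_dft.
oracle_spectra <- function(arr) {
  d <- dim(arr)
  power <- matrix(0, d[2], d[3])
  itc_m <- matrix(0, d[2], d[3])
  for (ch in seq_len(d[2])) {
    avg <- colMeans(arr[, ch, , drop = FALSE][, 1, ])
    power[ch, ] <- Mod(oracle_dft(avg) / d[3])^2
    z <- rep(0 + 0i, d[3])
    for (e in seq_len(d[1])) {
      X <- oracle_dft(arr[e, ch, ]) / d[3]
      m <- Mod(X)
      z <- z + ifelse(m > 0, X / m, 0 + 0i)
    }
    itc_m[ch, ] <- Mod(z) / d[1]
  }
  list(power = power, itc = itc_m)
}

# Brute-force spatio-temporal clustering: grow clusters by repeated
# pairwise merging (no BFS), used as the structural oracle.
oracle_clusters <- function(t_mat, t_crit, adj) {
  pts <- which(!is.na(t_mat) & abs(t_mat) > t_crit, arr.ind = TRUE)
  if (!nrow(pts)) return(list())
  lab <- seq_len(nrow(pts))
  connected <- function(i, j) {
    if (sign(t_mat[pts[i, , drop = FALSE]]) !=
        sign(t_mat[pts[j, , drop = FALSE]])) return(FALSE)
    ci <- pts[i, 1]; ti <- pts[i, 2]; cj <- pts[j, 1]; tj <- pts[j, 2]
    (ci == cj && abs(ti - tj) == 1) || (ti == tj && adj[ci, cj])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pts))) {
      for (j in seq_len(nrow(pts))) {
        if (lab[i] != lab[j] && connected(i, j)) {
          lab[lab == lab[j]] <- lab[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(unique(lab), function(l) pts[lab == l, , drop = FALSE])
}

# One-way repeated-measures ANOVA via explicit sum-of-squares sums
# (cell-by-cell loops, no matrix shortcuts).
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- sum(mat) / (n * k)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(mat[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(mat[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (mat[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- unname((ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1))))
  list(F = f, p = unname(stats::pf(f, k - 1, (k - 1) * (n - 1),
                                   lower.tail = FALSE)))
}

# Scan a token sequence for immediate repeats and k,j,k,j alternations.
has_forbidden_patterns <- function(x) {
  n <- length(x)
  rep2 <- any(x[-1] == x[-n])
  alt4 <- n >= 4 && any(x[1:(n - 3)] == x[3:(n - 1)] &
                          x[2:(n - 2)] == x[4:n] &
                          x[1:(n - 3)] != x[2:(n - 2)])
  rep2 || alt4
}
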