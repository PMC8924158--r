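# Adjacency, subject ERPs, and the cluster-based permutation test.

# A line of channels 2 cm apart: chain adjacency at the 3 cm threshold.
line_adjacency <- function(n_ch) {
  pos <- cbind(x = 2 * (seq_len(n_ch) - 1), y = 0, z = 1)
  ids <- sprintf("E%03d", seq_len(n_ch))
  rownames(pos) <- ids
  m <- structure(list(channels = ids, positions = pos, head_radius = 6,
                      reference = ids[1]), class = "montage")
  build_adjacency(m, 3)
}

test_that("adjacency follows the distance threshold", {
  adj <- line_adjacency(5)
  expect_true(adj$matrix[1, 2])        # 2 cm apart
  expect_false(adj$matrix[1, 3])       # 4 cm apart
  expect_false(any(diag(adj$matrix)))
  expect_true(isSymmetric(adj$matrix))
  expect_equal(adj$mean_degree, mean(c(1, 2, 2, 2, 1)))
  # 128 channels on a 6 cm hemisphere: sensible neighborhood sizes
  # geometric prediction: ~ pi*3^2 / (2*pi*6^2/128) - 1 ~ 15 neighbors,
  # minus edge effects at the equatorial rim
  big <- build_adjacency(make_montage(128, 6, seed = 1), 3)
  expect_gt(big$mean_degree, 10)
  expect_lt(big$mean_degree, 16)
  expect_length(big$isolated, 0L)
})

test_that("subject_condition_erps averages per condition with inclusion rule", {
  arr <- array(with_seed(1, rnorm(48 * 2 * 10)), c(48, 2, 10))
  md <- data.frame(onset_s = seq_len(48),
                   condition = rep(c("Word", "EdgeWord", "PartWord",
                                     "NonWord"), each = 12),
                   block = rep(1:8, 6), trial = seq_len(48))
  ep <- fix_epoch_set(arr, 20, tmin = 0, metadata = md)
  res <- subject_condition_erps(ep, min_trials = 12L)
  expect_equal(dim(res$erps), c(4L, 2L, 10L))
  expect_equal(unname(res$counts), rep(12L, 4L))
  expect_equal(res$erps["Word", , ],
               apply(arr[1:12, , , drop = FALSE], c(2, 3), mean),
               ignore_attr = TRUE)
  # identical trials average to the trial itself
  one <- arr; for (e in 1:48) one[e, , ] <- arr[1, , ]
  ep1 <- fix_epoch_set(one, 20, metadata = md)
  expect_equal(subject_condition_erps(ep1)$erps["NonWord", , ], arr[1, , ],
               ignore_attr = TRUE)
  # under-threshold subject is excluded with a classed error
  expect_error(subject_condition_erps(ep, min_trials = 13L),
               class = "entrainr_excluded")
  # averaging error shrinks ~ 1/sqrt(N)
  truth <- matrix(2, 2, 10)
  rmse <- function(n) {
    trials <- array(with_seed(2, rnorm(200 * 2 * 10)), c(200, 2, 10))
    est <- apply(trials[1:n, , , drop = FALSE], c(2, 3), mean) + truth
    sqrt(mean((est - truth)^2))
  }
  expect_gt(rmse(10) / rmse(160), 2)   # expect ~4, allow noise
})

test_that("identical sides give an empty cluster result", {
  adj <- line_adjacency(4)
  a <- array(with_seed(3, rnorm(6 * 4 * 20)), c(6, 4, 20))
  ct <- cluster_permutation(a, a, adj, times = (0:19) / 20,
                            window = c(0, 0.95), n_perm = 50, seed = 1)
  expect_equal(nrow(ct$clusters), 0L)
  expect_error(cluster_permutation(a[1, , , drop = FALSE],
                                   a[1, , , drop = FALSE], adj,
                                   (0:19) / 20), "2 subjects")
})

test_that("clustering matches the brute-force oracle and exact enumeration", {
  set.seed(42)
  n_s <- 5; n_ch <- 3; n_t <- 10
  adj <- line_adjacency(n_ch)
  for (rep in 1:5) {
    a <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
    b <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
    b[, 2, 4:7] <- b[, 2, 4:7] - 1.5      # planted effect
    times <- (0:(n_t - 1)) / 10
    ct <- cluster_permutation(a, b, adj, times, window = c(0, 0.95),
                              min_size = 1L, n_perm = 100, seed = rep)
    # structural oracle: same suprathreshold partition
    t_crit <- qt(0.975, n_s - 1)
    oracle <- oracle_clusters(ct$t_map, t_crit, adj$matrix)
    expect_equal(length(ct$points), length(oracle))
    key <- function(m) paste(sort(m[, 1] * 1000 + m[, 2]), collapse = ",")
    expect_setequal(vapply(ct$points, key, ""),
                    vapply(oracle, key, ""))
  }
  # exact p by enumerating all 2^5 sign patterns
  a <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
  b <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
  b[, 2, 4:7] <- b[, 2, 4:7] - 3
  times <- (0:(n_t - 1)) / 10
  diff_arr <- a - b
  t_crit <- qt(0.975, n_s - 1)
  signs_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_s)))
  null_exact <- apply(signs_all, 1, function(sg) {
    d <- diff_arr * sg
    tm <- apply(d, c(2, 3), function(v) mean(v) / (sd(v) / sqrt(n_s)))
    cl <- oracle_clusters(tm, t_crit, adj$matrix)
    if (!length(cl)) return(0)
    max(abs(vapply(cl, function(m) sum(tm[m]), 0)))
  })
  ct <- cluster_permutation(a, b, adj, times, window = c(0, 0.95),
                            min_size = 1L, n_perm = 4000, seed = 7)
  p_exact <- mean(null_exact >= abs(ct$clusters$mass[1]))
  expect_lt(abs(ct$clusters$p[1] - p_exact), 0.03)
})

test_that("permutation p is invariant to channel order and side swap", {
  set.seed(11)
  n_s <- 8; n_ch <- 4; n_t <- 12
  adj <- line_adjacency(n_ch)
  a <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
  b <- array(rnorm(n_s * n_ch * n_t), c(n_s, n_ch, n_t))
  a[, 1:2, 5:9] <- a[, 1:2, 5:9] + 1.2
  times <- (0:(n_t - 1)) / 10
  ct <- cluster_permutation(a, b, adj, times, c(0, 1.1), n_perm = 400,
                            seed = 3)
  # reverse channel order (adjacency of a line is reversal-symmetric)
  rev_idx <- n_ch:1
  ct_rev <- cluster_permutation(a[, rev_idx, , drop = FALSE],
                                b[, rev_idx, , drop = FALSE],
                                adj, times, c(0, 1.1), n_perm = 400,
                                seed = 3)
  expect_equal(ct$clusters$p, ct_rev$clusters$p)
  expect_equal(ct$clusters$mass, ct_rev$clusters$mass)
  # swapping sides flips polarity, keeps mass magnitude and p
  ct_sw <- cluster_permutation(b, a, adj, times, c(0, 1.1), n_perm = 400,
                               seed = 3)
  expect_equal(ct_sw$clusters$p, ct$clusters$p)
  expect_equal(abs(ct_sw$clusters$mass), abs(ct$clusters$mass))
  expect_false(identical(ct_sw$clusters$polarity, ct$clusters$polarity))
  # observed mass reproduced when its own labeling enters the null set
  expect_gte(max(ct$null_max),
             0)  # null exists
  d <- (a - b)[, , which(times >= 0 & times <= 1.1), drop = FALSE]
  X <- matrix(d, n_s, n_ch * sum(times >= 0 & times <= 1.1))
  t_self <- entrainr:::.paired_t_mat(X, n_ch, sum(times >= 0 & times <= 1.1))
  expect_equal(t_self, ct$t_map)
})

test_that("min_size, min_channels and polarity separation apply", {
  # crafted t map on a 3-channel chain: a single-channel temporal cluster
  # of 3 points, a 2-channel simultaneous cluster, an isolated point, and
  # an adjacent opposite-polarity point that must not merge
  adj <- line_adjacency(3)
  nb <- apply(adj$matrix, 1, which, simplify = FALSE)
  tm <- matrix(0, 3, 8)
  tm[1, 2:4] <- 5                     # 3 points, one channel
  tm[2, 6] <- 4; tm[3, 6] <- 4        # 2 channels, one sample
  tm[2, 1] <- 6                       # isolated single point
  tm[2, 7] <- -4                      # neighbor in time, opposite sign
  cl1 <- entrainr:::.cluster_masses(tm, 2.5, nb, min_size = 1L,
                                    min_channels = 1L)
  expect_length(cl1, 4L)
  cl2 <- entrainr:::.cluster_masses(tm, 2.5, nb, min_size = 2L,
                                    min_channels = 1L)
  expect_length(cl2, 2L)              # isolated points dropped
  cl3 <- entrainr:::.cluster_masses(tm, 2.5, nb, min_size = 1L,
                                    min_channels = 2L)
  expect_length(cl3, 1L)              # only the 2-channel cluster
  expect_equal(cl3[[1]]$mass, 8)
  pols <- vapply(cl1, `[[`, "", "polarity")
  expect_equal(sum(pols == "negative"), 1L)
})

test_that("block time course applies the 3-of-8 inclusion rule", {
  # two subjects, 8 blocks; subject 2 loses most side-a trials in block 3
  mk_subject <- function(drop_block3 = FALSE) {
    n_tr <- 128
    md <- data.frame(onset_s = seq_len(n_tr),
                     condition = rep(c("Word", "EdgeWord", "PartWord",
                                       "NonWord"), 32),
                     block = rep(1:8, each = 16),
                     trial = seq_len(n_tr))
    arr <- array(rnorm(n_tr * 2 * 10, sd = 0.1), c(n_tr, 2, 10))
    abx <- md$condition %in% c("Word", "EdgeWord")
    arr[abx, , 3:6] <- arr[abx, , 3:6] + 1      # constant injected effect
    if (drop_block3) {
      keep <- !(md$block == 3 & abx & md$trial %% 16 > 2)
      arr <- arr[keep, , , drop = FALSE]
      md <- md[keep, , drop = FALSE]
    }
    fix_epoch_set(arr, 10, tmin = 0, metadata = md)
  }
  set.seed(9)
  eps <- list(mk_subject(FALSE), mk_subject(TRUE))
  adj <- line_adjacency(2)
  cs <- contrast_spec("abx-bcx")
  times <- (0:9) / 10
  a <- b <- array(0, c(2, 2, 10))
  for (s in 1:2) {
    r <- subject_condition_erps(eps[[s]], min_trials = 5L)
    a[s, , ] <- apply(r$erps[cs$side_a, , , drop = FALSE], c(2, 3), mean)
    b[s, , ] <- apply(r$erps[cs$side_b, , , drop = FALSE], c(2, 3), mean)
  }
  ct <- cluster_permutation(a, b, adj, times, c(0, 0.9), min_size = 1L,
                            n_perm = 100, seed = 2)
  expect_gte(nrow(ct$clusters), 1L)
  bt <- block_time_course(eps, cs, ct, min_trials = 3L)
  # subject 2 block 3 excluded (only 2 side-a trials)
  expect_false(any(bt$points$subject == 2 & bt$points$block == 3))
  expect_true(all(bt$points$subject == 1 | bt$points$block != 3))
  # constant effect: block means are flat around the injected value
  fit <- stats::lm(mean ~ block, data = bt$summary)
  ci <- stats::confint(fit)["block", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("contrast specifications partition the four conditions", {
  for (nm in c("abx-bcx", "heard-unheard", "word-edge", "part-non")) {
    cs <- contrast_spec(nm)
    expect_length(intersect(cs$side_a, cs$side_b), 0L)
  }
  expect_setequal(c(contrast_spec("abx-bcx")$side_a,
                    contrast_spec("abx-bcx")$side_b),
                  c("Word", "EdgeWord", "PartWord", "NonWord"))
  expect_equal(contrast_spec("heard-unheard")$side_a,
               c("Word", "PartWord"))
})
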