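# ERP contrasts on isolated test words and the spatio-temporal
# cluster-based permutation test.
#
# The paired design (each subject contributes both sides of a contrast)
# admits an exact permutation scheme: random within-subject sign flips of
# the per-subject difference waveforms. Suprathreshold t-values are
# clustered over neighboring electrodes and contiguous time samples with
# matching polarity; cluster mass (summed t) is compared with the
# permutation distribution of the maximum cluster mass over both
# polarities.

#' Contrast specifications for the four test-word conditions
#'
#' `"abx-bcx"` contrasts triplets starting with a trained word onset
#' (Words + Edge-words) against position-shifted triplets (Part-words +
#' Non-words); `"heard-unheard"` contrasts triplets whose final
#' transition occurred in the stream against never-heard ones;
#' `"word-edge"` and `"part-non"` are the pairwise granularity probes.
#'
#' @param name Contrast name.
#' @return List with `name`, `side_a`, `side_b` (condition labels).
#' @export
contrast_spec <- function(name = c("abx-bcx", "heard-unheard",
                                   "word-edge", "part-non")) {
  name <- match.arg(name)
  sides <- switch(name,
    "abx-bcx" = list(a = c("Word", "EdgeWord"),
                     b = c("PartWord", "NonWord")),
    "heard-unheard" = list(a = c("Word", "PartWord"),
                           b = c("EdgeWord", "NonWord")),
    "word-edge" = list(a = "Word", b = "EdgeWord"),
    "part-non" = list(a = "PartWord", b = "NonWord"))
  list(name = name, side_a = sides$a, side_b = sides$b)
}

#' Per-condition average ERPs for one subject
#'
#' @param epochs A [preprocess_erp()] `epoch_set` with `condition`
#'   metadata.
#' @param conditions Condition labels to average.
#' @param min_trials Minimum retained trials per condition (default 12);
#'   below it an error of class `entrainr_excluded` is thrown.
#' @return List `erps` (condition x channels x samples array), `counts`
#'   (trials per condition), `times`.
#' @export
subject_condition_erps <- function(epochs,
                                   conditions = c("Word", "EdgeWord",
                                                  "PartWord", "NonWord"),
                                   min_trials = 12L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  counts <- vapply(conditions,
                   function(cc) sum(epochs$metadata$condition == cc), 0L)
  if (any(counts < min_trials)) {
    low <- conditions[counts < min_trials]
    stop(structure(class = c("entrainr_excluded", "error", "condition"),
                   list(message = sprintf(
                     "condition(s) %s below %d trials: subject excluded",
                     paste(low, collapse = ", "), min_trials),
                     call = NULL)))
  }
  arr <- array(0, dim = c(length(conditions), d[2], d[3]),
               dimnames = list(conditions, epochs$channels, NULL))
  for (j in seq_along(conditions)) {
    sel <- epochs$metadata$condition == conditions[j]
    arr[j, , ] <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1L)
  }
  list(erps = arr, counts = counts, times = epoch_times(epochs))
}

# Paired t statistics per (channel, sample) from a subjects x (channels *
# samples) matrix view. Zero-variance points yield NA and never enter a
# cluster. Vectorized: this is the permutation-loop hot path.
.paired_t_mat <- function(X, n_ch, n_t) {
  s <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - s * m^2) / (s - 1)
  v[v < 1e-300] <- 0
  t_vec <- m / sqrt(v / s)
  t_vec[v == 0] <- NA_real_
  matrix(t_vec, n_ch, n_t)
}

# Connected components of same-polarity suprathreshold points; adjacency
# = same channel & consecutive samples, or same sample & neighbor
# channels. Returns a list of integer matrices (channel, sample).
.find_clusters <- function(mask, nb_list) {
  n_ch <- nrow(mask); n_t <- ncol(mask)
  visited <- matrix(FALSE, n_ch, n_t)
  clusters <- list()
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    c0 <- idx[r, 1L]; t0 <- idx[r, 2L]
    if (visited[c0, t0]) next
    queue <- matrix(c(c0, t0), ncol = 2L)
    visited[c0, t0] <- TRUE
    members <- queue
    while (nrow(queue)) {
      ch <- queue[1L, 1L]; tt <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      cand <- rbind(
        if (tt > 1L) c(ch, tt - 1L),
        if (tt < n_t) c(ch, tt + 1L),
        if (length(nb_list[[ch]])) cbind(nb_list[[ch]], tt))
      if (!is.null(cand)) {
        for (q in seq_len(nrow(cand))) {
          cc <- cand[q, 1L]; ct <- cand[q, 2L]
          if (mask[cc, ct] && !visited[cc, ct]) {
            visited[cc, ct] <- TRUE
            queue <- rbind(queue, c(cc, ct))
            members <- rbind(members, c(cc, ct))
          }
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  clusters
}

# All same-polarity clusters of a t map passing the size filters, with
# their masses. Used for both observed data and permutations.
.cluster_masses <- function(t_mat, t_crit, nb_list, min_size,
                            min_channels) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(t_mat) & (sgn * t_mat > t_crit)
    if (!any(mask)) next
    cl <- .find_clusters(mask, nb_list)
    for (members in cl) {
      if (nrow(members) < min_size) next
      if (length(unique(members[, 1L])) < min_channels) next
      out[[length(out) + 1L]] <- list(
        points = members,
        polarity = if (sgn > 0) "positive" else "negative",
        mass = sum(t_mat[members]))
    }
  }
  out
}

#' Spatio-temporal cluster-based permutation test
#'
#' Paired t per (channel, sample) within the search window; points with
#' `|t|` above the two-sided alpha quantile are clustered by spatial
#' adjacency, temporal contiguity and matching polarity; cluster mass is
#' the summed t. The null distribution is the maximum absolute cluster
#' mass over `n_perm` random within-subject sign flips, and
#' `p = (1 + #\{null >= |mass|\}) / (1 + n_perm)`.
#'
#' @param erps_a,erps_b Subjects x channels x samples arrays (paired).
#' @param adjacency An [build_adjacency()] graph.
#' @param times Per-sample times (s) of the arrays.
#' @param window `c(start, end)` s searched.
#' @param alpha Point-level threshold (default 0.05, two-sided t).
#' @param min_size Minimum connected (channel, time) points (default 2).
#' @param min_channels Minimum distinct channels per cluster (default 1;
#'   set 2 for the stricter reading).
#' @param n_perm Permutations (default 5000).
#' @param seed RNG seed for the sign flips.
#' @return A `cluster_test`: data frame `clusters` (polarity, mass,
#'   n_points, n_channels, tmin/tmax s, p), list `points`, the t map,
#'   `window`, `times`, and the null distribution.
#' @export
cluster_permutation <- function(erps_a, erps_b, adjacency, times,
                                window = c(0, 0.5), alpha = 0.05,
                                min_size = 2L, min_channels = 1L,
                                n_perm = 5000L, seed = 0L) {
  stopifnot(inherits(adjacency, "adjacency_graph"),
            identical(dim(erps_a), dim(erps_b)))
  s <- dim(erps_a)[1]
  if (s < 2L) stopf("need at least 2 subjects")
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) stopf("window contains no samples")
  diff_arr <- (erps_a - erps_b)[, , sel, drop = FALSE]
  n_ch <- dim(diff_arr)[2]
  n_t <- dim(diff_arr)[3]
  X <- matrix(diff_arr, s, n_ch * n_t)   # column-major (channel, time) view
  nb_list <- apply(adjacency$matrix, 1L, which, simplify = FALSE)
  t_crit <- stats::qt(1 - alpha / 2, df = s - 1L)

  t_obs <- .paired_t_mat(X, n_ch, n_t)
  obs <- .cluster_masses(t_obs, t_crit, nb_list, min_size, min_channels)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      signs <- sample(c(-1, 1), s, replace = TRUE)
      t_p <- .paired_t_mat(X * signs, n_ch, n_t)
      cl <- .cluster_masses(t_p, t_crit, nb_list, min_size, min_channels)
      if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
    }, 0)
  })

  if (length(obs)) {
    df <- data.frame(
      cluster = seq_along(obs),
      polarity = vapply(obs, `[[`, "", "polarity"),
      mass = vapply(obs, `[[`, 0, "mass"),
      n_points = vapply(obs, function(cl) nrow(cl$points), 0L),
      n_channels = vapply(obs, function(cl)
        length(unique(cl$points[, 1L])), 0L),
      tmin_s = vapply(obs, function(cl)
        min(times[sel][cl$points[, 2L]]), 0),
      tmax_s = vapply(obs, function(cl)
        max(times[sel][cl$points[, 2L]]), 0))
    df$p <- vapply(df$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (1 + n_perm), 0)
    ord <- order(df$p, -abs(df$mass))
    df <- df[ord, ]
    df$cluster <- seq_len(nrow(df))
    rownames(df) <- NULL
    pts <- lapply(obs[ord], `[[`, "points")
  } else {
    df <- data.frame(cluster = integer(), polarity = character(),
                     mass = numeric(), n_points = integer(),
                     n_channels = integer(), tmin_s = numeric(),
                     tmax_s = numeric(), p = numeric())
    pts <- list()
  }
  structure(list(clusters = df, points = pts, t_map = t_obs,
                 window = window, times = times[sel],
                 null_max = null_max, alpha = alpha, n_perm = n_perm),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> window [%g, %g] s: %d cluster(s)\n",
              x$window[1], x$window[2], nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Write a cluster report TSV
#'
#' One row per cluster with its channel list and time extent.
#'
#' @param test A `cluster_test`.
#' @param channels Channel ids (in array order).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(test, channels, path) {
  df <- test$clusters
  df$channel_list <- vapply(test$points, function(p)
    paste(channels[sort(unique(p[, 1L]))], collapse = ","), "")
  df$window <- sprintf("[%g, %g]", test$window[1], test$window[2])
  write_tsv(df, path)
}

#' Per-block effect time course over a cluster
#'
#' For each subject and test block, averages the side A minus side B
#' difference over the cluster's (channel, time) points; a subject-block
#' point is included only when both sides retain at least `min_trials`
#' of their 8 trials in that block.
#'
#' @param epoch_list List of per-subject [preprocess_erp()] epoch sets.
#' @param contrast A [contrast_spec()].
#' @param cluster_test A [cluster_permutation()] result.
#' @param cluster Which cluster row to use (default 1).
#' @param min_trials Per-side inclusion threshold (default 3).
#' @return List `points` (subject, block, effect), `summary` (per-block
#'   group mean, SE, n).
#' @export
block_time_course <- function(epoch_list, contrast, cluster_test,
                              cluster = 1L, min_trials = 3L) {
  stopifnot(inherits(cluster_test, "cluster_test"),
            cluster <= length(cluster_test$points))
  pts <- cluster_test$points[[cluster]]
  rows <- list()
  for (s in seq_along(epoch_list)) {
    ep <- epoch_list[[s]]
    tt <- epoch_times(ep)
    sel_t <- which(tt >= cluster_test$window[1] &
                     tt <= cluster_test$window[2])
    for (b in sort(unique(ep$metadata$block))) {
      ia <- ep$metadata$block == b & ep$metadata$condition %in% contrast$side_a
      ib <- ep$metadata$block == b & ep$metadata$condition %in% contrast$side_b
      if (sum(ia) < min_trials || sum(ib) < min_trials) next
      avg_a <- colMeans(ep$data[ia, , , drop = FALSE], dims = 1L)
      avg_b <- colMeans(ep$data[ib, , , drop = FALSE], dims = 1L)
      dmat <- (avg_a - avg_b)[, sel_t, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, block = b, effect = mean(dmat[pts]))
    }
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = integer(), block = integer(), effect = numeric())
  summary <- do.call(rbind, lapply(split(points, points$block), function(g)
    data.frame(block = g$block[1], mean = mean(g$effect),
               se = stats::sd(g$effect) / sqrt(nrow(g)), n = nrow(g))))
  rownames(summary) <- NULL
  list(points = points, summary = summary)
}
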