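# Group-level statistics: electrode-wise one-sided t-tests with FDR
# correction, and the one-way repeated-measures ANOVA over conditions
# with Bonferroni-corrected post-hoc paired comparisons.

#' One-sample one-sided t-test (upper tail)
#'
#' Under no entrainment the SNR scores are zero-mean, so each electrode's
#' across-subject SNR is tested against zero, upper tail. Zero-variance
#' input is resolved by sign (p = 0.5 for all-zero data) with a message.
#'
#' @param values Per-subject values (length >= 2).
#' @return List `t`, `p`, `df`.
#' @export
ttest_one_sided <- function(values) {
  n <- length(values)
  if (n < 2L) stopf("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    message("zero variance in t-test input; p set by sign")
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(t = if (m == 0) 0 else sign(m) * Inf, p = p, df = n - 1L))
  }
  t_stat <- m / (s / sqrt(n))
  list(t = t_stat, p = stats::pt(t_stat, df = n - 1L, lower.tail = FALSE),
       df = n - 1L)
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List `rejected` (logical), `p_adjusted`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Electrode-wise significance of SNR scores
#'
#' One-sided t-test against zero per electrode across subjects, FDR
#' corrected across electrodes.
#'
#' @param snr Subjects x channels matrix.
#' @param q FDR level.
#' @return Data frame `channel`, `t`, `p`, `p_adjusted`, `significant`.
#' @export
electrode_tests <- function(snr, q = 0.05) {
  stopifnot(is.matrix(snr), nrow(snr) >= 2L)
  res <- apply(snr, 2L, ttest_one_sided)
  p <- vapply(res, `[[`, 0, "p")
  fdr <- fdr_correct(p, q)
  data.frame(channel = if (is.null(colnames(snr)))
               as.character(seq_len(ncol(snr))) else colnames(snr),
             t = vapply(res, `[[`, 0, "t"),
             p = p,
             p_adjusted = fdr$p_adjusted,
             significant = fdr$rejected,
             row.names = NULL)
}

#' One-way repeated-measures ANOVA
#'
#' Standard two-way (subject x condition) sum-of-squares decomposition
#' with sphericity assumed: `F = MS_condition / MS_(subject:condition)`,
#' df = (k - 1, (k - 1)(n - 1)). Post-hoc pairwise paired t-tests with
#' Bonferroni correction (p times the number of pairs, capped at 1).
#'
#' @param mat Subjects x conditions matrix, complete (no NA).
#' @return An `anova_result`: `F`, `df_num`, `df_den`, `p`, `post_hoc`
#'   data frame.
#' @export
rm_anova <- function(mat) {
  if (!is.matrix(mat) || anyNA(mat)) {
    stopf("mat must be a complete subjects x conditions matrix")
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 2L) stopf("need >= 3 subjects and >= 2 conditions")
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df_num <- k - 1L
  df_den <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_num
  ms_err <- ss_err / df_den
  # identical columns give 0/0; the condition effect is exactly zero
  f_stat <- if (ms_err == 0) {
    if (ms_cond <= .Machine$double.eps) 0 else Inf
  } else {
    ms_cond / ms_err
  }
  p <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  labs <- if (is.null(colnames(mat))) paste0("C", seq_len(k)) else
    colnames(mat)
  pairs <- utils::combn(k, 2L)
  ph <- data.frame(
    a = labs[pairs[1L, ]], b = labs[pairs[2L, ]],
    p_uncorrected = apply(pairs, 2L, function(ij) {
      stats::t.test(mat[, ij[1L]], mat[, ij[2L]], paired = TRUE)$p.value
    }))
  ph$p_bonferroni <- pmin(1, ph$p_uncorrected * ncol(pairs))
  structure(list(F = f_stat, df_num = df_num, df_den = df_den, p = p,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err),
                 post_hoc = ph),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d,%d) = %.3g, p = %.3g\n",
              x$df_num, x$df_den, x$F, x$p))
  print(x$post_hoc, row.names = FALSE)
  invisible(x)
}

#' Condition ANOVA over entrainment-responsive electrodes
#'
#' Follows the published selection: per target rate, electrodes
#' significant (one-sided t + FDR) in any condition are pooled, each
#' subject's SNR is averaged over that electrode union, and the three
#' condition means enter a repeated-measures ANOVA.
#'
#' @param snr_by_condition Named list (RestingState/Random/Structured) of
#'   subjects x channels SNR matrices for one target rate.
#' @param q FDR level for electrode selection.
#' @return List `anova` ([rm_anova()] result), `electrodes` (selected
#'   union), `matrix` (subjects x conditions means). `NULL` electrodes
#'   when nothing is significant.
#' @export
condition_anova <- function(snr_by_condition, q = 0.05) {
  stopifnot(is.list(snr_by_condition), length(snr_by_condition) >= 2L)
  sig <- lapply(snr_by_condition, function(m) electrode_tests(m, q))
  union_idx <- sort(unique(unlist(lapply(sig, function(df)
    which(df$significant)))))
  if (!length(union_idx) || nrow(snr_by_condition[[1L]]) < 3L) {
    return(list(anova = NULL, electrodes = integer(), matrix = NULL,
                tests = sig))
  }
  mat <- vapply(snr_by_condition, function(m)
    rowMeans(m[, union_idx, drop = FALSE]), numeric(nrow(snr_by_condition[[1]])))
  list(anova = rm_anova(mat), electrodes = union_idx, matrix = mat,
       tests = sig)
}
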