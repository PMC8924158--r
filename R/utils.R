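# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the caller's RNG state so
#' that library code never perturbs user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed, staying within 32-bit
# integer range. Deterministic and collision-poor for the handful of draws
# used per session.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
}

# Smallest 5-smooth integer >= n (and, optionally, divisible by `mult`).
# R's mixed-radix FFT degrades badly on lengths with large prime factors,
# so whole-recording transforms are zero-padded to a fast length.
fast_len <- function(n, mult = 1L) {
  target <- ceiling(n / mult)
  best <- Inf
  p5 <- 1
  while (p5 < 2 * target) {
    p3 <- p5
    while (p3 < 2 * target) {
      m <- p3
      while (m < target) m <- m * 2
      if (m < best) best <- m
      p3 <- p3 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best * mult)
}

# Near-equality for durations expressed in seconds.
near_multiple <- function(x, step, tol = 1e-9) {
  abs(x / step - round(x / step)) < tol
}

#' Write a data frame as a tab-separated table
#'
#' Plain TSV writer used for all tabular outputs (events, lexicons, spectra,
#' cluster reports). No quoting, no row names, `NA` written as empty string.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}
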