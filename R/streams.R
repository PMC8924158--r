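# Constrained stream generation and transitional-probability audits.
#
# Structured streams concatenate the four pseudo-words under two
# constraints: no immediate word repetition, and no two-word alternation
# repeated more than twice (W_k W_j W_k W_j forbidden). Word counts are
# exactly balanced, and successors are drawn among the currently
# least-used transitions, which keeps the 12 word-to-word transition
# counts nearly uniform -- in a 180 s stream each of the 12 part-words
# then occurs 18-21 times, as in the published stimulus sets. Random
# streams concatenate the 12 syllables under the same two constraints at
# the syllable level, again balancing transitions so that empirical
# syllable-to-syllable TPs are near-uniform (1/11 per allowed successor).

# Sample a constrained sequence over labels 1..n_lab: no immediate
# repetition, no x[t-3..t] = (k,j,k,j). If `quota` is given, each label is
# used exactly quota[label] times (sampling weighted by remaining counts).
# Candidates are restricted to the successors whose transition count from
# the previous label is minimal ("least-used transition" balancing); the
# count matrix can be carried across calls via `trans` to balance pooled
# counts over a series of streams. Restarts on dead ends.
.sample_constrained <- function(n_lab, n, quota = NULL, trans = NULL,
                                max_restarts = 10000L) {
  trans0 <- if (is.null(trans)) matrix(0L, n_lab, n_lab) else trans
  for (attempt in seq_len(max_restarts)) {
    seq_idx <- integer(n)
    remaining <- if (is.null(quota)) rep(1L, n_lab) else as.integer(quota)
    tr <- trans0
    ok <- TRUE
    for (t in seq_len(n)) {
      w <- if (is.null(quota)) rep(1, n_lab) else as.numeric(remaining)
      if (t >= 2L) {
        prev <- seq_idx[t - 1L]
        w[prev] <- 0
        if (t >= 4L && prev == seq_idx[t - 3L]) {
          # candidate equal to x[t-2] would complete k,j,k,j
          w[seq_idx[t - 2L]] <- 0
        }
        allowed <- which(w > 0)
        if (length(allowed)) {
          m <- min(tr[prev, allowed])
          w[allowed[tr[prev, allowed] > m]] <- 0
        }
      }
      if (sum(w) <= 0) { ok <- FALSE; break }
      pick <- sample.int(n_lab, 1L, prob = w)
      seq_idx[t] <- pick
      if (!is.null(quota)) remaining[pick] <- remaining[pick] - 1L
      if (t >= 2L) {
        tr[seq_idx[t - 1L], pick] <- tr[seq_idx[t - 1L], pick] + 1L
      }
    }
    if (ok) return(list(seq = seq_idx, trans = tr))
  }
  stopf(paste0("no constraint-satisfying sequence found after %d restarts; ",
               "try a different seed"), max_restarts)
}

.new_symbol_stream <- function(tokens, onsets, kind, lexicon,
                               word_index = NA_integer_,
                               position = NA_integer_) {
  df <- data.frame(onset = onsets, token = tokens,
                   word_index = word_index, position = position,
                   stringsAsFactors = FALSE)
  structure(list(tokens = df,
                 kind = kind,
                 list_id = lexicon$list_id,
                 syllable_duration = lexicon$syllable_duration,
                 duration = length(tokens) * lexicon$syllable_duration),
            class = "symbol_stream")
}

#' @export
print.symbol_stream <- function(x, ...) {
  cat(sprintf("<symbol_stream> %s, %.2f s, %d syllables (list %s)\n",
              x$kind, x$duration, nrow(x$tokens), x$list_id))
  invisible(x)
}

#' Generate a structured (word-concatenation) stream
#'
#' Words are concatenated with exactly balanced counts (each word appears
#' `duration / 0.75 / 4` times), no immediate repetition, and no two-word
#' alternation longer than two pairs. Generation is incremental sampling
#' weighted by remaining quota, restarting on dead ends.
#'
#' @param lexicon A [build_lexicon()] object.
#' @param duration Stream duration in seconds; must be a positive multiple
#'   of 0.75 with `duration/0.75` divisible by 4.
#' @param seed Integer seed; the stream is deterministic given it.
#' @return A `symbol_stream`: syllable tokens with onsets (0.25 s grid),
#'   word indices and within-word positions 1-3.
#' @examples
#' s <- generate_structured_stream(build_lexicon("A"), 30, seed = 1)
#' table(word_sequence(s))
#' @export
generate_structured_stream <- function(lexicon, duration, seed = 0L) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (!is.numeric(duration) || duration <= 0 ||
      !near_multiple(duration, WORD_DURATION) ||
      round(duration / WORD_DURATION) %% 4 != 0) {
    stopf(paste0("duration must be a positive multiple of 0.75 s with ",
                 "duration/0.75 divisible by 4 (got %s)"), duration)
  }
  generate_structured_streams(lexicon, duration, seed)[[1L]]
}

#' Generate a series of structured streams with pooled balancing
#'
#' Generates several structured streams in sequence, carrying the
#' transition-count state across streams so that word-to-word transition
#' counts are balanced in the pooled series as well as within each stream.
#' This mirrors how the eight 30 s re-familiarization streams of a session
#' hold their pooled part-word counts in a tight band (24-28 each).
#'
#' @param lexicon A [build_lexicon()] object.
#' @param durations Numeric vector of durations in seconds, each satisfying
#'   the [generate_structured_stream()] pre-conditions.
#' @param seed Integer seed.
#' @return A list of `symbol_stream`s.
#' @export
generate_structured_streams <- function(lexicon, durations, seed = 0L) {
  stopifnot(inherits(lexicon, "lexicon"))
  for (duration in durations) {
    if (!is.numeric(duration) || duration <= 0 ||
        !near_multiple(duration, WORD_DURATION) ||
        round(duration / WORD_DURATION) %% 4 != 0) {
      stopf(paste0("duration must be a positive multiple of 0.75 s with ",
                   "duration/0.75 divisible by 4 (got %s)"), duration)
    }
  }
  syl <- lexicon$syllables
  with_seed(seed, {
    trans <- NULL
    lapply(durations, function(duration) {
      n_words <- as.integer(round(duration / WORD_DURATION))
      res <- .sample_constrained(4L, n_words,
                                 quota = rep(n_words %/% 4L, 4L),
                                 trans = trans)
      trans <<- res$trans
      widx <- res$seq
      tokens <- as.vector(t(syl[widx, , drop = FALSE]))
      onsets <- (seq_along(tokens) - 1L) * SYLLABLE_DURATION
      .new_symbol_stream(tokens, onsets, "structured", lexicon,
                         word_index = rep(widx, each = 3L),
                         position = rep(1:3, n_words))
    })
  })
}

#' Generate a random (syllable-concatenation) stream
#'
#' The 12 syllables are concatenated with no immediate repetition and no
#' syllable alternation longer than two pairs; successors are otherwise
#' uniform, so empirical transitional probabilities approach 1/11.
#'
#' @param lexicon A [build_lexicon()] object (supplies the syllable set).
#' @param duration Seconds; positive multiple of 0.25.
#' @param seed Integer seed.
#' @return A `symbol_stream` with no word annotations.
#' @export
generate_random_stream <- function(lexicon, duration, seed = 0L) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (!is.numeric(duration) || duration <= 0 ||
      !near_multiple(duration, SYLLABLE_DURATION)) {
    stopf("duration must be a positive multiple of 0.25 s (got %s)", duration)
  }
  n <- as.integer(round(duration / SYLLABLE_DURATION))
  syls <- as.vector(lexicon$syllables)
  idx <- with_seed(seed, .sample_constrained(length(syls), n))$seq
  onsets <- (seq_len(n) - 1L) * SYLLABLE_DURATION
  .new_symbol_stream(syls[idx], onsets, "random", lexicon)
}

#' Word sequence of a structured stream
#'
#' @param stream A structured `symbol_stream`.
#' @return Integer vector of word indices, one per word token.
#' @export
word_sequence <- function(stream) {
  stopifnot(inherits(stream, "symbol_stream"))
  if (stream$kind != "structured") {
    stopf("word_sequence() requires a structured stream")
  }
  stream$tokens$word_index[stream$tokens$position == 1L]
}

#' Empirical transitional probabilities of a stream
#'
#' Counts adjacent pairs at the syllable or word level and converts them to
#' conditional probabilities. With `denominator = "transitions"` each row is
#' normalized by its outgoing-transition count (rows sum to 1; rows with no
#' outgoing transitions are flagged in `zero_rows` and left as zero). With
#' `denominator = "occurrences"` the divisor is the antecedent's occurrence
#' count, so the stream-final token's row sums to slightly less than 1 --
#' this is the estimator that reproduces the printed stream statistics
#' (mean between-word TP 0.332 for one 180 s stream, 0.325 pooled over
#' eight 30 s streams).
#'
#' @param stream A `symbol_stream`, or a list of them (counts pooled).
#' @param level `"syllable"` or `"word"` (word level requires structured
#'   streams).
#' @param denominator `"transitions"` (row-normalized) or `"occurrences"`.
#' @return A `tp_matrix`: `labels`, `counts`, `probabilities`, `zero_rows`.
#' @export
empirical_tps <- function(stream, level = c("syllable", "word"),
                          denominator = c("transitions", "occurrences")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  streams <- if (inherits(stream, "symbol_stream")) list(stream) else stream
  stopifnot(all(vapply(streams, inherits, TRUE, "symbol_stream")))
  seqs <- lapply(streams, function(s) {
    if (level == "word") as.character(word_sequence(s)) else s$tokens$token
  })
  if (sum(lengths(seqs)) == 0L) stopf("empty stream")
  labels <- sort(unique(unlist(seqs)))
  k <- length(labels)
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  occ <- stats::setNames(integer(k), labels)
  for (sq in seqs) {
    occ_t <- table(sq)
    occ[names(occ_t)] <- occ[names(occ_t)] + as.integer(occ_t)
    if (length(sq) >= 2L) {
      from <- sq[-length(sq)]
      to <- sq[-1L]
      tab <- table(factor(from, labels), factor(to, labels))
      counts <- counts + as.integer(tab)
    }
  }
  rs <- rowSums(counts)
  denom <- if (denominator == "transitions") rs else as.numeric(occ)
  probs <- counts / ifelse(denom > 0, denom, 1)
  structure(list(labels = labels, counts = counts, probabilities = probs,
                 occurrences = occ, zero_rows = labels[rs == 0L],
                 level = level, denominator = denominator),
            class = "tp_matrix")
}

#' Mean of the between-word transitional probabilities
#'
#' For a structured stream the 12 between-word TPs are the off-diagonal
#' entries of the word-level TP matrix (the diagonal is structurally zero).
#'
#' @param tp A word-level `tp_matrix`.
#' @return Mean of the 12 off-diagonal probabilities.
#' @export
between_word_tp_mean <- function(tp) {
  stopifnot(inherits(tp, "tp_matrix"), tp$level == "word")
  mean(tp$probabilities[row(tp$probabilities) != col(tp$probabilities)])
}

#' Count part-word occurrences in a structured stream
#'
#' Slides a 3-syllable window across the stream and counts each of the 12
#' part-word sequences B_i C_i A_k (k != i), i.e. the triplets straddling a
#' word boundary.
#'
#' @param stream A structured `symbol_stream`.
#' @param lexicon The lexicon it was generated from.
#' @return Named integer vector of length 12 (names `"i->k"`).
#' @export
part_word_counts <- function(stream, lexicon) {
  stopifnot(inherits(stream, "symbol_stream"), inherits(lexicon, "lexicon"))
  tok <- stream$tokens$token
  syl <- lexicon$syllables
  out <- integer(0)
  tri <- if (length(tok) >= 3L) {
    paste0(tok[seq_len(length(tok) - 2L)],
           tok[seq_len(length(tok) - 2L) + 1L],
           tok[seq_len(length(tok) - 2L) + 2L])
  } else character(0)
  for (i in 1:4) {
    for (k in setdiff(1:4, i)) {
      pw <- paste0(syl[i, 2], syl[i, 3], syl[k, 1])
      out[sprintf("%d->%d", i, k)] <- sum(tri == pw)
    }
  }
  out
}

#' Audit the statistics of a generated stream
#'
#' Summarizes word counts, part-word counts and between-word TP statistics
#' (mean, SD, range) under both TP denominators; flags streams whose
#' minimum part-word count falls outside the band typically observed for
#' balanced 180 s streams (18-21).
#'
#' @param stream A structured `symbol_stream` or a list of them (pooled).
#' @param lexicon Matching lexicon.
#' @return A list of class `stream_audit`.
#' @export
audit_stream <- function(stream, lexicon) {
  streams <- if (inherits(stream, "symbol_stream")) list(stream) else stream
  wc <- table(factor(unlist(lapply(streams, word_sequence)), 1:4))
  pw <- Reduce(`+`, lapply(streams, part_word_counts, lexicon = lexicon))
  tp_tr <- empirical_tps(streams, "word", "transitions")
  tp_oc <- empirical_tps(streams, "word", "occurrences")
  off <- function(tp) {
    p <- tp$probabilities
    p[row(p) != col(p)]
  }
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        min = min(x), max = max(x))
  structure(list(
    n_streams = length(streams),
    word_counts = as.integer(wc),
    part_word_counts = pw,
    tp_transitions = summ(off(tp_tr)),
    tp_occurrences = summ(off(tp_oc)),
    part_word_flag = min(pw) < 18L || max(pw) > 21L * length(streams)
  ), class = "stream_audit")
}

#' @export
print.stream_audit <- function(x, ...) {
  cat(sprintf("<stream_audit> %d stream(s)\n", x$n_streams))
  cat("  word counts:      ", paste(x$word_counts, collapse = " "), "\n")
  cat("  part-word counts: ", paste(x$part_word_counts, collapse = " "),
      "\n")
  cat(sprintf("  between-word TP (row-normalized): mean %.3f sd %.3f range [%.3f, %.3f]\n",
              x$tp_transitions["mean"], x$tp_transitions["sd"],
              x$tp_transitions["min"], x$tp_transitions["max"]))
  cat(sprintf("  between-word TP (occurrence):     mean %.3f sd %.3f range [%.3f, %.3f]\n",
              x$tp_occurrences["mean"], x$tp_occurrences["sd"],
              x$tp_occurrences["min"], x$tp_occurrences["max"]))
  invisible(x)
}
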