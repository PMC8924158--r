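# Session schedules: the full experimental protocol as a timed event table.
#
# Protocol: (1) 60 s resting state; (2) 120 s random stream; (3) 180 s
# structured stream (long learning stream); (4) eight series of a 30 s
# structured stream, 2.5 s silence, then 16 isolated test words with
# jittered ISI in [2, 2.5] s; (5) 120 s random stream; (6) 60 s resting
# state. Each test block presents all 16 test words in random order, so a
# session holds 128 test events, 4 per condition per block.

TEST_WORD_DURATION <- 0.75
TEST_SILENCE <- 2.5

.seg_row <- function(kind, start, duration, block = NA_integer_) {
  data.frame(kind = kind, start = start, duration = duration,
             block = block, stringsAsFactors = FALSE)
}

.stream_events <- function(stream, start, kind, block = NA_integer_) {
  tk <- stream$tokens
  data.frame(onset_s = start + tk$onset,
             duration_s = stream$syllable_duration,
             token = tk$token,
             segment_kind = kind,
             block = block,
             trial = NA_integer_,
             word_index = tk$word_index,
             position = tk$position,
             condition = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build a full session schedule
#'
#' Generates every stream of the protocol (deterministically from `seed`),
#' randomizes test-word order per block, and lays all segments on a common
#' timeline.
#'
#' @param lexicon A [build_lexicon()] object.
#' @param seed Integer master seed; segment streams, test orders and ISIs
#'   derive child seeds from it.
#' @return A `session_schedule` with `segments` (kind/start/duration/block),
#'   `events` (syllable-level event table; test-word syllables carry
#'   condition, block and trial), `test_words`, `lexicon`, `seed`,
#'   `total_duration`.
#' @export
build_session_schedule <- function(lexicon, seed = 0L) {
  stopifnot(inherits(lexicon, "lexicon"))
  tw <- make_test_words(lexicon)
  segs <- list()
  evts <- list()
  t <- 0
  k <- 0L
  add_seg <- function(kind, dur, block = NA_integer_) {
    segs[[length(segs) + 1L]] <<- .seg_row(kind, t, dur, block)
    t <<- t + dur
  }

  add_seg("RestingState", 60)

  rnd1 <- generate_random_stream(lexicon, 120, derive_seed(seed, k <- k + 1L))
  evts[[length(evts) + 1L]] <- .stream_events(rnd1, t, "RandomStream")
  add_seg("RandomStream", 120)

  long_str <- generate_structured_stream(lexicon, 180,
                                         derive_seed(seed, k <- k + 1L))
  evts[[length(evts) + 1L]] <- .stream_events(long_str, t, "StructuredStream")
  add_seg("StructuredStream", 180)

  # The eight 30 s re-familiarization streams share balancing state so
  # that their pooled transition counts stay in a tight band.
  shorts <- generate_structured_streams(lexicon, rep(30, 8L),
                                        derive_seed(seed, k <- k + 1L))
  trial <- 0L
  for (b in 1:8) {
    evts[[length(evts) + 1L]] <- .stream_events(shorts[[b]], t,
                                                "StructuredStream",
                                                block = b)
    add_seg("StructuredStream", 30, block = b)
    add_seg("Silence", TEST_SILENCE, block = b)
    ord_isi <- with_seed(derive_seed(seed, k <- k + 1L), {
      list(ord = sample.int(16L), isi = stats::runif(15L, 2.0, 2.5))
    })
    block_start <- t
    onset <- block_start
    rows <- vector("list", 16L)
    for (j in 1:16) {
      trial <- trial + 1L
      w <- tw[ord_isi$ord[j], ]
      rows[[j]] <- data.frame(
        onset_s = onset + (0:2) * SYLLABLE_DURATION,
        duration_s = SYLLABLE_DURATION,
        token = c(w$syl1, w$syl2, w$syl3),
        segment_kind = "TestBlock",
        block = b,
        trial = trial,
        word_index = w$word_index,
        position = 1:3,
        condition = w$condition,
        stringsAsFactors = FALSE)
      onset <- onset + TEST_WORD_DURATION +
        if (j < 16L) ord_isi$isi[j] else TEST_SILENCE
    }
    evts[[length(evts) + 1L]] <- do.call(rbind, rows)
    segs[[length(segs) + 1L]] <- .seg_row("TestBlock", block_start,
                                          onset - block_start, block = b)
    t <- onset
  }

  rnd2 <- generate_random_stream(lexicon, 120, derive_seed(seed, k <- k + 1L))
  evts[[length(evts) + 1L]] <- .stream_events(rnd2, t, "RandomStream")
  add_seg("RandomStream", 120)
  add_seg("RestingState", 60)

  events <- do.call(rbind, evts)
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL
  structure(list(segments = do.call(rbind, segs),
                 events = events,
                 test_words = tw,
                 lexicon = lexicon,
                 seed = seed,
                 total_duration = t),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> list %s, %.1f s total, %d segments, %d test events\n",
              x$lexicon$list_id, x$total_duration, nrow(x$segments),
              nrow(test_events(x))))
  invisible(x)
}

#' One row per isolated test-word event
#'
#' @param schedule A `session_schedule`.
#' @return Data frame with `trial`, `block`, `onset_s`, `condition`,
#'   `word_index`, `triplet`.
#' @export
test_events <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  ev <- schedule$events
  first <- ev[ev$segment_kind == "TestBlock" & ev$position == 1L, ]
  syl <- split(ev$token[ev$segment_kind == "TestBlock"],
               ev$trial[ev$segment_kind == "TestBlock"])
  data.frame(trial = first$trial, block = first$block,
             onset_s = first$onset_s, condition = first$condition,
             word_index = first$word_index,
             triplet = vapply(syl[as.character(first$trial)],
                              paste0, "", collapse = ""),
             stringsAsFactors = FALSE)
}

#' Write / read the events sidecar
#'
#' The sidecar is the TSV consumed by all downstream modules; it
#' round-trips exactly.
#'
#' @param schedule A `session_schedule` (or a bare events data frame).
#' @param path TSV path.
#' @return `path` / the events data frame.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- if (inherits(schedule, "session_schedule")) schedule$events
        else schedule
  write_tsv(ev, path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read_tsv(path)
  needed <- c("onset_s", "duration_s", "token", "segment_kind", "block",
              "trial", "word_index", "position", "condition")
  if (!all(needed %in% names(ev))) {
    stopf("events table lacks columns: %s",
          paste(setdiff(needed, names(ev)), collapse = ", "))
  }
  ev
}
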