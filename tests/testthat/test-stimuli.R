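# Lexicons, constrained streams, TP audits, session schedules.

test_that("lexicons reproduce the fixed stimulus lists", {
  lex <- build_lexicon("A")
  expect_equal(lex$words, c("dinapo", "lutiva", "fobumi", "sazogu"))
  expect_equal(unname(lex$syllables[, "A"]), c("di", "lu", "fo", "sa"))
  expect_length(unique(as.vector(lex$syllables)), 12L)
  for (id in c("A", "B", "C")) {
    l <- build_lexicon(id)
    expect_length(unique(as.vector(l$syllables)), 12L)
    expect_true(all(grepl("^[^aeiou][aeiou]$", as.vector(l$syllables))))
  }
  expect_error(build_lexicon("D"), "valid ids")
  expect_error(build_lexicon(1), "valid ids")
})

test_that("test words follow the condition templates and the fixed lists", {
  tw <- make_test_words(build_lexicon("A"))
  expect_equal(nrow(tw), 16L)
  expect_equal(as.integer(table(tw$condition)), rep(4L, 4L))
  get1 <- function(cond, i) tw$triplet[tw$condition == cond &
                                         tw$word_index == i]
  expect_equal(get1("NonWord", 1), "napodi")       # B1 C1 A1
  expect_equal(get1("EdgeWord", 1), "dinava")      # A1 B1 C2
  expect_equal(get1("PartWord", 1), "napolu")      # B1 C1 A2
  # NonWord i is a rotation of Word i: same syllable multiset
  for (i in 1:4) {
    w <- tw[tw$condition == "Word" & tw$word_index == i, ]
    nw <- tw[tw$condition == "NonWord" & tw$word_index == i, ]
    expect_setequal(unname(unlist(w[, c("syl1", "syl2", "syl3")])),
                    unname(unlist(nw[, c("syl1", "syl2", "syl3")])))
  }
  # deterministic (no RNG involvement) and list B matches its table
  expect_identical(tw, make_test_words(build_lexicon("A")))
  twb <- make_test_words(build_lexicon("B"))
  expect_equal(twb$triplet[twb$condition == "Word"],
               c("napolu", "tivafo", "bumisa", "zogudi"))
  expect_equal(twb$triplet[twb$condition == "EdgeWord" &
                             twb$word_index == 1], "napofo")
})

test_that("structured streams are balanced, constrained and deterministic", {
  lex <- build_lexicon("A")
  s <- generate_structured_stream(lex, 180, seed = 3)
  ws <- word_sequence(s)
  expect_equal(length(ws), 240L)
  expect_equal(as.integer(table(factor(ws, 1:4))), rep(60L, 4L))
  expect_false(has_forbidden_patterns(as.character(ws)))
  expect_equal(nrow(s$tokens), 720L)
  expect_equal(diff(s$tokens$onset), rep(0.25, 719L))
  # 3 s stream: one of each word, forced no-repeat
  s3 <- generate_structured_stream(lex, 3, seed = 1)
  expect_setequal(word_sequence(s3), 1:4)
  expect_identical(generate_structured_stream(lex, 30, seed = 9)$tokens,
                   generate_structured_stream(lex, 30, seed = 9)$tokens)
  expect_error(generate_structured_stream(lex, 100), "multiple of 0.75")
  expect_error(generate_structured_stream(lex, 1.5), "divisible by 4")
})

test_that("random streams satisfy syllable-level constraints with near-uniform TPs", {
  lex <- build_lexicon("B")
  r <- generate_random_stream(lex, 120, seed = 2)
  expect_equal(nrow(r$tokens), 480L)
  expect_false(has_forbidden_patterns(r$tokens$token))
  # 600 s: empirical TPs close to 1/11 per allowed successor
  r6 <- generate_random_stream(lex, 600, seed = 5)
  tp <- empirical_tps(r6, "syllable")
  off <- tp$probabilities[row(tp$probabilities) != col(tp$probabilities)]
  expect_lt(max(abs(off - 1 / 11)), 0.05)
  expect_error(generate_random_stream(lex, 0.3), "multiple of 0.25")
})

test_that("empirical_tps counts adjacent pairs and normalizes correctly", {
  lex <- build_lexicon("A")
  # hand-built stream s1 s2 s1 s3
  toy <- structure(list(tokens = data.frame(onset = (0:3) * 0.25,
                                            token = c("s1", "s2", "s1", "s3"),
                                            word_index = NA, position = NA),
                        kind = "random", list_id = "A",
                        syllable_duration = 0.25, duration = 1),
                   class = "symbol_stream")
  tp <- empirical_tps(toy, "syllable")
  expect_equal(tp$probabilities["s1", "s2"], 0.5)
  expect_equal(tp$probabilities["s1", "s3"], 0.5)
  expect_true("s3" %in% tp$zero_rows)
  # within-word syllable TPs are exactly 1 in structured streams
  s <- generate_structured_stream(lex, 30, seed = 1)
  stp <- empirical_tps(s, "syllable")
  for (i in 1:4) {
    expect_equal(stp$probabilities[lex$syllables[i, 1],
                                   lex$syllables[i, 2]], 1)
    expect_equal(stp$probabilities[lex$syllables[i, 2],
                                   lex$syllables[i, 3]], 1)
  }
  # word-level rows sum to 1 under the transition denominator
  wtp <- empirical_tps(s, "word")
  expect_equal(unname(rowSums(wtp$probabilities)), rep(1, 4))
  expect_error(empirical_tps(list(), "syllable"), "empty")
})

test_that("between-word TP means converge and match both estimators", {
  lex <- build_lexicon("A")
  # across >= 50 seeds the row-normalized mean is within 0.02 of 1/3
  means_tr <- means_oc <- numeric(50)
  for (k in 1:50) {
    s <- generate_structured_stream(lex, 180, seed = k)
    means_tr[k] <- between_word_tp_mean(empirical_tps(s, "word"))
    means_oc[k] <- between_word_tp_mean(
      empirical_tps(s, "word", "occurrences"))
  }
  expect_lt(abs(mean(means_tr) - 1 / 3), 0.02)
  # occurrence denominator: mean is exactly (4 - 1/60)/12 per stream
  expect_equal(means_oc, rep((4 - 1 / 60) / 12, 50), tolerance = 1e-12)
})

test_that("part-word counts fall in the published bands across seeds", {
  lex <- build_lexicon("C")
  n_seeds <- 60
  ok_long <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    pw <- part_word_counts(generate_structured_stream(lex, 180, seed = k),
                           lex)
    ok_long[k] <- min(pw) >= 18L && max(pw) <= 21L
  }
  expect_gte(mean(ok_long), 0.95)
  # pooled over eight 30 s streams: [24, 28] for >= 90% of seeds
  ok_pool <- logical(40)
  for (k in seq_len(40)) {
    shorts <- generate_structured_streams(lex, rep(30, 8), seed = 1000 + k)
    pw <- Reduce(`+`, lapply(shorts, part_word_counts, lexicon = lex))
    ok_pool[k] <- min(pw) >= 24L && max(pw) <= 28L
  }
  expect_gte(mean(ok_pool), 0.9)
})

test_that("session schedules implement the full protocol", {
  lex <- build_lexicon("A")
  sch <- build_session_schedule(lex, seed = 4)
  segs <- sch$segments
  expect_equal(segs$kind[1:3], c("RestingState", "RandomStream",
                                 "StructuredStream"))
  expect_equal(segs$duration[1:3], c(60, 120, 180))
  expect_equal(tail(segs$kind, 2), c("RandomStream", "RestingState"))
  expect_equal(sum(segs$kind == "StructuredStream"), 9L)  # long + 8 short
  expect_equal(sum(segs$kind == "TestBlock"), 8L)
  te <- test_events(sch)
  expect_equal(nrow(te), 128L)
  tab <- table(te$condition, te$block)
  expect_true(all(tab == 4L))
  expect_equal(dim(tab), c(4L, 8L))
  # ISIs (offset to next onset) within [2, 2.5]
  for (b in 1:8) {
    on <- sort(te$onset_s[te$block == b])
    isi <- diff(on) - 0.75
    expect_true(all(isi >= 2 - 1e-9 & isi <= 2.5 + 1e-9))
  }
  # 2.5 s silence between each short stream and its test block
  for (b in 1:8) {
    str_end <- segs$start[segs$kind == "StructuredStream" &
                            !is.na(segs$block) & segs$block == b] +
      segs$duration[segs$kind == "StructuredStream" &
                      !is.na(segs$block) & segs$block == b]
    first_test <- min(te$onset_s[te$block == b])
    expect_equal(first_test - str_end, 2.5)
  }
})

test_that("lexicon and events tables round-trip through TSV", {
  lex <- build_lexicon("B")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, p)
  df <- read_tsv(p)
  expect_equal(nrow(df), 48L)          # 16 triplets x 3 positions
  # seed-invariant: test words don't depend on RNG state
  set.seed(99); tw1 <- make_test_words(lex)
  set.seed(7); tw2 <- make_test_words(lex)
  expect_identical(tw1, tw2)
  sch <- build_session_schedule(lex, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch, p2)
  ev <- read_events_tsv(p2)
  expect_equal(ev$onset_s, sch$events$onset_s)
  expect_equal(ev$token, sch$events$token)
})

test_that("stream audit reports counts and flags", {
  lex <- build_lexicon("A")
  s <- generate_structured_stream(lex, 180, seed = 2)
  a <- audit_stream(s, lex)
  expect_equal(a$word_counts, rep(60L, 4L))
  expect_equal(sum(a$part_word_counts), 239L)   # one per word transition
  expect_output(print(a), "between-word TP")
})
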