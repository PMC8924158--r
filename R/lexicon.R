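# Lexicons and test words for the artificial-language segmentation task.
#
# Each of the three stimulus lists defines four trisyllabic pseudo-words
# built from 12 distinct consonant-vowel syllables. Word i has syllables
# (A_i, B_i, C_i). Test triplets cross two violations: transitional
# probability (last transition heard in the stream or not) and ordinal
# position (syllables at their trained within-word rank or not):
#   Word      A_i B_i C_i   heard,   positions correct
#   EdgeWord  A_i B_i C_k   unheard, positions correct
#   PartWord  B_i C_i A_k   heard,   positions shifted
#   NonWord   B_i C_i A_i   unheard, positions shifted
# The partner index k is i + 1 (mod 4), fixed per list.

# Word inventories per list, one row per word, syllables A, B, C.
.lexicon_table <- list(
  A = matrix(c("di", "na", "po",
               "lu", "ti", "va",
               "fo", "bu", "mi",
               "sa", "zo", "gu"), ncol = 3, byrow = TRUE),
  B = matrix(c("na", "po", "lu",
               "ti", "va", "fo",
               "bu", "mi", "sa",
               "zo", "gu", "di"), ncol = 3, byrow = TRUE),
  C = matrix(c("po", "lu", "ti",
               "va", "fo", "bu",
               "mi", "sa", "zo",
               "gu", "di", "na"), ncol = 3, byrow = TRUE)
)

# Partner word for Edge-words (replacement C_k) and Part-words (appended
# A_k): the next word in list order, wrapping around.
.partner_index <- function(i) i %% 4L + 1L

#' Build a stimulus lexicon
#'
#' Returns one of the three fixed lists of four trisyllabic pseudo-words.
#' Every syllable is consonant-vowel and occurs in exactly one word and one
#' within-word position; the lists permute the syllable-to-role assignment
#' so that conditions are acoustically counterbalanced across participants.
#'
#' @param list_id One of `"A"`, `"B"`, `"C"`.
#' @return An object of class `lexicon` with elements `list_id`, `words`
#'   (character vector of 4 concatenated words), `syllables` (4 x 3 matrix
#'   of syllables, columns A/B/C), and `syllable_duration` (0.25 s).
#' @examples
#' lex <- build_lexicon("A")
#' lex$words
#' @export
build_lexicon <- function(list_id) {
  if (!is.character(list_id) || length(list_id) != 1L ||
      !list_id %in% names(.lexicon_table)) {
    stopf("unknown list_id %s; valid ids are: %s",
          deparse(substitute(list_id)),
          paste(names(.lexicon_table), collapse = ", "))
  }
  syl <- .lexicon_table[[list_id]]
  colnames(syl) <- c("A", "B", "C")
  all_syl <- as.vector(syl)
  if (length(all_syl) != 12L || anyDuplicated(all_syl) ||
      !all(grepl("^[^aeiou][aeiou]$", all_syl))) {
    stopf("internal lexicon table for list %s is malformed", list_id)
  }
  structure(
    list(list_id = list_id,
         words = apply(syl, 1L, paste0, collapse = ""),
         syllables = syl,
         syllable_duration = 0.25),
    class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> list %s: %s\n", x$list_id,
              paste(x$words, collapse = ", ")))
  invisible(x)
}

#' Build the 16 test triplets for a lexicon
#'
#' Four triplets per condition (Word, EdgeWord, PartWord, NonWord), fixed by
#' the list; the output is independent of any RNG state.
#'
#' @param lexicon A [build_lexicon()] object.
#' @return A data frame with one row per triplet: `condition`, `triplet`
#'   (concatenated syllables), `syl1`, `syl2`, `syl3`, `word_index` (the
#'   source word i), `partner_index` (k for Edge- and Part-words, `NA`
#'   otherwise).
#' @export
make_test_words <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  syl <- lexicon$syllables
  rows <- list()
  for (i in 1:4) {
    k <- .partner_index(i)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = c("Word", "EdgeWord", "PartWord", "NonWord"),
      syl1 = c(syl[i, 1], syl[i, 1], syl[i, 2], syl[i, 2]),
      syl2 = c(syl[i, 2], syl[i, 2], syl[i, 3], syl[i, 3]),
      syl3 = c(syl[i, 3], syl[k, 3], syl[k, 1], syl[i, 1]),
      word_index = i,
      partner_index = c(NA, k, k, NA),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$triplet <- paste0(out$syl1, out$syl2, out$syl3)
  out <- out[order(match(out$condition,
                         c("Word", "EdgeWord", "PartWord", "NonWord")),
                   out$word_index), ]
  rownames(out) <- NULL
  out[, c("condition", "triplet", "syl1", "syl2", "syl3",
          "word_index", "partner_index")]
}

#' Write a lexicon and its test words as TSV
#'
#' One row per (word, position) for the lexicon proper, followed by the test
#' triplets; the table round-trips losslessly through [read_tsv()].
#'
#' @param lexicon A [build_lexicon()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  tw <- make_test_words(lexicon)
  long <- data.frame(
    word_index = rep(tw$word_index, each = 3L),
    position = rep(1:3, nrow(tw)),
    syllable = as.vector(t(as.matrix(tw[, c("syl1", "syl2", "syl3")]))),
    condition = rep(tw$condition, each = 3L),
    stringsAsFactors = FALSE)
  write_tsv(long, path)
}
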