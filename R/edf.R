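# Minimal European Data Format (EDF) writer/reader plus TSV/JSON sidecars.
#
# None of the available packages reads EDF, so the subset needed here is
# implemented directly: one data record per second, 16-bit samples,
# integer physical limits per channel. The true sample count is stored in
# the header's reserved field so that recordings whose duration is not a
# whole number of seconds round-trip without trailing padding.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field too wide: '%s'", x)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF with sidecars
#'
#' Writes `<base>.edf` (16-bit EDF), `<base>_events.tsv` (events sidecar),
#' `<base>_montage.tsv` and `<base>_meta.json` (rate, sample count,
#' segment table). Data are quantized to the 16-bit grid spanned by each
#' channel's rounded physical range.
#'
#' @param recording An `eeg_recording`.
#' @param base Path prefix (no extension).
#' @return `base`, invisibly.
#' @export
write_recording <- function(recording, base) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  rate <- recording$rate
  if (rate != round(rate)) stopf("EDF writer requires an integer rate")
  n_ch <- nrow(data)
  n <- ncol(data)
  spr <- as.integer(rate)            # samples per 1 s record
  n_rec <- as.integer(ceiling(n / spr))
  pmin_ <- floor(apply(data, 1L, min))
  pmax_ <- ceiling(apply(data, 1L, max))
  same <- pmax_ <= pmin_
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(paste0(base, ".edf"), "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.01", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (n_ch + 1L), 8),
    .edf_pad(sprintf("n=%d", n), 44),
    .edf_pad(n_rec, 8), .edf_pad(1L, 8), .edf_pad(n_ch, 4))
  labels <- paste0(vapply(rownames(data), .edf_pad, "", width = 16),
                   collapse = "")
  sig <- paste0(
    labels,
    paste0(vapply(rep("", n_ch), .edf_pad, "", width = 80), collapse = ""),
    paste0(vapply(rep("uV", n_ch), .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(pmin_, .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(pmax_, .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep(dmin, n_ch), .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep(dmax, n_ch), .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep("", n_ch), .edf_pad, "", width = 80), collapse = ""),
    paste0(vapply(rep(spr, n_ch), .edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep("", n_ch), .edf_pad, "", width = 32), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((data - pmin_) * scale + dmin)
  if (n_rec * spr > n) {
    dig <- cbind(dig, matrix(0L, n_ch, n_rec * spr - n))
  }
  # record-major layout: per record, each signal's samples in sequence
  out <- integer(n_rec * spr * n_ch)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    out[pos + seq_len(spr * n_ch)] <- as.integer(t(dig[, idx, drop = FALSE]))
    pos <- pos + spr * n_ch
  }
  writeBin(out, con, size = 2L, endian = "little")

  ev <- recording$events
  ev$sample <- NULL                    # derived; recomputed on read
  write_events_tsv(ev, paste0(base, "_events.tsv"))
  write_montage_tsv(recording$montage, paste0(base, "_montage.tsv"))
  jsonlite::write_json(list(rate = rate, n_samples = n,
                            segments = recording$segments),
                       paste0(base, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path prefix used when writing.
#' @return An `eeg_recording` (data restored to 16-bit precision).
#' @export
read_recording <- function(base) {
  edf_path <- paste0(base, ".edf")
  if (!file.exists(edf_path)) stopf("EDF file not found: %s", edf_path)
  for (sc in c("_events.tsv", "_montage.tsv", "_meta.json")) {
    if (!file.exists(paste0(base, sc))) {
      stopf("missing sidecar: expected %s", paste0(base, sc))
    }
  }
  con <- file(edf_path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  rd(80 * n_ch); rd(8 * n_ch)
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(80 * n_ch)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(32 * n_ch)
  if (length(unique(spr)) != 1L) stopf("heterogeneous sampling rates")
  rate <- spr[1L] / rec_dur

  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  if (!isTRUE(all.equal(meta$rate, rate))) {
    stopf("rate mismatch: EDF header says %g Hz, sidecar says %g Hz",
          rate, meta$rate)
  }
  raw <- readBin(con, "integer", n = n_rec * spr[1L] * n_ch, size = 2L,
                 signed = TRUE, endian = "little")
  data <- matrix(0, n_ch, n_rec * spr[1L])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    blk <- matrix(raw[pos + seq_len(spr[1L] * n_ch)], spr[1L], n_ch)
    data[, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <- t(blk)
    pos <- pos + spr[1L] * n_ch
  }
  n_true <- if (grepl("^n=", reserved)) {
    as.integer(sub("^n=", "", reserved))
  } else {
    ncol(data)
  }
  data <- data[, seq_len(n_true), drop = FALSE]
  data <- (data - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  rownames(data) <- labels
  ev <- read_events_tsv(paste0(base, "_events.tsv"))
  ev$sample <- as.integer(round(ev$onset_s * rate)) + 1L
  montage <- read_montage_tsv(paste0(base, "_montage.tsv"))
  structure(list(data = data, rate = rate, events = ev,
                 segments = as.data.frame(meta$segments),
                 montage = montage, config = NULL, components = NULL),
            class = "eeg_recording")
}
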