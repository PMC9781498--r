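# Minimal EDF (European Data Format) support: continuous multichannel
# recordings with a common sampling rate, 16-bit samples, one data
# record per second. Enough for resting-state EEG interchange; no
# annotations, no per-channel rates.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param data channels x samples numeric matrix.
#' @param labels channel labels (length = nrow(data)).
#' @param fs_hz sampling rate; samples are split into 1-s data records,
#'   truncating any trailing partial second.
#' @param path output file.
#' @param physical_unit unit string stored per channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, labels, fs_hz, path, physical_unit = "uV") {
  stopifnot(is.matrix(data), length(labels) == nrow(data))
  ns <- nrow(data)
  spr <- as.integer(round(fs_hz))
  n_rec <- floor(ncol(data) / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  data <- data[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(vapply(x, edf_pad, "", width = width),
                                            collapse = ""),
                                     con, eos = NULL)
  wr("0", 8)                                   # version
  wr("synthetic", 80)                          # patient id
  wr("synthetic", 80)                          # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256 * (ns + 1)), 8)          # header bytes
  wr("", 44)                                   # reserved
  wr(as.character(n_rec), 8)
  wr("1", 8)                                   # record duration (s)
  wr(as.character(ns), 4)
  wr(labels, 16)
  wr(rep("EEG", ns), 80)                       # transducer
  wr(rep(physical_unit, ns), 8)
  wr(formatC(pmin_, format = "g", digits = 7), 8)
  wr(formatC(pmax_, format = "g", digits = 7), 8)
  wr(rep(as.character(dmin), ns), 8)
  wr(rep(as.character(dmax), ns), 8)
  wr(rep("", ns), 80)                          # prefiltering
  wr(rep(as.character(spr), ns), 8)
  wr(rep("", ns), 32)                          # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- seq((r - 1) * spr + 1, r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written with a common per-channel sampling rate.
#' @return list with `data` (channels x samples), `labels`, `fs_hz`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("per-channel sampling rates differ; not supported")
  seek(con, header_bytes)
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, seq((r - 1) * spr[1] + 1, r * spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  list(data = data, labels = labels, fs_hz = spr[1] / rec_dur)
}
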