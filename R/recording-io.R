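#' An EEG recording container
#'
#' @param data channels x samples numeric matrix.
#' @param labels channel labels matching the rows.
#' @param fs_hz sampling rate in Hz.
#' @param reference reference-electrode note (metadata only).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels, fs_hz = 250,
                          reference = "right earlobe") {
  stopifnot(is.matrix(data), length(labels) == nrow(data))
  rownames(data) <- labels
  structure(list(data = data, labels = labels, fs_hz = fs_hz,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  invisible(x)
}

#' Read a resting-state EEG recording
#'
#' Accepts either a delimited numeric matrix (rows = samples, header =
#' electrode labels; comma or tab separated) or an EDF file. Channel
#' labels must match the expected montage exactly (case-insensitive);
#' rows are reordered to the montage order. Recordings shorter than
#' `min_duration_s` are accepted but flagged with a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"delim"` or `"edf"`.
#' @param fs_hz sampling rate for delimited input (EDF carries its own).
#' @param expected_labels montage the labels must cover.
#' @param min_duration_s minimum expected duration (default 5 min).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "delim", "edf"),
                           fs_hz = 250, expected_labels = tracefc_montage(),
                           min_duration_s = 300) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delim"
  if (format == "edf") {
    e <- read_edf(path)
    data <- e$data; labels <- e$labels; fs_hz <- e$fs_hz
  } else {
    d <- data.table::fread(path, data.table = FALSE)
    labels <- names(d)
    data <- t(as.matrix(d))
  }
  lab_up <- toupper(trimws(labels))
  exp_up <- toupper(expected_labels)
  missing <- setdiff(exp_up, lab_up)
  if (length(missing))
    stop("recording is missing expected electrode(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(lab_up, exp_up)
  if (length(extra))
    stop("recording has unknown electrode label(s): ",
         paste(extra, collapse = ", "))
  data <- data[match(exp_up, lab_up), , drop = FALSE]
  rec <- eeg_recording(data, expected_labels, fs_hz)
  if (ncol(data) / fs_hz < min_duration_s) {
    warning(sprintf("recording is %.1f s, shorter than the expected %g s",
                    ncol(data) / fs_hz, min_duration_s))
    attr(rec, "short") <- TRUE
  }
  rec
}

#' Write a recording
#'
#' Delimited output stores samples as rows under a label header, with
#' full 17-significant-digit precision so a write/read round trip is
#' bit-identical. EDF output quantizes to 16 bits.
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param format `"auto"` (by extension), `"delim"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "delim", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delim"
  if (format == "edf") {
    write_edf(rec$data, rec$labels, rec$fs_hz, path)
  } else {
    chars <- as.data.frame(apply(t(rec$data), 2, sprintf, fmt = "%.17g"),
                           stringsAsFactors = FALSE)
    names(chars) <- rec$labels
    data.table::fwrite(chars, path, quote = FALSE)
  }
  invisible(path)
}
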