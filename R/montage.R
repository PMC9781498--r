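#' Standard 32-electrode 10-20 montage
#'
#' Electrode labels for the 32-channel gel cap assumed throughout the
#' package, in acquisition order. All Table-style pair labels (e.g.
#' `"T7-CP6"`) refer to this set.
#'
#' @return Character vector of 32 unique 10-20 labels.
#' @export
tracefc_montage <- function() {
  c("FP1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "PZ", "PO3", "O1", "OZ",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "FP2", "FZ", "CZ")
}

#' All unordered electrode pairs of a montage
#'
#' @param labels electrode labels (default the standard 32-channel montage,
#'   giving the 496 = C(32,2) pairs used for connectivity analysis).
#' @return data.frame with integer columns `i`, `j` (i < j) and a `pair`
#'   label column `"A-B"`.
#' @export
electrode_pairs <- function(labels = tracefc_montage()) {
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  idx <- utils::combn(length(labels), 2L)
  data.frame(
    i = idx[1L, ], j = idx[2L, ],
    pair = paste(labels[idx[1L, ]], labels[idx[2L, ]], sep = "-"),
    stringsAsFactors = FALSE
  )
}
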