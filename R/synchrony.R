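#' Analysis window over 1-s epochs
#'
#' The connectivity index for each electrode pair and center frequency
#' is the maximum per-epoch synchronization value inside a window of
#' `window_epochs` epochs starting `offset_s` seconds into the
#' recording (defaults: a 2-min window after a 30-s settling offset,
#' out of a 5-min recording's 300 epochs).
#'
#' @param epoch_s epoch length in seconds.
#' @param offset_s offset of the analysis window from recording start.
#' @param window_epochs number of epochs in the window.
#' @param full_epochs nominal number of epochs in a full recording.
#' @return object of class `analysis_window`.
#' @export
analysis_window <- function(epoch_s = 1, offset_s = 30, window_epochs = 120,
                            full_epochs = 300) {
  if (offset_s %% epoch_s != 0)
    stop("offset_s must be a whole number of epochs")
  structure(list(epoch_s = epoch_s, offset_s = offset_s,
                 window_epochs = as.integer(window_epochs),
                 full_epochs = as.integer(full_epochs)),
            class = "analysis_window")
}

metric_names <- function() {
  c("phase_clustering", "spectral_coherence", "imag_coherence", "pli", "wpli")
}

#' Per-epoch synchronization between two analytic signals
#'
#' Computes one of five synchronization estimators over consecutive
#' non-overlapping epochs of `epoch_s` seconds, from the cross spectrum
#' `S = x * Conj(y)`:
#' \describe{
#'   \item{phase_clustering}{`|mean(exp(i dphi))|` (PLV).}
#'   \item{pli}{`|mean(sign(Im exp(i dphi)))|`, with `sign(0) = 0`.}
#'   \item{wpli}{`|mean(Im S)| / mean(|Im S|)`, 0 when the denominator
#'     is 0.}
#'   \item{spectral_coherence}{`|mean S|^2 / (mean|x|^2 * mean|y|^2)`.}
#'   \item{imag_coherence}{`|Im(mean S / sqrt(mean|x|^2 * mean|y|^2))|`.}
#' }
#' All are symmetric in (x, y) and bounded in \[0, 1\].
#'
#' @param x,y equal-length complex vectors (analytic signals at one
#'   center frequency).
#' @param metric one of `metric_names()`.
#' @param fs_hz sampling rate.
#' @param epoch_s epoch length in seconds.
#' @return numeric vector, one value per complete epoch.
#' @export
epoch_synchrony <- function(x, y, metric = metric_names(), fs_hz = 250,
                            epoch_s = 1) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("x and y must have equal length")
  spe <- as.integer(round(fs_hz * epoch_s))
  n_ep <- length(x) %/% spe
  if (n_ep < 1) stop("signals shorter than one epoch")
  idx <- seq_len(n_ep * spe)
  S <- matrix(x[idx] * Conj(y[idx]), spe, n_ep)
  px <- matrix(Mod(x[idx])^2, spe, n_ep)
  py <- matrix(Mod(y[idx])^2, spe, n_ep)
  epoch_stat(metric, S, colMeans(px), colMeans(py))
}

# metric value per epoch from the cross-spectrum matrix S
# (samples-per-epoch x n_epochs) and per-epoch mean powers.
epoch_stat <- function(metric, S, mpx, mpy) {
  switch(metric,
    phase_clustering = {
      modS <- Mod(S)
      U <- S
      nz <- modS > 0
      U[nz] <- S[nz] / modS[nz]
      U[!nz] <- 0
      Mod(colMeans(U))
    },
    pli = abs(colMeans(sign(Im(S)))),
    wpli = {
      num <- abs(colMeans(Im(S)))
      den <- colMeans(abs(Im(S)))
      ifelse(den > 0, num / den, 0)
    },
    spectral_coherence = {
      den <- mpx * mpy
      ifelse(den > 0, Mod(colMeans(S))^2 / den, 0)
    },
    imag_coherence = {
      den <- sqrt(mpx * mpy)
      ifelse(den > 0, abs(Im(colMeans(S))) / den, 0)
    },
    stop("unknown metric: ", metric))
}

#' Peak-detected connectivity index from an epoch series
#'
#' The single connectivity index for a (pair, center frequency) cell is
#' the maximum per-epoch value inside the analysis window.
#'
#' @param epoch_series numeric vector of per-epoch synchronization values.
#' @param window an [analysis_window()].
#' @return the window maximum.
#' @export
peak_index <- function(epoch_series, window = analysis_window()) {
  stopifnot(inherits(window, "analysis_window"))
  off <- as.integer(window$offset_s / window$epoch_s)
  need <- off + window$window_epochs
  if (length(epoch_series) < need)
    stop(sprintf("epoch series has %d epochs; window needs %d",
                 length(epoch_series), need))
  max(epoch_series[(off + 1):need])
}

#' Full connectivity-index table for one recording
#'
#' Runs the connectivity stage end to end: FIR bandpass front end,
#' Morlet filter bank, per-epoch synchronization for every unordered
#' electrode pair at every center frequency, and peak detection over the
#' analysis window. Deterministic for a fixed input.
#'
#' @param rec an [eeg_recording()] (>= `offset + window` seconds long).
#' @param metrics subset of `metric_names()` to compute.
#' @param scheme a [band_scheme()].
#' @param window an [analysis_window()].
#' @param bandpass `c(lo, hi)` for the FIR front end, or `NULL` to skip.
#' @param keep_epochs if `TRUE`, also return the per-epoch tensors
#'   (`pairs x centers x epochs` per metric).
#' @return object of class `connectivity_result`: list with `index`
#'   (data.frame `pair, center_hz, metric, value`), `pairs`, `centers_hz`,
#'   `n_epochs`, and (optionally) `epochs`, a named list of 3-d arrays.
#' @export
connectivity_pipeline <- function(rec, metrics = metric_names(),
                                  scheme = band_scheme(),
                                  window = analysis_window(),
                                  bandpass = c(1, 45),
                                  keep_epochs = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  fs <- rec$fs_hz
  spe <- as.integer(round(fs * window$epoch_s))
  n_ep <- ncol(rec$data) %/% spe
  need <- as.integer(window$offset_s / window$epoch_s) + window$window_epochs
  if (n_ep < need)
    stop(sprintf("recording has %d epochs; analysis window needs %d",
                 n_ep, need))
  if (!is.null(bandpass))
    rec <- fir_bandpass(rec, bandpass[1], bandpass[2])
  pairs <- electrode_pairs(rec$labels)
  bank <- morlet_filterbank(scheme, fs)
  centers <- vapply(bank, `[[`, 0, "center_hz")
  n_pair <- nrow(pairs)

  tensors <- lapply(metrics, function(m)
    array(NA_real_, c(n_pair, length(bank), n_ep),
          dimnames = list(pairs$pair, centers, NULL)))
  names(tensors) <- metrics

  block_ep <- max(1L, min(n_ep, 2400000L %/% (spe * n_pair) + 1L))
  for (w in seq_along(bank)) {
    A <- t(analytic_signal(rec, bank[[w]]))  # samples x channels
    for (b0 in seq(1L, n_ep, by = block_ep)) {
      b1 <- min(b0 + block_ep - 1L, n_ep)
      rows <- ((b0 - 1L) * spe + 1L):(b1 * spe)
      nb <- b1 - b0 + 1L
      Ab <- A[rows, , drop = FALSE]
      S <- Ab[, pairs$i, drop = FALSE] * Conj(Ab[, pairs$j, drop = FALSE])
      P <- Mod(Ab)^2
      mp <- colMeans_by_epoch(P, spe, nb)          # nb x channels
      mpx <- t(mp[, pairs$i, drop = FALSE])        # pairs x nb
      mpy <- t(mp[, pairs$j, drop = FALSE])
      for (m in metrics) {
        vals <- epoch_stat_block(m, S, spe, nb, mpx, mpy)  # pairs x nb
        tensors[[m]][, w, b0:b1] <- vals
      }
    }
  }

  idx <- do.call(rbind, lapply(metrics, function(m) {
    peak <- apply_window_max(tensors[[m]], window)
    data.frame(pair = rep(pairs$pair, times = length(centers)),
               center_hz = rep(centers, each = n_pair),
               metric = m,
               value = as.vector(peak),
               stringsAsFactors = FALSE)
  }))
  out <- list(index = idx, pairs = pairs, centers_hz = centers,
              n_epochs = n_ep, window = window, metrics = metrics)
  if (keep_epochs) out$epochs <- tensors
  structure(out, class = "connectivity_result")
}

# column means over consecutive sample blocks: X is (spe*nb) x k
colMeans_by_epoch <- function(X, spe, nb) {
  k <- ncol(X)
  dim(X) <- c(spe, nb * k)
  m <- .colMeans(X, spe, nb * k)
  matrix(m, nb, k)
}

# block version of epoch_stat: S is (spe*nb) x pairs; returns pairs x nb
epoch_stat_block <- function(metric, S, spe, nb, mpx, mpy) {
  ep_means <- function(X) t(colMeans_by_epoch(X, spe, nb))
  switch(metric,
    phase_clustering = {
      modS <- Mod(S)
      re <- Re(S); im <- Im(S)
      nz <- modS > 0
      re[nz] <- re[nz] / modS[nz]; re[!nz] <- 0
      im[nz] <- im[nz] / modS[nz]; im[!nz] <- 0
      sqrt(ep_means(re)^2 + ep_means(im)^2)
    },
    pli = abs(ep_means(sign(Im(S)))),
    wpli = {
      im <- Im(S)
      num <- abs(ep_means(im))
      den <- ep_means(abs(im))
      out <- num * 0
      pos <- den > 0
      out[pos] <- num[pos] / den[pos]
      out
    },
    spectral_coherence = {
      num <- ep_means(Re(S))^2 + ep_means(Im(S))^2
      den <- mpx * mpy
      out <- num * 0
      pos <- den > 0
      out[pos] <- num[pos] / den[pos]
      out
    },
    imag_coherence = {
      num <- abs(ep_means(Im(S)))
      den <- sqrt(mpx * mpy)
      out <- num * 0
      pos <- den > 0
      out[pos] <- num[pos] / den[pos]
      out
    },
    stop("unknown metric: ", metric))
}

apply_window_max <- function(tensor, window) {
  off <- as.integer(window$offset_s / window$epoch_s)
  sel <- (off + 1):(off + window$window_epochs)
  apply(tensor[, , sel, drop = FALSE], c(1, 2), max)
}

#' Connectivity index table as a pairs x centers matrix
#'
#' @param conn a `connectivity_result`.
#' @param metric which metric to extract.
#' @return 496 x 15 matrix (rows = pair labels, columns = centers).
#' @export
connectivity_matrix <- function(conn, metric) {
  stopifnot(inherits(conn, "connectivity_result"))
  d <- conn$index[conn$index$metric == metric, ]
  if (!nrow(d)) stop("metric not present: ", metric)
  matrix(d$value, nrow = nrow(conn$pairs),
         dimnames = list(conn$pairs$pair, conn$centers_hz))
}

#' Write a connectivity index table
#'
#' @param conn a `connectivity_result`.
#' @param path output CSV with columns `pair,center_hz,metric,value`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(conn, path) {
  data.table::fwrite(conn$index, path)
  invisible(path)
}
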