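#' A single tracing trial
#'
#' Bundles one trial's pointer trajectory with the track section it was
#' traced against.
#'
#' @param section section id (1..8).
#' @param direction `"forward"` or `"reverse"` along the section.
#' @param trace matrix or data.frame with columns `x`, `y` (pixels) and
#'   `t` (seconds, strictly increasing, starting at 0).
#' @param track two-column polyline of the section, oriented in the
#'   traced direction (start vertex first).
#' @return object of class `trial_record`.
#' @export
trial_record <- function(section, direction, trace, track) {
  direction <- match.arg(direction, c("forward", "reverse"))
  if (is.matrix(trace)) trace <- as.data.frame(trace)
  stopifnot(all(c("x", "y", "t") %in% names(trace)))
  if (nrow(trace) < 1) stop("trace must be non-empty")
  if (any(diff(trace$t) <= 0)) stop("trace timestamps must be strictly increasing")
  if (trace$t[1] != 0) stop("trace time must start at 0")
  structure(list(section = as.integer(section), direction = direction,
                 trace = trace, track = as_xy(track),
                 dwell_required_s = 1.0),
            class = "trial_record")
}

#' Score one tracing trial
#'
#' Computes the position error (area between trace and track, converted
#' to cm^2), the tracing time (first motion to the start of the 1-s
#' dwell at the destination vertex), the endpoint penalty (per-sample
#' offsets from the destination accumulated between first arrival inside
#' the arrival radius and the start of the dwell, converted through the
#' linear pixel scale), and the position-time product. Trials whose
#' pointer never comes to rest at the destination are flagged
#' incomplete.
#'
#' @param trial a `trial_record`.
#' @param pixel_area_cm2 physical area per pixel (default 0.25 mm^2).
#' @param dwell_radius_px radius around the destination vertex counting
#'   as "at the vertex".
#' @param motion_threshold_px displacement from the start vertex that
#'   defines the trial-time origin.
#' @param penalty_timing whether the endpoint penalty is added to the
#'   position error before multiplying by time (`"pre"`, default) or
#'   added after the multiplication (`"post"`).
#' @return object of class `trial_score`: list with
#'   `position_error_cm2`, `trace_time_s`, `endpoint_penalty_cm2`,
#'   `pos_time_cm2s`, `incomplete`.
#' @export
score_trial <- function(trial, pixel_area_cm2 = 0.0025, dwell_radius_px = 5,
                        motion_threshold_px = 1,
                        penalty_timing = c("pre", "post")) {
  stopifnot(inherits(trial, "trial_record"))
  penalty_timing <- match.arg(penalty_timing)
  tr <- trial$trace
  dest <- trial$track[nrow(trial$track), ]
  start <- trial$track[1, ]
  d_dest <- sqrt((tr$x - dest[1])^2 + (tr$y - dest[2])^2)
  d_start <- sqrt((tr$x - start[1])^2 + (tr$y - start[2])^2)
  n <- nrow(tr)
  dwell_s <- trial$dwell_required_s

  # start of dwell: first sample i such that every later sample up to
  # t_i + dwell_s is within the radius, and that much time was recorded
  within <- d_dest <= dwell_radius_px
  # last index of the final run of consecutive within==TRUE samples
  dwell_start <- NA_integer_
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    if (within[i]) {
      if (is.na(run_start)) run_start <- i
      if (tr$t[i] - tr$t[run_start] >= dwell_s) { dwell_start <- run_start; break }
    } else run_start <- NA_integer_
  }
  incomplete <- is.na(dwell_start)
  if (incomplete) dwell_start <- n

  i0 <- which(d_start > motion_threshold_px)
  i0 <- if (length(i0)) i0[1] else 1L
  t0 <- tr$t[i0]
  trace_time_s <- max(tr$t[dwell_start] - t0, 0)

  # tracing portion: from first motion to start of dwell
  seg <- tr[min(i0, dwell_start):dwell_start, , drop = FALSE]
  area_px2 <- if (nrow(seg) >= 2)
    position_error(cbind(seg$x, seg$y), trial$track) else 0
  position_error_cm2 <- area_px2 * pixel_area_cm2

  # endpoint penalty: samples after first arrival-radius crossing until
  # the dwell begins, each contributing its offset from the destination
  pixel_scale_cm <- sqrt(pixel_area_cm2)
  arrive <- which(within)
  arrive <- if (length(arrive)) arrive[1] else dwell_start
  pen_idx <- if (dwell_start > arrive) seq(arrive, dwell_start - 1L) else integer(0)
  endpoint_penalty_cm2 <- sum(d_dest[pen_idx]) * pixel_scale_cm

  pos_time_cm2s <- if (penalty_timing == "pre")
    (position_error_cm2 + endpoint_penalty_cm2) * trace_time_s
  else position_error_cm2 * trace_time_s + endpoint_penalty_cm2

  structure(list(position_error_cm2 = position_error_cm2,
                 trace_time_s = trace_time_s,
                 endpoint_penalty_cm2 = endpoint_penalty_cm2,
                 pos_time_cm2s = pos_time_cm2s,
                 incomplete = incomplete),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf(
    "<trial_score> pos %.4g cm^2, time %.3g s, penalty %.4g, pos-time %.4g cm^2 s%s\n",
    x$position_error_cm2, x$trace_time_s, x$endpoint_penalty_cm2,
    x$pos_time_cm2s, if (x$incomplete) " [incomplete]" else ""))
  invisible(x)
}

trial_metric <- function(scores, metric = c("pos", "pos_time")) {
  metric <- match.arg(metric)
  if (inherits(scores, "trial_score")) scores <- list(scores)
  if (is.list(scores))
    scores <- vapply(scores, function(s)
      if (metric == "pos") s$position_error_cm2 else s$pos_time_cm2s, 0)
  as.numeric(scores)
}

#' Summarize a training session into behavioral measures
#'
#' Sessions of (nominally 90) trial scores are reduced either to the
#' median over all trials (single-median option) or to the medians of
#' the first 30 and last 30 trials (dual-median option, separating
#' pre- and post-training performance within the session). Even-count
#' medians use the usual midpoint-of-two convention.
#'
#' @param scores numeric vector of per-trial values, or a list of
#'   `trial_score` objects combined with `metric`.
#' @param metric which per-trial value to summarize when `scores` are
#'   `trial_score` objects: `"pos"` or `"pos_time"`.
#' @param option `"single"` (needs >= 1 trial) or `"dual"` (needs >= 60
#'   trials).
#' @param block number of trials in each dual-median block.
#' @return object of class `session_performance`: list with `metric`,
#'   `option`, `n_trials` and either `single_median` or
#'   `dual_median_pre` / `dual_median_post`.
#' @export
summarize_session <- function(scores, metric = c("pos", "pos_time"),
                              option = c("single", "dual"), block = 30L) {
  metric <- match.arg(metric)
  option <- match.arg(option)
  v <- trial_metric(scores, metric)
  if (option == "single") {
    if (length(v) < 1) stop("single-median option needs at least one trial")
    out <- list(metric = metric, option = option, n_trials = length(v),
                single_median = stats::median(v))
  } else {
    if (length(v) < 2 * block)
      stop(sprintf("dual-median option needs at least %d trials", 2 * block))
    out <- list(metric = metric, option = option, n_trials = length(v),
                dual_median_pre = stats::median(v[seq_len(block)]),
                dual_median_post = stats::median(v[seq(length(v) - block + 1,
                                                       length(v))]))
  }
  structure(out, class = "session_performance")
}

#' SD-Ratio diagnostic over the first trials of a session
#'
#' Ratio of the standard deviation of tracing performance over the first
#' `n` trials to the corresponding median of those trials; used to judge
#' how many trials are needed for a stable performance estimate.
#'
#' @param scores per-trial values (or `trial_score` list).
#' @param n number of leading trials to use.
#' @param metric see [summarize_session()].
#' @return non-negative ratio (0 for constant trials).
#' @export
sd_ratio <- function(scores, n, metric = c("pos", "pos_time")) {
  v <- trial_metric(scores, match.arg(metric))
  if (n < 2 || n > length(v)) stop("n must be in 2..number of trials")
  v <- v[seq_len(n)]
  m <- stats::median(v)
  if (m == 0) {
    if (stats::sd(v) == 0) return(0)
    stop("median of first trials is zero; SD-Ratio undefined")
  }
  stats::sd(v) / m
}
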