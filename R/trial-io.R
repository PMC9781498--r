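#' Read a session's tracing-trial log
#'
#' Trial logs are delimited text with columns
#' `trial,section,direction,t,x,y`, one file per session. Each trial's
#' rows are matched with its track section polyline (oriented by the
#' logged direction) to form [trial_record()]s.
#'
#' @param path CSV file.
#' @param track `track_pattern` the trials were traced against.
#' @return list of `trial_record`, ordered by trial number.
#' @export
read_trial_log <- function(path, track) {
  stopifnot(inherits(track, "track_pattern"))
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("trial", "section", "direction", "t", "x", "y")
  if (!all(need %in% names(d)))
    stop("trial log must have columns ", paste(need, collapse = ","))
  lapply(split(d, d$trial)[as.character(sort(unique(d$trial)))], function(g) {
    g <- g[order(g$t), ]
    trial_record(g$section[1], g$direction[1],
                 data.frame(x = g$x, y = g$y, t = g$t - g$t[1]),
                 track_section(track, g$section[1], g$direction[1]))
  })
}

#' Write a session's tracing-trial log
#'
#' @param trials list of `trial_record`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i, section = tr$section, direction = tr$direction,
               t = tr$trace$t, x = tr$trace$x, y = tr$trace$y)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Write session behavioral summaries
#'
#' @param summaries data.frame with columns `session,metric,option,value`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_session_summary <- function(summaries, path) {
  stopifnot(all(c("session", "metric", "option", "value") %in% names(summaries)))
  data.table::fwrite(summaries, path)
  invisible(path)
}
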