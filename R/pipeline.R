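#' Default run configuration
#'
#' @param sessions list of per-session input lists with elements `pre`,
#'   `post` (EEG files) and `trials` (trial-log CSV).
#' @param out_dir output directory.
#' @param ... overrides of the defaults (see Details).
#' @details Tunables and defaults: `track` (extents/pixel area),
#'   `fs_hz = 250`, `centers_hz` (default scheme), `wavelet_cycles = 7`,
#'   `window` (epoch 1 s, offset 30 s, 120-epoch window),
#'   `bandpass = c(1, 45)`, `metrics` (all five),
#'   `pls = list(n_perm = 2000, n_boot = 1000, n_reps = 50, frac = 0.8,
#'   bsr_threshold = 2, target_power = 0.8, alpha = 0.05)`, `seed = 1`,
#'   `cache = TRUE`.
#' @return config list of class `run_config`.
#' @export
run_config <- function(sessions, out_dir, ...) {
  cfg <- list(
    sessions = sessions, out_dir = out_dir,
    track = list(extent_x_px = 1000, extent_y_px = 700,
                 pixel_area_cm2 = 0.0025),
    fs_hz = 250,
    centers_hz = NULL, wavelet_cycles = 7,
    window = list(epoch_s = 1, offset_s = 30, window_epochs = 120,
                  full_epochs = 300),
    bandpass = c(1, 45),
    metrics = metric_names(),
    pls = list(n_perm = 2000, n_boot = 1000, n_reps = 50, frac = 0.8,
               bsr_threshold = 2, target_power = 0.8, alpha = 0.05,
               n_latent = 1),
    seed = 1L, cache = TRUE, cache_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with at least a `sessions` block; all other
#'   keys override [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sessions)) stop("config must list sessions")
  sessions <- lapply(y$sessions, function(s)
    if (!is.null(s$files)) s$files else s)
  extra <- y[setdiff(names(y), c("sessions"))]
  do.call(run_config, c(list(sessions = sessions,
                             out_dir = y$out_dir %||% "tracefc-out"),
                        extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[sort(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

connectivity_cached <- function(path, cfg, scheme, window) {
  key <- NULL
  if (isTRUE(cfg$cache)) {
    cache_dir <- cfg$cache_dir %||% file.path(cfg$out_dir, "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    key <- file.path(cache_dir, paste0(
      unname(tools::md5sum(path)), "-",
      config_hash(list(metrics = cfg$metrics, scheme = scheme,
                       window = window, bandpass = cfg$bandpass)), ".rds"))
    if (file.exists(key)) return(readRDS(key))
  }
  rec <- read_recording(path, fs_hz = cfg$fs_hz,
                        min_duration_s = window$offset_s +
                          window$window_epochs * window$epoch_s)
  conn <- connectivity_pipeline(rec, metrics = cfg$metrics, scheme = scheme,
                                window = window, bandpass = cfg$bandpass)
  if (!is.null(key)) saveRDS(conn, key)
  conn
}

#' Run the full individualized analysis for one participant
#'
#' Scores every session's tracing trials into the four behavioral
#' variants, computes peak-detected connectivity indices for the pre-
#' and post-training recordings of every session, searches the
#' candidate grid for the best model, and writes the leaderboard, the
#' serialized best model, the per-session estimated-vs-actual table and
#' a run manifest to the output directory. Sessions with missing or
#' unreadable inputs are dropped with a warning; fewer than 4 usable
#' sessions aborts the run.
#'
#' @param config a [run_config()], or path to a YAML file for
#'   [read_run_config()].
#' @return (invisibly) list with `search` (the
#'   [model_search()] result), `behavior`, `conn`, `dropped`, `files`.
#' @export
run_participant <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  track <- build_track(cfg$track$extent_x_px, cfg$track$extent_y_px,
                       pixel_area_cm2 = cfg$track$pixel_area_cm2)
  scheme <- band_scheme(centers_hz = cfg$centers_hz,
                        wavelet_cycles = cfg$wavelet_cycles)
  window <- do.call(analysis_window, cfg$window)

  usable <- list(); dropped <- integer(0)
  for (s in seq_along(cfg$sessions)) {
    se <- cfg$sessions[[s]]
    res <- tryCatch({
      trials <- read_trial_log(se$trials, track)
      scores <- lapply(trials, score_trial,
                       pixel_area_cm2 = cfg$track$pixel_area_cm2)
      conn <- list(pre = connectivity_cached(se$pre, cfg, scheme, window),
                   post = connectivity_cached(se$post, cfg, scheme, window))
      list(scores = scores, conn = conn)
    }, error = function(e) {
      warning(sprintf("dropping session %d: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) dropped <- c(dropped, s) else usable[[length(usable) + 1]] <- res
  }
  if (length(usable) < 4)
    stop(sprintf("only %d usable session(s); at least 4 required",
                 length(usable)))

  behavior <- behavior_table(lapply(usable, `[[`, "scores"))
  centers <- scheme$center_hz
  n_pair <- nrow(usable[[1]]$conn$pre$pairs)
  conn <- lapply(c(pre = "pre", post = "post"), function(cond) {
    out <- lapply(cfg$metrics, function(m) {
      arr <- array(NA_real_, c(length(usable), n_pair, length(centers)),
                   dimnames = list(NULL, usable[[1]]$conn[[cond]]$pairs$pair,
                                   centers))
      for (s in seq_along(usable))
        arr[s, , ] <- connectivity_matrix(usable[[s]]$conn[[cond]], m)
      arr
    })
    names(out) <- cfg$metrics
    out
  })

  search <- model_search(conn, behavior,
                         n_perm = cfg$pls$n_perm, n_boot = cfg$pls$n_boot,
                         n_reps = cfg$pls$n_reps, frac = cfg$pls$frac,
                         bsr_threshold = cfg$pls$bsr_threshold,
                         target_power = cfg$pls$target_power,
                         alpha = cfg$pls$alpha,
                         n_latent = cfg$pls$n_latent, seed = cfg$seed)

  files <- list(leaderboard = file.path(cfg$out_dir, "leaderboard.csv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  data.table::fwrite(search$leaderboard, files$leaderboard)
  if (!is.null(search$best_model)) {
    files$model <- file.path(cfg$out_dir, "model.json")
    write_model_json(search, files$model)
    files$estimates <- file.path(cfg$out_dir, "estimates.csv")
    ev <- search$best_evaluation
    data.table::fwrite(data.frame(session = seq_len(ev$n),
                                  actual = ev$actual,
                                  estimated = ev$loo_predictions),
                       files$estimates)
  }
  manifest <- list(config_hash = config_hash(unclass(cfg)),
                   seed = cfg$seed,
                   n_sessions_used = length(usable),
                   dropped_sessions = dropped,
                   metrics = cfg$metrics, centers_hz = centers,
                   window = cfg$window, pls = cfg$pls,
                   best = if (!is.null(search$best))
                     as.list(search$best) else NULL)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(search = search, behavior = behavior, conn = conn,
                 dropped = dropped, files = files, config = cfg))
}
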