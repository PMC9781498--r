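#' Behavioral measures per session
#'
#' Computes all four behavioral variants (single/dual median for both
#' the position-only and position-time metrics) for a list of sessions.
#' Dual medians are kept separately for the first-30 (pre-training) and
#' last-30 (post-training) blocks: the pre block is correlated with
#' pre-training EEG and the post block with post-training EEG.
#'
#' @param session_scores list (one element per session) of numeric
#'   trial-score containers accepted by [summarize_session()]; for
#'   `trial_score` lists both metrics are extracted.
#' @return data.frame with one row per session and columns
#'   `single_pos`, `single_pos_time`, `dual_pre_pos`, `dual_post_pos`,
#'   `dual_pre_pos_time`, `dual_post_pos_time`.
#' @export
behavior_table <- function(session_scores) {
  rows <- lapply(seq_along(session_scores), function(s) {
    sc <- session_scores[[s]]
    one <- function(metric) {
      sm <- summarize_session(sc, metric, "single")$single_median
      du <- summarize_session(sc, metric, "dual")
      c(single = sm, pre = du$dual_median_pre, post = du$dual_median_post)
    }
    pos <- one("pos"); pt <- one("pos_time")
    data.frame(session = s,
               single_pos = pos["single"], dual_pre_pos = pos["pre"],
               dual_post_pos = pos["post"],
               single_pos_time = pt["single"], dual_pre_pos_time = pt["pre"],
               dual_post_pos_time = pt["post"], row.names = NULL)
  })
  do.call(rbind, rows)
}

behavior_for <- function(behavior, option, metric, condition) {
  col <- if (option == "single") paste0("single_", metric)
  else paste0("dual_", if (condition == "pre") "pre_" else "post_", metric)
  if (!col %in% names(behavior)) stop("behavior table lacks column ", col)
  behavior[[col]]
}

#' Assemble a design matrix for one candidate model
#'
#' @param conn named list `condition -> metric -> array` of connectivity
#'   indices with dimensions sessions x pairs x centers (dimnames on
#'   pairs and centers).
#' @param behavior a [behavior_table()].
#' @param metric synchronization metric name.
#' @param center_hz center frequency (matched against the array's
#'   center dimnames).
#' @param condition `"pre"` or `"post"` EEG.
#' @param option `"single"` or `"dual"` behavioral option.
#' @param behavior_metric `"pos"` or `"pos_time"`.
#' @return list with `X` (sessions x 496) and `y`.
#' @export
design_matrix <- function(conn, behavior, metric, center_hz, condition,
                          option, behavior_metric) {
  arr <- conn[[condition]][[metric]]
  if (is.null(arr)) stop("no connectivity data for ", condition, "/", metric)
  ci <- match(as.character(center_hz), dimnames(arr)[[3]])
  if (is.na(ci)) stop("center frequency not in connectivity data: ", center_hz)
  X <- arr[, , ci, drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = dim(arr)[1])
  colnames(X) <- dimnames(arr)[[2]]
  list(X = X, y = behavior_for(behavior, option, behavior_metric, condition))
}

#' Search the candidate grid for the best individualized model
#'
#' Runs the full selection procedure over every candidate combination of
#' synchronization metric, center frequency, EEG condition (pre/post)
#' and behavioral option: PLSC permutation screening (candidates with
#' `p_perm >= alpha` are not modeled), bootstrap-consensus channel
#' selection, power-constrained pruning and leave-one-out evaluation.
#' The winner is the modeled candidate with the smallest RMSE
#' percentage, ties broken by fewer channels and then lower permutation
#' p-value.
#'
#' @param conn,behavior as in [design_matrix()].
#' @param metrics,centers_hz,conditions,options,behavior_metrics grid
#'   axes; defaults cover everything present in `conn`.
#' @param n_perm,n_boot,n_reps,frac,bsr_threshold,target_power,alpha
#'   selection parameters (see [plsc()], [consensus_channels()],
#'   [prune_channels()]).
#' @param n_latent latent components used for pruning and evaluation;
#'   the default 1 reflects that a single behavioral variable with
#'   strongly collinear consensus channels supports one predictive
#'   latent variable (`NULL` uses the [plsr_fit()] default
#'   `min(k, n - 2)`).
#' @param seed integer seed; each candidate gets an independent derived
#'   stream, so results are reproducible.
#' @return object of class `model_search_result`: `best` (row of the
#'   leaderboard or NULL), `best_model`, `best_evaluation`,
#'   `leaderboard` (one row per grid cell).
#' @export
model_search <- function(conn, behavior,
                         metrics = NULL, centers_hz = NULL,
                         conditions = NULL,
                         options = c("single", "dual"),
                         behavior_metrics = c("pos", "pos_time"),
                         n_perm = 2000, n_boot = 1000, n_reps = 50,
                         frac = 0.8, bsr_threshold = 2,
                         target_power = 0.8, alpha = 0.05,
                         n_latent = 1, seed = 1L) {
  if (is.null(conditions)) conditions <- names(conn)
  if (is.null(metrics)) metrics <- names(conn[[conditions[1]]])
  if (is.null(centers_hz))
    centers_hz <- dimnames(conn[[conditions[1]]][[metrics[1]]])[[3]]
  grid <- expand.grid(metric = metrics, center_hz = centers_hz,
                      condition = conditions, option = options,
                      behavior_metric = behavior_metrics,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  evals <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cand <- grid[g, ]
    dm <- design_matrix(conn, behavior, cand$metric, cand$center_hz,
                        cand$condition, cand$option, cand$behavior_metric)
    cand_seed <- (seed + 104729 * g) %% .Machine$integer.max
    row <- data.frame(cand, p_perm = NA_real_, k = NA_integer_,
                      r2 = NA_real_, power = NA_real_, rmse_pct = NA_real_,
                      slope = NA_real_, channels = NA_character_,
                      stringsAsFactors = FALSE)
    ok <- tryCatch({
      fit <- suppressWarnings(
        plsc(dm$X, dm$y, n_perm = n_perm, n_boot = 0, seed = cand_seed))
      row$p_perm <- fit$p_perm
      TRUE
    }, error = function(e) FALSE)
    if (ok && !is.na(row$p_perm) && row$p_perm < alpha) {
      cons <- suppressMessages(suppressWarnings(
        consensus_channels(dm$X, dm$y, n_reps = n_reps, frac = frac,
                           bsr_threshold = bsr_threshold, n_boot = n_boot,
                           seed = cand_seed + 1)))
      if (length(cons$channels)) {
        pr <- suppressWarnings(
          prune_channels(dm$X[, cons$channels, drop = FALSE], dm$y,
                         target_power = target_power, alpha = alpha,
                         n_latent = n_latent))
        row$k <- length(pr$channels)
        row$r2 <- pr$model$r2
        row$power <- pr$power
        row$rmse_pct <- pr$evaluation$rmse_pct
        row$slope <- pr$evaluation$slope
        row$channels <- paste(pr$channels, collapse = ";")
        models[[g]] <- pr$model
        evals[[g]] <- pr$evaluation
      }
    }
    rows[[g]] <- row
  }
  leaderboard <- do.call(rbind, rows)
  scored <- which(!is.na(leaderboard$rmse_pct))
  best <- NULL; best_model <- NULL; best_eval <- NULL
  if (length(scored)) {
    ord <- scored[order(leaderboard$rmse_pct[scored],
                        leaderboard$k[scored],
                        leaderboard$p_perm[scored])]
    best <- leaderboard[ord[1], ]
    best_model <- models[[ord[1]]]
    best_eval <- evals[[ord[1]]]
  }
  structure(list(best = best, best_model = best_model,
                 best_evaluation = best_eval, leaderboard = leaderboard),
            class = "model_search_result")
}

#' @export
print.model_search_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<model_search_result> no candidate passed screening\n")
  } else {
    b <- x$best
    cat(sprintf(
      "<model_search_result> best: %s @ %s Hz, %s EEG, %s %s | k=%d, R2=%.3f, LOO RMSE %.2f%%\n",
      b$metric, b$center_hz, b$condition, b$option, b$behavior_metric,
      b$k, b$r2, b$rmse_pct))
  }
  invisible(x)
}

#' Serialize a selected model to JSON
#'
#' @param search a `model_search_result` with a non-NULL best model.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(search, path) {
  stopifnot(inherits(search, "model_search_result"))
  if (is.null(search$best_model)) stop("no model to serialize")
  m <- search$best_model
  b <- search$best
  ev <- search$best_evaluation
  obj <- list(
    metric = b$metric, center_hz = as.numeric(b$center_hz),
    eeg_condition = b$condition,
    behavior = list(option = b$option, metric = b$behavior_metric),
    channels = as.list(stats::setNames(as.numeric(m$coefficients),
                                       names(m$coefficients))),
    intercept = m$intercept,
    scaling = list(x_center = as.list(stats::setNames(m$x_center, m$features)),
                   x_scale = as.list(stats::setNames(m$x_scale, m$features)),
                   y_center = m$y_center),
    n_latent = m$n_latent,
    evaluation = list(r2 = m$r2, power = b$power, p_perm = b$p_perm,
                      rmse = ev$rmse, rmse_pct = ev$rmse_pct,
                      slope = ev$slope, n = ev$n, k = ev$k)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
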