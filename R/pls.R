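#' PLS correlation between behavior and connectivity features
#'
#' For a single behavioral variable the brain-behavior cross-correlation
#' is a vector, so its SVD has one latent pair: the salience vector is
#' the unit-normalized correlation profile `cor(y, X)` and the singular
#' value is its Euclidean norm. Significance is assessed by permuting
#' the behavior labels; robustness by bootstrap resampling of sessions,
#' summarized per feature as the bootstrap ratio (salience divided by
#' its bootstrap standard error).
#'
#' @param X sessions x features numeric matrix (column names carry the
#'   (pair, center) identity). Columns are z-scored internally.
#' @param y behavioral value per session.
#' @param n_perm number of label permutations (`0` skips the test).
#' @param n_boot number of bootstrap resamples (`0` skips).
#' @param seed optional integer; fixing it makes the result bit-identical.
#' @return object of class `plsc_result`: `saliences` (unit norm),
#'   `singular_value`, `p_perm`, `bootstrap_ratios`, `features`,
#'   `dropped` (zero-variance columns removed with a warning).
#' @export
plsc <- function(X, y, n_perm = 2000, n_boot = 1000, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("PLSC needs at least 4 sessions")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (stats::sd(y) == 0) stop("behavior y has zero variance")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) stop("no features left after dropping zero-variance columns")

  run <- function() {
    Xs <- scale(X)
    ys <- as.vector(scale(y))
    r <- as.vector(crossprod(Xs, ys)) / (n - 1)
    sv <- sqrt(sum(r^2))
    sal <- if (sv > 0) r / sv else r
    p_perm <- NA_real_
    if (n_perm > 0) {
      Yp <- vapply(seq_len(n_perm), function(b) ys[sample.int(n)], numeric(n))
      svp <- sqrt(colSums((crossprod(Xs, Yp) / (n - 1))^2))
      p_perm <- (1 + sum(svp >= sv)) / (1 + n_perm)
    }
    bsr <- rep(NA_real_, ncol(X))
    if (n_boot > 0) {
      B <- matrix(NA_real_, ncol(X), n_boot)
      for (b in seq_len(n_boot)) {
        for (try in 1:50) {
          idx <- sample.int(n, replace = TRUE)
          if (stats::sd(y[idx]) > 0) break
        }
        rb <- suppressWarnings(stats::cor(X[idx, , drop = FALSE], y[idx]))
        rb[is.na(rb)] <- 0
        nb <- sqrt(sum(rb^2))
        B[, b] <- if (nb > 0) rb / nb else rb
      }
      se <- apply(B, 1, stats::sd)
      bsr <- ifelse(se > 0, sal / se, 0)
    }
    list(sal = sal, sv = sv, p = p_perm, bsr = bsr)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  structure(list(saliences = stats::setNames(res$sal, colnames(X)),
                 singular_value = res$sv,
                 p_perm = res$p,
                 bootstrap_ratios = stats::setNames(res$bsr, colnames(X)),
                 features = colnames(X), dropped = dropped,
                 n_perm = n_perm, n_boot = n_boot, n = n),
            class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  cat(sprintf("<plsc_result> %d features, n=%d, singular value %.3f, p_perm %s\n",
              length(x$features), x$n, x$singular_value,
              format.pval(x$p_perm)))
  invisible(x)
}

#' Bootstrap-consensus channel selection
#'
#' Repeats the PLSC bootstrap with independent resampling streams and
#' keeps the features whose absolute bootstrap ratio exceeds
#' `bsr_threshold` in more than `frac` of the repetitions.
#'
#' @param X,y design matrix and behavior as in [plsc()].
#' @param n_reps number of repetitions.
#' @param frac consensus fraction; a feature is kept when its selection
#'   fraction is strictly greater than `frac`.
#' @param bsr_threshold absolute bootstrap-ratio cutoff (default 2.0,
#'   about a 95% normal interval).
#' @param n_boot bootstrap resamples per repetition.
#' @param seed optional integer seed for the whole procedure.
#' @return object of class `consensus_result`: `channels` (selected
#'   feature names, possibly empty), `fraction` (per-feature selection
#'   fraction), plus the parameters.
#' @export
consensus_channels <- function(X, y, n_reps = 50, frac = 0.8,
                               bsr_threshold = 2, n_boot = 1000,
                               seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  seeds <- if (is.null(seed)) rep(list(NULL), n_reps)
  else as.list((seed + 9973 * seq_len(n_reps)) %% .Machine$integer.max)
  hits <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (r in seq_len(n_reps)) {
    fit <- suppressWarnings(
      plsc(X, y, n_perm = 0, n_boot = n_boot, seed = seeds[[r]]))
    sel <- names(fit$bootstrap_ratios)[abs(fit$bootstrap_ratios) >= bsr_threshold]
    hits[sel] <- hits[sel] + 1
  }
  fraction <- hits / n_reps
  channels <- names(fraction)[fraction > frac]
  if (!length(channels))
    message("consensus selection is empty (no feature exceeded |BSR| >= ",
            bsr_threshold, " in more than ", round(100 * frac),
            "% of repetitions)")
  structure(list(channels = channels, fraction = fraction,
                 n_reps = n_reps, frac = frac,
                 bsr_threshold = bsr_threshold, n_boot = n_boot),
            class = "consensus_result")
}

#' PLS1 regression with iterative deflation
#'
#' Single-response partial least squares: per component, the weight
#' vector is the (normalized) covariance between the deflated predictors
#' and response; scores, loadings and a rank-one deflation follow, and
#' the latent-space coefficients are mapped back to the feature space.
#' Predictors are z-scored and the response mean-centered; both
#' transformations are stored in the model.
#'
#' @param X sessions x features matrix (consensus-restricted features).
#' @param y response per session.
#' @param n_latent number of latent components; default
#'   `min(ncol(X), nrow(X) - 2)` (at least 1). A warning is issued when
#'   `n_latent > nrow(X) - 2`.
#' @return object of class `plsr_model`: feature-space `coefficients`
#'   (original scale) with `intercept`, standardized coefficients
#'   `coef_std`, `n_latent`, centering/scaling vectors, in-sample `r2`
#'   and `fitted`.
#' @export
plsr_fit <- function(X, y, n_latent = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  my <- mean(y)
  if (p == 0 || stats::sd(y) == 0) {
    # mean-only fallback: constant response or no predictors
    fitted <- rep(my, n)
    return(structure(list(coefficients = stats::setNames(numeric(p), colnames(X)),
                          intercept = my,
                          coef_std = stats::setNames(numeric(p), colnames(X)),
                          n_latent = 0L, x_center = mx, x_scale = sx,
                          y_center = my, r2 = if (stats::sd(y) == 0) 1 else 0,
                          fitted = fitted, features = colnames(X)),
                     class = "plsr_model"))
  }
  if (is.null(n_latent)) n_latent <- max(1L, min(p, n - 2L))
  if (n_latent > n - 2)
    warning("n_latent > n - 2; model may be overfit")
  if (n_latent > min(p, n)) stop("n_latent exceeds the achievable rank")

  Xd <- sweep(sweep(X, 2, mx), 2, sx, "/")
  yd <- y - my
  W <- P <- matrix(0, p, 0)
  qv <- numeric(0)
  for (h in seq_len(n_latent)) {
    w <- as.vector(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- as.vector(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pl <- as.vector(crossprod(Xd, t_)) / tt
    q <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pl)
    yd <- yd - t_ * q
    W <- cbind(W, w); P <- cbind(P, pl); qv <- c(qv, q)
  }
  if (!ncol(W)) {
    b_std <- numeric(p)
  } else {
    b_std <- as.vector(W %*% solve(crossprod(P, W), qv))
  }
  b <- b_std / sx
  intercept <- my - sum(b * mx)
  fitted <- as.vector(X %*% b) + intercept
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else 1
  structure(list(coefficients = stats::setNames(b, colnames(X)),
                 intercept = intercept,
                 coef_std = stats::setNames(b_std, colnames(X)),
                 n_latent = ncol(W), x_center = mx, x_scale = sx,
                 y_center = my, r2 = r2, fitted = fitted,
                 features = colnames(X)),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$coefficients) == 0) return(rep(object$intercept, nrow(newdata)))
  if (!is.null(colnames(newdata)) && all(object$features %in% colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  else if (ncol(newdata) != length(object$coefficients))
    stop("newdata does not match the model's features")
  as.vector(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d feature(s), %d latent component(s), R2 = %.4f\n",
              length(x$coefficients), x$n_latent, x$r2))
  invisible(x)
}

#' Leave-one-out evaluation of a PLS regression
#'
#' Each session is held out in turn, the model refit on the remainder
#' (with centering/scaling recomputed inside the fold) and the held-out
#' session predicted. The RMSE over held-out predictions is also
#' expressed as a percentage of the mean behavior, and a zero-intercept
#' least-squares line of estimated versus actual summarizes calibration.
#'
#' @param X,y design matrix and behavior.
#' @param n_latent latent components per fold; default
#'   `min(ncol(X), n_fold - 2)`.
#' @return object of class `model_evaluation`: `loo_predictions`,
#'   `rmse`, `rmse_pct`, `slope` (zero-intercept estimated-vs-actual),
#'   `n`, `k`.
#' @export
loo_evaluate <- function(X, y, n_latent = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 sessions")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- plsr_fit(X[-i, , drop = FALSE], y[-i], n_latent = n_latent)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  rmse <- sqrt(mean((preds - y)^2))
  rmse_pct <- if (mean(y) != 0) 100 * rmse / mean(y) else NA_real_
  slope <- if (sum(y^2) > 0) sum(y * preds) / sum(y^2) else NA_real_
  structure(list(loo_predictions = preds, actual = y, rmse = rmse,
                 rmse_pct = rmse_pct, slope = slope, n = n, k = ncol(X)),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "<model_evaluation> n=%d, k=%d: LOO RMSE %.4g (%.2f%% of mean), slope %.3f\n",
    x$n, x$k, x$rmse, x$rmse_pct, x$slope))
  invisible(x)
}

#' Statistical power of a multiple regression
#'
#' Power of the overall F test at level `alpha` for a regression with
#' `k` predictors and `n` observations achieving coefficient of
#' determination `R2`, via Cohen's effect size `f2 = R2 / (1 - R2)` and
#' the noncentral F distribution with `df1 = k`, `df2 = n - k - 1` and
#' noncentrality `f2 * n`.
#'
#' @param r2 in-sample R-squared, in (0, 1) (0 is allowed as the null
#'   limit, where the power equals `alpha`).
#' @param n number of observations.
#' @param k number of predictors; requires `n > k + 1`.
#' @param alpha test level.
#' @return power in \[0, 1\].
#' @export
regression_power <- function(r2, n, k, alpha = 0.05) {
  if (n <= k + 1) stop("power undefined: need n > k + 1")
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  f2 <- r2 / (1 - r2)
  lambda <- f2 * n
  crit <- stats::qf(1 - alpha, k, n - k - 1)
  1 - stats::pf(crit, k, n - k - 1, ncp = lambda)
}

#' Power-constrained channel pruning
#'
#' Starting from the consensus channel set, fits a PLS regression,
#' computes the power of the overall F test from the in-sample R2, and
#' while the power is below `target_power` removes the channel with the
#' smallest absolute standardized coefficient (ties broken by column
#' order) and refits, stopping when the target is met or one channel
#' remains. Channel counts exceeding `n - 2` are treated as
#' under-powered and pruned unconditionally.
#'
#' @param X,y design matrix (consensus channels) and behavior.
#' @param target_power required power (default 0.8).
#' @param alpha test level.
#' @param n_latent latent components (default `min(k, n - 2)` at each
#'   step).
#' @return list with `model` (final [plsr_fit()]), `evaluation`
#'   ([loo_evaluate()] on the final channel set), `power`, `power_met`,
#'   `channels`, and `history` (data.frame of k, R2, power per step).
#' @export
prune_channels <- function(X, y, target_power = 0.8, alpha = 0.05,
                           n_latent = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!ncol(X)) stop("initial channel set is empty")
  n <- nrow(X)
  keep <- colnames(X)
  history <- NULL
  repeat {
    Xk <- X[, keep, drop = FALSE]
    fit <- plsr_fit(Xk, y, n_latent = n_latent)
    k <- length(keep)
    pw <- if (n > k + 1)
      regression_power(min(fit$r2, 1 - 1e-12), n, k, alpha) else NA_real_
    history <- rbind(history,
                     data.frame(k = k, r2 = fit$r2, power = pw))
    done <- !is.na(pw) && pw >= target_power
    if (done || k == 1) {
      if (!done)
        warning("target power not reached with a single channel")
      ev <- loo_evaluate(Xk, y, n_latent = n_latent)
      return(list(model = fit, evaluation = ev, power = pw,
                  power_met = done, channels = keep, history = history))
    }
    drop_ix <- which.min(abs(fit$coef_std))  # first index on ties
    keep <- keep[-drop_ix]
  }
}
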