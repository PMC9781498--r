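# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Even-odd scanline rasterization of the region between two polylines:
# closes the trace-forward / track-backward polygon and sums covered
# scanline lengths on a grid of step h.
raster_area <- function(trace, track, h = 0.1, npoly = 800) {
  A <- tracefc::resample_polyline(trace, npoly)
  C <- tracefc::resample_polyline(track, npoly)
  poly <- rbind(A, C[nrow(C):1, ])
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  ys <- seq(min(y1) - h, max(y1) + h, by = h)
  tot <- 0
  for (y in ys) {
    cr <- which((y1 <= y & y2 > y) | (y2 <= y & y1 > y))
    if (!length(cr)) next
    xs <- sort(x1[cr] + (y - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr]))
    if (length(xs) %% 2 == 0)
      tot <- tot + sum(xs[seq(2, length(xs), 2)] - xs[seq(1, length(xs), 2)])
  }
  tot * h
}

# smooth tapered perturbation of a polyline (windowed, correlated
# noise). Draws are rejected if the perturbed trace intersects itself:
# the even-odd rasterization oracle counts overlapping sub-loops once
# while the area definition sums them, so the two agree only on simple
# traces (the regime of real pointer trajectories).
smooth_perturb <- function(base, sd_px, m = 150, k = 25) {
  pts <- tracefc::resample_polyline(base, m)
  win <- sin(pi * seq(0, 1, length.out = m))
  g <- function() {
    v <- stats::filter(stats::rnorm(m), rep(1 / k, k), circular = TRUE)
    as.vector(scale(as.numeric(v)))
  }
  for (try in 1:50) {
    out <- pts + cbind(g(), g()) * (sd_px * win)
    if (!polyline_self_intersects(out)) return(out)
  }
  out
}

polyline_self_intersects <- function(p) {
  n <- nrow(p) - 1L
  ax <- p[1:n, 1]; ay <- p[1:n, 2]
  bx <- p[2:(n + 1), 1]; by <- p[2:(n + 1), 2]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    d1 <- (bx[i] - ax[i]) * (ay[j] - ay[i]) - (by[i] - ay[i]) * (ax[j] - ax[i])
    d2 <- (bx[i] - ax[i]) * (by[j] - ay[i]) - (by[i] - ay[i]) * (bx[j] - ax[i])
    d3 <- (bx[j] - ax[j]) * (ay[i] - ay[j]) - (by[j] - ay[j]) * (ax[i] - ax[j])
    d4 <- (bx[j] - ax[j]) * (by[i] - ay[j]) - (by[j] - ay[j]) * (bx[i] - ax[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# textbook PLS1: standardize, iterate weight/score/loading deflation,
# and accumulate predictions in score space (no coefficient
# back-mapping) — an independent route to the same estimator.
ref_pls1_predict <- function(X, y, n_latent, Xnew) {
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd); sx[sx == 0] <- 1
  Xc <- scale(X, mx, sx); yc <- y - mean(y)
  Xn <- scale(Xnew, mx, sx)
  pred <- rep(mean(y), nrow(Xn))
  for (h in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2)); if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2); if (tt < 1e-12) break
    p <- crossprod(Xc, t_) / tt
    q <- sum(yc * t_) / tt
    tn <- Xn %*% w
    pred <- pred + as.vector(tn) * q
    Xc <- Xc - t_ %*% t(p); yc <- yc - as.vector(t_) * q
    Xn <- Xn - tn %*% t(p)
  }
  as.vector(pred)
}

# design matrix with 3 planted channels (coupling SNR snr) among noise
planted_design <- function(n = 8, p = 496, snr = 5, seed = 1,
                           y = NULL) {
  withr::with_seed(seed, {
    if (is.null(y)) y <- seq(5.6, 7.8, length.out = n) + stats::rnorm(n, 0, 0.1)
    X <- matrix(stats::rnorm(n * p), n, p)
    for (j in 1:3)
      X[, j] <- scale(y)[, 1] + stats::rnorm(n, 0, 1 / snr)
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = y, planted = paste0("f", 1:3))
  })
}

# complex white-noise "analytic" signal (iid circular phases)
cwn <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
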