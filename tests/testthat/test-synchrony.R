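test_that("synchronization metrics reproduce hand-worked values", {
  # phase-difference signs +,-,+,+ over one 4-sample epoch: PLI = 1/2
  x <- exp(1i * c(0.5, -0.5, 0.5, 0.5))
  y <- rep(1 + 0i, 4)
  expect_equal(epoch_synchrony(x, y, "pli", fs_hz = 4), 0.5,
               tolerance = 1e-12)
  # Im(S) = (2, -1, 3): wPLI = |2-1+3| / (2+1+3) = 2/3
  x2 <- complex(imaginary = c(2, -1, 3))
  y2 <- rep(1 + 0i, 3)
  expect_equal(epoch_synchrony(x2, y2, "wpli", fs_hz = 3), 4 / 6,
               tolerance = 1e-12)
  # constant lag pi/3: unit-modulus mean
  ph <- 2 * pi * 10 * (1:250) / 250
  xc <- exp(1i * (ph + pi / 3)); yc <- exp(1i * ph)
  expect_equal(epoch_synchrony(xc, yc, "phase_clustering"), 1,
               tolerance = 1e-12)
  expect_equal(epoch_synchrony(xc, yc, "pli"), 1, tolerance = 1e-12)
  # identical signals: sign(0) = 0 and real coherency
  z <- cwn(250)
  expect_equal(epoch_synchrony(z, z, "pli"), 0, tolerance = 1e-12)
  expect_equal(epoch_synchrony(z, z, "imag_coherence"), 0, tolerance = 1e-12)
  expect_equal(epoch_synchrony(z, z, "spectral_coherence"), 1,
               tolerance = 1e-12)
  expect_error(epoch_synchrony(z, z[1:100], "pli"), "equal length")
})

test_that("metrics respect ranges, symmetry and amplitude invariance", {
  withr::with_seed(31, {
    n_ep <- 200
    x <- cwn(250 * n_ep); y <- cwn(250 * n_ep)
    amp <- rep(exp(rnorm(n_ep)), each = 250)  # positive per-epoch scaling
    for (m in metric_names()) {
      v <- epoch_synchrony(x, y, m)
      expect_true(all(v >= 0 & v <= 1 + 1e-12), info = m)
      expect_equal(epoch_synchrony(y, x, m), v, tolerance = 1e-12, info = m)
    }
    for (m in c("pli", "wpli", "phase_clustering"))
      expect_equal(epoch_synchrony(x * amp, y, m),
                   epoch_synchrony(x, y, m), tolerance = 1e-12, info = m)
    expect_equal(epoch_synchrony(x * 3.7, y * 0.2, "spectral_coherence"),
                 epoch_synchrony(x, y, "spectral_coherence"),
                 tolerance = 1e-12)
  })
})

test_that("white-noise PLV follows the sqrt(pi/4)/sqrt(n) null regime", {
  withr::with_seed(17, {
    n_ep <- 400
    x <- cwn(500 * n_ep); y <- cwn(500 * n_ep)
    plv250 <- mean(epoch_synchrony(x[1:(250 * n_ep)], y[1:(250 * n_ep)],
                                   "phase_clustering"))
    plv500 <- mean(epoch_synchrony(x, y, "phase_clustering", fs_hz = 500))
    expect_equal(plv250, sqrt(pi / 4) / sqrt(250), tolerance = 0.1)
    expect_equal(plv500, sqrt(pi / 4) / sqrt(500), tolerance = 0.1)
    expect_lt(plv500, plv250)
  })
})

test_that("zero-lag common sources inflate PLV/coherence but not lag metrics", {
  withr::with_seed(41, {
    n <- 250 * 120
    s <- cwn(n)
    x <- s + 0.4 * cwn(n)
    y <- s + 0.4 * cwn(n)
    m <- vapply(metric_names(), function(mm)
      mean(epoch_synchrony(x, y, mm)), 0)
    expect_gt(m["phase_clustering"], 0.7)
    expect_gt(m["spectral_coherence"], 0.7)
    expect_lt(m["pli"], 0.2)
    expect_lt(m["wpli"], 0.2)
    expect_lt(m["imag_coherence"], 0.2)
  })
})

test_that("peak detection takes the maximum inside the analysis window", {
  win <- analysis_window(epoch_s = 1, offset_s = 30, window_epochs = 120)
  expect_equal(peak_index(rep(0.4, 300), win), 0.4)
  ser <- rep(0.1, 300); ser[77] <- 0.9
  expect_equal(peak_index(ser, win), 0.9)
  # spike before the offset is ignored
  ser2 <- rep(0.1, 300); ser2[10] <- 0.95; ser2[40] <- 0.3
  expect_equal(peak_index(ser2, win), 0.3)
  expect_error(peak_index(rep(0.1, 100), win), "window needs")
  expect_error(analysis_window(offset_s = 0.5), "whole number")
})

test_that("connectivity pipeline produces a full deterministic table", {
  labs <- c("C3", "C4", "CZ", "PZ", "FZ", "OZ")
  withr::with_seed(9, {
    data <- matrix(rnorm(6 * 250 * 16), 6)
    data[2, ] <- data[1, ]  # duplicate channel: zero-lag pair
  })
  rec <- eeg_recording(data, labs, 250)
  win <- analysis_window(epoch_s = 1, offset_s = 2, window_epochs = 10,
                         full_epochs = 16)
  conn <- connectivity_pipeline(rec, metrics = c("pli", "wpli"),
                                window = win)
  expect_equal(nrow(conn$index), choose(6, 2) * 15 * 2)
  expect_equal(conn$n_epochs, 16L)
  M <- connectivity_matrix(conn, "pli")
  expect_equal(dim(M), c(15L, 15L))
  expect_true(all(M >= 0 & M <= 1))
  # duplicate channels: every PLI index for that pair is exactly 0
  expect_true(all(M["C3-C4", ] == 0))
  conn2 <- connectivity_pipeline(rec, metrics = c("pli", "wpli"),
                                 window = win)
  expect_identical(conn$index, conn2$index)
  expect_error(connectivity_pipeline(rec, window = analysis_window()),
               "analysis window")
})

test_that("pipeline enumerates all 496 pairs for a 32-channel recording", {
  des <- synthetic_design(seed = 8, duration_s = 8)
  rec <- simulate_recording(des, 1, "pre")
  win <- analysis_window(epoch_s = 1, offset_s = 1, window_epochs = 6,
                         full_epochs = 8)
  conn <- connectivity_pipeline(rec, metrics = "pli", window = win)
  expect_equal(nrow(conn$pairs), 496L)
  expect_equal(nrow(conn$index), 496L * 15L)
  expect_equal(conn$n_epochs, 8L)
  # epoch tensor agrees with the direct per-pair computation
  conn_t <- connectivity_pipeline(rec, metrics = "pli", window = win,
                                  keep_epochs = TRUE)
  bank <- morlet_filterbank()
  a <- analytic_signal(fir_bandpass(rec), bank[[11]])
  direct <- epoch_synchrony(a["T7", ], a["CP6", ], "pli")
  expect_equal(as.vector(conn_t$epochs$pli["T7-CP6", 11, ]), direct,
               tolerance = 1e-9)
})
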