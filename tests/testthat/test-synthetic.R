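test_that("pink noise has a 1/f spectral slope", {
  withr::with_seed(2, x <- pink_noise(2^15, 250))
  expect_equal(mean(x), 0, tolerance = 1e-9)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 250 / length(x)
  lo <- mean(sp[f > 1 & f < 4])
  hi <- mean(sp[f > 16 & f < 64])
  # 1/f power: 16x frequency ratio -> ~16x power ratio
  expect_equal(log2(lo / hi), 4, tolerance = 1.2)
})

test_that("generator output is deterministic under a fixed seed", {
  des <- synthetic_design(seed = 14, duration_s = 4, n_trials = 5)
  expect_identical(simulate_recording(des, 2, "pre")$data,
                   simulate_recording(des, 2, "pre")$data)
  expect_identical(design_behavior(des), design_behavior(des))
  tk <- build_track(500, 350)
  t1 <- simulate_session_trials(des, 1, tk)
  t2 <- simulate_session_trials(des, 1, tk)
  expect_identical(t1[[3]]$trace, t2[[3]]$trace)
  # sessions differ and conditions differ
  expect_false(identical(simulate_recording(des, 1, "pre")$data,
                         simulate_recording(des, 2, "pre")$data))
  expect_false(identical(simulate_recording(des, 1, "pre")$data,
                         simulate_recording(des, 1, "post")$data))
})

test_that("behavior map is linear in coupling with planted noise", {
  des <- synthetic_design(seed = 31, behavior_noise_sd = 0)
  b <- design_behavior(des)
  expect_equal(b, des$behavior_beta[1] + des$behavior_beta[2] * des$coupling,
               tolerance = 1e-12)
  expect_error(synthetic_design(coupling = rep(2, 7)), "0, 1")
  expect_error(synthetic_design(planted_pairs = list(c("QQ", "C3"))),
               "unknown electrode")
})

test_that("simulated trials cover the track sections with valid records", {
  des <- synthetic_design(seed = 6, n_trials = 90, duration_s = 4)
  tk <- build_track(1000, 700)
  trials <- simulate_session_trials(des, 1, tk)
  expect_length(trials, 90L)
  secs <- vapply(trials, `[[`, 0L, "section")
  expect_true(all(secs %in% 1:8))
  expect_gt(length(unique(secs)), 4L)
  for (tr in trials[1:5]) {
    expect_s3_class(tr, "trial_record")
    expect_true(all(diff(tr$trace$t) > 0))
  }
})

test_that("median position error rises monotonically with trace noise", {
  tk <- build_track(1000, 700)
  meds <- vapply(c(0.5, 2, 6), function(b1) {
    des <- synthetic_design(seed = 44, behavior_beta = c(b1, 0),
                            behavior_noise_sd = 0, n_trials = 20,
                            duration_s = 4)
    sc <- vapply(simulate_session_trials(des, 1, tk),
                 function(tr) score_trial(tr)$position_error_cm2, 0)
    median(sc)
  }, 0)
  expect_true(all(diff(meds) > 0))
  # zero skill noise: errors vanish
  des0 <- synthetic_design(seed = 45, behavior_beta = c(0, 0),
                           behavior_noise_sd = 0, n_trials = 5,
                           duration_s = 4)
  sc0 <- vapply(simulate_session_trials(des0, 1, tk),
                function(tr) score_trial(tr)$position_error_cm2, 0)
  # residual area comes only from pointer-rate chord discretization of
  # the curved section (well under a tenth of a cm^2 over a ~34 cm path)
  expect_lt(max(sc0), 0.1)
})

test_that("scored session medians track the planted behavior", {
  des <- synthetic_design(seed = 3, n_trials = 60)
  tk <- build_track(1000, 700)
  b <- design_behavior(des)
  for (s in c(1, 7)) {
    sc <- vapply(simulate_session_trials(des, s, tk),
                 function(tr) score_trial(tr)$position_error_cm2, 0)
    expect_equal(median(sc), b[s], tolerance = 0.15)
  }
})

test_that("planted coupling shows up in peak PLI at the planted cell", {
  des <- synthetic_design(seed = 51, coupling = rep(0.7, 7), duration_s = 80)
  rec <- simulate_recording(des, 1, "pre")
  bank <- morlet_filterbank()
  a <- analytic_signal(fir_bandpass(rec), bank[[11]])  # 21 Hz
  mean_pli <- function(aa, p1, p2)
    mean(epoch_synchrony(aa[p1, ], aa[p2, ], "pli"))
  planted <- vapply(des$planted_pairs, function(pp)
    mean_pli(a, pp[1], pp[2]), 0)
  null_pairs <- list(c("F7", "O2"), c("FP2", "P7"), c("AF3", "CP2"))
  nulls <- vapply(null_pairs, function(pp) mean_pli(a, pp[1], pp[2]), 0)
  expect_gt(min(planted), max(nulls))
  # post-training recording carries no planted coupling
  rec0 <- simulate_recording(des, 1, "post")
  a0 <- analytic_signal(fir_bandpass(rec0), bank[[11]])
  expect_lt(mean_pli(a0, "T7", "CP6"), min(planted))
  # coupling raises the mean epoch synchronization monotonically
  des_lo <- synthetic_design(seed = 51, coupling = rep(0.3, 7),
                             duration_s = 80)
  a_lo <- analytic_signal(fir_bandpass(simulate_recording(des_lo, 1, "pre")),
                          bank[[11]])
  expect_lt(mean_pli(a_lo, "T7", "CP6"), mean_pli(a, "T7", "CP6"))
})

test_that("zero-lag common-source confound spares the lag-based metrics", {
  des <- synthetic_design(seed = 52, coupling = rep(0.9, 7),
                          zero_lag_common = TRUE, duration_s = 40)
  rec <- simulate_recording(des, 1, "pre")
  win <- analysis_window(epoch_s = 1, offset_s = 5, window_epochs = 30,
                         full_epochs = 40)
  bank <- morlet_filterbank()
  a <- analytic_signal(fir_bandpass(rec), bank[[11]])
  m_of <- function(p1, p2, m) mean(epoch_synchrony(a[p1, ], a[p2, ], m))
  # lag-based metrics stay near the narrowband null level (an uncoupled
  # pink-noise pair in the same recording); PLV is inflated well above it
  expect_gt(m_of("T7", "CP6", "phase_clustering"),
            m_of("F7", "O2", "phase_clustering") + 0.2)
  expect_lt(m_of("T7", "CP6", "wpli"), m_of("F7", "O2", "wpli") + 0.15)
  expect_lt(m_of("T7", "CP6", "imag_coherence"),
            m_of("F7", "O2", "imag_coherence") + 0.15)
})

test_that("make_study writes a complete, reproducible participant dataset", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  des <- synthetic_design(seed = 77, n_sessions = 4, duration_s = 3,
                          n_trials = 4)
  st <- make_study(des, dir1)
  expect_equal(nrow(st$sessions), 4L)
  expect_true(all(file.exists(st$sessions$pre, st$sessions$post,
                              st$sessions$trials)))
  expect_true(file.exists(file.path(dir1, "ground_truth.json")))
  expect_true(file.exists(file.path(dir1, "config.yaml")))
  gt <- jsonlite::read_json(file.path(dir1, "ground_truth.json"))
  expect_equal(unlist(gt$planted_pairs),
               c("T7-CP6", "FC1-P4", "C4-P3", "PZ-OZ", "FZ-FC5"))
  expect_equal(gt$planted_center_hz, 21)
  # bit-identical regeneration under the same seed
  make_study(des, dir2)
  f1 <- file.path(dir1, "session-01", "pre.csv")
  f2 <- file.path(dir2, "session-01", "pre.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(
    unname(tools::md5sum(file.path(dir1, "session-02", "trials.csv"))),
    unname(tools::md5sum(file.path(dir2, "session-02", "trials.csv"))))
})
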