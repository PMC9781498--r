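#' 1/f (pink) background noise
#'
#' Spectrally shaped Gaussian noise: a random-phase half spectrum with
#' amplitude proportional to `1/sqrt(f)`, mirrored and inverse
#' transformed, then standardized to zero mean and unit SD.
#'
#' @param n number of samples.
#' @param fs_hz sampling rate (sets the frequency axis only).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs_hz = 250) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs_hz / n
  amp <- 1 / sqrt(f)
  half <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- half
  spec[n:(n - nf + 2)] <- Conj(half[seq_len(nf - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Design of a synthetic longitudinal participant
#'
#' Describes the planted brain-behavior structure used by the simulators:
#' phase coupling at chosen electrode pairs and a center frequency, a
#' per-session coupling strength series `kappa`, a behavior series that
#' is a noisy linear function of `kappa`, and a tracing-skill trajectory
#' derived from the behavior so the simulated trial logs reproduce it.
#'
#' @param n_sessions number of training sessions (study scale 6-8).
#' @param planted_pairs list of electrode label pairs carrying coupling.
#' @param planted_center_hz center frequency of the planted coupling.
#' @param planted_condition which EEG condition (`"pre"`/`"post"`)
#'   carries the coupling.
#' @param coupling per-session coupling strengths `kappa` in \[0, 1\]
#'   (default linearly decreasing, emulating training-related change).
#' @param behavior_beta `c(beta0, beta1)`: behavior
#'   `b = beta0 + beta1 * kappa + eps` in cm^2.
#' @param behavior_noise_sd SD of `eps` (chosen so the planted linear
#'   relation sits in the high-R2 regime).
#' @param osc_amp oscillator amplitude relative to the unit-SD pink
#'   background.
#' @param phase_lag preferred phase lag between the two coupled
#'   electrodes when locked (nonzero so lag-sensitive metrics can
#'   detect it).
#' @param detune_hz natural-frequency detuning between the two planted
#'   oscillators; below the locking threshold the relative phase slips
#'   at rate `detune_hz * sqrt(1 - kappa^2)`.
#' @param phase_noise phase-diffusion SD of the relative phase
#'   (rad / sqrt(s)).
#' @param zero_lag_common if `TRUE`, the planted pairs receive a
#'   zero-lag common source instead of lagged locking (volume-conduction
#'   confound: inflates amplitude-sensitive metrics while PLI/wPLI/
#'   imaginary coherence stay near their null level).
#' @param duration_s recording duration per EEG collection.
#' @param fs_hz sampling rate.
#' @param n_trials tracing trials per session.
#' @param trace_speed_px_s nominal pointer speed for simulated trials.
#' @param seed integer seed making the whole participant reproducible.
#' @return object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_sessions = 7,
                             planted_pairs = list(c("T7", "CP6"),
                                                  c("FC1", "P4"),
                                                  c("C4", "P3"),
                                                  c("PZ", "OZ"),
                                                  c("FZ", "FC5")),
                             planted_center_hz = 21,
                             planted_condition = "pre",
                             coupling = seq(0.72, 0.55,
                                            length.out = n_sessions),
                             behavior_beta = c(2, 8),
                             behavior_noise_sd = 0.15,
                             osc_amp = 1,
                             phase_lag = pi / 4,
                             detune_hz = 1.2,
                             phase_noise = 0.15,
                             zero_lag_common = FALSE,
                             duration_s = 300,
                             fs_hz = 250,
                             n_trials = 90,
                             trace_speed_px_s = 600,
                             seed = 1L) {
  labels <- tracefc_montage()
  for (p in planted_pairs)
    if (!all(p %in% labels))
      stop("planted pair uses unknown electrode(s): ", paste(p, collapse = "-"))
  if (length(coupling) != n_sessions)
    stop("coupling must have one value per session")
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  if (behavior_noise_sd < 0) stop("behavior_noise_sd must be >= 0")
  structure(list(n_sessions = as.integer(n_sessions),
                 planted_pairs = planted_pairs,
                 planted_center_hz = planted_center_hz,
                 planted_condition = planted_condition,
                 coupling = coupling, behavior_beta = behavior_beta,
                 behavior_noise_sd = behavior_noise_sd,
                 osc_amp = osc_amp, phase_lag = phase_lag,
                 detune_hz = detune_hz, phase_noise = phase_noise,
                 zero_lag_common = zero_lag_common,
                 duration_s = duration_s,
                 fs_hz = fs_hz, n_trials = as.integer(n_trials),
                 trace_speed_px_s = trace_speed_px_s,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

derive_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) + sum(7919 * seq_along(k) * k)) %%
               .Machine$integer.max)
}

#' Planted behavior series of a synthetic design
#'
#' `b_s = beta0 + beta1 * kappa_s + eps_s`, with the noise drawn
#' reproducibly from the design seed.
#'
#' @param design a [synthetic_design()].
#' @return numeric vector, one tracing-error value (cm^2) per session.
#' @export
design_behavior <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  withr::with_seed(derive_seed(design$seed, 1L), {
    design$behavior_beta[1] + design$behavior_beta[2] * design$coupling +
      stats::rnorm(design$n_sessions, 0, design$behavior_noise_sd)
  })
}

#' Simulate one resting-state EEG recording
#'
#' 32 channels of independent pink-noise background. When `condition`
#' matches the design's planted condition, each planted electrode pair
#' additionally receives a pair of weakly coupled oscillators at the
#' planted center frequency: the relative phase follows Adler (Kuramoto
#' two-oscillator) dynamics with natural detuning `detune_hz` and
#' coupling strength proportional to the session coupling `kappa_s`.
#' Below the locking threshold the relative phase slips at rate
#' `detune_hz * sqrt(1 - kappa^2)`, so per-epoch phase-lag
#' synchronization rises smoothly and monotonically with `kappa_s`
#' and, unlike a hard-locked oscillator pair, does not pin the
#' peak-detected index to 1. At `kappa = 1` the pair is fully locked at
#' `phase_lag` and PLI approaches 1. With `zero_lag_common` the planted
#' pairs instead share a zero-lag common source (volume-conduction
#' confound).
#'
#' @param design a [synthetic_design()].
#' @param session session index.
#' @param condition `"pre"` or `"post"`.
#' @return an [eeg_recording()].
#' @export
simulate_recording <- function(design, session, condition = "pre") {
  stopifnot(inherits(design, "synthetic_design"),
            session %in% seq_len(design$n_sessions))
  labels <- tracefc_montage()
  fs <- design$fs_hz
  n <- round(design$duration_s * fs)
  cond_id <- if (condition == "pre") 1L else 2L
  withr::with_seed(derive_seed(design$seed, 2L, session, cond_id), {
    data <- t(vapply(seq_along(labels),
                     function(ch) pink_noise(n, fs), numeric(n)))
    if (identical(condition, design$planted_condition)) {
      kappa <- design$coupling[session]
      t <- seq_len(n) / fs
      for (pp in design$planted_pairs) {
        i <- match(pp[1], labels); j <- match(pp[2], labels)
        phi <- 2 * pi * design$planted_center_hz * t +
          stats::runif(1, 0, 2 * pi)
        data[i, ] <- data[i, ] + design$osc_amp * cos(phi)
        if (design$zero_lag_common) {
          data[j, ] <- data[j, ] + design$osc_amp * cos(phi)
          next
        }
        theta <- adler_phase(n, kappa, design$detune_hz,
                             design$phase_noise, fs)
        psi <- phi - design$phase_lag - theta
        data[j, ] <- data[j, ] + design$osc_amp * cos(psi)
      }
    }
    eeg_recording(data, labels, fs)
  })
}

# relative phase theta of a detuned oscillator pair under Adler
# dynamics: theta' = d_omega - K sin(theta) + noise, K = kappa * 1.05 *
# d_omega (locking threshold just below kappa = 1).
adler_phase <- function(n, kappa, detune_hz, phase_noise, fs) {
  dt <- 1 / fs
  d_omega <- 2 * pi * detune_hz
  K <- kappa * 1.05 * d_omega
  eps <- stats::rnorm(n, 0, phase_noise * sqrt(dt))
  theta <- numeric(n)
  theta[1] <- stats::runif(1, 0, 2 * pi)
  for (s in 2:n)
    theta[s] <- theta[s - 1] + dt * (d_omega - K * sin(theta[s - 1])) + eps[s]
  theta
}

#' Simulate one session of tracing trials
#'
#' Trials are the track-section polyline plus smooth correlated noise
#' whose SD follows the session's skill level; sections and directions
#' are drawn at random and timestamps follow a constant-speed model with
#' per-trial speed jitter, finishing with a dwell at the destination
#' vertex. The skill (trace-noise SD) is calibrated so the expected
#' median position error matches the session's planted behavior value.
#'
#' @param design a [synthetic_design()].
#' @param session session index.
#' @param track a [build_track()] pattern.
#' @param pointer_hz pointer sampling rate of the simulated trials.
#' @return list of [trial_record()]s of length `design$n_trials`.
#' @export
simulate_session_trials <- function(design, session, track,
                                    pointer_hz = 60) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(track, "track_pattern"))
  b <- design_behavior(design)[session]
  L <- polyline_length(track$sections[[1]])  # all sections congruent
  # E[area] ~ sigma * sqrt(2/pi) * mean(sine window) * L, in px^2;
  # behavior is in cm^2
  target_px2 <- max(b, 0) / track$pixel_area_cm2
  sigma <- target_px2 / (L * sqrt(2 / pi) * (2 / pi))
  withr::with_seed(derive_seed(design$seed, 3L, session), {
    lapply(seq_len(design$n_trials), function(tr) {
      section <- sample.int(8L, 1L)
      direction <- sample(c("forward", "reverse"), 1L)
      base <- track_section(track, section, direction)
      speed <- design$trace_speed_px_s * stats::rlnorm(1, 0, 0.15)
      trace_t <- L / speed
      m <- max(8L, ceiling(trace_t * pointer_hz))
      pts <- resample_polyline(base, m)
      # smooth noise, tapered to zero at both endpoints, per-trial
      # lognormal spread around the session skill level
      sd_tr <- sigma * stats::rlnorm(1, 0, 0.25)
      wiggle <- function() {
        g <- stats::rnorm(m)
        k <- max(3L, round(m / 12))
        g <- stats::filter(g, rep(1 / k, k), sides = 2, circular = TRUE)
        as.vector(scale(as.numeric(g)))
      }
      win <- sin(pi * seq(0, 1, length.out = m))
      noisy <- pts + cbind(wiggle(), wiggle()) * (sd_tr * win)
      tvec <- seq(0, trace_t, length.out = m)
      # dwell: ~1.3 s resting within 1 px of the destination vertex
      nd <- ceiling(1.3 * pointer_hz)
      dest <- base[nrow(base), ]
      dwell_xy <- cbind(dest[1] + stats::rnorm(nd, 0, 0.3),
                        dest[2] + stats::rnorm(nd, 0, 0.3))
      dwell_t <- trace_t + seq_len(nd) / pointer_hz
      trial_record(section, direction,
                   data.frame(x = c(noisy[, 1], dwell_xy[, 1]),
                              y = c(noisy[, 2], dwell_xy[, 2]),
                              t = c(tvec, dwell_t)),
                   base)
    })
  })
}

#' Generate a full synthetic participant study on disk
#'
#' Writes, per session, the pre- and post-training EEG recordings and
#' the tracing-trial log, in the same formats the pipeline reads, plus a
#' `ground_truth.json` card recording the planted structure and a
#' `config.yaml` consumable by the command-line pipeline.
#'
#' @param design a [synthetic_design()].
#' @param dir output directory (created if needed).
#' @param track track pattern used for the trial simulation.
#' @param eeg_format `"delim"` (CSV) or `"edf"`.
#' @return invisible list describing the layout (`sessions` data.frame
#'   with file paths, `ground_truth`, `track`).
#' @export
make_study <- function(design, dir, track = build_track(1000, 700),
                       eeg_format = c("delim", "edf")) {
  stopifnot(inherits(design, "synthetic_design"))
  eeg_format <- match.arg(eeg_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (eeg_format == "edf") "edf" else "csv"
  sessions <- data.frame(session = seq_len(design$n_sessions),
                         pre = NA_character_, post = NA_character_,
                         trials = NA_character_)
  for (s in seq_len(design$n_sessions)) {
    sdir <- file.path(dir, sprintf("session-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    for (cond in c("pre", "post")) {
      rec <- simulate_recording(design, s, cond)
      p <- file.path(sdir, sprintf("%s.%s", cond, ext))
      write_recording(rec, p, format = eeg_format)
      sessions[[cond]][s] <- p
    }
    trials <- simulate_session_trials(design, s, track)
    tp <- file.path(sdir, "trials.csv")
    write_trial_log(trials, tp)
    sessions$trials[s] <- tp
  }
  gt <- list(planted_pairs = lapply(design$planted_pairs,
                                    function(p) paste(p, collapse = "-")),
             planted_center_hz = design$planted_center_hz,
             planted_condition = design$planted_condition,
             coupling = design$coupling,
             behavior_beta = design$behavior_beta,
             behavior = design_behavior(design),
             seed = design$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(track = list(extent_x_px = unname(track$extent_px["x"]),
                           extent_y_px = unname(track$extent_px["y"]),
                           pixel_area_cm2 = track$pixel_area_cm2),
              fs_hz = design$fs_hz,
              sessions = lapply(seq_len(design$n_sessions), function(s)
                list(pre = basename(dirname(sessions$pre[s])),
                     files = list(pre = sessions$pre[s],
                                  post = sessions$post[s],
                                  trials = sessions$trials[s]))),
              seed = design$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(sessions = sessions, ground_truth = gt, track = track,
                 dir = dir))
}
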