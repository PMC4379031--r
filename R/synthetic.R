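#' Configuration of a synthetic timed-response target-jump session
#'
#' Defaults emulate the timed-response paradigm the package analyses: a
#' target appears on a 0.08 m ring in one of eight directions at the first of
#' four tones 500 ms apart, movement is initiated at the fourth (go) tone
#' with Gaussian timing jitter (SD 79 ms), the target jumps on 30% of trials
#' by +/-45, 90 or 135 deg at a uniformly random time 150-550 ms before the
#' go tone, the fingertip is sampled at 130 Hz, and the required peak speed
#' is 0.9 m/s.
#'
#' @param n_trials number of trials.
#' @param jump_probability fraction of jump trials.
#' @param jump_amplitudes_deg signed jump amplitudes sampled uniformly on
#'   jump trials.
#' @param jump_window_ms interval (lower, upper) before the go tone in which
#'   the jump time is uniform.
#' @param initiation_jitter_sd_ms SD of movement-initiation time around the
#'   go tone, ms.
#' @param direction_noise_sd_deg SD of initial-direction noise, degrees
#'   (generation-time counterpart of the fitter's `sigma_theta`).
#' @param outlier_rate fraction of trials whose direction is drawn uniformly
#'   from `outlier_range_deg` instead.
#' @param outlier_range_deg angular range of outlier directions (normalized
#'   frame).
#' @param sample_rate_hz trajectory sampling rate.
#' @param target_radius_m radius of the target ring, m.
#' @param peak_speed_mps required peak tangential speed, m/s.
#' @param movement_extent_m straight-line movement extent, m (must exceed the
#'   target radius so excursions pass the 5 cm rule).
#' @param pre_onset_noise_sd_m SD of stationary positional noise before
#'   onset, m.
#' @param go_tone_ms time of the go (fourth) tone from trial start, ms.
#' @param curvature_ramp_deg_per_ms optional heading ramp centred 100 ms
#'   after onset, for exercising the curvature exclusion; 0 = straight.
#' @param curvature_window_ms half-width of the interval around onset +
#'   100 ms within which the heading ramps; outside it the heading is held
#'   at the ramp's endpoint values.
#' @param seed integer seed; with the seed fixed the session is
#'   bit-reproducible.
#' @return list of class `"session_config"`.
#' @export
session_config <- function(n_trials = 1000, jump_probability = 0.3,
                           jump_amplitudes_deg = c(-135, -90, -45, 45, 90, 135),
                           jump_window_ms = c(150, 550),
                           initiation_jitter_sd_ms = 79,
                           direction_noise_sd_deg = 10.7,
                           outlier_rate = 0.04,
                           outlier_range_deg = c(-90, 225),
                           sample_rate_hz = 130,
                           target_radius_m = 0.08,
                           peak_speed_mps = 0.9,
                           movement_extent_m = 0.11,
                           pre_onset_noise_sd_m = 5e-4,
                           go_tone_ms = 1500,
                           curvature_ramp_deg_per_ms = 0,
                           curvature_window_ms = 30,
                           seed = 1L) {
  stopifnot(n_trials >= 1,
            jump_probability >= 0, jump_probability <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            length(jump_window_ms) == 2,
            jump_window_ms[1] < jump_window_ms[2],
            sample_rate_hz > 0, peak_speed_mps > 0,
            movement_extent_m > 0, target_radius_m > 0)
  structure(as.list(environment()), class = "session_config")
}

#' Ground-truth sigmoid parameters per jump amplitude
#'
#' One sigmoid per (absolute) jump amplitude, with `A` equal to the
#' amplitude, mirroring the fitting assumption. The defaults give steeper
#' (smaller `tau`) and later-starting transitions for larger jumps while the
#' 95%-compensation times stay nearly aligned — the qualitative pattern of
#' behaviour across 45/90/135 deg jumps.
#'
#' @param amplitude absolute jump amplitudes, degrees.
#' @param t50 half-compensation latencies, ms.
#' @param tau transition timescales, ms.
#' @return data frame of class `"sigmoid_truth"`.
#' @export
sigmoid_truth <- function(amplitude = c(45, 90, 135),
                          t50 = c(250, 285, 310),
                          tau = c(30, 20, 10)) {
  stopifnot(length(amplitude) == length(t50), length(t50) == length(tau),
            all(tau > 0), all(amplitude > 0))
  structure(data.frame(amplitude = amplitude, t50 = t50, tau = tau),
            class = c("sigmoid_truth", "data.frame"))
}

#' Synthesize a single reach trajectory
#'
#' Stationary (small positional noise) before onset, then a straight
#' minimum-jerk reach: bell-shaped speed profile
#' `v(s) = 30 (D/T) s^2 (1-s)^2` scaled so the peak equals the configured
#' peak speed, heading `direction_deg` (optionally ramped around onset +
#' 100 ms to inject curvature). Positions are obtained by trapezoidal
#' integration of the velocity.
#'
#' @param direction_deg initial heading, degrees.
#' @param onset_time_ms movement onset, ms from trial start.
#' @param config a [session_config()].
#' @param curvature_ramp_deg_per_ms heading ramp slope, deg/ms; overrides
#'   the config value when given.
#' @return data frame `t_ms`, `x_m`, `y_m`.
#' @export
generate_trajectory <- function(direction_deg, onset_time_ms,
                                config = session_config(),
                                curvature_ramp_deg_per_ms = NULL) {
  ramp <- if (is.null(curvature_ramp_deg_per_ms))
    config$curvature_ramp_deg_per_ms else curvature_ramp_deg_per_ms
  dt <- 1000 / config$sample_rate_hz
  D <- config$movement_extent_m
  t_mov <- 1.875 * D / config$peak_speed_mps * 1000     # min-jerk: v_pk = 1.875 D/T
  if (t_mov <= 0) stop("movement duration must be positive")
  t_end <- onset_time_ms + t_mov + 200
  t <- seq(0, t_end, by = dt)
  s <- pmin(pmax((t - onset_time_ms) / t_mov, 0), 1)
  speed <- 30 * (D / t_mov) * s^2 * (1 - s)^2 * 1000    # m/s
  w <- config$curvature_window_ms
  head_deg <- direction_deg +
    ramp * pmin(pmax(t - onset_time_ms - 100, -w), w)
  head_deg[s <= 0 | s >= 1] <- direction_deg
  vx <- speed * cos(head_deg * pi / 180)
  vy <- speed * sin(head_deg * pi / 180)
  # trapezoidal integration, m (dt in ms)
  integ <- function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt / 1000))
  x <- integ(vx); y <- integ(vy)
  pre <- t < onset_time_ms
  if (config$pre_onset_noise_sd_m > 0) {
    x[pre] <- x[pre] + stats::rnorm(sum(pre), 0, config$pre_onset_noise_sd_m)
    y[pre] <- y[pre] + stats::rnorm(sum(pre), 0, config$pre_onset_noise_sd_m)
  }
  data.frame(t_ms = t, x_m = x, y_m = y)
}

#' Simulate a full timed-response target-jump session
#'
#' Generates trials with known ground truth: on jump trials the true mean
#' (frame-normalized) initial direction follows the condition's sigmoid
#' evaluated at the realized re-preparation time (onset minus jump time;
#' initiation jitter makes small and even negative rPTs possible), observed
#' directions add Gaussian noise or are replaced by uniform outliers, and a
#' straight minimum-jerk trajectory consistent with the observed direction
#' is synthesized.
#'
#' @param config a [session_config()].
#' @param truth a [sigmoid_truth()] table covering every configured absolute
#'   jump amplitude.
#' @return object of class `"reach_session"`: list with `trials` (list of
#'   trial records, each holding `trial_id`, `trajectory`,
#'   `target_dir_initial_deg`, `target_dir_final_deg`, `jump_time_ms`,
#'   `go_tone_time_ms`, `condition`), `meta` (per-trial ground-truth data
#'   frame), `config` and `truth`.
#' @export
simulate_reach_session <- function(config = session_config(),
                                   truth = sigmoid_truth()) {
  amps <- unique(abs(config$jump_amplitudes_deg))
  missing <- setdiff(amps, truth$amplitude)
  if (length(missing))
    stop("no ground-truth sigmoid parameters for jump amplitude(s): ",
         paste(missing, collapse = ", "))
  set.seed(config$seed)
  n <- config$n_trials
  dirs8 <- seq(0, 315, by = 45)
  target0 <- sample(dirs8, n, replace = TRUE)
  is_jump <- stats::runif(n) < config$jump_probability
  amp <- rep(NA_real_, n)
  amp[is_jump] <- sample(config$jump_amplitudes_deg, sum(is_jump),
                         replace = TRUE)
  jump_time <- rep(NA_real_, n)
  jump_time[is_jump] <- config$go_tone_ms -
    stats::runif(sum(is_jump), config$jump_window_ms[1], config$jump_window_ms[2])
  onset <- config$go_tone_ms +
    stats::rnorm(n, 0, config$initiation_jitter_sd_ms)
  rpt <- onset - jump_time
  theta_mean <- rep(0, n)
  for (i in which(is_jump)) {
    p <- truth[truth$amplitude == abs(amp[i]), ]
    theta_mean[i] <- sigmoid_response(rpt[i], p$amplitude, p$t50, p$tau)
  }
  is_out <- stats::runif(n) < config$outlier_rate
  theta_obs <- theta_mean + stats::rnorm(n, 0, config$direction_noise_sd_deg)
  theta_obs[is_out] <- stats::runif(sum(is_out), config$outlier_range_deg[1],
                                    config$outlier_range_deg[2])
  # map normalized direction back to the raw frame (invert the reflection)
  sgn <- ifelse(is_jump & amp < 0, -1, 1)
  theta_raw <- wrap_angle(target0 + sgn * theta_obs)
  target_final <- ifelse(is_jump, wrap_angle(target0 + amp), target0)

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    trials[[i]] <- list(
      trial_id = i,
      trajectory = generate_trajectory(theta_raw[i], onset[i], config),
      target_dir_initial_deg = target0[i],
      target_dir_final_deg = target_final[i],
      jump_time_ms = jump_time[i],
      go_tone_time_ms = config$go_tone_ms,
      condition = if (is_jump[i]) paste0("jump", abs(amp[i])) else "nojump")
  }
  meta <- data.frame(trial_id = seq_len(n),
                     condition = vapply(trials, `[[`, "", "condition"),
                     is_jump = is_jump, jump_amplitude_deg = amp,
                     jump_time_ms = jump_time, go_tone_ms = config$go_tone_ms,
                     onset_true_ms = onset, rpt_true_ms = rpt,
                     theta_mean_norm_deg = theta_mean,
                     theta_obs_norm_deg = theta_obs,
                     theta_raw_deg = theta_raw,
                     target_dir_initial_deg = target0,
                     target_dir_final_deg = target_final,
                     is_outlier = is_out)
  structure(list(trials = trials, meta = meta, config = config, truth = truth),
            class = "reach_session")
}

#' @export
print.reach_session <- function(x, ...) {
  cat(sprintf("Synthetic timed-response session: %d trials (%d jump, %d outlier)\n",
              nrow(x$meta), sum(x$meta$is_jump), sum(x$meta$is_outlier)))
  cat(sprintf("  jump window %g-%g ms before go tone; jitter SD %g ms; sigma_theta %g deg\n",
              x$config$jump_window_ms[1], x$config$jump_window_ms[2],
              x$config$initiation_jitter_sd_ms,
              x$config$direction_noise_sd_deg))
  invisible(x)
}

#' Write / read a session as plain-text files
#'
#' `write_session()` stores one long-format trajectory CSV
#' (`trajectories.csv`: trial_id, t_ms, x_m, y_m), one trial-metadata CSV
#' (`trials.csv`) and the ground truth (`ground_truth.json`) in `dir`.
#' `read_session()` reconstructs the trial-record list from those files.
#'
#' @param session a `"reach_session"`.
#' @param dir output directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a list with `trials` and `meta`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- do.call(rbind, lapply(session$trials, function(tr)
    cbind(trial_id = tr$trial_id, tr$trajectory)))
  utils::write.csv(traj, file.path(dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(session$meta, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(truth = session$truth,
                            config = session$config[setdiff(names(session$config), "")]),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  traj <- utils::read.csv(file.path(dir, "trajectories.csv"))
  meta <- utils::read.csv(file.path(dir, "trials.csv"))
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    list(trial_id = m$trial_id,
         trajectory = traj[traj$trial_id == m$trial_id,
                           c("t_ms", "x_m", "y_m")],
         target_dir_initial_deg = m$target_dir_initial_deg,
         target_dir_final_deg = m$target_dir_final_deg,
         jump_time_ms = m$jump_time_ms,
         go_tone_time_ms = m$go_tone_ms,
         condition = m$condition)
  })
  list(trials = trials, meta = meta)
}
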