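#' Preprocessing configuration for raw trajectories
#'
#' Defaults follow standard practice for 130 Hz planar reaching data:
#' 2nd-order Savitzky-Golay smoothing with a 54 ms half-width, movement onset
#' as the last sub-threshold (0.02 m/s) sample before the speed peak, initial
#' direction from the smoothed velocity 100 ms after onset, exclusion of
#' trials with excursion under 5 cm or a direction rate-of-change above
#' 1.3 deg/ms.
#'
#' @param sg_order polynomial order of the Savitzky-Golay filter.
#' @param sg_halfwidth_ms filter half-width, ms; converted to samples and the
#'   window forced odd.
#' @param onset_speed_mps tangential-speed threshold for movement onset, m/s.
#' @param direction_eval_ms offset after onset at which initial direction is
#'   read, ms.
#' @param min_excursion_m minimum distance from the start location, m.
#' @param curvature_rate_limit direction rate-of-change threshold, deg/ms.
#' @param delta_ms half-interval over which the direction rate is
#'   differenced, ms; defaults to one inter-sample interval at 130 Hz.
#' @return list of class `"exclusion_config"`.
#' @export
exclusion_config <- function(sg_order = 2, sg_halfwidth_ms = 54,
                             onset_speed_mps = 0.02, direction_eval_ms = 100,
                             min_excursion_m = 0.05,
                             curvature_rate_limit = 1.3,
                             delta_ms = 1000 / 130) {
  stopifnot(sg_order >= 1, sg_halfwidth_ms > 0, onset_speed_mps > 0,
            direction_eval_ms > 0, min_excursion_m > 0,
            curvature_rate_limit > 0, delta_ms > 0)
  structure(list(sg_order = sg_order, sg_halfwidth_ms = sg_halfwidth_ms,
                 onset_speed_mps = onset_speed_mps,
                 direction_eval_ms = direction_eval_ms,
                 min_excursion_m = min_excursion_m,
                 curvature_rate_limit = curvature_rate_limit,
                 delta_ms = delta_ms),
            class = "exclusion_config")
}

# odd SG window length (samples) for a given half-width and sample interval
.sg_window <- function(cfg, dt_ms) {
  half <- max(round(cfg$sg_halfwidth_ms / dt_ms), ceiling(cfg$sg_order / 2))
  2L * as.integer(half) + 1L
}

#' Savitzky-Golay smoothing of a trajectory
#'
#' Replaces positions by locally fitted polynomial values and derives
#' velocities from the filter's first-derivative output.
#'
#' @param traj data frame with columns `t_ms`, `x_m`, `y_m`, uniformly
#'   sampled.
#' @param cfg an [exclusion_config()].
#' @return the trajectory with smoothed `x_m`, `y_m` and added `vx`, `vy`
#'   (m/s), `speed` (m/s) and `dir_deg` (heading of the velocity vector,
#'   `NA` where speed is zero).
#' @export
smooth_trajectory <- function(traj, cfg = exclusion_config()) {
  stopifnot(all(c("t_ms", "x_m", "y_m") %in% names(traj)))
  dt_ms <- stats::median(diff(traj$t_ms))
  if (any(diff(traj$t_ms) <= 0)) stop("sample times must be increasing")
  n_win <- .sg_window(cfg, dt_ms)
  if (nrow(traj) < n_win)
    stop("trajectory too short for smoothing: need at least ", n_win,
         " samples, got ", nrow(traj))
  dt_s <- dt_ms / 1000
  sm <- function(v, m) signal::sgolayfilt(v, p = cfg$sg_order, n = n_win,
                                          m = m, ts = dt_s)
  out <- traj
  out$x_m <- sm(traj$x_m, 0)
  out$y_m <- sm(traj$y_m, 0)
  out$vx <- sm(traj$x_m, 1)
  out$vy <- sm(traj$y_m, 1)
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  out$dir_deg <- ifelse(out$speed > 0,
                        atan2(out$vy, out$vx) * 180 / pi, NA_real_)
  out
}

#' Movement onset from the smoothed speed profile
#'
#' The latest sample before the global tangential-speed peak at which the
#' smoothed speed is below the threshold.
#'
#' @param traj a smoothed trajectory (see [smooth_trajectory()]).
#' @param cfg an [exclusion_config()].
#' @return onset time in ms.
#' @export
detect_onset <- function(traj, cfg = exclusion_config()) {
  if (is.null(traj$speed)) traj <- smooth_trajectory(traj, cfg)
  peak <- which.max(traj$speed)
  below <- which(traj$speed[seq_len(peak)] < cfg$onset_speed_mps)
  if (length(below) == 0L)
    stop("speed never below onset threshold before the peak; trial unusable")
  traj$t_ms[max(below)]
}

#' Initial reach direction
#'
#' Heading of the smoothed velocity vector a fixed delay (default 100 ms)
#' after movement onset.
#'
#' @param traj a smoothed trajectory.
#' @param onset onset time, ms.
#' @param cfg an [exclusion_config()].
#' @return direction in degrees, counter-clockwise from +x, in (-180, 180];
#'   `NA` if the trajectory does not extend far enough.
#' @export
initial_direction <- function(traj, onset, cfg = exclusion_config()) {
  if (is.null(traj$speed)) traj <- smooth_trajectory(traj, cfg)
  t_eval <- onset + cfg$direction_eval_ms
  if (t_eval > max(traj$t_ms)) return(NA_real_)
  i <- which.min(abs(traj$t_ms - t_eval))
  wrap_angle(atan2(traj$vy[i], traj$vx[i]) * 180 / pi)
}

#' Rate of change of movement direction at the evaluation point
#'
#' Central circular difference of the heading around onset + 100 ms:
#' `|theta(t+delta) - theta(t-delta)| / (2 delta)`, used to flag excessively
#' curved movements.
#'
#' @param traj a smoothed trajectory.
#' @param onset onset time, ms.
#' @param cfg an [exclusion_config()].
#' @return rate in deg/ms; `NA` if the heading is undefined at the required
#'   times.
#' @export
curvature_rate <- function(traj, onset, cfg = exclusion_config()) {
  if (is.null(traj$speed)) traj <- smooth_trajectory(traj, cfg)
  t0 <- onset + cfg$direction_eval_ms
  th <- function(tt) {
    if (tt < min(traj$t_ms) || tt > max(traj$t_ms)) return(NA_real_)
    traj$dir_deg[which.min(abs(traj$t_ms - tt))]
  }
  a <- th(t0 + cfg$delta_ms); b <- th(t0 - cfg$delta_ms)
  if (is.na(a) || is.na(b)) return(NA_real_)
  abs(circ_diff(a, b)) / (2 * cfg$delta_ms)
}

#' Summarize a session of raw trials
#'
#' Applies the full preprocessing chain per trial: smoothing, onset
#' detection, initial direction, curvature statistic, exclusion rules, frame
#' normalization and rPT computation. Per-trial failures become exclusion
#' flags, never errors.
#'
#' The common reference frame places the initial target at 0 deg with the
#' jump in the positive direction: directions are rotated by minus the
#' initial target direction and reflected when the jump amplitude is
#' negative. In that frame a perfect pre-jump movement scores 0 and a
#' perfect post-jump movement scores +|jump amplitude|.
#'
#' @param trials list of trial records as produced by
#'   [simulate_reach_session()] (each with `trajectory`, `target_dir_initial_deg`,
#'   `target_dir_final_deg`, `jump_time_ms` (`NA` if no jump),
#'   `go_tone_time_ms`, `condition`).
#' @param cfg an [exclusion_config()].
#' @return data frame with one row per trial: `trial_id`, `condition`,
#'   `is_jump`, `jump_amplitude_deg`, `onset_ms`, `rpt_ms`, `theta_raw_deg`,
#'   `theta_norm_deg`, `curvature_deg_per_ms`, `excursion_m`, `excluded`,
#'   `flag` (one of `""`, `"short_excursion"`, `"excess_curvature"`,
#'   `"undefined_direction"`).
#' @export
summarize_trials <- function(trials, cfg = exclusion_config()) {
  rows <- lapply(trials, function(tr) {
    res <- list(trial_id = tr$trial_id, condition = tr$condition,
                is_jump = !is.na(tr$jump_time_ms),
                jump_amplitude_deg = NA_real_, onset_ms = NA_real_,
                rpt_ms = NA_real_, theta_raw_deg = NA_real_,
                theta_norm_deg = NA_real_,
                curvature_deg_per_ms = NA_real_, excursion_m = NA_real_,
                excluded = FALSE, flag = "")
    amp <- circ_diff(tr$target_dir_final_deg, tr$target_dir_initial_deg)
    res$jump_amplitude_deg <- amp
    sm <- try(smooth_trajectory(tr$trajectory, cfg), silent = TRUE)
    if (inherits(sm, "try-error")) {
      res$excluded <- TRUE; res$flag <- "undefined_direction"
      return(res)
    }
    start <- c(sm$x_m[1], sm$y_m[1])
    res$excursion_m <- max(sqrt((sm$x_m - start[1])^2 + (sm$y_m - start[2])^2))
    onset <- try(detect_onset(sm, cfg), silent = TRUE)
    if (inherits(onset, "try-error")) {
      res$excluded <- TRUE; res$flag <- "undefined_direction"
      return(res)
    }
    res$onset_ms <- onset
    if (res$is_jump) res$rpt_ms <- onset - tr$jump_time_ms
    th <- initial_direction(sm, onset, cfg)
    if (is.na(th)) {
      res$excluded <- TRUE; res$flag <- "undefined_direction"
      return(res)
    }
    res$theta_raw_deg <- th
    norm <- circ_diff(th, tr$target_dir_initial_deg)
    if (res$is_jump && amp < 0) norm <- -norm
    res$theta_norm_deg <- norm
    res$curvature_deg_per_ms <- curvature_rate(sm, onset, cfg)
    if (res$excursion_m < cfg$min_excursion_m) {
      res$excluded <- TRUE; res$flag <- "short_excursion"
    } else if (is.na(res$curvature_deg_per_ms)) {
      res$excluded <- TRUE; res$flag <- "undefined_direction"
    } else if (res$curvature_deg_per_ms > cfg$curvature_rate_limit) {
      res$excluded <- TRUE; res$flag <- "excess_curvature"
    }
    res
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
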