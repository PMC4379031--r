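make_traj <- function(x, y, dt = SAMPLE_DT) {
  data.frame(t_ms = seq_along(x) * dt - dt, x_m = x, y_m = y)
}

test_that("Savitzky-Golay smoothing reproduces quadratics and their derivative", {
  t <- seq(0, 2000, by = SAMPLE_DT)
  x <- 1e-4 * t + 3e-8 * t^2
  y <- -2e-4 * t + 1e-8 * t^2
  sm <- smooth_trajectory(make_traj(x, y))
  expect_equal(sm$x_m, x, tolerance = 1e-10)
  expect_equal(sm$y_m, y, tolerance = 1e-10)
  # velocity from the first-derivative output, converted to m/s
  expect_equal(sm$vx, (1e-4 + 2 * 3e-8 * t) * 1000, tolerance = 1e-8)
  # constant position gives identically zero velocity
  sm0 <- smooth_trajectory(make_traj(rep(0.3, 260), rep(-0.1, 260)))
  expect_equal(sm0$speed, rep(0, 260), tolerance = 1e-12)
  expect_true(all(is.na(sm0$dir_deg) | sm0$speed < 1e-12))
  expect_error(smooth_trajectory(make_traj(1:5 / 100, 1:5 / 100)), "too short")
})

test_that("smoothing beats raw finite differences on a noisy reach", {
  set.seed(2)
  cfg <- session_config(pre_onset_noise_sd_m = 0)
  Tm <- minjerk_duration(cfg$movement_extent_m, cfg$peak_speed_mps)
  tr <- generate_trajectory(0, 800, cfg)
  truth <- minjerk_speed(tr$t_ms, 800, cfg$movement_extent_m, Tm)
  noisy <- tr
  noisy$x_m <- noisy$x_m + rnorm(nrow(tr), 0, 5e-4)
  noisy$y_m <- noisy$y_m + rnorm(nrow(tr), 0, 5e-4)
  sm <- smooth_trajectory(noisy)
  vraw <- c(NA, sqrt(diff(noisy$x_m)^2 + diff(noisy$y_m)^2) /
              diff(noisy$t_ms) * 1000)
  i <- 10:(nrow(tr) - 10)
  rmse <- function(v) sqrt(mean((v[i] - truth[i])^2))
  expect_lt(rmse(sm$speed), rmse(vraw))
})

test_that("onset lands within one sample of the filtered profile's threshold crossing", {
  cfg <- session_config(pre_onset_noise_sd_m = 0)
  Tm <- minjerk_duration(cfg$movement_extent_m, cfg$peak_speed_mps)
  for (t0 in c(1450, 1500, 1533)) {
    tr <- generate_trajectory(25, t0, cfg)
    onset <- detect_onset(smooth_trajectory(tr))
    expect_lt(abs(onset - sg_onset_oracle(t0, cfg$movement_extent_m, Tm)),
              SAMPLE_DT)
  }
})

test_that("onset anchors to the crossing before the global peak, not an early bump", {
  dt <- SAMPLE_DT
  t <- seq(0, 3000, by = dt)
  # small bump (peak 0.1 m/s) at 500 ms, main reach at 1500 ms
  x <- 0.012 * exp(-((t - 550) / 60)^2) + minjerk_pos(t, 1500, 0.11, 229)
  sm <- smooth_trajectory(make_traj(x, rep(0, length(t))))
  onset <- detect_onset(sm)
  expect_gt(onset, 1400)
  # speed never below threshold -> unusable trial
  ramp <- make_traj(0.001 * t, rep(0, length(t)))
  expect_error(detect_onset(smooth_trajectory(ramp)), "threshold")
})

test_that("initial direction follows the smoothed velocity heading", {
  cfg <- session_config(pre_onset_noise_sd_m = 0)
  # straight movement along +y reads 90 degrees
  tr <- generate_trajectory(90, 1500, cfg)
  sm <- smooth_trajectory(tr)
  expect_lt(abs(initial_direction(sm, detect_onset(sm)) - 90), 0.5)
  # equal velocity components read 45 degrees
  tr45 <- generate_trajectory(45, 1500, cfg)
  sm45 <- smooth_trajectory(tr45)
  i <- which.max(sm45$speed)
  expect_equal(sm45$vx[i], sm45$vy[i], tolerance = 1e-6)
  expect_lt(abs(initial_direction(sm45, detect_onset(sm45)) - 45), 0.5)
  # curved path: match the continuous-filter heading oracle within 1 degree
  Tm <- minjerk_duration(cfg$movement_extent_m, cfg$peak_speed_mps)
  tr_c <- generate_trajectory(10, 1500, cfg, curvature_ramp_deg_per_ms = 0.5)
  sm_c <- smooth_trajectory(tr_c)
  onset <- detect_onset(sm_c)
  path <- ramped_path(10, 0.5, 1500, cfg$movement_extent_m, Tm,
                      max(tr_c$t_ms))
  expect_lt(abs(circ_diff(initial_direction(sm_c, onset),
                          sg_heading_oracle(onset + 100, path))), 1)
  # too-short trajectory yields NA
  short <- sm_c[sm_c$t_ms <= onset + 50, ]
  expect_true(is.na(initial_direction(short, onset)))
})

test_that("curvature statistic matches the filtered heading rate and drives exclusion", {
  cfg <- session_config(pre_onset_noise_sd_m = 0)
  Tm <- minjerk_duration(cfg$movement_extent_m, cfg$peak_speed_mps)
  tr <- generate_trajectory(0, 1500, cfg)
  sm <- smooth_trajectory(tr)
  expect_lt(curvature_rate(sm, detect_onset(sm)), 1e-6)
  # injected 3 deg/ms ramp: statistic equals the smoothed heading's central
  # difference (the filter attenuates the raw ramp)
  tr2 <- generate_trajectory(0, 1500, cfg, curvature_ramp_deg_per_ms = 3)
  sm2 <- smooth_trajectory(tr2)
  on2 <- detect_onset(sm2)
  stat <- curvature_rate(sm2, on2)
  path <- ramped_path(0, 3, 1500, cfg$movement_extent_m, Tm, max(tr2$t_ms))
  d <- SAMPLE_DT
  oracle <- abs(circ_diff(sg_heading_oracle(on2 + 100 + d, path),
                          sg_heading_oracle(on2 + 100 - d, path))) / (2 * d)
  expect_lt(abs(stat - oracle), 0.1)
  expect_gt(stat, 1.3)
})

test_that("trial summaries apply exclusions, normalization and exact rPT", {
  cfg <- session_config(n_trials = 60, seed = 9)
  s <- simulate_reach_session(cfg)
  su <- summarize_trials(s$trials)
  expect_equal(nrow(su), 60)
  # rPT is exactly onset minus jump time
  j <- which(su$is_jump & !su$excluded)
  expect_equal(su$rpt_ms[j],
               su$onset_ms[j] - s$meta$jump_time_ms[j])
  # clean sessions at matched noise lose at most 1% of trials
  expect_lte(mean(su$excluded), 0.01)
  # negative jump with raw direction -10 deg normalizes to +10
  rec <- s$trials[[j[1]]]
  rec$target_dir_initial_deg <- 0
  rec$target_dir_final_deg <- -45
  rec$trajectory <- generate_trajectory(-10, 1500, cfg)
  one <- summarize_trials(list(rec))
  expect_equal(one$theta_norm_deg, 10, tolerance = 0.5)
  # short excursion is flagged, not errored
  rec2 <- rec
  rec2$trajectory <- generate_trajectory(
    0, 1500, session_config(movement_extent_m = 0.04))
  two <- summarize_trials(list(rec2))
  expect_true(two$excluded)
  expect_equal(two$flag, "short_excursion")
  # excess curvature: a sharp localized turn on a long reach keeps the
  # excursion above 5 cm while the heading rate exceeds the limit
  rec3 <- rec
  rec3$trajectory <- generate_trajectory(
    0, 1500, session_config(movement_extent_m = 0.2, pre_onset_noise_sd_m = 0),
    curvature_ramp_deg_per_ms = 3)
  three <- summarize_trials(list(rec3))
  expect_equal(three$flag, "excess_curvature")
})

test_that("shifting all event times leaves rPT and directions unchanged", {
  cfg <- session_config(n_trials = 20, seed = 13)
  s <- simulate_reach_session(cfg)
  su <- summarize_trials(s$trials)
  shift <- 400
  shifted <- lapply(s$trials, function(tr) {
    tr$trajectory$t_ms <- tr$trajectory$t_ms + shift
    tr$jump_time_ms <- tr$jump_time_ms + shift
    tr$go_tone_time_ms <- tr$go_tone_time_ms + shift
    tr
  })
  su2 <- summarize_trials(shifted)
  expect_equal(su2$rpt_ms, su$rpt_ms, tolerance = 1e-9)
  expect_equal(su2$theta_norm_deg, su$theta_norm_deg, tolerance = 1e-9)
  expect_equal(su2$onset_ms, su$onset_ms + shift, tolerance = 1e-9)
})
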