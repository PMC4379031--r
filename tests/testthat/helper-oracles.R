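# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: direct least-squares fits, plain quadrature,
# plain recursion.

SAMPLE_DT <- 1000 / 130

# closed-form min-jerk position along a straight line (m), t in ms
minjerk_pos <- function(t, t0, D, Tm) {
  s <- pmin(pmax((t - t0) / Tm, 0), 1)
  D * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

minjerk_speed <- function(t, t0, D, Tm) {
  s <- pmin(pmax((t - t0) / Tm, 0), 1)
  30 * (D / Tm) * s^2 * (1 - s)^2 * 1000      # m/s
}

# movement duration implied by extent and peak speed
minjerk_duration <- function(D, v_peak) 1.875 * D / v_peak * 1000

# Continuous-time Savitzky-Golay speed estimate: for a window centred at tc,
# least-squares-fit a quadratic to the closed-form 1-D position sampled at
# tc + k*h (k = -half..half) and take the slope at the centre. For symmetric
# windows the quadratic term is orthogonal to the slope, so the plain LS
# slope suffices.
sg_speed_oracle <- function(tc, t0, D, Tm, h = SAMPLE_DT, half = 7) {
  k <- (-half):half
  tt <- tc + k * h
  p <- minjerk_pos(tt, t0, D, Tm)
  slope <- sum(k * h * p) / sum((k * h)^2)    # m per ms
  abs(slope) * 1000                           # m/s
}

# continuous-time crossing of the smoothed speed through `thr`
sg_onset_oracle <- function(t0, D, Tm, thr = 0.02, h = SAMPLE_DT, half = 7) {
  stats::uniroot(function(tc) sg_speed_oracle(tc, t0, D, Tm, h, half) - thr,
                 interval = c(t0 - 150, t0 + Tm / 2), tol = 1e-6)$root
}

# fine-grid positions of a reach whose heading ramps linearly around
# t0 + 100 ms; returns interpolating functions for x(t), y(t)
ramped_path <- function(dir_deg, ramp, t0, D, Tm, t_max, dt_fine = 0.05,
                        window = 30) {
  t <- seq(0, t_max, by = dt_fine)
  v <- minjerk_speed(t, t0, D, Tm)
  s <- (t - t0) / Tm
  head <- dir_deg + ramp * pmin(pmax(t - t0 - 100, -window), window)
  head[s <= 0 | s >= 1] <- dir_deg
  vx <- v * cos(head * pi / 180); vy <- v * sin(head * pi / 180)
  cum <- function(u) c(0, cumsum((u[-1] + u[-length(u)]) / 2 * dt_fine / 1000))
  x <- cum(vx); y <- cum(vy)
  list(x = stats::approxfun(t, x), y = stats::approxfun(t, y))
}

# continuous-time SG heading of a 2-D path at centre tc
sg_heading_oracle <- function(tc, path, h = SAMPLE_DT, half = 7) {
  k <- (-half):half
  tt <- tc + k * h
  sx <- sum(k * h * path$x(tt)) / sum((k * h)^2)
  sy <- sum(k * h * path$y(tt)) / sum((k * h)^2)
  atan2(sy, sx) * 180 / pi
}

# plain fine-grid trapezoid for the EIV integral, independent arithmetic
fine_eiv_loglik <- function(rpt, theta, A, t50, tau, sigma_theta, sigma_t,
                            span = 5, n_nodes = 8001) {
  vapply(seq_along(rpt), function(i) {
    e <- seq(rpt[i] - span * sigma_t, rpt[i] + span * sigma_t,
             length.out = n_nodes)
    s <- A / (1 + exp(-(e - t50) / tau))
    f <- stats::dnorm(e, rpt[i], sigma_t) * stats::dnorm(theta[i], s, sigma_theta)
    h <- e[2] - e[1]
    log(sum(f) * h - (f[1] + f[n_nodes]) * h / 2)
  }, numeric(1))
}

# random tiny control problem with enumeration cost ~ (n_u * n_r)^n_steps
random_tiny_problem <- function(seed) {
  set.seed(seed)
  n_steps <- sample(2:3, 1, prob = c(0.8, 0.2))
  sep <- sample(c(2, 4, 6), 1)
  # keep enumeration cost (n_u * n_r)^n_steps per state small for 3 steps
  u_max <- if (n_steps == 3) 1 else sample(1:2, 1)
  r_step <- if (n_steps == 3) 2.25 else stats::runif(1, 1.5, 3)
  control_problem(separation_deg = sep, a = sample(c(1, 2), 1),
                  w_max = stats::runif(1, 0, 0.01),
                  sigma_r = stats::runif(1, 0.3, 1.6),
                  T_ms = n_steps * 10, dt_ms = 10,
                  x_step = 1,
                  x_margin = sample(c(2, 3), 1),
                  r_step = r_step,
                  r_half_range = 4.5,
                  u_max = u_max,
                  alpha1 = sample(c(1, 1, 10), 1),
                  barrier = sample(c(FALSE, FALSE, TRUE), 1))
}

# Q-values of every first action at t = 0 from a DP solution
dp_first_action_q <- function(sol) {
  prob <- sol$prob
  nx <- length(sol$x); nr <- length(sol$r)
  us <- seq(-prob$u_steps, prob$u_steps)
  W <- sol$V[, , 2L] %*% t(prob$kernel)
  if (prob$barrier) W[is.nan(W)] <- Inf
  q <- array(Inf, c(nx, nr, length(us)))
  for (j in seq_along(us)) {
    idx <- seq_len(nx) + us[j]
    ok <- idx >= 1L & idx <= nx
    q[ok, , j] <- W[idx[ok], ]                # w_t = 0 at t = 0
  }
  list(q = q, us = us * prob$x_step)
}
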