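test_that("sigmoid evaluation and derived latencies obey their closed forms", {
  expect_equal(sigmoid_response(300, A = 45, t50 = 300, tau = 25), 22.5)
  expect_equal(sigmoid_response(300 + 25 * log(19), 45, 300, 25), 0.95 * 45)
  expect_equal(sigmoid_response(350, 45, 300, 25), 45 / (1 + exp(-2)))
  expect_error(sigmoid_response(300, 45, 300, tau = -1), "tau")
  tms <- derived_times(300, 25)
  expect_equal(unname(tms["t95"]), 300 + 25 * log(19))
  expect_equal(unname(tms["t95"] - tms["t05"]), 2 * log(19) * 25)
  expect_true(tms["t05"] < tms["t50"] && tms["t50"] < tms["t95"])
  # self-consistency: the sigmoid reaches 95% of A at t95
  expect_equal(sigmoid_response(tms["t95"], 45, 300, 25), 0.95 * 45,
               ignore_attr = TRUE)
})

test_that("EIV likelihood reduces to a plain Gaussian as timing noise vanishes", {
  set.seed(4)
  rpt <- runif(30, 100, 500)
  theta <- sigmoid_response(rpt, 45, 250, 30) + rnorm(30, 0, 10)
  cfg <- fit_control(sigma_t = 1e-3)
  ll <- eiv_loglik(rpt, theta, 45, 250, 30, cfg)$log_lik
  direct <- dnorm(theta, sigmoid_response(rpt, 45, 250, 30), cfg$sigma_theta,
                  log = TRUE)
  expect_equal(ll, direct, tolerance = 1e-4)
})

test_that("trapezoid integration matches a 100x-finer quadrature oracle", {
  set.seed(5)
  rpt <- runif(50, 0, 600)
  theta <- sigmoid_response(rpt, 45, 250, 30) + rnorm(50, 0, 10.7)
  cfg <- fit_control()
  ll <- eiv_loglik(rpt, theta, 45, 250, 30, cfg)$log_lik
  fine <- fine_eiv_loglik(rpt, theta, 45, 250, 30,
                          cfg$sigma_theta, cfg$sigma_t)
  expect_equal(ll, fine, tolerance = 1e-6)
})

test_that("data exactly on the sigmoid maximize the likelihood over direction perturbations", {
  rpt <- seq(100, 500, by = 10)
  theta <- sigmoid_response(rpt, 45, 250, 30)
  base <- eiv_loglik(rpt, theta, 45, 250, 30)$total
  for (eps in c(-2, 1, 3))
    expect_lt(eiv_loglik(rpt, theta + eps, 45, 250, 30)$total, base)
})

test_that("the shallow-slope penalty rewards larger tau", {
  rpt <- seq(100, 500, by = 10)
  theta <- sigmoid_response(rpt, 45, 250, 30)
  cfg0 <- fit_control(alpha = 0)
  expect_equal(penalized_loglik(rpt, theta, 45, 250, 30, cfg0),
               eiv_loglik(rpt, theta, 45, 250, 30, cfg0)$total)
  cfg <- fit_control(alpha = 0.02)
  expect_equal(penalized_loglik(rpt, theta, 45, 250, 30, cfg),
               eiv_loglik(rpt, theta, 45, 250, 30, cfg)$total + 0.02 * 30)
  # with no trials in the transition region the penalized fit is shallower
  set.seed(6)
  d <- simulate_sigmoid_trials(240, A = 45, t50 = 250, tau = 25,
                               sigma_theta = 10.7, sigma_t = 10, seed = 6)
  gap <- d$rpt < 180 | d$rpt > 320
  fit_pen <- reach_sigmoid(rpt = d$rpt[gap], theta = d$theta[gap], A = 45)
  fit_un <- reach_sigmoid(rpt = d$rpt[gap], theta = d$theta[gap], A = 45,
                          control = fit_control(alpha = 0))
  expect_gte(coef(fit_pen)["tau"], coef(fit_un)["tau"])
})

test_that("noise-free data are recovered to optimizer tolerance", {
  d <- simulate_sigmoid_trials(150, A = 45, t50 = 250, tau = 30,
                               sigma_theta = 0.05, sigma_t = 0.05,
                               outlier_rate = 0, seed = 7)
  fit <- reach_sigmoid(theta ~ rpt, data = d, A = 45,
                       control = fit_control(sigma_theta = 0.05, sigma_t = 0.05))
  expect_lt(abs(coef(fit)["t50"] - 250), 1)
  expect_lt(abs(coef(fit)["tau"] - 30) / 30, 0.05)
  expect_true(fit$converged)
})

test_that("fitting is invariant under joint time translation", {
  d <- simulate_sigmoid_trials(200, A = 45, t50 = 250, tau = 30, seed = 8)
  ll1 <- eiv_loglik(d$rpt, d$theta, 45, 250, 30)$log_lik
  ll2 <- eiv_loglik(d$rpt + 700, d$theta, 45, 950, 30)$log_lik
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("negating directions and amplitude mirrors the fit", {
  d <- simulate_sigmoid_trials(300, A = 45, t50 = 250, tau = 30,
                               outlier_rate = 0.03, seed = 9)
  f1 <- reach_sigmoid(rpt = d$rpt, theta = d$theta, A = 45)
  f2 <- reach_sigmoid(rpt = d$rpt, theta = -d$theta, A = -45)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  expect_equal(predict(f1, c(200, 300)), -predict(f2, c(200, 300)),
               tolerance = 1e-3)
})

test_that("the EM mixture identifies planted outliers and reports sane posteriors", {
  d <- simulate_sigmoid_trials(500, A = 45, t50 = 250, tau = 30,
                               outlier_rate = 0.06, seed = 10)
  fit <- reach_sigmoid(theta ~ rpt, data = d, A = 45)
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  expect_true(all(diff(fit$trace) > -1e-8))
  # most flagged outliers are planted ones, far off the curve
  resid <- abs(d$theta - predict(fit))
  expect_gt(mean(resid[fit$outliers]), mean(resid[!fit$outliers]))
  planted_far <- d$is_outlier & resid > 4 * 10.7
  expect_gt(mean(fit$posterior[planted_far]), 0.9)
})

test_that("fit errors are informative", {
  expect_error(eiv_loglik(numeric(0), numeric(0), 45, 250, 30), "no trials")
  expect_error(reach_sigmoid(rpt = 1:10, theta = rnorm(10), A = 45),
               "at least")
})

test_that("model methods are mutually consistent", {
  d <- simulate_sigmoid_trials(250, A = 90, t50 = 285, tau = 20, seed = 11)
  fit <- reach_sigmoid(theta ~ rpt, data = d, A = 90)
  expect_s3_class(fit, "reach_sigmoid")
  expect_equal(fitted(fit) + residuals(fit), fit$data$theta)
  expect_equal(predict(fit, data.frame(rpt = fit$times["t50"]))[[1]], 45,
               tolerance = 1e-9)
  expect_output(print(fit), "t50")
  expect_output(print(summary(fit)), "outliers")
  expect_equal(attr(logLik(fit), "nobs"), fit$n)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2))
  # a plot renders without error
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit, band = 10.7); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("identical predictors give identical time-base likelihoods", {
  d <- simulate_sigmoid_trials(300, A = 45, t50 = 250, tau = 30,
                               sigma_t = 0, jitter_sd = 0, seed = 12)
  # zero jitter: rPT and absolute time coincide trial by trial
  expect_equal(d$rpt, d$t_abs)
  cmp <- compare_time_bases(d$rpt, d$t_abs, d$theta, A = 45)
  expect_equal(cmp$loglik_rpt, cmp$loglik_abs, tolerance = 1e-10)
})
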