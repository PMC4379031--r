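#' @export
print.reach_sigmoid <- function(x, ...) {
  cat("Errors-in-variables sigmoid fit (EM outlier mixture)\n")
  cat(sprintf("  A (fixed): %.1f deg, n = %d trials\n", x$A, x$n))
  cat(sprintf("  t50 = %.1f ms, tau = %.1f ms\n",
              x$coefficients["t50"], x$coefficients["tau"]))
  cat(sprintf("  t05 = %.1f, t95 = %.1f ms\n", x$times["t05"], x$times["t95"]))
  cat(sprintf("  outliers: %d (mixture weight %.3f)\n",
              sum(x$outliers), x$pi_out))
  cat(sprintf("  penalized mixture objective: %.3f (%s, %d EM iterations)\n",
              x$objective,
              if (x$converged) "converged" else "NOT converged",
              length(x$trace) - 1L))
  invisible(x)
}

#' @export
coef.reach_sigmoid <- function(object, ...) object$coefficients

#' @export
logLik.reach_sigmoid <- function(object, ...) {
  structure(object$log_lik_total, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
summary.reach_sigmoid <- function(object, ...) {
  out <- list(coefficients = object$coefficients, A = object$A,
              times = object$times, n = object$n,
              n_outliers = sum(object$outliers), pi_out = object$pi_out,
              objective = object$objective, converged = object$converged)
  class(out) <- "summary.reach_sigmoid"
  out
}

#' @export
print.summary.reach_sigmoid <- function(x, ...) {
  cat("Sigmoid fit of initial reach direction vs re-preparation time\n\n")
  cat(sprintf("Amplitude A (fixed): %10.1f deg\n", x$A))
  cat(sprintf("t50                : %10.1f ms\n", x$coefficients["t50"]))
  cat(sprintf("tau                : %10.1f ms\n", x$coefficients["tau"]))
  cat(sprintf("t05, t95           : %10.1f, %.1f ms  (t95 - t05 = 2 ln19 tau)\n",
              x$times["t05"], x$times["t95"]))
  cat(sprintf("trials / outliers  : %10d / %d (mixture weight %.3f)\n",
              x$n, x$n_outliers, x$pi_out))
  cat(sprintf("penalized objective: %10.3f  converged: %s\n",
              x$objective, x$converged))
  invisible(x)
}

#' Predicted mean initial direction at given rPTs
#' @param object a fitted `"reach_sigmoid"`.
#' @param newdata optional data frame with an `rpt` column, or a numeric
#'   vector of rPTs; defaults to the fitted data.
#' @param ... ignored.
#' @export
predict.reach_sigmoid <- function(object, newdata = NULL, ...) {
  rpt <- if (is.null(newdata)) object$data$rpt
         else if (is.data.frame(newdata)) newdata$rpt else newdata
  sigmoid_response(rpt, object$A, object$coefficients["t50"],
                   object$coefficients["tau"])
}

#' @export
fitted.reach_sigmoid <- function(object, ...) predict(object)

#' @export
residuals.reach_sigmoid <- function(object, ...) {
  object$data$theta - fitted(object)
}

#' Simulate responses from a fitted sigmoid model
#'
#' Draws new directions at the fitted model's rPTs from the generative model:
#' a latent timing error `N(0, sigma_t^2)` perturbs each rPT, the sigmoid is
#' evaluated there, Gaussian direction noise `sigma_theta` is added, and with
#' probability equal to the fitted mixture weight the direction is replaced
#' by a uniform outlier draw on \[-90, 225\] degrees.
#'
#' @param object a fitted `"reach_sigmoid"`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return a data frame with `nsim` columns, one simulated `theta` per row of
#'   the fitted data.
#' @export
simulate.reach_sigmoid <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rpt <- object$data$rpt
  n <- length(rpt)
  cfg <- object$control
  sims <- replicate(nsim, {
    e <- rpt + stats::rnorm(n, 0, cfg$sigma_t)
    th <- sigmoid_response(e, object$A, object$coefficients["t50"],
                           object$coefficients["tau"]) +
      stats::rnorm(n, 0, cfg$sigma_theta)
    out <- stats::runif(n) < object$pi_out
    th[out] <- stats::runif(sum(out), -90, 225)
    th
  })
  as.data.frame(sims)
}

#' Plot a fitted sigmoid over the trial scatter
#'
#' @param x a fitted `"reach_sigmoid"`.
#' @param band optional SD of non-jump-trial directions; when given, a
#'   95% band (`1.96 * band`) is shaded around zero.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reach_sigmoid <- function(x, band = NULL, ...) {
  d <- x$data
  graphics::plot(d$rpt, d$theta, pch = 16, col = "grey40",
                 xlab = "re-preparation time (ms)",
                 ylab = "initial reach direction (deg)", ...)
  if (!is.null(band))
    graphics::rect(graphics::par("usr")[1], -1.96 * band,
                   graphics::par("usr")[2], 1.96 * band,
                   col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  if (any(x$outliers))
    graphics::points(d$rpt[x$outliers], d$theta[x$outliers],
                     pch = 4, col = "red")
  rr <- seq(min(d$rpt), max(d$rpt), length.out = 200)
  graphics::lines(rr, predict(x, rr), lwd = 2, col = "darkorange")
  graphics::abline(h = c(0, x$A), lty = 3)
  invisible(x)
}

#' Simulate (rPT, direction) pairs from the sigmoid generative model
#'
#' A lightweight trial generator at the level of fitted quantities (no
#' trajectories): true rPTs are drawn uniformly over `rpt_range` (emulating
#' the jump-time window plus initiation jitter when `jitter_sd > 0`),
#' directions follow the sigmoid plus Gaussian noise, the *observed* rPT is
#' the true rPT plus Gaussian timing noise `sigma_t`, and a fraction
#' `outlier_rate` of directions is replaced by uniform draws on
#' `outlier_range`.
#'
#' @param n number of trials.
#' @param A,t50,tau true sigmoid parameters.
#' @param sigma_theta direction noise SD, degrees.
#' @param sigma_t timing noise SD on the observed rPT, ms.
#' @param outlier_rate fraction of outlier trials.
#' @param outlier_range angular range of the uniform outlier component.
#' @param rpt_range range of true rPTs, ms.
#' @param jitter_sd SD of movement-initiation jitter added to the true rPT
#'   (ms); when positive, the returned `t_abs` column (jump-to-go-tone delay)
#'   and the rPT decouple, as in a timed-response session.
#' @param seed optional integer seed.
#' @return data frame with columns `rpt` (observed), `rpt_true`, `t_abs`,
#'   `theta`, `is_outlier`.
#' @export
simulate_sigmoid_trials <- function(n, A, t50, tau,
                                    sigma_theta = 10.7, sigma_t = 10,
                                    outlier_rate = 0, outlier_range = c(-90, 225),
                                    rpt_range = c(150, 550), jitter_sd = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_abs <- stats::runif(n, rpt_range[1], rpt_range[2])
  rpt_true <- t_abs + stats::rnorm(n, 0, jitter_sd)
  theta <- sigmoid_response(rpt_true, A, t50, tau) +
    stats::rnorm(n, 0, sigma_theta)
  is_out <- stats::runif(n) < outlier_rate
  theta[is_out] <- stats::runif(sum(is_out), outlier_range[1], outlier_range[2])
  rpt_obs <- rpt_true + stats::rnorm(n, 0, sigma_t)
  data.frame(rpt = rpt_obs, rpt_true = rpt_true, t_abs = t_abs,
             theta = theta, is_outlier = is_out)
}

#' Ordinary least-squares sigmoid fit (for comparison)
#'
#' Minimizes the sum of squared direction residuals over `(t50, tau)` with
#' `A` fixed, ignoring timing noise and outliers. Provided as the naive
#' baseline against which the errors-in-variables fit is compared: with
#' noise on the rPT, least squares systematically overestimates `tau`.
#'
#' @inheritParams eiv_loglik
#' @param tau_bounds permissible `tau` range, ms.
#' @return list with `coefficients` (t50, tau) and `rss`.
#' @export
ols_sigmoid <- function(rpt, theta, A, tau_bounds = c(1, 500)) {
  sse <- function(par) {
    tau <- exp(par[2])
    if (tau < tau_bounds[1] || tau > tau_bounds[2]) return(1e12)
    sum((theta - sigmoid_response(rpt, A, par[1], tau))^2)
  }
  t50g <- seq(stats::quantile(rpt, 0.05), stats::quantile(rpt, 0.95),
              length.out = 21)
  taug <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 13))
  grid <- expand.grid(t50 = t50g, tau = taug)
  sc <- vapply(seq_len(nrow(grid)),
               function(i) sse(c(grid$t50[i], log(grid$tau[i]))), numeric(1))
  best <- grid[which.min(sc), ]
  opt <- stats::optim(c(best$t50, log(best$tau)), sse, method = "Nelder-Mead")
  list(coefficients = c(t50 = opt$par[1], tau = exp(opt$par[2])),
       rss = opt$value)
}

#' Compare rPT against absolute jump time as the predictor
#'
#' Fits the same EIV sigmoid mixture model twice: once with the
#' re-preparation time (jump-to-movement-onset delay) as predictor and once
#' with the absolute jump time (jump-to-go-tone delay), and reports the total
#' mixture log-likelihood of each fit computed over *all* points, including
#' those classified as outliers. With initiation-time jitter the two clocks
#' decouple and the better predictor attains the higher total.
#'
#' @param rpt observed re-preparation times, ms.
#' @param t_abs absolute jump times (go tone minus jump time), ms.
#' @param theta normalized initial directions, degrees.
#' @param A jump amplitude, degrees.
#' @param control an [fit_control()] configuration.
#' @return list of class `"timebase_comparison"` with the two fits and their
#'   total log-likelihoods `loglik_rpt`, `loglik_abs`.
#' @export
compare_time_bases <- function(rpt, t_abs, theta, A, control = fit_control()) {
  stopifnot(length(rpt) == length(t_abs), length(rpt) == length(theta))
  fit_rpt <- reach_sigmoid(rpt = rpt, theta = theta, A = A, control = control)
  fit_abs <- reach_sigmoid(rpt = t_abs, theta = theta, A = A, control = control)
  out <- list(fit_rpt = fit_rpt, fit_abs = fit_abs,
              loglik_rpt = fit_rpt$log_lik_total,
              loglik_abs = fit_abs$log_lik_total)
  class(out) <- "timebase_comparison"
  out
}

#' @export
print.timebase_comparison <- function(x, ...) {
  cat("Predictor comparison (total mixture log-likelihood, all points):\n")
  cat(sprintf("  re-preparation time : %.3f\n", x$loglik_rpt))
  cat(sprintf("  absolute jump time  : %.3f\n", x$loglik_abs))
  cat(sprintf("  preferred           : %s\n",
              if (x$loglik_rpt >= x$loglik_abs) "rPT" else "absolute time"))
  invisible(x)
}
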