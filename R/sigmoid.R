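#' Sigmoidal compensation curve
#'
#' Mean initial reach direction as a function of re-preparation time (rPT),
#' `S(t) = A / (1 + exp(-(t - t50) / tau))`. `A` is the jump amplitude
#' (degrees, fixed, never estimated), `t50` the latency at which half of the
#' jump is compensated (ms), and `tau` the transition timescale (ms).
#'
#' @param rpt re-preparation time(s), ms.
#' @param A jump amplitude, degrees.
#' @param t50 half-compensation latency, ms.
#' @param tau transition timescale, ms; must be > 0.
#' @return mean initial reach direction(s), degrees, in (0, A) for finite rPT.
#' @export
#' @examples
#' sigmoid_response(300, A = 45, t50 = 300, tau = 25)  # A/2
sigmoid_response <- function(rpt, A, t50, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be > 0")
  A / (1 + exp(-(rpt - t50) / tau))
}

#' Latencies at 5%, 50% and 95% compensation
#'
#' Closed form of the sigmoid: `t05/t95 = t50 -/+ tau * log(19)`, so that
#' `t95 - t05 = 2 * log(19) * tau`.
#'
#' @param t50 half-compensation latency, ms.
#' @param tau transition timescale, ms.
#' @return named numeric vector `c(t05, t50, t95)`.
#' @export
derived_times <- function(t50, tau) {
  c(t05 = t50 - tau * log(19), t50 = t50, t95 = t50 + tau * log(19))
}

#' Fitting configuration for the errors-in-variables sigmoid
#'
#' @param sigma_theta SD of reach-direction noise, degrees. Default 10.7.
#' @param sigma_t SD of the latent timing error on rPT, ms. Default 10.
#' @param alpha shallow-slope penalty weight per ms of `tau`: the penalized
#'   objective is the total log-likelihood plus `alpha * tau`, biasing fits
#'   towards the shallowest slope consistent with the data. Default 0.02.
#' @param L0 fixed likelihood density (per degree) of the uniform outlier
#'   component. Default `1/315`, a uniform over the normalized direction
#'   range \[-90, 225\] degrees.
#' @param pi_init initial mixture weight of the outlier component.
#' @param n_nodes number of trapezoid nodes for the integral over the latent
#'   timing error. Default 81.
#' @param node_span half-width of the integration grid in units of
#'   `sigma_t`. Default 5.
#' @param tau_bounds permissible range for `tau`, ms.
#' @param max_iter maximum EM iterations.
#' @param tol absolute convergence tolerance on the penalized mixture
#'   objective.
#' @param optim_maxit iteration cap for the Nelder-Mead refinement inside
#'   each M-step.
#' @param min_trials minimum number of trials required to attempt a fit.
#' @param outlier_threshold posterior above which a trial is reported as an
#'   outlier.
#' @return a list of class `"eiv_control"`.
#' @export
fit_control <- function(sigma_theta = 10.7, sigma_t = 10, alpha = 0.02,
                        L0 = 1 / 315, pi_init = 0.05,
                        n_nodes = 81, node_span = 5,
                        tau_bounds = c(1, 500),
                        max_iter = 100, tol = 1e-6, optim_maxit = 80,
                        min_trials = 20, outlier_threshold = 0.5) {
  stopifnot(sigma_theta > 0, sigma_t > 0, L0 > 0,
            n_nodes >= 5, node_span >= 4,
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[1] < tau_bounds[2],
            pi_init > 0, pi_init < 1)
  structure(list(sigma_theta = sigma_theta, sigma_t = sigma_t, alpha = alpha,
                 L0 = L0, pi_init = pi_init, n_nodes = n_nodes,
                 node_span = node_span, tau_bounds = tau_bounds,
                 max_iter = max_iter, tol = tol, optim_maxit = optim_maxit,
                 min_trials = min_trials,
                 outlier_threshold = outlier_threshold),
            class = "eiv_control")
}

# row-wise log(sum(exp(x))) with max-shift; rows all -Inf give -Inf
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Errors-in-variables log-likelihood of the sigmoid
#'
#' Per-trial log density of the observed initial direction given the observed
#' rPT, marginalizing a Gaussian latent error on the timing:
#' `L_i = integral N(e; rPT_i, sigma_t^2) N(theta_i; S(e), sigma_theta^2) de`,
#' evaluated by trapezoidal quadrature on a grid of `n_nodes` nodes spanning
#' `rPT_i +/- node_span * sigma_t`. Densities are properly normalized (per
#' degree) so totals are comparable across predictors and against the uniform
#' outlier density.
#'
#' @param rpt,theta paired numeric vectors: observed rPT (ms) and normalized
#'   initial reach direction (degrees).
#' @param A,t50,tau sigmoid parameters (see [sigmoid_response()]).
#' @param control an [fit_control()] list.
#' @return list with `log_lik` (per-trial log densities) and `total`.
#' @export
eiv_loglik <- function(rpt, theta, A, t50, tau, control = fit_control()) {
  if (length(rpt) == 0L) stop("no trials supplied")
  stopifnot(length(rpt) == length(theta))
  z <- seq(-control$node_span, control$node_span, length.out = control$n_nodes)
  h <- z[2] - z[1]
  wt <- rep(h, control$n_nodes); wt[c(1, control$n_nodes)] <- h / 2
  # e = rpt_i + sigma_t * z_k  (n x K)
  e <- outer(rpt, control$sigma_t * z, "+")
  s <- A / (1 + exp(-(e - t50) / tau))
  lg <- stats::dnorm(z, log = TRUE)            # latent-time factor, in z units
  ld <- -0.5 * ((theta - s) / control$sigma_theta)^2 -
    log(control$sigma_theta) - 0.5 * log(2 * pi)
  lm <- sweep(ld, 2L, lg + log(wt), "+")
  ll <- .row_logsumexp(lm)
  # floor far-outlying points at the smallest representable density; the
  # mixture component dominates there anyway
  ll <- pmax(ll, -690)
  list(log_lik = ll, total = sum(ll))
}

#' Penalized log-likelihood
#'
#' Total EIV log-likelihood plus the shallow-slope penalty `alpha * tau`.
#' The penalty *rewards* larger `tau`: where the data do not constrain the
#' slope, the shallowest consistent slope is preferred.
#'
#' @inheritParams eiv_loglik
#' @return scalar penalized objective.
#' @export
penalized_loglik <- function(rpt, theta, A, t50, tau, control = fit_control()) {
  eiv_loglik(rpt, theta, A, t50, tau, control)$total + control$alpha * tau
}

# mixture objective and E-step weights at fixed parameters
.mixture_state <- function(rpt, theta, A, t50, tau, pi_out, control) {
  ll <- eiv_loglik(rpt, theta, A, t50, tau, control)$log_lik
  la <- log1p(-pi_out) + ll
  lb <- log(pi_out) + log(control$L0)
  tot <- .row_logsumexp(cbind(la, lb))
  w <- exp(lb - tot)                         # posterior outlier weight
  list(log_lik = ll, w = w,
       objective = sum(tot) + control$alpha * tau)
}

# weighted M-step objective over (t50, log tau)
.mstep_objective <- function(par, rpt, theta, A, w1, cfg) {
  t50 <- par[1]; tau <- exp(par[2])
  if (tau < cfg$tau_bounds[1] || tau > cfg$tau_bounds[2]) return(-1e10)
  ll <- eiv_loglik(rpt, theta, A, t50, tau, cfg)$log_lik
  sum(w1 * ll) + cfg$alpha * tau
}

#' Fit the rPT-direction sigmoid by errors-in-variables maximum likelihood
#'
#' Fits `theta = S(rPT) + noise` with the jump amplitude `A` fixed, Gaussian
#' noise on both the direction (`sigma_theta`) and the timing of the rPT
#' (`sigma_t`), a penalty `alpha * tau` biasing towards shallow slopes, and a
#' uniform outlier mixture component with fixed density `L0`. Estimation is by
#' expectation-maximization: the E-step computes posterior outlier weights,
#' the M-step re-estimates the mixture weight in closed form and refines
#' `(t50, tau)` by a coarse grid scan (first iteration) followed by
#' Nelder-Mead. The penalized mixture objective is non-decreasing across
#' iterations by construction.
#'
#' @param formula,data model formula `theta ~ rpt` and a data frame holding
#'   the two variables (direction in degrees, rPT in ms). Alternatively call
#'   the default method with bare vectors.
#' @param rpt,theta numeric vectors (default method).
#' @param A jump amplitude in degrees; fixed, not estimated.
#' @param control an [fit_control()] configuration.
#' @param init optional `c(t50, tau)` starting values; when omitted a grid
#'   scan chooses them.
#' @param ... passed between methods.
#' @return an object of class `"reach_sigmoid"`: a list with elements
#'   `coefficients` (t50, tau), `A`, `times` (t05/t50/t95), `pi_out`
#'   (fitted outlier mixture weight), `posterior` (per-trial outlier
#'   posterior), `outliers` (logical, posterior above threshold),
#'   `objective` (final penalized mixture objective), `log_lik_total`
#'   (unpenalized mixture total over all points), `trace` (objective per EM
#'   iteration), `converged`, `data`, and `control`.
#' @seealso [sigmoid_response()], [derived_times()], [compare_time_bases()]
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_sigmoid_trials(200, A = 45, t50 = 250, tau = 30, seed = 1)
#' fit <- reach_sigmoid(theta ~ rpt, data = d, A = 45)
#' coef(fit)
#' summary(fit)
reach_sigmoid <- function(...) UseMethod("reach_sigmoid")

#' @rdname reach_sigmoid
#' @export
reach_sigmoid.formula <- function(formula, data, A, control = fit_control(),
                                  init = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  reach_sigmoid.default(rpt = mf[[2L]], theta = mf[[1L]], A = A,
                        control = control, init = init, ...)
}

#' @rdname reach_sigmoid
#' @export
reach_sigmoid.default <- function(rpt, theta, A, control = fit_control(),
                                  init = NULL, ...) {
  stopifnot(is.numeric(rpt), is.numeric(theta), length(rpt) == length(theta))
  keep <- is.finite(rpt) & is.finite(theta)
  rpt <- rpt[keep]; theta <- theta[keep]
  n <- length(rpt)
  if (n < control$min_trials)
    stop("need at least ", control$min_trials, " trials; got ", n)

  if (is.null(init)) {
    t50g <- seq(stats::quantile(rpt, 0.05), stats::quantile(rpt, 0.95),
                length.out = 21)
    taug <- exp(seq(log(control$tau_bounds[1]), log(control$tau_bounds[2]),
                    length.out = 13))
    grid <- expand.grid(t50 = t50g, tau = taug)
    sc <- vapply(seq_len(nrow(grid)), function(i) {
      .mixture_state(rpt, theta, A, grid$t50[i], grid$tau[i],
                     control$pi_init, control)$objective
    }, numeric(1))
    best <- grid[which.max(sc), ]
    t50 <- best$t50; tau <- best$tau
  } else {
    t50 <- init[1]; tau <- init[2]
  }
  pi_out <- control$pi_init

  st <- .mixture_state(rpt, theta, A, t50, tau, pi_out, control)
  trace <- st$objective
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    w <- st$w
    pi_new <- min(max(mean(w), 1e-6), 0.95)
    if (mean(w) > 0.9)
      stop("degenerate fit: nearly all trials classified as outliers")
    opt <- stats::optim(c(t50, log(tau)), .mstep_objective,
                        rpt = rpt, theta = theta, A = A, w1 = 1 - w,
                        cfg = control, method = "Nelder-Mead",
                        control = list(fnscale = -1,
                                       maxit = control$optim_maxit))
    t50 <- opt$par[1]; tau <- exp(opt$par[2])
    pi_out <- pi_new
    st_new <- .mixture_state(rpt, theta, A, t50, tau, pi_out, control)
    trace <- c(trace, st_new$objective)
    if (abs(st_new$objective - st$objective) < control$tol) {
      st <- st_new
      converged <- TRUE
      break
    }
    st <- st_new
  }

  tms <- derived_times(t50, tau)
  out <- list(coefficients = c(t50 = t50, tau = tau), A = A,
              times = tms, pi_out = pi_out,
              posterior = st$w,
              outliers = st$w > control$outlier_threshold,
              objective = st$objective,
              log_lik_total = st$objective - control$alpha * tau,
              trace = trace, converged = converged, n = n,
              data = data.frame(rpt = rpt, theta = theta),
              control = control, call = match.call())
  class(out) <- "reach_sigmoid"
  out
}
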