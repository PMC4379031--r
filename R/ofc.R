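#' Belief from log-odds
#'
#' The belief state `r` is the log-odds that the target has jumped, i.e. that
#' the post-jump location `g2` is the true goal: `p = 1 / (1 + exp(-r))`.
#' Negative infinity means certainty in the original target `g1`, positive
#' infinity certainty in `g2`.
#'
#' @param r log-odds value(s).
#' @return belief in the post-jump target, in (0, 1).
#' @export
belief_from_logodds <- function(r) stats::plogis(r)

#' One-dimensional control problem with goal uncertainty
#'
#' The hand's angular position `x` follows the integrator `x_{t+1} = x_t +
#' u_t` (the command is an instantaneous angular velocity), the belief `r`
#' about which of two targets is the goal follows a zero-drift Gaussian
#' random walk with per-step SD `sigma_r`, and the expected terminal cost
#' weighs a step miss-cost of width `a` around each target by the terminal
#' belief. Effort costs `w_t u_t^2` accrue per step with `w_t` rising
#' linearly from 0 at `t = 0` to `w_max` at the horizon, so late corrections
#' are the expensive ones. `alpha1 > 1` scales the original target's
#' miss-cost (asymmetric variant); `barrier = TRUE` confines `x` at every
#' step to channels of half-width `a/2` around the two targets, reducing the
#' initial choice to a discrete one.
#'
#' @param separation_deg angular separation of the targets; they are placed
#'   symmetrically at `-/+ separation_deg / 2` unless `g1`, `g2` are given.
#' @param g1,g2 original and post-jump target angles, degrees.
#' @param a miss-cost step width, degrees.
#' @param w_max terminal effort weight.
#' @param sigma_r belief random-walk SD per time step.
#' @param T_ms movement-time horizon, ms.
#' @param dt_ms time step, ms; must divide `T_ms`.
#' @param x_step angular grid spacing, degrees.
#' @param x_margin grid margin beyond the outermost target, degrees; must be
#'   at least `a`.
#' @param r_step belief grid spacing.
#' @param r_half_range belief grid extends over `[-r_half_range,
#'   +r_half_range]`.
#' @param u_max largest angular displacement per step, degrees (rounded to a
#'   whole number of grid steps).
#' @param alpha1 scale on the original target's miss-cost; 1 = symmetric.
#' @param barrier logical; confine movement to the two target channels.
#' @return list of class `"control_problem"` with the grids attached
#'   (`x`, `r`, `n_steps`, `kernel`).
#' @export
control_problem <- function(separation_deg = 45, g1 = NULL, g2 = NULL,
                            a = 1, w_max = 0.001, sigma_r = 1,
                            T_ms = 200, dt_ms = 10,
                            x_step = 0.1, x_margin = 2.5,
                            r_step = 0.5, r_half_range = 10,
                            u_max = 3, alpha1 = 1, barrier = FALSE) {
  if (is.null(g1)) g1 <- -separation_deg / 2
  if (is.null(g2)) g2 <- separation_deg / 2
  stopifnot(a > 0, sigma_r >= 0, alpha1 >= 1, x_step > 0, r_step > 0,
            T_ms > 0, dt_ms > 0, u_max >= x_step, x_margin >= a)
  if (abs(T_ms / dt_ms - round(T_ms / dt_ms)) > 1e-9)
    stop("'dt_ms' must divide 'T_ms'")
  n_steps <- as.integer(round(T_ms / dt_ms))
  half <- max(abs(g1), abs(g2)) + x_margin
  x <- seq(-round(half / x_step), round(half / x_step)) * x_step
  r <- seq(-round(r_half_range / r_step), round(r_half_range / r_step)) * r_step
  # belief transition kernel: bin-integrated Gaussian, edge bins absorb tails
  if (sigma_r == 0) {
    kernel <- diag(length(r))
  } else {
    lost <- 2 * stats::pnorm(-r_half_range / sigma_r)
    if (lost > 0.01)
      stop("more than 1% of the belief random-walk mass falls beyond the ",
           "grid in a single step; widen 'r_half_range'")
    edges <- c(-Inf, (r[-1] + r[-length(r)]) / 2, Inf)
    kernel <- t(vapply(r, function(ri)
      diff(stats::pnorm(edges, mean = ri, sd = sigma_r)),
      numeric(length(r))))
  }
  structure(list(g1 = g1, g2 = g2, a = a, w_max = w_max, sigma_r = sigma_r,
                 T_ms = T_ms, dt_ms = dt_ms, n_steps = n_steps,
                 x_step = x_step, r_step = r_step,
                 x = x, r = r, kernel = kernel,
                 u_steps = as.integer(round(u_max / x_step)),
                 alpha1 = alpha1, barrier = barrier),
            class = "control_problem")
}

#' @export
print.control_problem <- function(x, ...) {
  cat(sprintf("1-D goal-uncertain control problem: targets %g / %g deg%s%s\n",
              x$g1, x$g2,
              if (x$alpha1 != 1) sprintf(", alpha1 = %g", x$alpha1) else "",
              if (x$barrier) ", barrier" else ""))
  cat(sprintf("  horizon %g ms (dt %g), x grid %d pts (%g deg), r grid %d pts (%g), u_max %g deg/step\n",
              x$T_ms, x$dt_ms, length(x$x), x$x_step, length(x$r), x$r_step,
              x$u_steps * x$x_step))
  invisible(x)
}

# step miss-cost of width a around 0
.jx <- function(d, a) ifelse(abs(d) < a / 2, 0, 1)

#' Expected terminal cost of ending at angle x with belief r
#'
#' `alpha1 * (1 - p) * Jx(x - g1) + p * Jx(x - g2)`, where `p` is the belief
#' that the target jumped ([belief_from_logodds()]) and `Jx` is a step
#' function of width `a`.
#'
#' @param x terminal angle(s), degrees.
#' @param r terminal belief log-odds (scalar or same length as `x`).
#' @param prob a [control_problem()].
#' @return expected cost(s).
#' @export
endpoint_cost <- function(x, r, prob) {
  p <- belief_from_logodds(r)
  prob$alpha1 * (1 - p) * .jx(x - prob$g1, prob$a) +
    p * .jx(x - prob$g2, prob$a)
}

# logical mask of x values inside the two target channels
.channel_mask <- function(prob) {
  abs(prob$x - prob$g1) <= prob$a / 2 + 1e-9 |
    abs(prob$x - prob$g2) <= prob$a / 2 + 1e-9
}

#' Solve the control problem by backward dynamic programming
#'
#' Backward recursion on the discretized (x, r, t) grid:
#' `V(x, r, t) = min_u { w_t u^2 + E_{r'|r} V(x + u, r', t + dt) }` with the
#' terminal value equal to [endpoint_cost()]. Actions are integer multiples
#' of the x-grid step up to `u_max`; actions leaving the grid are
#' inadmissible. With `barrier = TRUE`, states outside the two target
#' channels are inadmissible at every time.
#'
#' @param prob a [control_problem()].
#' @return object of class `"ofc_solution"`: list with `V` (array `n_x` x
#'   `n_r` x `n_steps + 1`; time slice 1 is `t = 0`), `policy` (optimal
#'   action in degrees, same shape minus the terminal slice), `x`, `r`, and
#'   `prob`.
#' @seealso [policy_curve()], [solve_ofc_enum()]
#' @export
solve_ofc <- function(prob) {
  nx <- length(prob$x); nr <- length(prob$r); ns <- prob$n_steps
  tK <- t(prob$kernel)
  us <- seq(-prob$u_steps, prob$u_steps)        # actions in grid steps
  us <- us[order(abs(us))]                      # ties resolve to smallest |u|
  Vt <- outer(prob$x, prob$r, function(xx, rr) endpoint_cost(xx, rr, prob))
  if (prob$barrier) Vt[!.channel_mask(prob), ] <- Inf
  V <- array(NA_real_, c(nx, nr, ns + 1L))
  policy <- array(NA_real_, c(nx, nr, ns))
  V[, , ns + 1L] <- Vt
  Vnext <- Vt
  for (k in (ns - 1L):0L) {
    W <- Vnext %*% tK                           # E over r' given r
    # Inf * 0 from barrier-inadmissible states; the true expectation is Inf
    if (prob$barrier) W[is.nan(W)] <- Inf
    w_t <- prob$w_max * (k * prob$dt_ms) / prob$T_ms
    best <- matrix(Inf, nx, nr)
    bestu <- matrix(NA_real_, nx, nr)
    for (du in us) {
      idx <- seq_len(nx) + du
      ok <- idx >= 1L & idx <= nx
      if (!any(ok)) next
      cand <- matrix(Inf, nx, nr)
      cand[ok, ] <- W[idx[ok], ] + w_t * (du * prob$x_step)^2
      upd <- cand < best
      best[upd] <- cand[upd]
      bestu[upd] <- du * prob$x_step
    }
    if (prob$barrier) {
      best[!.channel_mask(prob), ] <- Inf
      bestu[!.channel_mask(prob), ] <- NA_real_
    }
    V[, , k + 1L] <- best
    policy[, , k + 1L] <- bestu
    Vnext <- best
  }
  structure(list(V = V, policy = policy, x = prob$x, r = prob$r, prob = prob),
            class = "ofc_solution")
}

#' @export
print.ofc_solution <- function(x, ...) {
  cat("Dynamic-programming solution of a goal-uncertain reach problem\n")
  print(x$prob)
  invisible(x)
}

#' Exhaustive-enumeration reference solver
#'
#' Computes `V(x, r, 0)` by plain recursion: for every admissible action the
#' expectation over all discretized belief paths is evaluated by recursing
#' into each successor belief, with no memoization or vectorization. The
#' cost of enumeration grows as `(n_actions * n_r)^n_steps` per state, so
#' this is only usable on tiny instances; it exists as an independent exact
#' reference for [solve_ofc()].
#'
#' @param prob a (tiny) [control_problem()].
#' @return list with `V0` (matrix `n_x` x `n_r` of values at `t = 0`) and
#'   `argmin` (matrix of optimal first actions, degrees).
#' @export
solve_ofc_enum <- function(prob) {
  nx <- length(prob$x); nr <- length(prob$r)
  term <- outer(prob$x, prob$r, function(xx, rr) endpoint_cost(xx, rr, prob))
  mask <- if (prob$barrier) .channel_mask(prob) else rep(TRUE, nx)
  term[!mask, ] <- Inf
  us <- seq(-prob$u_steps, prob$u_steps)
  rec <- function(xi, ri, k) {
    if (k == prob$n_steps) return(term[xi, ri])
    if (!mask[xi]) return(Inf)
    w_t <- prob$w_max * (k * prob$dt_ms) / prob$T_ms
    best <- Inf
    for (du in us) {
      xj <- xi + du
      if (xj < 1L || xj > nx) next
      if (prob$barrier && !mask[xj]) next
      ev <- 0
      for (rj in seq_len(nr)) {
        kr <- prob$kernel[ri, rj]
        if (kr == 0) next
        ev <- ev + kr * rec(xj, rj, k + 1L)
      }
      val <- w_t * (du * prob$x_step)^2 + ev
      if (val < best) best <- val
    }
    best
  }
  V0 <- matrix(NA_real_, nx, nr)
  argmin <- matrix(NA_real_, nx, nr)
  for (xi in seq_len(nx)) for (ri in seq_len(nr)) {
    if (!mask[xi]) { V0[xi, ri] <- Inf; next }
    w_t <- 0
    vals <- vapply(us, function(du) {
      xj <- xi + du
      if (xj < 1L || xj > nx) return(Inf)
      if (prob$barrier && !mask[xj]) return(Inf)
      ev <- 0
      for (rj in seq_len(nr)) {
        kr <- prob$kernel[ri, rj]
        if (kr > 0) ev <- ev + kr * rec(xj, rj, 1L)
      }
      w_t * (du * prob$x_step)^2 + ev
    }, numeric(1))
    V0[xi, ri] <- min(vals)
    argmin[xi, ri] <- us[which.min(vals)] * prob$x_step
  }
  list(V0 = V0, argmin = argmin)
}

#' Optimal initial reach angle as a function of the onset belief
#'
#' For each belief value `r0` on the grid, the argmin set of `V(x, r0, 0)`
#' over x. Ties (within a relative tolerance of 1e-9) are resolved
#' deterministically: to the tie-set member closest to the currently favored
#' target (the sign of `r0`), and to the midpoint of the set at `r0 = 0`.
#' Angles are also reported normalized so 0 is the original target and 1 the
#' post-jump target.
#'
#' @param sol an [solve_ofc()] solution.
#' @param r0_values belief values at which to evaluate; must lie on the
#'   solution's r grid. Defaults to the whole grid.
#' @param tol relative tie tolerance.
#' @return data frame of class `"ofc_policy"`: `r0`, `x_star_deg`,
#'   `x_star_norm`, `n_ties`, `tie_lo_deg`, `tie_hi_deg`.
#' @export
policy_curve <- function(sol, r0_values = NULL, tol = 1e-9) {
  prob <- sol$prob
  if (is.null(r0_values)) r0_values <- sol$r
  idx <- match(round(r0_values / prob$r_step), round(sol$r / prob$r_step))
  if (anyNA(idx)) stop("all 'r0_values' must lie on the solution's r grid")
  rows <- lapply(seq_along(r0_values), function(i) {
    v <- sol$V[, idx[i], 1L]
    m <- min(v)
    ties <- sol$x[v <= m + tol * (1 + abs(m))]
    r0 <- r0_values[i]
    fav <- if (r0 > 0) prob$g2 else prob$g1
    xs <- if (r0 == 0) mean(range(ties)) else ties[which.min(abs(ties - fav))]
    data.frame(r0 = r0, x_star_deg = xs,
               x_star_norm = (xs - prob$g1) / (prob$g2 - prob$g1),
               n_ties = length(ties),
               tie_lo_deg = min(ties), tie_hi_deg = max(ties))
  })
  out <- do.call(rbind, rows)
  attr(out, "prob") <- prob
  class(out) <- c("ofc_policy", "data.frame")
  out
}

#' Width of the policy curve's transition in belief units
#'
#' Length of the `r0` interval over which the normalized policy curve rises
#' from `lo` to `hi`; `+Inf` if a level is never reached. A level's crossing
#' is the first belief grid point at which the curve reaches it — the solver
#' only knows the policy at grid resolution, so widths are reported in whole
#' grid steps rather than interpolated below it. The curve must be
#' nondecreasing in `r0` after tie resolution.
#'
#' @param curve an [policy_curve()] result.
#' @param lo,hi normalized levels, defaults 0.05 and 0.95.
#' @return interval length in belief (log-odds) units.
#' @export
transition_width <- function(curve, lo = 0.05, hi = 0.95) {
  stopifnot(lo < hi)
  ord <- order(curve$r0)
  r0 <- curve$r0[ord]; y <- curve$x_star_norm[ord]
  if (any(diff(y) < -1e-9))
    stop("policy curve is not monotone in r0 (max decrease ",
         format(-min(diff(y))), "); cannot define a transition width")
  crossing <- function(level) {
    j <- which(y >= level - 1e-12)
    if (!length(j)) return(Inf)
    r0[j[1]]
  }
  crossing(hi) - crossing(lo)
}

#' Plot normalized policy curves
#'
#' @param x an `"ofc_policy"` data frame (or a list of them, given as
#'   `x` plus `...`).
#' @param ... further policy curves to overlay.
#' @param labels optional legend labels.
#' @export
plot.ofc_policy <- function(x, ..., labels = NULL) {
  curves <- c(list(x), list(...))
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
  graphics::plot(NA, xlim = range(x$r0), ylim = c(-0.1, 1.1),
                 xlab = "belief at movement onset, r0 (log-odds)",
                 ylab = "normalized initial reach angle")
  graphics::abline(h = c(0, 1), lty = 3)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$r0, curves[[i]]$x_star_norm,
                    col = cols[i], lwd = 2)
  if (!is.null(labels))
    graphics::legend("topleft", legend = labels, col = cols[seq_along(curves)],
                     lwd = 2, bty = "n")
  invisible(x)
}
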