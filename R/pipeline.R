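#' Run the full analysis pipeline on a synthetic experiment
#'
#' Orchestrates simulate -> preprocess -> fit -> solve into one reproducible
#' run: generates a session, summarizes trials, fits one sigmoid per
#' absolute jump amplitude (pooling positive and negative jumps after frame
#' normalization), solves the control model at the requested target
#' separations, and writes every stage's outputs as CSV/JSON under
#' `out_dir`.
#'
#' @param config list with components `session` (a [session_config()]),
#'   `truth` (a [sigmoid_truth()]), `exclusion` (an [exclusion_config()]),
#'   `fit` (an [fit_control()]), `separations` (numeric, degrees),
#'   `barrier_separations` (numeric, degrees, may be empty) and optional
#'   `model_args` (list passed on to [control_problem()]). Missing
#'   components take the package defaults. Alternatively the path to a YAML
#'   file with the same structure (requires the `yaml` package).
#' @param out_dir output directory, created if needed.
#' @param seed integer; overrides the session config's seed so one argument
#'   reproduces the whole run.
#' @return (invisibly) a list with `summaries`, `fits` (per amplitude),
#'   `fit_table`, `curves`, `width_table`, `out_dir`.
#' @export
run_experiment <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
    config$session <- do.call(session_config, config$session %||% list())
    config$truth <- do.call(sigmoid_truth, config$truth %||% list())
    config$exclusion <- do.call(exclusion_config, config$exclusion %||% list())
    config$fit <- do.call(fit_control, config$fit %||% list())
  }
  ses_cfg <- config$session %||% session_config()
  truth <- config$truth %||% sigmoid_truth()
  exc <- config$exclusion %||% exclusion_config()
  fc <- config$fit %||% fit_control()
  seps <- config$separations %||% unique(abs(ses_cfg$jump_amplitudes_deg))
  bseps <- config$barrier_separations %||% numeric(0)
  margs <- config$model_args %||% list()
  if (!is.null(seed)) ses_cfg$seed <- as.integer(seed)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  session <- simulate_reach_session(ses_cfg, truth)
  write_session(session, file.path(out_dir, "session"))

  summaries <- summarize_trials(session$trials, exc)
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)

  amps <- sort(unique(abs(ses_cfg$jump_amplitudes_deg)))
  fits <- list()
  rows <- list()
  for (A in amps) {
    keep <- summaries$is_jump & !summaries$excluded &
      abs(summaries$jump_amplitude_deg) == A
    fit <- reach_sigmoid(rpt = summaries$rpt_ms[keep],
                         theta = summaries$theta_norm_deg[keep],
                         A = A, control = fc)
    fits[[as.character(A)]] <- fit
    rows[[as.character(A)]] <- data.frame(
      amplitude = A, n = fit$n, n_outliers = sum(fit$outliers),
      t50 = unname(coef(fit)["t50"]), tau = unname(coef(fit)["tau"]),
      t05 = unname(fit$times["t05"]), t95 = unname(fit$times["t95"]),
      loglik = fit$log_lik_total, converged = fit$converged)
  }
  fit_table <- do.call(rbind, rows)
  utils::write.csv(fit_table, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  for (A in names(fits))
    jsonlite::write_json(
      list(amplitude = as.numeric(A), coefficients = as.list(coef(fits[[A]])),
           times = as.list(fits[[A]]$times),
           outlier_trials = which(fits[[A]]$outliers)),
      file.path(out_dir, paste0("fit_", A, ".json")),
      auto_unbox = TRUE, digits = NA)

  curves <- list(); wrows <- list()
  for (s in seps) {
    prob <- do.call(control_problem, c(list(separation_deg = s), margs))
    pc <- policy_curve(solve_ofc(prob))
    curves[[paste0("sep", s)]] <- pc
    wrows[[paste0("sep", s)]] <- data.frame(
      separation = s, barrier = FALSE, width = transition_width(pc))
  }
  for (s in bseps) {
    prob <- do.call(control_problem,
                    c(list(separation_deg = s, barrier = TRUE), margs))
    pc <- policy_curve(solve_ofc(prob))
    curves[[paste0("sep", s, "_barrier")]] <- pc
    wrows[[paste0("sep", s, "_barrier")]] <- data.frame(
      separation = s, barrier = TRUE, width = transition_width(pc))
  }
  width_table <- do.call(rbind, wrows)
  utils::write.csv(width_table, file.path(out_dir, "policy_widths.csv"),
                   row.names = FALSE)
  for (nm in names(curves))
    utils::write.csv(curves[[nm]],
                     file.path(out_dir, paste0("policy_", nm, ".csv")),
                     row.names = FALSE)

  jsonlite::write_json(
    list(seed = ses_cfg$seed, n_trials = ses_cfg$n_trials,
         separations = seps, barrier_separations = bseps,
         package_version = as.character(utils::packageVersion("hedgereach"))),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(summaries = summaries, fits = fits, fit_table = fit_table,
                 curves = curves, width_table = width_table,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render summary figures for a completed run
#'
#' One page per fitted amplitude (rPT-direction scatter, fitted sigmoid,
#' non-jump 95% band) and one page of normalized policy curves, written as
#' a single PDF.
#'
#' @param run a [run_experiment()] result, or the path of its output
#'   directory.
#' @param file output PDF path; defaults to `figures.pdf` in the run
#'   directory.
#' @return the PDF path, invisibly.
#' @export
plot_results <- function(run, file = NULL) {
  if (is.character(run)) {
    dir <- run
    summaries <- utils::read.csv(file.path(dir, "summaries.csv"))
    fit_table <- utils::read.csv(file.path(dir, "fits.csv"))
    curve_files <- list.files(dir, pattern = "^policy_.*\\.csv$",
                              full.names = TRUE)
    if (!nrow(fit_table) || !length(curve_files))
      stop("run directory is missing fit or policy-curve artifacts")
    curves <- lapply(curve_files, utils::read.csv)
    names(curves) <- sub("^policy_(.*)\\.csv$", "\\1", basename(curve_files))
    fits <- NULL
  } else {
    dir <- run$out_dir
    summaries <- run$summaries
    fit_table <- run$fit_table
    curves <- run$curves
    fits <- run$fits
  }
  if (is.null(file)) file <- file.path(dir, "figures.pdf")
  band <- stats::sd(summaries$theta_norm_deg[!summaries$is_jump &
                                               !summaries$excluded])
  grDevices::pdf(file, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  for (i in seq_len(nrow(fit_table))) {
    A <- fit_table$amplitude[i]
    keep <- summaries$is_jump & !summaries$excluded &
      abs(summaries$jump_amplitude_deg) == A
    d <- summaries[keep, ]
    graphics::plot(d$rpt_ms, d$theta_norm_deg, pch = 16, col = "grey40",
                   xlab = "re-preparation time (ms)",
                   ylab = "initial reach direction (deg)",
                   main = sprintf("%g deg jumps", A))
    graphics::rect(graphics::par("usr")[1], -1.96 * band,
                   graphics::par("usr")[2], 1.96 * band,
                   col = grDevices::adjustcolor("steelblue", 0.2),
                   border = NA)
    rr <- seq(min(d$rpt_ms), max(d$rpt_ms), length.out = 200)
    graphics::lines(rr, sigmoid_response(rr, A, fit_table$t50[i],
                                         fit_table$tau[i]),
                    lwd = 2, col = "darkorange")
    graphics::abline(h = c(0, A), lty = 3)
  }
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
  graphics::plot(NA, xlim = range(curves[[1]]$r0), ylim = c(-0.1, 1.1),
                 xlab = "belief at movement onset, r0 (log-odds)",
                 ylab = "normalized initial reach angle",
                 main = "model policy curves")
  graphics::abline(h = c(0, 1), lty = 3)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$r0, curves[[i]]$x_star_norm,
                    col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = names(curves),
                   col = cols[seq_along(curves)], lwd = 2, bty = "n")
  invisible(file)
}
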