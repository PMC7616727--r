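# End-to-end analysis pipelines built from the fitting and group-stats
# blocks; used by the command-line interface, the test suite and the
# acceptance script.

#' Fit every scan of a simulated fMRS cohort and run group inference
#'
#' For each subject and condition the dynamic GLM fit is run (mean-
#' spectrum initialization), the per-scan stimulation effect is the
#' average of the two stimulation-regressor betas (a first-level
#' contrast with its delta-propagated variance), and a paired
#' variance-weighted GLM tests stimulation vs control per metabolite.
#'
#' @param cohort a [gen_fmrs_cohort()] result.
#' @return list with `fits` (per subject: stim/ctrl results tables),
#'   `subject_correlation` (per scan, Pearson r between recovered and
#'   true concentration betas), `group` (data.frame metabolite, beta, z,
#'   p), `cope_table`.
#' @export
run_cohort_analysis <- function(cohort) {
  mets <- cohort$basis$names
  w_stim <- c(0.5, 0.5)
  rows <- list()
  cors <- numeric(0)
  fits <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    for (cond in c("stim", "ctrl")) {
      fit <- fit_dynamic(sub[[cond]], cohort$basis, cohort$config,
                         cohort$tvar, cohort$opts, init = "mean")
      fits[[paste0("s", s, "_", cond)]] <- fit
      truth <- sub[[paste0("truth_", cond)]]
      bsel <- grep("^conc_.*_beta", names(fit$par), value = TRUE)
      cors <- c(cors, stats::cor(fit$par[bsel], truth[bsel]))
      for (m in mets) {
        w <- stats::setNames(w_stim, paste0("conc_", m, c("_beta0", "_beta1")))
        cp <- first_level_cope(fit, w)
        rows[[length(rows) + 1L]] <-
          data.frame(metabolite = m, subject = s, condition = cond,
                     cope = cp$cope, varcope = cp$varcope)
      }
    }
  }
  cope_table <- do.call(rbind, rows)
  # paired design: stimulation scans first, then control, subject order
  design <- group_design_paired(length(cohort$subjects))
  group <- do.call(rbind, lapply(mets, function(m) {
    d <- cope_table[cope_table$metabolite == m, ]
    d <- d[order(match(d$condition, c("stim", "ctrl")), d$subject), ]
    g <- group_glm(d$cope, d$varcope, design, "condition")
    data.frame(metabolite = m, beta = g$cope, z = g$z, p = g$p)
  }))
  list(fits = fits, subject_correlation = cors, group = group,
       cope_table = cope_table)
}

#' Pooled GABA RMSE ratios of the MEGA-PRESS strategy comparison
#'
#' Runs the CS2-style Monte Carlo over a grid of linewidths and SNR
#' levels and pools the GABA RMSE per strategy (root of the mean squared
#' error across conditions), the quantity the strategy ratios are
#' reported on.
#'
#' @param linewidths numeric vector of Lorentzian FWHMs (Hz).
#' @param snrs numeric vector of NAA matched-filter SNRs.
#' @param n_reps Monte Carlo repetitions per condition.
#' @param seed master seed.
#' @return list with `per_condition` (data.frame linewidth, snr,
#'   strategy, metabolite rmse columns) and `pooled_gaba` (named vector
#'   of pooled GABA RMSE per strategy).
#' @export
run_mega_grid <- function(linewidths, snrs, n_reps, seed) {
  rows <- list()
  i <- 0L
  for (lw in linewidths) for (sn in snrs) {
    i <- i + 1L
    mc <- run_monte_carlo(mc_scenario_cs2(lw, sn), n_reps,
                          derive_seed(seed, i * 1000L))
    for (strat in names(mc$metrics)) {
      m <- mc$metrics[[strat]]
      rows[[length(rows) + 1L]] <- data.frame(
        linewidth = lw, snr = sn, strategy = strat,
        param = m$param, rmse = m$rmse, sd = m$sd, bias = m$bias)
    }
  }
  per_condition <- do.call(rbind, rows)
  gaba <- per_condition[per_condition$param == "GABA", ]
  pooled <- vapply(split(gaba, gaba$strategy),
                   function(d) sqrt(mean(d$rmse^2)), 0)
  list(per_condition = per_condition, pooled_gaba = pooled)
}
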