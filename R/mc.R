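# Monte Carlo harness: scenario runners for the simulation case studies
# and the estimator-comparison metrics (RMSE, SD, bias, SD ratios, mean
# parameter correlation, fraction-scaled stick error).

#' Monte Carlo metrics for one estimate matrix
#'
#' Population-SD convention so that `rmse^2 = sd^2 + bias^2` holds
#' exactly per parameter.
#'
#' @param est matrix (n_reps x P) of estimates, named columns.
#' @param truth named numeric truth vector (recycled by name).
#' @return data.frame with columns param, truth, mean, bias, sd, rmse.
#' @export
mc_metrics <- function(est, truth) {
  params <- colnames(est)
  tr <- truth[params]
  mu <- colMeans(est)
  bias <- mu - tr
  sd_pop <- sqrt(colMeans(sweep(est, 2, mu)^2))
  rmse <- sqrt(colMeans(sweep(est, 2, tr)^2))
  data.frame(param = params, truth = unname(tr), mean = unname(mu),
             bias = unname(bias), sd = unname(sd_pop), rmse = unname(rmse),
             row.names = NULL)
}

#' Run a Monte Carlo experiment
#'
#' Repeats a scenario `n_reps` times with deterministic child seeds
#' derived from `seed`; every strategy within one rep sees the same
#' generated data (common random numbers, needed for paired strategy
#' comparisons). Non-converged reps are flagged and excluded from the
#' metrics with a reported count; an error is raised only when all reps
#' of a strategy fail.
#'
#' @param scenario a scenario object with fields `generator(seed)` and
#'   `run_rep(gen)` returning a named list of per-strategy named estimate
#'   vectors (see [mc_scenario_cs1()] and friends), and `truth(gen)`.
#' @param n_reps number of repetitions (>= 2).
#' @param seed master seed.
#' @return object of class `mc_result`: `estimates` (per strategy,
#'   n_ok x P), `metrics` (per strategy), `truth`, `n_reps`, `failed`.
#' @export
run_monte_carlo <- function(scenario, n_reps, seed) {
  if (n_reps < 2) stop_domain("n_reps must be >= 2")
  all_est <- list()
  truth <- NULL
  failed <- integer(0)
  for (r in seq_len(n_reps)) {
    gen <- scenario$generator(derive_seed(seed, r))
    if (is.null(truth)) truth <- scenario$truth(gen)
    res <- tryCatch(scenario$run_rep(gen), error = function(e) NULL)
    if (is.null(res)) { failed <- c(failed, r); next }
    for (strat in names(res)) {
      all_est[[strat]] <- rbind(all_est[[strat]], res[[strat]])
    }
  }
  if (!length(all_est)) stop_domain("all Monte Carlo reps failed")
  metrics <- lapply(all_est, mc_metrics, truth = truth)
  structure(list(estimates = all_est, metrics = metrics, truth = truth,
                 n_reps = n_reps, seed = seed, failed = failed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d reps (%d failed), strategies: %s\n", x$n_reps,
              length(x$failed), paste(names(x$estimates), collapse = ", ")))
  invisible(x)
}

#' Ratio of Monte Carlo SDs between two strategies
#' @param mc an [run_monte_carlo()] result.
#' @param strategy_a,strategy_b strategy names (numerator/denominator).
#' @param parameter parameter name.
#' @export
uncertainty_ratio <- function(mc, strategy_a, strategy_b, parameter) {
  ma <- mc$metrics[[strategy_a]]; mb <- mc$metrics[[strategy_b]]
  ma$sd[ma$param == parameter] / mb$sd[mb$param == parameter]
}

#' Mean absolute correlation of one parameter with all others
#'
#' Across Monte Carlo reps, the mean |Pearson correlation| between the
#' named (concentration) estimate and every other estimated parameter of
#' the same strategy.
#'
#' @param mc an [run_monte_carlo()] result.
#' @param strategy strategy name.
#' @param parameter concentration parameter name.
#' @export
mean_param_correlation <- function(mc, strategy, parameter) {
  E <- mc$estimates[[strategy]]
  others <- setdiff(colnames(E), parameter)
  others <- others[apply(E[, others, drop = FALSE], 2, stats::sd) > 0]
  if (!length(others)) return(0)
  mean(abs(stats::cor(E[, parameter], E[, others, drop = FALSE])))
}

#' Fraction-scaled stick-vector error
#'
#' For every ground-truth stick, the Euclidean distance between the
#' fraction-scaled vectors `f v` with the estimated stick direction
#' sign-rectified (a stick is antipodally symmetric), summed after
#' matching estimated to true sticks by the total-error-minimizing
#' permutation.
#'
#' @param est,truth matrices with one row per stick: `(f, x, y, z)`
#'   (directions need not be normalized; they are).
#' @return summed error (scalar).
#' @export
stick_error <- function(est, truth) {
  norm_rows <- function(M) {
    M <- as.matrix(M)
    v <- M[, 2:4, drop = FALSE]
    nv <- sqrt(rowSums(v^2))
    nv[nv == 0] <- 1
    cbind(M[, 1], v / nv)
  }
  E <- norm_rows(est); Tr <- norm_rows(truth)
  ns <- nrow(Tr)
  pair_err <- function(e, t) {
    ev <- e[1] * e[2:4]; tv <- t[1] * t[2:4]
    min(sqrt(sum((ev - tv)^2)), sqrt(sum((ev + tv)^2)))
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(p) c(v[i], p))))
  }
  perms <- all_perms(seq_len(ns))
  min(vapply(perms, function(p)
    sum(vapply(seq_len(ns), function(i) pair_err(E[p[i], ], Tr[i, ]), 0)), 0))
}

sticks_from_theta <- function(theta, met) {
  f1 <- theta[[paste0("conc_", met, "_f1")]]
  f2 <- theta[[paste0("conc_", met, "_f2")]]
  v1 <- stick_vec(theta[[paste0("conc_", met, "_theta1")]],
                  theta[[paste0("conc_", met, "_phi1")]])
  v2 <- stick_vec(theta[[paste0("conc_", met, "_theta2")]],
                  theta[[paste0("conc_", met, "_phi2")]])
  rbind(c(f1, v1), c(f2, v2))
}

# ---- scenario constructors -------------------------------------------------

#' CS1 toy two-peak scenario
#'
#' Strategies: `independent` (per-transient fits, then ordinary least
#' squares of the concentration series on the design) and `dynamic`
#' (joint GLM-constrained fit). `linked = TRUE` shares one shift and one
#' broadening between the peaks (the standard linked model); FALSE frees
#' them per peak.
#'
#' @param separation_ppm peak separation.
#' @param snr peak-A matched-filter SNR.
#' @param linked share nuisance parameters between the two peaks.
#' @return scenario for [run_monte_carlo()]; estimates are the baseline
#'   and stimulation betas of peak B (`beta0`, `beta1`).
#' @export
mc_scenario_cs1 <- function(separation_ppm, snr, linked = FALSE) {
  list(
    generator = function(seed) {
      gen <- gen_two_peak(separation_ppm, snr, seed)
      if (linked) {
        b <- gen$basis
        gen$basis <- basis_set(b$fids, b$names, b$grid,
                               groups = stats::setNames(rep("g0", 2), b$names))
      }
      gen
    },
    truth = function(gen) c(beta0 = 1, beta1 = 0.2),
    run_rep = function(gen) {
      fi <- fit_independent(gen$series, gen$basis, gen$opts,
                            covariance = FALSE)
      X <- as.matrix(gen$tvar$columns)
      bh <- qr.coef(qr(X), fi$estimates["conc_B", ])
      # mean-spectrum start: per-transient fits can label-swap the two
      # peaks at small separation, which poisons an inverted start
      fd <- fit_dynamic(gen$series, gen$basis, gen$config, gen$tvar,
                        gen$opts, init = "mean")
      if (!fd$converged) stop("dynamic fit did not converge")
      list(independent = c(beta0 = unname(bh[1]), beta1 = unname(bh[2])),
           dynamic = c(beta0 = unname(fd$par[["conc_B_beta0"]]),
                       beta1 = unname(fd$par[["conc_B_beta1"]])))
    })
}

#' CS2 MEGA-PRESS scenario
#'
#' Strategies: `OFF` (edit-off only, half noise variance), `DIFF`
#' (difference spectrum with the subtracted basis), `DYN` (joint fit of
#' both conditions with shared concentrations and nuisances). Estimates
#' are GABA, Glx (Glu + Gln), tNAA and tCr concentrations (DIFF carries
#' only the edited GABA and Glx).
#'
#' @param linewidth_hz Lorentzian FWHM (study grid 5 to 9 Hz).
#' @param snr NAA matched-filter SNR (study grid 30 to 330).
#' @export
mc_scenario_cs2 <- function(linewidth_hz, snr) {
  list(
    generator = function(seed) gen_mega(linewidth_hz, seed, snr = snr),
    truth = function(gen) {
      cc <- gen$truth$conc
      c(GABA = unname(cc["GABA"]), Glx = unname(cc["Glu"] + cc["Gln"]),
        tNAA = unname(cc["NAA"] + cc["NAAG"]),
        tCr = unname(cc["Cr"] + cc["PCr"]))
    },
    run_rep = function(gen) {
      grab <- function(est) c(GABA = unname(est[["conc_GABA"]]),
                              Glx = unname(est[["conc_Glu"]] + est[["conc_Gln"]]),
                              tNAA = unname(est[["conc_NAA"]] + est[["conc_NAAG"]]),
                              tCr = unname(est[["conc_Cr"]] + est[["conc_PCr"]]))
      f_off <- fit_independent(gen$off_half, gen$basis_off, gen$opts,
                               covariance = FALSE)
      diff_fid <- gen$pair$transients[2, ] - gen$pair$transients[1, ]
      # difference spectra are fitted over the edited region only, the
      # standard GABA+ window (excludes the saturated 1.9 ppm lobe)
      opts_diff <- gen$opts
      opts_diff$ppm_range <- c(2.5, 4.2)
      f_diff <- fit_independent(fid_series(diff_fid, gen$pair$grid),
                                gen$basis_diff, opts_diff,
                                covariance = FALSE)
      # warm start: the OFF-only fit, replicated over both conditions
      f_dyn <- fit_dynamic(gen$pair, gen$basis, gen$config, gen$tvar,
                           gen$opts,
                           independent_fits = f_off$estimates[, c(1, 1)])
      ed <- f_diff$estimates[, 1]
      list(OFF = grab(f_off$estimates[, 1]),
           DIFF = c(GABA = unname(ed[["conc_GABA"]]),
                    Glx = unname(ed[["conc_Glu"]] + ed[["conc_Gln"]])),
           DYN = grab(f_dyn$par))
    })
}

#' CS5 multi-direction diffusion scenario
#'
#' One strategy (`dyn`) per direction count: joint ball-and-two-sticks
#' fit, initialized either with the ground truth ("truth") or by
#' inverting the dynamic model from independent fits ("invert"). The
#' estimates are the fraction-scaled stick errors per metabolite and
#' their total, so the Monte Carlo mean (bias against a truth of zero)
#' is the mean stick error.
#'
#' @param n_dir 6 or 60 directions.
#' @param init "truth" or "invert".
#' @param snr b = 0 NAA SNR of the 6-direction protocol.
#' @export
mc_scenario_cs5 <- function(n_dir, init = "truth", snr = 40) {
  list(
    generator = function(seed) gen_dmrs_directions(n_dir, seed, snr = snr),
    truth = function(gen) c(NAA = 0, Cr = 0, Ins = 0, total = 0),
    run_rep = function(gen) {
      fd <- if (init == "truth") {
        fit_dynamic(gen$series, gen$basis, gen$config, gen$tvar, gen$opts,
                    init = unname(gen$truth_theta))
      } else {
        fit_dynamic(gen$series, gen$basis, gen$config, gen$tvar, gen$opts,
                    init = "invert")
      }
      if (!fd$converged) stop("dynamic fit did not converge")
      errs <- vapply(c("NAA", "Cr", "Ins"), function(m)
        stick_error(sticks_from_theta(fd$par, m),
                    sticks_from_theta(gen$truth_theta, m)), 0)
      list(dyn = c(errs, total = sum(errs)))
    })
}
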