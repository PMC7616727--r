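# Synthetic-data generators: stated truths, reproducibility, SNR
# calibration, per-case structural properties.

test_that("two-peak toy series implements the stated paradigm", {
  g <- gen_two_peak(0.1, Inf, seed = 1)
  expect_equal(n_transients(g$series), 64L)
  expect_equal(g$truth_theta[["conc_B_beta1"]] /
                 g$truth_theta[["conc_B_beta0"]], 0.2)
  # off-stimulation transients share one expected spectrum
  tr <- g$series$transients
  for (t in c(2:16, 50:64))
    expect_lt(max(Mod(tr[t, ] - tr[1, ])), 1e-12)
  expect_gt(max(Mod(tr[33, ] - tr[1, ])), 1e-3)  # stimulation differs
  expect_error(gen_two_peak(20, Inf, seed = 1),
               class = "mrsdyn_domain_error")
  # bit-reproducible given the seed
  a <- gen_two_peak(0.1, 15, seed = 7)
  b <- gen_two_peak(0.1, 15, seed = 7)
  expect_identical(a$series$transients, b$series$transients)
  expect_false(identical(a$series$transients,
                         gen_two_peak(0.1, 15, seed = 8)$series$transients))
})

test_that("generated singlet SNR matches the request within 10%", {
  for (snr in c(20, 100)) {
    g <- gen_two_peak(0.1, snr, seed = 3)
    meas <- vapply(1:16, function(t)
      measure_snr(g$series$transients[t, ], g$series$grid,
                  ppm_range = c(4.5, 4.65), lw_hz = 5,
                  noise_sd = g$truth$noise_sd), 0)
    expect_lt(abs(mean(meas) / snr - 1), 0.10)
  }
})

test_that("realistic fMRS simulation modulates only the target", {
  g <- gen_fmrs_spectrum("NAA", 6, seed = 2, snr = Inf)
  expect_equal(n_transients(g$series), 60L)
  th <- g$truth_theta
  stim_betas <- th[grep("_beta1$", names(th))]
  stim_betas <- stim_betas[grep("^conc_", names(stim_betas))]
  expect_equal(unname(stim_betas[["conc_NAA_beta1"]]),
               0.2 * brain_metabolites()$NAA$conc)
  expect_true(all(stim_betas[names(stim_betas) != "conc_NAA_beta1"] == 0))
  # dynamic fit on noiseless output recovers the 20% increase
  fd <- fit_dynamic(g$series, g$basis, g$config, g$tvar, g$opts)
  expect_equal(fd$par[["conc_NAA_beta1"]] / fd$par[["conc_NAA_beta0"]],
               0.2, tolerance = 1e-3)
})

test_that("wider simulated linewidth yields broader fitted gamma", {
  fit_gamma <- function(lw, seed) {
    g <- gen_fmrs_spectrum("NAA", lw, seed = seed, snr = 30)
    fit_dynamic(g$series, g$basis, g$config, g$tvar, g$opts,
                init = "mean")$par[["gamma_g0"]]
  }
  g6 <- vapply(1:3, function(i) fit_gamma(6, 400 + i), 0)
  g10 <- vapply(1:3, function(i) fit_gamma(10, 400 + i), 0)
  expect_gt(mean(g10), mean(g6))
})

test_that("MEGA generator: editing structure, noise accounting", {
  g <- gen_mega(5, seed = 4, snr = 60)
  expect_equal(length(g$basis$names), 19L)
  expect_equal(n_transients(g$pair), 2L)
  # edit-off-only arm carries half the noise variance: check across reps
  set.seed(1)
  vs <- t(vapply(1:120, function(i) {
    gi <- gen_mega(5, seed = 1000 + i, snr = 60)
    nl <- mrsdyn:::synth_transients(
      dyn_plan(gi$config, gi$basis, gi$tvar, 2L), gi$truth_theta,
      gi$basis, gi$pair$grid, 2L)
    c(var(Re(gi$pair$transients[1, ] - nl[1, ])),
      var(Re(gi$off_half$transients[1, ] - nl[1, ])))
  }, c(0, 0)))
  expect_equal(mean(vs[, 2]) / mean(vs[, 1]), 0.5, tolerance = 0.1)
  # non-edited metabolites cancel in the difference basis
  expect_false("Cr" %in% g$basis_diff$names)
  expect_false("NAA" %in% g$basis_diff$names)
  expect_true(all(c("GABA", "Glu", "Gln") %in% g$basis_diff$names))
  # noiseless difference fit recovers the GABA truth
  gn <- gen_mega(5, seed = 5, noise_sd = 0)
  diff_fid <- gn$pair$transients[2, ] - gn$pair$transients[1, ]
  fd <- fit_independent(fid_series(diff_fid, gn$pair$grid), gn$basis_diff,
                        gn$opts)
  expect_equal(unname(fd$estimates["conc_GABA", 1]), 1.5, tolerance = 1e-3)
})

test_that("fMRS cohort: design, truths, inter-subject structure", {
  co <- gen_fmrs_cohort(3, seed = 9)
  expect_equal(ncol(co$design), 4L)
  expect_equal(colnames(co$design), c("stim1", "stim2", "drift", "const"))
  s <- co$subjects[[1]]
  # control condition carries no stimulation effects
  ctrl_stim <- s$truth_ctrl[grep("_beta[01]$", names(s$truth_ctrl))]
  expect_true(all(ctrl_stim == 0))
  # stimulation condition modulates exactly the four target metabolites
  st <- s$truth_stim[grep("^conc_.*_beta0$", names(s$truth_stim))]
  nz <- names(st)[st != 0]
  expect_setequal(nz, paste0("conc_", c("Glu", "Lac", "Glc", "Asp"),
                             "_beta0"))
  expect_gt(s$truth_stim[["conc_Glu_beta0"]], 0)
  expect_lt(s$truth_stim[["conc_Glc_beta0"]], 0)
  # BOLD line narrowing: negative gamma stimulation effect
  expect_lt(s$truth_stim[["gamma_g0_beta0"]], 0)
  expect_equal(s$truth_ctrl[["gamma_g0_beta0"]], 0)
})

test_that("multi-direction diffusion series has the stated scheme", {
  g <- gen_dmrs_directions(6, seed = 10, snr = Inf)
  expect_equal(n_transients(g$series), 2L * 6L + 1L)
  expect_equal(sort(unique(g$tvar$columns$b)), c(0, 1, 3))
  # b = 0 transient carries unattenuated concentrations: its mapped
  # concentration equals the amplitude truth
  plan <- dyn_plan(g$config, g$basis, g$tvar, -1L)
  v0 <- map_parameters(plan, g$truth_theta, 1)
  expect_equal(unname(v0["conc_NAA"]), 10)
  # mapped attenuation matches the direct ball+sticks closed form,
  # written out independently of the model code
  for (t in c(3, 9, 13)) {
    vt <- map_parameters(plan, g$truth_theta, t)
    gvec <- unlist(g$tvar$columns[t, c("gx", "gy", "gz")])
    b <- g$tvar$columns$b[t]
    a1 <- gvec[["gx"]]; a2 <- gvec[["gy"]]  # sticks on the x and y axes
    S <- (1 - 0.7) * exp(-b * 0.35) + 0.35 * exp(-b * 0.35 * a1^2) +
      0.35 * exp(-b * 0.35 * a2^2)
    expect_equal(unname(vt["conc_NAA"]), 10 * S, tolerance = 1e-10)
  }
  # 60-direction protocol has 10x the noise variance
  g6 <- gen_dmrs_directions(6, seed = 11)
  g60 <- gen_dmrs_directions(60, seed = 11)
  expect_equal(g60$truth$noise_sd / g6$truth$noise_sd, sqrt(10),
               tolerance = 1e-10)
})

test_that("multi-b diffusion series: grid and decay structure", {
  g <- gen_dmrs_multib(seed = 12, snr = Inf)
  b <- g$truth$bvals
  expect_equal(b[1], 0.02)
  expect_equal(b[7], 50)
  expect_equal(diff(log(b)), rep(diff(log(b))[1], 6))  # log-spaced
  # macromolecule trajectory is mono-exponential: log-linear in b
  plan <- dyn_plan(g$config, g$basis, g$tvar, 1L)
  mm <- vapply(1:7, function(t)
    map_parameters(plan, g$truth_theta, t)[["conc_MM"]], 0)
  fitl <- stats::lm(log(mm) ~ b)
  expect_lt(max(abs(stats::resid(fitl))), 1e-10)
  # baseline coefficient follows exponential-plus-offset
  bl <- vapply(1:7, function(t)
    map_parameters(plan, g$truth_theta, t)[["b_re_0"]], 0)
  expect_equal(bl, 0.5 * exp(-b * 1.5) + 0.05, tolerance = 1e-12)
})
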