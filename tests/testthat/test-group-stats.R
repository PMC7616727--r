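# First-level contrasts, metabolite combination, group-level GLM.

# a small dynamic fit shared across tests: two metabolites on a GLM
fixture_glm_fit <- function(noise = 0.02, seed = 21) {
  basis <- toy_basis()
  T_n <- 12L
  X <- cbind(const = 1, stim = rep(c(0, 1), each = 6))
  tvar <- time_variable(as.data.frame(X))
  cfg <- dynamic_config(list(
    conc = list(model = "glm", covariates = c("const", "stim")),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed"))
  plan <- dyn_plan(cfg, basis, tvar, -1L)
  th <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  th["conc_A_beta0"] <- 1.2; th["conc_A_beta1"] <- 0.3
  th["conc_B_beta0"] <- 0.8; th["conc_B_beta1"] <- 0.1
  th[c("gamma_A", "gamma_B")] <- 5
  tr <- mrsdyn:::synth_transients(plan, th, basis, basis$grid)
  set.seed(seed)
  tr <- tr + complex(real = rnorm(length(tr), 0, noise),
                     imaginary = rnorm(length(tr), 0, noise))
  fit_dynamic(fid_series(tr, basis$grid), basis, cfg, tvar,
              fit_options(baseline_order = -1L))
}

test_that("first-level copes: selector, analytic varcope, delta ratio", {
  fit <- fixture_glm_fit()
  # selector contrast returns the estimate and its variance
  cp <- first_level_cope(fit, c(conc_A_beta1 = 1))
  expect_equal(cp$cope, unname(fit$par[["conc_A_beta1"]]))
  expect_equal(cp$varcope, unname(fit$cov["conc_A_beta1", "conc_A_beta1"]))
  expect_error(first_level_cope(fit, c(nope = 1)),
               class = "mrsdyn_format_error")
  # w = (1, 1) with unit variances and covariance 0.5 gives varcope 3
  fake <- fit
  fake$par <- c(a = 0, b = 0)
  fake$cov <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                           c("a", "b")))
  expect_equal(first_level_cope(fake, c(a = 1, b = 1))$varcope, 3)
  # delta-method percent change: finite, positive variance, and close to
  # a Monte Carlo of the ratio under the fit's own covariance
  rr <- first_level_ratio(fit, "conc_A_beta1", "conc_A_beta0")
  expect_true(is.finite(rr$cope) && rr$varcope > 0)
  set.seed(1)
  V <- fit$cov[c("conc_A_beta1", "conc_A_beta0"),
               c("conc_A_beta1", "conc_A_beta0")]
  L <- chol(V)
  draws <- matrix(rnorm(2 * 4000), ncol = 2) %*% L
  ratio <- (fit$par[["conc_A_beta1"]] + draws[, 1]) /
    (fit$par[["conc_A_beta0"]] + draws[, 2])
  expect_equal(rr$varcope, var(ratio), tolerance = 0.15)
})

test_that("combine_metabolites sums betas and propagates covariance", {
  fit <- fixture_glm_fit()
  comb <- combine_metabolites(fit, c("A", "B"), "AB")
  idx <- c("conc_A_beta0", "conc_B_beta0")
  expect_equal(unname(comb$par[1]),
               unname(sum(fit$par[idx])))
  expect_equal(unname(comb$cov[1, 1]),
               sum(fit$cov[idx, idx]))  # includes cross-covariances
  # with zero cross-covariance the variance is the plain sum
  fit0 <- fit
  fit0$cov[idx[1], idx[2]] <- 0
  fit0$cov[idx[2], idx[1]] <- 0
  comb0 <- combine_metabolites(fit0, c("A", "B"), "AB")
  expect_equal(unname(comb0$cov[1, 1]), sum(diag(fit0$cov[idx, idx])))
  # combined-then-contrast equals contrast-then-combined
  w <- c(0.5, 0.5)
  c1 <- drop(w %*% comb$par)
  c2 <- sum(vapply(c("A", "B"), function(m)
    first_level_cope(fit, stats::setNames(w, paste0("conc_", m,
                                                    c("_beta0", "_beta1"))))$cope,
    0))
  expect_equal(c1, c2, tolerance = 1e-12)
  # combination conserves total modelled concentration at every transient
  X <- cbind(1, rep(c(0, 1), each = 6))
  tot_comb <- drop(X %*% comb$par)
  tot_sep <- fit$mapped["conc_A", ] + fit$mapped["conc_B", ]
  expect_equal(tot_comb, unname(tot_sep), tolerance = 1e-10)
  # nonlinear models refuse combination
  g <- gen_dmrs_multib(seed = 2, snr = Inf)
  fitb <- fit_dynamic(g$series, g$basis, g$config, g$tvar, g$opts,
                      init = unname(g$truth_theta))
  expect_error(combine_metabolites(fitb, c("NAA", "Cr")),
               class = "mrsdyn_format_error")
})

test_that("group GLM: symmetry, paired-t equivalence, recovery", {
  n_sub <- 8
  design <- group_design_paired(n_sub)
  # identical stimulation and control copes: zero effect, z = 0
  copes <- rep(rnorm(n_sub, 1, 0.1), 2)
  g0 <- group_glm(copes, rep(0.05, 2 * n_sub), design, "condition")
  expect_equal(g0$cope, 0, tolerance = 1e-12)
  expect_equal(g0$z, 0, tolerance = 1e-12)
  expect_error(group_glm(copes, rep(0, 2 * n_sub), design, "condition"),
               class = "mrsdyn_domain_error")
  # equal varcopes reduce to the classical paired t statistic
  set.seed(5)
  a <- rnorm(n_sub, 1.3, 0.4); b <- rnorm(n_sub, 1.0, 0.4)
  g1 <- group_glm(c(a, b), rep(0.2, 2 * n_sub), design, "condition")
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(g1$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(g1$p, tt$p.value, tolerance = 1e-8)
  expect_equal(2 * g1$cope, unname(tt$estimate), tolerance = 1e-8)
  # known condition effect recovered within 3 SE over replicates
  set.seed(6)
  delta <- 0.4
  ests <- replicate(200, {
    offs <- rnorm(n_sub, 5, 1)
    stim <- offs + delta / 2 + rnorm(n_sub, 0, 0.3)
    ctrl <- offs - delta / 2 + rnorm(n_sub, 0, 0.3)
    group_glm(c(stim, ctrl), rep(0.09, 2 * n_sub), design, "condition")$cope
  })
  expect_lt(abs(mean(2 * ests) - delta), 3 * sd(2 * ests) / sqrt(200))
  expect_error(group_glm(c(a, b), rep(0.1, 2 * n_sub),
                         cbind(design, design[, 1]), "condition"),
               class = "mrsdyn_domain_error")
})

test_that("group GLM type-I error is calibrated under the null", {
  set.seed(8)
  n_sub <- 10
  design <- group_design_paired(n_sub)
  n_sim <- 1500
  p <- replicate(n_sim, {
    offs <- rnorm(n_sub, 2, 0.5)
    stim <- offs + rnorm(n_sub, 0, 0.25)
    ctrl <- offs + rnorm(n_sub, 0, 0.25)
    group_glm(c(stim, ctrl), rep(0.0625, 2 * n_sub), design, "condition")$p
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
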