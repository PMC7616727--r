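# Independent and dynamic fitting, initialization, covariance.

noiseless_series <- function(params, basis) {
  fid_series(matrix(spectrum_to_fid(forward_spectrum(params, basis,
                                                     baseline_order = -1L)),
                    1), basis$grid)
}

test_that("noiseless single-transient fit recovers interior truth", {
  basis <- toy_basis()
  truth <- spectral_params(conc = c(1.3, 0.7), gamma = c(4, 6),
                           eps = c(3, -5), phi0 = 0.1, phi1 = 2e-4)
  series <- noiseless_series(truth, basis)
  f <- fit_independent(series, basis, fit_options(baseline_order = -1L))
  est <- f$estimates[, 1]
  tv <- mrsdyn:::pack_spectral(truth, basis, -1L)
  expect_lt(max(abs(est - tv) / pmax(abs(tv), 1e-3)), 1e-6)
  expect_true(all(f$converged))
})

test_that("identical transients give identical estimates (determinism)", {
  basis <- toy_basis()
  set.seed(1)
  fid <- spectrum_to_fid(forward_spectrum(toy_params(), basis,
                                          baseline_order = -1L)) +
    complex(real = rnorm(256, 0, 0.02), imaginary = rnorm(256, 0, 0.02))
  series <- fid_series(rbind(fid, fid), basis$grid)
  f <- fit_independent(series, basis, fit_options(baseline_order = -1L))
  expect_identical(f$estimates[, 1], f$estimates[, 2])
  f2 <- fit_independent(series, basis, fit_options(baseline_order = -1L))
  expect_identical(f$estimates, f2$estimates)
})

test_that("init_spectral locates shift within a bin and is deterministic", {
  basis <- toy_basis()
  dnu <- 1 / (256 * 1e-3)
  truth <- spectral_params(conc = c(1, 1), gamma = c(2, 2),
                           eps = c(40, 40))  # shared true shift
  series <- noiseless_series(truth, basis)
  ini <- init_spectral(series$transients[1, ], basis,
                       fit_options(baseline_order = -1L))
  expect_lt(abs(ini$eps[1] - 40), 2 * pi * dnu)
  ini2 <- init_spectral(series$transients[1, ], basis,
                        fit_options(baseline_order = -1L))
  expect_identical(ini, ini2)
  # zero signal: zero concentrations
  z <- init_spectral(rep(0 + 0i, 256), basis, fit_options())
  expect_equal(z$conc, c(0, 0))
})

test_that("all-variable dynamic fit matches independent fits (equivalence)", {
  basis <- toy_basis()
  set.seed(2)
  T_n <- 3L
  base_fid <- spectrum_to_fid(forward_spectrum(toy_params(), basis,
                                               baseline_order = -1L))
  tr <- t(vapply(1:T_n, function(t)
    base_fid + complex(real = rnorm(256, 0, 0.05),
                       imaginary = rnorm(256, 0, 0.05)), complex(256)))
  series <- fid_series(tr, basis$grid)
  tvar <- time_variable(data.frame(idx = seq_len(T_n)))
  cfg <- dynamic_config(list(conc = "variable", gamma = "variable",
                             eps = "variable", phi0 = "variable",
                             phi1 = "variable"))
  opts <- fit_options(baseline_order = -1L, ftol = 1e-12, gtol = 1e-9)
  fi <- fit_independent(series, basis, opts)
  fd <- fit_dynamic(series, basis, cfg, tvar, opts)
  expect_equal(fd$rss, sum(fi$rss), tolerance = 1e-6)
  # dynamic parameter count never exceeds the independent count when
  # any behavior is constrained
  cfg2 <- dynamic_config(list(conc = "variable", gamma = "fixed",
                              eps = "fixed", phi0 = "fixed",
                              phi1 = "fixed"))
  plan2 <- dyn_plan(cfg2, basis, tvar, -1L)
  expect_lt(plan2$n_theta, T_n * length(plan2$spars))
})

test_that("T = 1 all-fixed dynamic fit equals the independent fit", {
  basis <- toy_basis()
  set.seed(3)
  fid <- spectrum_to_fid(forward_spectrum(toy_params(), basis,
                                          baseline_order = -1L)) +
    complex(real = rnorm(256, 0, 0.03), imaginary = rnorm(256, 0, 0.03))
  series <- fid_series(matrix(fid, 1), basis$grid)
  tvar <- time_variable(data.frame(c0 = 1))
  cfg <- dynamic_config(list(conc = "fixed", gamma = "fixed", eps = "fixed",
                             phi0 = "fixed", phi1 = "fixed"))
  opts <- fit_options(baseline_order = -1L, ftol = 1e-12, gtol = 1e-9)
  fi <- fit_independent(series, basis, opts)
  fd <- fit_dynamic(series, basis, cfg, tvar, opts)
  expect_equal(unname(fd$par[paste0("conc_", basis$names)]),
               unname(fi$estimates[paste0("conc_", basis$names), 1]),
               tolerance = 1e-6)
  expect_equal(fd$rss, fi$rss[1], tolerance = 1e-8)
})

test_that("initialize_dynamic inverts models and echoes values", {
  basis <- toy_basis()
  T_n <- 12L
  X <- cbind(const = 1, stim = rep(c(0, 1), each = 6))
  tvar <- time_variable(as.data.frame(X))
  cfg <- dynamic_config(list(
    conc = list(model = "glm", covariates = c("const", "stim")),
    gamma = "fixed", eps = "fixed", phi0 = "variable", phi1 = "fixed"))
  plan <- dyn_plan(cfg, basis, tvar, -1L)
  # closed-form inversion: noiseless conc series gives exact betas
  beta_true <- c(2, 0.5)
  E <- matrix(0, length(plan$spars), T_n, dimnames = list(plan$spars, NULL))
  E["conc_A", ] <- drop(X %*% beta_true)
  E["conc_B", ] <- 1
  E["gamma_A", ] <- 3; E["gamma_B", ] <- 4
  E["phi0", ] <- seq(0, 1.1, length.out = T_n)
  th <- initialize_dynamic("invert", plan, independent_fits = E)
  expect_equal(unname(th[c("conc_A_beta0", "conc_A_beta1")]), beta_true,
               tolerance = 1e-10)
  expect_equal(unname(th["gamma_A"]), 3)              # fixed -> mean
  expect_equal(unname(th[grep("^phi0_t", names(th))]),
               E["phi0", ])                            # variable -> series
  # singular design: model inversion failure is an init error
  tvar_bad <- time_variable(data.frame(const = rep(1, T_n),
                                       stim = rep(1, T_n)))
  plan_bad <- dyn_plan(cfg, basis, tvar_bad, -1L)
  expect_error(initialize_dynamic("invert", plan_bad,
                                  independent_fits = E),
               class = "mrsdyn_init_error")
  # "values" echoes verbatim (within bounds)
  v <- runif(plan$n_theta, 0.1, 0.9)
  expect_equal(unname(initialize_dynamic("values", plan, values = v)), v)
  expect_error(initialize_dynamic("values", plan, values = 1:3),
               class = "mrsdyn_init_error")
})

test_that("ball-and-two-sticks inversion recovers noiseless attenuations", {
  dirs <- mrsdyn:::fibonacci_hemisphere(60)
  tv <- data.frame(b = c(0, rep(1, 60), rep(3, 60)),
                   gx = c(1, dirs[, 1], dirs[, 1]),
                   gy = c(0, dirs[, 2], dirs[, 2]),
                   gz = c(0, dirs[, 3], dirs[, 3]))
  p_true <- c(5, 0.35, 0.3, 0.35, pi / 2, 0, pi / 2, pi / 2)
  mod <- get_dynamic_model("ball2sticks")
  y <- vapply(seq_len(nrow(tv)), function(t)
    mrsdyn:::ball2sticks_val(p_true, tv$b[t],
                             c(tv$gx[t], tv$gy[t], tv$gz[t])), 0)
  p0 <- mod$invert(y, tv)
  rf <- function(p) vapply(seq_along(y), function(t)
    mrsdyn:::ball2sticks_val(p, tv$b[t], c(tv$gx[t], tv$gy[t], tv$gz[t])), 0) - y
  jf <- function(p) t(vapply(seq_along(y), function(t)
    mrsdyn:::ball2sticks_grad(p, tv$b[t], c(tv$gx[t], tv$gy[t], tv$gz[t])),
    numeric(8)))
  ref <- mrsdyn:::lm_fit(rf, jf, p0, lower = mod$lower, upper = mod$upper)
  est <- rbind(c(ref$par[2], mrsdyn:::stick_vec(ref$par[5], ref$par[6])),
               c(ref$par[3], mrsdyn:::stick_vec(ref$par[7], ref$par[8])))
  tru <- rbind(c(0.35, 1, 0, 0), c(0.3, 0, 1, 0))
  expect_lt(stick_error(est, tru), 0.02)
  expect_equal(unname(ref$par[1]), 5, tolerance = 1e-3)
})

test_that("covariance estimation: identity, guards and MC calibration", {
  # orthonormal Jacobian with unit residual variance -> identity covariance
  n <- 40
  J <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  r <- rnorm(n)
  cv <- estimate_covariance(J, r * sqrt((n - 3) / sum(r^2)))
  expect_equal(unname(cv$cov), diag(3), tolerance = 1e-10)
  expect_error(estimate_covariance(matrix(1, 2, 3), c(1, 1)),
               class = "mrsdyn_domain_error")
  # rank-deficient Jacobian: guarded inverse flags the null direction
  Jd <- cbind(J[, 1], J[, 1], J[, 2])
  cvd <- estimate_covariance(Jd, r)
  expect_length(cvd$degenerate, 1L)
  expect_true(all(is.finite(cvd$cov)))

  # spectral-fit Monte Carlo at SNR ~ 50: the covariance-predicted SD of
  # a concentration tracks the sampling SD within 20%
  basis <- toy_basis()
  truth <- spectral_params(conc = c(1, 0.7), gamma = c(5, 5))
  base_fid <- spectrum_to_fid(forward_spectrum(truth, basis,
                                               baseline_order = -1L))
  sigma <- max(Mod(fid_to_spectrum(base_fid))) / 50
  opts <- fit_options(baseline_order = -1L)
  set.seed(77)
  pred_sd <- NULL
  ests <- vapply(1:200, function(i) {
    fid <- base_fid + complex(real = rnorm(256, 0, sigma),
                              imaginary = rnorm(256, 0, sigma))
    f <- fit_independent(fid_series(matrix(fid, 1), basis$grid), basis,
                         opts, covariance = (i == 1))
    if (i == 1) pred_sd <<- f$fits[[1]]$uncertainties[["conc_A"]]
    f$estimates["conc_A", 1]
  }, 0)
  expect_lt(abs(sd(ests) / pred_sd - 1), 0.2)
})

test_that("noiseless dynamic fits recover every generator truth", {
  # closes the loop for each case-study generator at <= 1e-3 relative
  tol_check <- function(fit, truth) {
    tr <- truth[names(fit$par)]
    expect_lt(max(abs(fit$par - tr) / pmax(abs(tr), 0.05)), 1e-3)
    expect_true(fit$converged)
  }
  g1 <- gen_two_peak(0.08, Inf, seed = 5)
  tol_check(fit_dynamic(g1$series, g1$basis, g1$config, g1$tvar, g1$opts),
            g1$truth_theta)
  g6 <- gen_dmrs_multib(seed = 6, snr = Inf)
  tol_check(fit_dynamic(g6$series, g6$basis, g6$config, g6$tvar, g6$opts,
                        init = unname(g6$truth_theta) * 1.05),
            g6$truth_theta)
})
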