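# Dynamic model library, configuration semantics, parameter mapping.

test_that("free-parameter accounting matches the behavior layout", {
  basis <- toy_basis()
  T_n <- 64L
  tvar <- time_variable(data.frame(const = rep(1, T_n),
                                   stim = rep(0:1, each = 32)))
  # all conc on a 2-covariate GLM, nuisances fixed -> 2K + n_nuisance
  cfg <- dynamic_config(list(
    conc = list(model = "glm", covariates = c("const", "stim")),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed"))
  plan <- dyn_plan(cfg, basis, tvar, baseline_order = -1L)
  expect_equal(plan$n_theta, 2L * 2L + 2L + 2L + 2L)
  # "variable" phi0 contributes T free parameters
  cfg2 <- dynamic_config(list(
    conc = "fixed", gamma = "fixed", eps = "fixed",
    phi0 = "variable", phi1 = "fixed"))
  plan2 <- dyn_plan(cfg2, basis, tvar, baseline_order = -1L)
  expect_equal(plan2$n_theta, 2L + 2L + 2L + T_n + 1L)
  expect_equal(sum(grepl("^phi0_t", plan2$theta_names)), T_n)
  # mixed config property over random draws
  set.seed(3)
  for (i in 1:5) {
    beh <- sample(c("fixed", "variable"), 8, replace = TRUE)
    names(beh) <- plan$spars[1:8]
    cfg3 <- dynamic_config(as.list(beh))
    plan3 <- dyn_plan(cfg3, basis, tvar, baseline_order = -1L)
    expect_equal(plan3$n_theta,
                 sum(ifelse(beh == "variable", T_n, 1L)))
  }
})

test_that("map_parameters implements fixed/variable/model semantics", {
  basis <- toy_basis()
  tvar <- time_variable(data.frame(const = c(1, 1, 1), stim = c(0, 1, 1),
                                   b = c(0, 1, 3)))
  cfg <- dynamic_config(list(
    conc_A = "fixed",
    conc_B = list(model = "glm", covariates = c("const", "stim")),
    gamma = "variable", eps = "fixed", phi0 = "fixed", phi1 = "fixed"))
  plan <- dyn_plan(cfg, basis, tvar, baseline_order = -1L)
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  theta["conc_A"] <- 3.0
  theta["conc_B_beta0"] <- 1.0
  theta["conc_B_beta1"] <- 0.2
  theta[grep("^gamma_A_t", plan$theta_names)] <- c(1, 2, 3)
  v1 <- map_parameters(plan, theta, 1)
  v2 <- map_parameters(plan, theta, 2)
  expect_equal(unname(v1["conc_A"]), 3.0)   # fixed: same at every t
  expect_equal(unname(v2["conc_A"]), 3.0)
  expect_equal(unname(v1["conc_B"]), 1.0)   # glm dot product
  expect_equal(unname(v2["conc_B"]), 1.2)
  expect_equal(unname(v1["gamma_A"]), 1)    # variable: t-th element
  expect_equal(unname(v2["gamma_A"]), 2)
  expect_error(map_parameters(plan, theta, 4), class = "mrsdyn_shape_error")

  # gradient structure and finite-difference agreement
  M <- map_gradient(plan, theta, 2)
  expect_equal(unname(M["conc_B", c("conc_B_beta0", "conc_B_beta1")]),
               c(1, 1))  # design row, independent of beta
  set.seed(11)
  for (t in 1:3) {
    th <- theta + rnorm(length(theta)) * 0.1
    M <- map_gradient(plan, th, t)
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-6 * max(1, abs(th[i]))
      tp <- th; tm <- th; tp[i] <- th[i] + h; tm[i] <- th[i] - h
      (map_parameters(plan, tp, t) - map_parameters(plan, tm, t)) / (2 * h)
    }, numeric(length(plan$spars)))
    expect_lt(max(abs(M - fd)), 1e-6 * max(1, max(abs(M))))
  }
})

test_that("exponential-family models match closed forms and gradients", {
  reg <- get_dynamic_model("exp")
  expect_equal(reg$fn(c(2, 0.5), c(b = 0)), 2)           # b = 0 -> A
  expect_equal(reg$fn(c(1, 1), c(b = 1)), exp(-1), tolerance = 1e-6)
  off <- get_dynamic_model("exp_offset")
  expect_equal(off$fn(c(3, 0.8, 0.25), c(b = 1e6)), 0.25)  # large-b limit
  bi <- get_dynamic_model("biexp")
  for (b in c(0, 0.5, 2, 10)) {
    expect_equal(bi$fn(c(2, 1, 0.7, 0.1), c(b = b)),
                 reg$fn(c(2, 0.7), c(b = b)))  # f = 1 collapses to monoexp
  }
  set.seed(5)
  for (mod in list(reg, off, bi)) {
    np <- mod$nparam
    for (i in 1:3) {
      p <- runif(np, 0.1, 1.5)
      x <- c(b = runif(1, 0, 3))
      g <- mod$grad(p, x)
      gfd <- fd_model_grad(mod$fn, p, x)
      expect_lt(max(abs(g - gfd)) / max(1, max(abs(g))), 1e-6)
    }
  }
})

test_that("ball-and-two-sticks attenuation has the stated geometry", {
  v1 <- c(1, 0, 0)
  # no sticks: isotropic ball for any direction
  expect_equal(as.numeric(model_ball_two_sticks(0, 0, 0.4, 0, 0, 0, 0,
                                                b = 2, g = c(0, 1, 0))),
               exp(-2 * 0.4))
  # single stick, perpendicular gradient: no attenuation
  expect_equal(as.numeric(model_ball_two_sticks(1, 0, 0.4, pi / 2, 0, 0, 0,
                                                b = 3, g = c(0, 0, 1))), 1)
  # single stick, parallel gradient: full attenuation
  expect_equal(as.numeric(model_ball_two_sticks(1, 0, 0.4, pi / 2, 0, 0, 0,
                                                b = 3, g = v1)),
               exp(-3 * 0.4))
  # antipodal symmetry: v -> -v leaves the signal unchanged
  set.seed(9)
  for (i in 1:5) {
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    g <- mrsdyn:::stick_vec(runif(1, 0, pi), runif(1, 0, 2 * pi))
    a <- model_ball_two_sticks(0.4, 0.3, 0.35, th, ph, 1, 2, b = 2, g = g)
    b_ <- model_ball_two_sticks(0.4, 0.3, 0.35, pi - th, ph + pi, 1, 2,
                                b = 2, g = g)
    expect_equal(as.numeric(a), as.numeric(b_), tolerance = 1e-12)
  }
  # constraint violations error out
  expect_error(model_ball_two_sticks(0.7, 0.5, 0.3, 0, 0, 0, 0, b = 1,
                                     g = v1), class = "mrsdyn_domain_error")
  expect_error(model_ball_two_sticks(0.2, 0.2, 0.3, 0, 0, 0, 0, b = 1,
                                     g = c(2, 0, 0)),
               class = "mrsdyn_domain_error")
  # analytic gradient vs central differences (registry form with amp)
  mod <- get_dynamic_model("ball2sticks")
  set.seed(13)
  for (i in 1:5) {
    p <- c(runif(1, 1, 5), runif(2, 0.1, 0.4), runif(1, 0.1, 0.6),
           runif(1, 0.2, 2.8), runif(1, 0, 6), runif(1, 0.2, 2.8),
           runif(1, 0, 6))
    gdir <- mrsdyn:::stick_vec(runif(1, 0, pi), runif(1, 0, 2 * pi))
    x <- c(b = runif(1, 0.5, 3), gx = gdir[1], gy = gdir[2], gz = gdir[3])
    expect_lt(max(abs(mod$grad(p, x) - fd_model_grad(mod$fn, p, x))) /
                max(1, max(abs(mod$grad(p, x)))), 1e-6)
  }
})

test_that("Glover HRF and design construction", {
  expect_equal(glover_hrf(0), 0)
  # dense numeric argmax near 5.4 s
  tg <- seq(0, 30, by = 0.001)
  expect_lt(abs(tg[which.max(glover_hrf(tg))] - 5.4), 0.3)
  X <- convolve_design(onsets = c(20), durations = c(30),
                       n_transients = 40, tr = 2)
  expect_equal(colnames(X), c("stim1", "drift", "const"))
  expect_equal(unname(X[, "const"]), rep(1, 40))
  expect_equal(sum(X[, "drift"]), 0)
  expect_equal(max(X[, "stim1"]), 1)      # peak-normalized
  expect_equal(unname(X[1, "stim1"]), 0)  # nothing before the first onset
  expect_error(convolve_design(c(10), c(-5), 40, 2),
               class = "mrsdyn_domain_error")
  expect_error(convolve_design(c(70), c(20), 40, 2),
               class = "mrsdyn_domain_error")
})

test_that("custom models can be registered and used in configs", {
  register_dynamic_model("lin_b", nparam = 2L,
                         fn = function(p, x) p[1] + p[2] * x[["b"]],
                         grad = function(p, x) c(1, x[["b"]]),
                         suffixes = c("a", "slope"), covariates = "b")
  basis <- toy_basis()
  tvar <- time_variable(data.frame(b = c(0, 1, 2)))
  cfg <- dynamic_config(list(conc = list(model = "lin_b")))
  plan <- dyn_plan(cfg, basis, tvar, baseline_order = -1L)
  expect_true("conc_A_slope" %in% plan$theta_names)
  th <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  th["conc_A_a"] <- 1; th["conc_A_slope"] <- 0.5
  expect_equal(unname(map_parameters(plan, th, 3)["conc_A"]), 2.0)
})
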