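# Fitting: independent per-transient nonlinear least squares, joint
# dynamic fitting with chained analytic gradients, initialization
# strategies, and covariance-based uncertainty.

#' Fitting options
#'
#' @param ppm_range numeric (low, high) window the objective is evaluated
#'   on, or NULL for the full spectrum.
#' @param baseline_order complex polynomial baseline order; -1 disables
#'   the baseline.
#' @param max_iter maximum optimizer iterations (>= 1).
#' @param ftol relative cost-decrease convergence threshold.
#' @param gtol gradient convergence threshold.
#' @param seed optional seed for any stochastic restart (the default
#'   optimizer is deterministic).
#' @return an object of class `fit_options`.
#' @export
fit_options <- function(ppm_range = NULL, baseline_order = 2L,
                        max_iter = 200L, ftol = 1e-7, gtol = 1e-6,
                        seed = NULL) {
  if (!is.null(ppm_range) && ppm_range[1] >= ppm_range[2])
    stop_domain("ppm_range low must be < high")
  if (max_iter < 1) stop_domain("max_iter must be >= 1")
  structure(list(ppm_range = ppm_range,
                 baseline_order = as.integer(baseline_order),
                 max_iter = as.integer(max_iter), ftol = ftol, gtol = gtol,
                 seed = seed),
            class = "fit_options")
}

default_spectral_bounds <- function(spar_names) {
  bd <- vapply(spar_names, default_spar_bounds, numeric(2))
  list(lower = stats::setNames(bd[1, ], spar_names),
       upper = stats::setNames(bd[2, ], spar_names))
}

# peak FWHM (Hz) of the tallest peak of a magnitude spectrum
measure_fwhm <- function(mag, nu) {
  i <- which.max(mag)
  half <- mag[i] / 2
  left <- i
  while (left > 1 && mag[left] > half) left <- left - 1
  right <- i
  while (right < length(mag) && mag[right] > half) right <- right + 1
  interp <- function(a, b) {
    if (mag[b] == mag[a]) return(nu[a])
    nu[a] + (half - mag[a]) * (nu[b] - nu[a]) / (mag[b] - mag[a])
  }
  fl <- if (left < i) interp(left, left + 1) else nu[1]
  fr <- if (right > i) interp(right, right - 1) else nu[length(nu)]
  max(fr - fl, nu[2] - nu[1])
}

#' Initial spectral parameter estimate for one transient
#'
#' Phases start at zero; the shift comes from the cross-correlation of
#' the data and unit-concentration model magnitude spectra; the
#' broadening from a matched-filter linewidth estimate minus the basis
#' linewidth (floored at zero); concentrations from non-negative linear
#' least squares at those nuisances; baseline at zero. Deterministic.
#'
#' @param fid complex FID vector of one transient.
#' @param basis a [basis_set()].
#' @param opts a [fit_options()].
#' @return a [spectral_params()] starting point.
#' @export
init_spectral <- function(fid, basis, opts = fit_options()) {
  grid <- basis$grid
  window <- fit_window(grid, opts$ppm_range)
  nu <- freq_axis(grid)[window]
  dnu <- 1 / (grid$n_points * grid$dwell_time)
  dspec <- fid_to_spectrum(fid)[window]
  gi <- basis_group_index(basis)
  G <- length(gi$labels)
  K <- length(basis$names)

  model_fid <- colSums(matrix(rep(1, K), K, 1)[, 1] * basis$fids)
  mspec <- fid_to_spectrum(model_fid)[window]
  dmag <- Mod(dspec); mmag <- Mod(mspec)
  if (max(dmag) <= 0) {
    return(spectral_params(conc = rep(0, K), gamma = rep(0, G),
                           eps = rep(0, G)))
  }
  maxlag <- min(50L, floor(length(nu) / 4))
  lags <- -maxlag:maxlag
  score <- vapply(lags, function(L) {
    if (L >= 0) sum(dmag[(1 + L):length(dmag)] * mmag[1:(length(mmag) - L)])
    else sum(dmag[1:(length(dmag) + L)] * mmag[(1 - L):length(mmag)])
  }, 0)
  lag <- lags[which.max(score)]
  eps0 <- -2 * pi * lag * dnu  # model peak shifts by -eps/2pi Hz

  fwhm_d <- measure_fwhm(dmag, nu)
  fwhm_m <- measure_fwhm(mmag, nu)
  gamma0 <- max(0, pi * (fwhm_d - fwhm_m))

  p0 <- spectral_params(conc = rep(0, K), gamma = rep(gamma0, G),
                        eps = rep(eps0, G))
  Jc <- spectral_gradient(p0, basis, grid, opts$ppm_range, baseline_order = -1L)
  A <- rbind(Re(Jc[, seq_len(K), drop = FALSE]),
             Im(Jc[, seq_len(K), drop = FALSE]))
  conc0 <- nnls_cd(A, c(Re(dspec), Im(dspec)))
  spectral_params(conc = conc0, gamma = rep(gamma0, G), eps = rep(eps0, G))
}

#' Covariance of free parameters from the Jacobian at the optimum
#'
#' Residual-variance scaled Gauss-Newton covariance with a rank-guarded
#' pseudo-inverse: `sigma2 = RSS / (n - P)`, `Cov = sigma2 (J'J)^-1`.
#'
#' @param jacobian real residual Jacobian (n x P), or complex (stacked
#'   internally as real and imaginary parts).
#' @param residuals real residual vector (complex accepted, stacked).
#' @return list with `cov`, `sd` (sqrt of the diagonal), `sigma2`, and
#'   `degenerate` (indices of near-null directions).
#' @export
estimate_covariance <- function(jacobian, residuals) {
  if (is.complex(jacobian)) jacobian <- rbind(Re(jacobian), Im(jacobian))
  if (is.complex(residuals)) residuals <- c(Re(residuals), Im(residuals))
  n <- nrow(jacobian); P <- ncol(jacobian)
  if (P >= n) stop_domain("need more data points than parameters")
  rss <- sum(residuals^2)
  sigma2 <- rss / (n - P)
  pin <- pinv_sym(crossprod(jacobian))
  cov <- sigma2 * pin$inv
  dimnames(cov) <- list(colnames(jacobian), colnames(jacobian))
  list(cov = cov, sd = sqrt(pmax(diag(cov), 0)), sigma2 = sigma2,
       degenerate = pin$degenerate)
}

cov_from_jtj <- function(JtJ, rss, n_data, names = NULL) {
  P <- ncol(JtJ)
  if (P >= n_data) stop_domain("need more data points than parameters")
  sigma2 <- rss / (n_data - P)
  pin <- pinv_sym(JtJ)
  cov <- sigma2 * pin$inv
  dimnames(cov) <- list(names, names)
  list(cov = cov, sd = stats::setNames(sqrt(pmax(diag(cov), 0)), names),
       sigma2 = sigma2, degenerate = pin$degenerate)
}

basis_per_t_list <- function(basis, T_n) {
  if (is.null(basis$per_timepoint)) return(NULL)
  bl <- lapply(basis$per_timepoint, function(b) t(b$fids))
  if (length(bl) != T_n) bl <- rep_len(bl, T_n)
  bl
}

#' Independent per-transient spectral fitting
#'
#' Bound-constrained nonlinear least squares on the concatenated real and
#' imaginary frequency-domain residuals of each transient separately.
#' Non-convergence is flagged in the result, not raised.
#'
#' @param data an [fid_series()].
#' @param basis a [basis_set()]; a `per_timepoint` basis is matched to
#'   transients in order.
#' @param opts a [fit_options()].
#' @param covariance compute the per-transient covariance (slower).
#' @return an object of class `independent_fits`: list with `estimates`
#'   (flat spectral parameter matrix, P x T), `fits` (per-transient
#'   results tables when `covariance`), `rss`, `converged`.
#' @export
fit_independent <- function(data, basis, opts = fit_options(),
                            covariance = TRUE) {
  grid <- data$grid
  T_n <- n_transients(data)
  ctx <- eval_context(basis, grid, opts$ppm_range, opts$baseline_order)
  spars <- spectral_param_names(basis, opts$baseline_order)
  bd <- default_spectral_bounds(spars)
  bpt <- basis_per_t_list(basis, T_n)

  specs <- vapply(seq_len(T_n),
                  function(t) fid_to_spectrum(data$transients[t, ])[ctx$window],
                  complex(length(ctx$window)))
  specs <- matrix(specs, ncol = T_n)

  p0 <- if (is.null(bpt) && T_n > 1L) {
    # shared nuisance init from the coherent average, per-transient
    # non-negative least squares for the concentrations
    mean_fid <- colMeans(data$transients)
    ip <- init_spectral(mean_fid, basis, opts)
    K <- length(basis$names)
    Jc <- spectral_gradient(ip, basis, grid, opts$ppm_range,
                            baseline_order = -1L)[, seq_len(K), drop = FALSE]
    A <- rbind(Re(Jc), Im(Jc))
    AtA <- crossprod(A)
    vapply(seq_len(T_n), function(t) {
      conc0 <- nnls_cd_pre(AtA, crossprod(A, c(Re(specs[, t]), Im(specs[, t]))))
      ip_t <- ip
      ip_t$conc <- conc0
      pack_spectral(ip_t, basis, opts$baseline_order)
    }, numeric(length(spars)))
  } else {
    vapply(seq_len(T_n), function(t) {
      b_t <- if (!is.null(basis$per_timepoint))
        basis$per_timepoint[[((t - 1L) %% length(basis$per_timepoint)) + 1L]]
      else basis
      pack_spectral(init_spectral(data$transients[t, ], b_t, opts), basis,
                    opts$baseline_order)
    }, numeric(length(spars)))
  }
  p0 <- matrix(p0, ncol = T_n)

  if (is.null(bpt)) {
    res <- cpp_fit_block(specs, ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel,
                         ctx$Breg, p0, bd$lower, bd$upper, opts$max_iter,
                         opts$ftol, opts$gtol)
  } else {
    # per-condition basis: fit each transient against its own basis
    est <- matrix(0, length(spars), T_n)
    rssv <- numeric(T_n); niter <- integer(T_n); conv <- integer(T_n)
    for (t in seq_len(T_n)) {
      r1 <- cpp_fit_transient(specs[, t], bpt[[t]], ctx$gidx, ctx$tau, ctx$nu,
                              ctx$sel, ctx$Breg, p0[, t], bd$lower, bd$upper,
                              opts$max_iter, opts$ftol, opts$gtol)
      est[, t] <- r1$par; rssv[t] <- r1$rss; niter[t] <- r1$niter
      conv[t] <- as.integer(r1$converged)
    }
    res <- list(par = est, rss = rssv, niter = niter, converged = conv)
  }
  rownames(res$par) <- spars
  n_data <- 2L * length(ctx$window)

  fits <- NULL
  if (covariance) {
    fits <- lapply(seq_len(T_n), function(t) {
      pm <- matrix(res$par[, t], ncol = 1)
      ev <- cpp_eval_block(if (is.null(bpt)) ctx$bmat else bpt[[t]], ctx$gidx,
                          ctx$tau, ctx$nu, ctx$sel, ctx$Breg, pm, TRUE)
      Jc <- ev$jac[, , 1]
      colnames(Jc) <- spars
      r <- drop(ev$spec) - specs[, t]
      cv <- estimate_covariance(Jc, r)
      results_table(par = stats::setNames(res$par[, t], spars), cov = cv$cov,
                    mapped = matrix(res$par[, t], ncol = 1,
                                    dimnames = list(spars, NULL)),
                    rss = res$rss[t], n_data = n_data,
                    converged = res$converged[t] == 1,
                    niter = res$niter[t],
                    init = list(strategy = "init_spectral"))
    })
  }
  structure(list(estimates = res$par, fits = fits, rss = res$rss,
                 converged = res$converged == 1, spars = spars,
                 n_data = n_data),
            class = "independent_fits")
}

#' @export
print.independent_fits <- function(x, ...) {
  cat(sprintf("<independent_fits> %d transients, %d params each, %d converged\n",
              ncol(x$estimates), nrow(x$estimates), sum(x$converged)))
  invisible(x)
}

#' Results table of a fit
#'
#' Container for free-parameter estimates, their covariance and
#' uncertainties (`sqrt(diag(cov))`), the mapped per-transient spectral
#' parameters, AIC and the initialization record.
#'
#' @param par named estimate vector.
#' @param cov covariance matrix (P x P).
#' @param mapped matrix of mapped spectral parameters (P_spec x T).
#' @param rss residual sum of squares.
#' @param n_data number of real-valued data points fitted.
#' @param converged logical convergence flag.
#' @param niter iterations used.
#' @param init initialization record (list).
#' @return object of class `results_table`.
#' @export
results_table <- function(par, cov, mapped, rss, n_data, converged,
                          niter = NA_integer_, init = list()) {
  un <- if (!is.null(cov)) stats::setNames(sqrt(pmax(diag(cov), 0)),
                                           names(par)) else NULL
  structure(list(par = par, cov = cov, uncertainties = un, mapped = mapped,
                 rss = rss, n_data = n_data,
                 aic = aic(max(rss, 1e-300), n_data, length(par)),
                 converged = converged, niter = niter, init = init),
            class = "results_table")
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table> %d free params, RSS %.6g, AIC %.4g, %s\n",
              length(x$par), x$rss, x$aic,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  sd <- x$uncertainties %||% rep(NA_real_, length(x$par))
  df <- data.frame(estimate = x$par, sd = sd)
  print(utils::head(df, 25))
  if (length(x$par) > 25) cat("...\n")
  invisible(x)
}

#' Initialize the free dynamic parameters
#'
#' Strategy `"invert"` least-squares fits each bound dynamic model to the
#' per-transient independent estimates (linear models in closed form,
#' nonlinear models by bounded Levenberg-Marquardt from the model's coarse
#' start); fixed parameters start at the mean of the independent
#' estimates and variable parameters at the per-transient estimates.
#' Strategy `"values"` uses a user-supplied theta verbatim.
#'
#' @param strategy "invert" or "values".
#' @param plan a [dyn_plan()].
#' @param independent_fits an [fit_independent()] result (or a P_spec x T
#'   estimate matrix) for "invert".
#' @param values numeric theta vector for "values".
#' @return named numeric theta vector of length `plan$n_theta`.
#' @export
initialize_dynamic <- function(strategy, plan, independent_fits = NULL,
                               values = NULL) {
  if (strategy == "values") {
    if (is.null(values) || length(values) != plan$n_theta)
      stop_with("mrsdyn_init_error",
                sprintf("init strategy 'values' needs %d values", plan$n_theta))
    theta <- as.numeric(values)
    names(theta) <- plan$theta_names
    return(pmin(pmax(theta, plan$lower), plan$upper))
  }
  if (strategy != "invert")
    stop_with("mrsdyn_init_error", sprintf("unknown init strategy '%s'", strategy))
  E <- if (inherits(independent_fits, "independent_fits"))
    independent_fits$estimates else independent_fits
  if (is.null(E) || nrow(E) != length(plan$spars) || ncol(E) != plan$T)
    stop_with("mrsdyn_init_error",
              "init strategy 'invert' needs independent estimates (P_spec x T)")
  theta <- numeric(plan$n_theta)
  for (i in seq_along(plan$spars)) {
    spar <- plan$spars[i]
    blk <- plan$blocks[[i]]
    y <- E[i, ]
    if (blk$type == "fixed") theta[blk$pos] <- mean(y)
    else if (blk$type == "variable") theta[blk$pos] <- y
    else {
      X <- as.data.frame(blk$X)
      p0 <- if (!is.null(blk$model$invert)) blk$model$invert(y, X) else
        rep(0, length(blk$pos))
      if (any(!is.finite(p0)))
        stop_with("mrsdyn_init_error",
                  sprintf("model inversion failed for '%s' (singular design?)",
                          spar))
      lo <- plan$lower[blk$pos]; hi <- plan$upper[blk$pos]
      if (blk$model$name != "glm") {
        # refine by bounded LM on the model-vs-series least squares
        rf <- function(p) vapply(seq_along(y), function(t)
          blk$model$fn(p, blk$X[t, ]), 0) - y
        jf <- function(p) t(vapply(seq_along(y), function(t)
          blk$model$grad(p, blk$X[t, ]), numeric(length(p))))
        p0 <- lm_fit(rf, jf, pmin(pmax(p0, lo), hi), lo, hi)$par
      }
      theta[blk$pos] <- pmin(pmax(p0, lo), hi)
    }
  }
  names(theta) <- plan$theta_names
  pmin(pmax(theta, plan$lower), plan$upper)
}

# Generic box-constrained Levenberg-Marquardt on residual/Jacobian
# callbacks (used for small dynamic-model inversions).
lm_fit <- function(resid_fn, jac_fn, p0, lower = -Inf, upper = Inf,
                   max_iter = 100L, ftol = 1e-12, gtol = 1e-10) {
  lower <- rep_len(lower, length(p0)); upper <- rep_len(upper, length(p0))
  p <- pmin(pmax(p0, lower), upper)
  r <- resid_fn(p); J <- jac_fn(p)
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < gtol * (1 + cost)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    D <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    for (tries in 1:50) {
      A <- JtJ + diag(lambda * D, nrow(JtJ))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      pn <- pmin(pmax(p + delta, lower), upper)
      rn <- resid_fn(pn)
      costn <- sum(rn^2)
      if (costn < cost) {
        rel <- (cost - costn) / max(cost, 1e-300)
        p <- pn; r <- rn; cost <- costn; J <- jac_fn(p)
        lambda <- max(lambda * 0.3, 1e-12)
        accepted <- TRUE
        if (rel < ftol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = p, rss = cost, converged = converged)
}

#' Joint dynamic fit of a transient series
#'
#' Minimizes the summed squared frequency-domain residual over all
#' transients with respect to the free dynamic parameters theta, using
#' chained analytic gradients and bound-constrained Levenberg-Marquardt.
#'
#' @param data an [fid_series()] with T transients.
#' @param basis a [basis_set()] (optionally with per-condition bases).
#' @param config a [dynamic_config()].
#' @param tvar a [time_variable()] with T rows.
#' @param opts a [fit_options()].
#' @param init "invert" (default; inverts the dynamic models from
#'   independent per-transient fits), "values" (use `init_values`), or a
#'   numeric theta vector (shorthand for "values").
#' @param init_values numeric theta start for `init = "values"`.
#' @param independent_fits optional precomputed [fit_independent()] result
#'   reused by the "invert" strategy.
#' @return a [results_table()] with theta estimates, covariance, mapped
#'   per-transient spectral parameters, AIC and the initialization
#'   record.
#' @export
fit_dynamic <- function(data, basis, config, tvar, opts = fit_options(),
                        init = "invert", init_values = NULL,
                        independent_fits = NULL) {
  T_n <- n_transients(data)
  if (nrow(tvar$columns) != T_n)
    stop_shape("time variable rows must match number of transients")
  plan <- dyn_plan(config, basis, tvar, opts$baseline_order)
  grid <- data$grid
  ctx <- eval_context(basis, grid, opts$ppm_range, opts$baseline_order)
  bpt <- basis_per_t_list(basis, T_n)

  specs <- vapply(seq_len(T_n),
                  function(t) fid_to_spectrum(data$transients[t, ])[ctx$window],
                  complex(length(ctx$window)))
  specs <- matrix(specs, ncol = T_n)

  if (is.numeric(init)) { init_values <- init; init <- "values" }
  theta <- if (init == "invert") {
    ind <- independent_fits %||% fit_independent(data, basis, opts,
                                                 covariance = FALSE)
    initialize_dynamic("invert", plan, independent_fits = ind)
  } else if (init == "mean") {
    # one fit of the coherent average, broadcast through model inversion
    mean_series <- fid_series(matrix(colMeans(data$transients), nrow = 1),
                              grid)
    mfit <- fit_independent(mean_series, basis, opts, covariance = FALSE)
    E <- matrix(mfit$estimates[, 1], nrow = length(plan$spars),
                ncol = T_n)
    rownames(E) <- plan$spars
    initialize_dynamic("invert", plan, independent_fits = E)
  } else {
    initialize_dynamic(init, plan, values = init_values)
  }

  eval_ne <- function(th) {
    params <- map_all_parameters(plan, th)
    M <- map_all_gradients(plan, th)
    cpp_dyn_normal_eqs(ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel, ctx$Breg,
                       params, M, specs, bpt)
  }
  eval_rss <- function(th) {
    params <- map_all_parameters(plan, th)
    cpp_dyn_rss(ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel, ctx$Breg,
                params, specs, bpt)
  }

  ne <- eval_ne(theta)
  cost <- ne$rss
  lambda <- 1e-3
  converged <- FALSE
  niter <- 0L
  for (it in seq_len(opts$max_iter)) {
    niter <- it
    if (max(abs(ne$Jtg)) < opts$gtol * (1 + cost)) { converged <- TRUE; break }
    D <- pmax(diag(ne$JtJ), 1e-12)
    accepted <- FALSE
    for (tries in 1:50) {
      A <- ne$JtJ + diag(lambda * D, nrow(ne$JtJ))
      delta <- tryCatch(solve(A, -ne$Jtg), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      thn <- pmin(pmax(theta + delta, plan$lower), plan$upper)
      costn <- eval_rss(thn)
      if (costn < cost) {
        rel <- (cost - costn) / max(cost, 1e-300)
        theta <- thn
        ne <- eval_ne(theta)
        cost <- costn
        lambda <- max(lambda * 0.3, 1e-12)
        accepted <- TRUE
        if (rel < opts$ftol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }

  n_data <- 2L * nrow(specs) * T_n
  cv <- cov_from_jtj(ne$JtJ, cost, n_data, plan$theta_names)
  mapped <- map_all_parameters(plan, theta)
  rownames(mapped) <- plan$spars
  names(theta) <- plan$theta_names
  out <- results_table(par = theta, cov = cv$cov, mapped = mapped,
                       rss = cost, n_data = n_data, converged = converged,
                       niter = niter,
                       init = list(strategy = init,
                                   theta0 = NULL))
  out$plan <- plan
  out$sigma2 <- cv$sigma2
  out$degenerate <- cv$degenerate
  out
}
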