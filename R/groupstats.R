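# First-level contrasts, metabolite combination with covariance
# propagation, and variance-weighted group-level GLM inference.

#' A first-level contrast of free parameters
#' @param name contrast label.
#' @param weights named numeric vector over free-parameter names.
#' @export
contrast <- function(name, weights) {
  structure(list(name = name, weights = weights), class = "mrs_contrast")
}

#' Contrast of parameter estimates (COPE) and its variance (VARCOPE)
#'
#' `cope = w' beta_hat`, `varcope = w' Cov w` using the fit covariance.
#'
#' @param fit a [results_table()].
#' @param contrast an [contrast()] (or named weight vector).
#' @return list with `cope`, `varcope`, `name`.
#' @export
first_level_cope <- function(fit, contrast) {
  w <- if (inherits(contrast, "mrs_contrast")) contrast$weights else contrast
  nm <- if (inherits(contrast, "mrs_contrast")) contrast$name else "contrast"
  missing_par <- setdiff(names(w), names(fit$par))
  if (length(missing_par))
    stop_format(sprintf("contrast references absent parameters: %s",
                        paste(missing_par, collapse = ", ")))
  wv <- stats::setNames(rep(0, length(fit$par)), names(fit$par))
  wv[names(w)] <- w
  cope <- sum(wv * fit$par)
  varcope <- drop(t(wv) %*% fit$cov %*% wv)
  list(name = nm, cope = cope, varcope = varcope)
}

#' Delta-method percent-change contrast (stimulation over baseline beta)
#'
#' For the ratio `beta_num / beta_den`, linearizes around the estimate:
#' gradient `(1/beta_den, -beta_num/beta_den^2)` and propagates the 2x2
#' covariance block.
#'
#' @param fit a [results_table()].
#' @param num,den names of the numerator and denominator parameters.
#' @return list with `cope` (the ratio), `varcope`.
#' @export
first_level_ratio <- function(fit, num, den) {
  if (!all(c(num, den) %in% names(fit$par)))
    stop_format("ratio references absent parameters")
  bn <- fit$par[[num]]; bd <- fit$par[[den]]
  g <- c(1 / bd, -bn / bd^2)
  V <- fit$cov[c(num, den), c(num, den)]
  list(name = sprintf("%s/%s", num, den), cope = bn / bd,
       varcope = drop(t(g) %*% V %*% g))
}

#' Combine metabolites bound to the same linear dynamic model
#'
#' Sums the per-regressor betas of the named metabolites (e.g. NAA +
#' NAAG -> tNAA) and propagates the covariance including cross-metabolite
#' terms. Errors when any named metabolite is bound to a nonlinear
#' dynamic model, for which summing betas is undefined.
#'
#' @param fit a [results_table()] from [fit_dynamic()].
#' @param names_to_sum character vector of metabolite names.
#' @param new_name label of the combined metabolite.
#' @return list with `par` (combined betas), `cov`, `sd`.
#' @export
combine_metabolites <- function(fit, names_to_sum, new_name = "combined") {
  plan <- fit$plan
  if (is.null(plan)) stop_format("fit lacks a dynamic plan")
  spars <- paste0("conc_", names_to_sum)
  blocks <- plan$blocks[spars]
  if (any(vapply(blocks, is.null, TRUE)))
    stop_format("metabolite not present in fit")
  types <- vapply(blocks, function(b) b$type, "")
  models <- vapply(blocks, function(b)
    if (b$type == "model") b$model$name else b$type, "")
  if (length(unique(models)) != 1)
    stop_format("metabolites must share the same dynamic model to combine")
  if (types[1] == "model" && !models[1] %in% "glm")
    stop_format(sprintf("combination undefined for nonlinear model '%s'",
                        models[1]))
  poss <- lapply(blocks, function(b) b$pos)
  nreg <- length(poss[[1]])
  A <- matrix(0, nreg, length(fit$par))
  for (p in poss) A[cbind(seq_len(nreg), p)] <- 1
  parc <- drop(A %*% fit$par)
  covc <- A %*% fit$cov %*% t(A)
  sfx <- sub(paste0("^", spars[1], "_?"), "", plan$theta_names[poss[[1]]])
  nms <- if (all(nzchar(sfx))) paste0("conc_", new_name, "_", sfx)
  else paste0("conc_", new_name)
  names(parc) <- nms
  dimnames(covc) <- list(nms, nms)
  list(par = parc, cov = covc, sd = sqrt(pmax(diag(covc), 0)))
}

#' Group design for a paired t-test
#'
#' One row per scan, all condition-A scans first: per-subject indicator
#' columns plus a condition column coded +1 (A) / -1 (B). The condition
#' beta is half the mean paired difference.
#'
#' @param n_subjects number of subjects.
#' @return design matrix with `subj*` and `condition` columns.
#' @export
group_design_paired <- function(n_subjects) {
  S <- diag(n_subjects)
  X <- rbind(cbind(S, condition = 1), cbind(S, condition = -1))
  colnames(X) <- c(paste0("subj", seq_len(n_subjects)), "condition")
  X
}

#' Group-level GLM on first-level copes
#'
#' Variance-weighted least squares of the copes on the group design
#' (weights `1 / varcope`), residual-based variance estimate, t statistic
#' for the contrast, z through the normal quantile map, two-sided p.
#' With equal varcopes and a paired design this reduces to the classical
#' paired t test.
#'
#' @param copes numeric vector, one per scan (design row).
#' @param varcopes matching first-level variances (> 0).
#' @param design numeric matrix (scans x EVs), full column rank.
#' @param contrast numeric contrast vector over design columns (or a
#'   column name).
#' @return list with `beta` (all EVs), `cope`, `se`, `t`, `df`, `z`, `p`.
#' @export
group_glm <- function(copes, varcopes, design, contrast) {
  X <- as.matrix(design)
  n <- length(copes)
  if (nrow(X) != n || length(varcopes) != n)
    stop_shape("copes, varcopes and design rows must match")
  if (any(varcopes <= 0)) stop_domain("varcopes must be positive")
  if (qr(X)$rank < ncol(X)) stop_domain("group design is rank deficient")
  if (is.character(contrast)) {
    cvec <- stats::setNames(rep(0, ncol(X)), colnames(X))
    cvec[contrast] <- 1
  } else cvec <- contrast
  w <- 1 / varcopes
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * copes))
  resid <- copes - drop(X %*% beta)
  df <- n - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  Vb <- sigma2 * solve(XtWX)
  cope <- drop(crossprod(cvec, beta))
  se <- sqrt(drop(t(cvec) %*% Vb %*% cvec))
  scale <- max(abs(copes), 1e-300)
  # guard the 0/0 of numerically perfect fits
  tstat <- if (abs(cope) < 1e-10 * scale) 0
  else if (se > 0) cope / se else sign(cope) * Inf
  p <- 2 * stats::pt(-abs(tstat), df)
  z <- sign(tstat) * stats::qnorm(1 - p / 2)
  list(beta = drop(beta), cope = cope, se = se, t = tstat, df = df,
       z = z, p = p)
}

#' Group inference across metabolites with optional Bonferroni flag
#'
#' Convenience wrapper running [group_glm()] per metabolite given a named
#' list of per-scan (cope, varcope) pairs; mirrors a `stats` command-line
#' output table.
#'
#' @param cope_table data.frame with columns `metabolite`, `scan`,
#'   `cope`, `varcope` (scan order matches the design rows).
#' @param design group design matrix.
#' @param contrast contrast vector or design column name.
#' @param bonferroni apply Bonferroni correction across metabolites.
#' @return data.frame (metabolite, beta, z, p).
#' @export
group_stats_table <- function(cope_table, design, contrast,
                              bonferroni = FALSE) {
  mets <- unique(cope_table$metabolite)
  out <- do.call(rbind, lapply(mets, function(m) {
    d <- cope_table[cope_table$metabolite == m, ]
    d <- d[order(d$scan), ]
    g <- group_glm(d$cope, d$varcope, design, contrast)
    data.frame(metabolite = m, beta = g$cope, z = g$z, p = g$p)
  }))
  if (bonferroni) out$p <- pmin(1, out$p * length(mets))
  out
}
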