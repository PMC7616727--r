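# Dynamic configuration: which spectral parameters are fixed across
# transients, free per transient ("variable"), or constrained by a named
# dynamic model of the time variable.

behavior_spec <- function(x) {
  if (is.character(x) && length(x) == 1 && x %in% c("fixed", "variable"))
    return(list(type = x))
  if (is.list(x) && !is.null(x$model))
    return(list(type = "model", model = x$model,
                covariates = x$covariates))
  stop_format("behavior must be 'fixed', 'variable', or list(model=, covariates=)")
}

#' Declare a dynamic configuration
#'
#' `behaviors` maps spectral parameter names, or parameter classes, to a
#' time-dependent behavior: `"fixed"` (one shared value), `"variable"`
#' (one value per transient), or `list(model = "<name>", covariates =
#' c(...))` binding the parameter to a registered dynamic model driven by
#' named time-variable columns. Classes are `"conc"`, `"gamma"`, `"eps"`,
#' `"phi0"`, `"phi1"`, `"baseline"`; specific names (e.g. `"conc_NAA"`,
#' `"gamma_g1"`, `"b_re_0"`) win over their class. Unlisted parameters
#' default to `"fixed"`.
#'
#' @param behaviors named list of behaviors (see above).
#' @param bounds named list mapping free-parameter (theta) names, spectral
#'   parameter names, or classes to `c(lower, upper)`.
#' @return an object of class `dynamic_config`.
#' @export
dynamic_config <- function(behaviors = list(), bounds = list()) {
  behaviors <- lapply(behaviors, behavior_spec)
  for (b in behaviors) {
    if (b$type == "model") get_dynamic_model(b$model)  # errors when unknown
  }
  for (nm in names(bounds)) {
    bd <- bounds[[nm]]
    if (length(bd) != 2 || (is.finite(bd[1]) && is.finite(bd[2]) && bd[1] > bd[2]))
      stop_format(sprintf("malformed bounds for '%s' (need lower <= upper)", nm))
  }
  structure(list(behaviors = behaviors, bounds = bounds),
            class = "dynamic_config")
}

#' Parse a declarative dynamic configuration (JSON)
#'
#' The JSON dialect has top-level objects `behaviors` and `bounds`;
#' behavior values are the strings `"fixed"`/`"variable"` or objects
#' `{"model": "...", "covariates": [...]}`; bound values are two-element
#' arrays (`null` = unbounded). Custom models must be registered through
#' [register_dynamic_model()] before parsing.
#'
#' @param path_or_text file path, or a JSON string.
#' @return a [dynamic_config()].
#' @export
parse_config <- function(path_or_text) {
  txt <- if (length(path_or_text) == 1 && !grepl("[{]", path_or_text)) {
    if (!file.exists(path_or_text))
      stop_format(sprintf("config file not found: %s", path_or_text))
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  } else paste(path_or_text, collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  behaviors <- lapply(obj$behaviors %||% list(), function(v) {
    if (is.character(v)) v else list(model = v$model,
                                     covariates = unlist(v$covariates))
  })
  bounds <- lapply(obj$bounds %||% list(), function(v) {
    v <- unlist(lapply(v, function(z) if (is.null(z)) NA_real_ else z))
    c(ifelse(is.na(v[1]), -Inf, v[1]), ifelse(is.na(v[2]), Inf, v[2]))
  })
  dynamic_config(behaviors, bounds)
}

spar_class <- function(spar) {
  if (startsWith(spar, "conc_")) "conc"
  else if (startsWith(spar, "gamma_")) "gamma"
  else if (startsWith(spar, "eps_")) "eps"
  else if (startsWith(spar, "b_re_") || startsWith(spar, "b_im_")) "baseline"
  else spar
}

default_spar_bounds <- function(spar) {
  cl <- spar_class(spar)
  if (cl == "conc") c(0, Inf)
  else if (cl == "gamma") c(0, Inf)
  else c(-Inf, Inf)
}

resolve_behavior <- function(config, spar) {
  b <- config$behaviors[[spar]]
  if (is.null(b)) b <- config$behaviors[[spar_class(spar)]]
  if (is.null(b)) b <- list(type = "fixed")
  b
}

#' Build the fitting plan: theta layout for a config/basis/time-variable
#'
#' Resolves every spectral parameter to its behavior, lays out the flat
#' free-parameter vector theta with deterministic names, and captures the
#' covariate matrices dynamic models need. The free-parameter count is
#' the sum over spectral parameters of 1 (fixed), T (variable) or the
#' model's parameter count.
#'
#' @param config a [dynamic_config()].
#' @param basis a [basis_set()].
#' @param tvar a [time_variable()] with T rows.
#' @param baseline_order baseline polynomial order (-1 = none).
#' @return an object of class `dyn_plan`.
#' @export
dyn_plan <- function(config, basis, tvar, baseline_order = -1) {
  spars <- spectral_param_names(basis, baseline_order)
  T_n <- nrow(tvar$columns)
  blocks <- list()
  theta_names <- character(0)
  lower <- numeric(0)
  upper <- numeric(0)
  pos <- 0L
  for (i in seq_along(spars)) {
    spar <- spars[i]
    b <- resolve_behavior(config, spar)
    def_bd <- default_spar_bounds(spar)
    if (b$type == "fixed") {
      nm <- spar
      blocks[[spar]] <- list(type = "fixed", pos = pos + 1L)
      theta_names <- c(theta_names, nm)
      lower <- c(lower, def_bd[1]); upper <- c(upper, def_bd[2])
      pos <- pos + 1L
    } else if (b$type == "variable") {
      nms <- sprintf("%s_t%03d", spar, seq_len(T_n) - 1L)
      blocks[[spar]] <- list(type = "variable", pos = pos + seq_len(T_n))
      theta_names <- c(theta_names, nms)
      lower <- c(lower, rep(def_bd[1], T_n)); upper <- c(upper, rep(def_bd[2], T_n))
      pos <- pos + T_n
    } else {
      model <- get_dynamic_model(b$model)
      cov_names <- b$covariates %||% model$covariates
      if (is.null(cov_names))
        stop_format(sprintf("model '%s' for '%s' needs covariates", b$model, spar))
      missing_cov <- setdiff(cov_names, names(tvar$columns))
      if (length(missing_cov))
        stop_format(sprintf("covariates not in time variable: %s",
                            paste(missing_cov, collapse = ", ")))
      np <- model_np(model, length(cov_names))
      sfx <- model_suffixes(model, length(cov_names))
      X <- as.matrix(tvar$columns[cov_names])
      blocks[[spar]] <- list(type = "model", pos = pos + seq_len(np),
                             model = model, X = X)
      theta_names <- c(theta_names, paste0(spar, "_", sfx))
      lower <- c(lower, rep_len(model$lower, np))
      upper <- c(upper, rep_len(model$upper, np))
      pos <- pos + np
    }
  }
  names(lower) <- names(upper) <- theta_names
  # bound overrides: theta name > spectral name > class
  for (j in seq_along(theta_names)) {
    tn <- theta_names[j]
    spar <- NULL
    for (sp in spars) {
      if (tn == sp || startsWith(tn, paste0(sp, "_"))) { spar <- sp; break }
    }
    bd <- config$bounds[[tn]] %||% config$bounds[[spar %||% ""]] %||%
      config$bounds[[spar_class(spar %||% tn)]]
    if (!is.null(bd)) { lower[j] <- bd[1]; upper[j] <- bd[2] }
  }
  structure(list(spars = spars, blocks = blocks, theta_names = theta_names,
                 n_theta = pos, T = T_n, lower = lower, upper = upper,
                 baseline_order = baseline_order,
                 config = config),
            class = "dyn_plan")
}

#' @export
print.dyn_plan <- function(x, ...) {
  cat(sprintf("<dyn_plan> %d spectral params x %d transients -> %d free params\n",
              length(x$spars), x$T, x$n_theta))
  invisible(x)
}

#' Map free dynamic parameters to spectral parameters at one transient
#'
#' Deterministic, side-effect free: fixed parameters take the shared
#' value at every `t`, variable parameters the t-th element, model-bound
#' parameters the model evaluated on the covariates at `t`.
#'
#' @param plan a [dyn_plan()].
#' @param theta numeric free-parameter vector (length `plan$n_theta`).
#' @param t transient index (1-based, in 1..T).
#' @return named numeric vector of spectral parameters at `t`.
#' @export
map_parameters <- function(plan, theta, t) {
  if (t < 1 || t > plan$T) stop_shape("transient index out of range")
  v <- vapply(plan$blocks, function(blk) {
    switch(blk$type,
           fixed = theta[blk$pos],
           variable = theta[blk$pos[t]],
           model = blk$model$fn(theta[blk$pos], blk$X[t, ]))
  }, 0)
  names(v) <- plan$spars
  v
}

#' Jacobian of [map_parameters()] with respect to theta
#'
#' @inheritParams map_parameters
#' @return numeric matrix (length(spars) x n_theta); fixed rows have a
#'   single 1, variable rows select the t-th theta, model rows carry the
#'   model's analytic gradient at the covariates of `t`.
#' @export
map_gradient <- function(plan, theta, t) {
  if (t < 1 || t > plan$T) stop_shape("transient index out of range")
  M <- matrix(0, length(plan$spars), plan$n_theta,
              dimnames = list(plan$spars, plan$theta_names))
  for (i in seq_along(plan$spars)) {
    blk <- plan$blocks[[i]]
    if (blk$type == "fixed") M[i, blk$pos] <- 1
    else if (blk$type == "variable") M[i, blk$pos[t]] <- 1
    else M[i, blk$pos] <- blk$model$grad(theta[blk$pos], blk$X[t, ])
  }
  M
}

# Spectral parameter matrix (P_spec x T) and chain cube for all transients.
map_all_parameters <- function(plan, theta) {
  vapply(seq_len(plan$T), function(t) map_parameters(plan, theta, t),
         numeric(length(plan$spars)))
}

map_all_gradients <- function(plan, theta) {
  M <- array(0, dim = c(length(plan$spars), plan$n_theta, plan$T))
  for (t in seq_len(plan$T)) M[, , t] <- map_gradient(plan, theta, t)
  M
}
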