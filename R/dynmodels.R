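# Dynamic-model library: named models that constrain how a spectral
# parameter evolves across transients as a function of the time variable.
# Each model supplies value, analytic gradient, default bounds, parameter
# suffixes, and an inversion heuristic used for initialisation.

dynamic_model_registry <- new.env(parent = emptyenv())

#' Register a dynamic model
#'
#' Models map a small free-parameter vector `p` and a per-transient
#' covariate row `x` to the value of one spectral parameter at that
#' transient. Registration makes the model available to
#' [parse_config()]/[dynamic_config()] under `name`.
#'
#' @param name model name used in configurations.
#' @param nparam integer number of free parameters, or a
#'   `function(n_covariates)` returning it.
#' @param fn `function(p, x)` returning the scalar parameter value.
#' @param grad `function(p, x)` returning the length-`nparam` gradient.
#' @param suffixes character vector (or `function(n_covariates)`) naming
#'   the free parameters; appended to the spectral parameter name.
#' @param lower,upper default bounds (recycled to `nparam`).
#' @param covariates default covariate column names, or NULL when the
#'   configuration must name them.
#' @param invert optional `function(y, X)` with `y` a per-transient series
#'   of the spectral parameter and `X` the covariate data.frame, returning
#'   a starting value for the free parameters (used by the "invert"
#'   initialization strategy).
#' @export
register_dynamic_model <- function(name, nparam, fn, grad, suffixes,
                                   lower = -Inf, upper = Inf,
                                   covariates = NULL, invert = NULL) {
  assign(name, list(name = name, nparam = nparam, fn = fn, grad = grad,
                    suffixes = suffixes, lower = lower, upper = upper,
                    covariates = covariates, invert = invert),
         envir = dynamic_model_registry)
  invisible(name)
}

#' Look up a dynamic model by name
#' @param name model name.
#' @export
get_dynamic_model <- function(name) {
  if (!exists(name, envir = dynamic_model_registry, inherits = FALSE))
    stop_format(sprintf("unknown dynamic model '%s' (registered: %s)", name,
                        paste(dynamic_models(), collapse = ", ")))
  get(name, envir = dynamic_model_registry, inherits = FALSE)
}

#' Names of all registered dynamic models
#' @export
dynamic_models <- function() sort(ls(dynamic_model_registry))

model_np <- function(model, ncov) {
  if (is.function(model$nparam)) model$nparam(ncov) else model$nparam
}
model_suffixes <- function(model, ncov) {
  if (is.function(model$suffixes)) model$suffixes(ncov) else model$suffixes
}

# ---- built-in models -------------------------------------------------------

stick_vec <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Ball-and-two-sticks diffusion attenuation
#'
#' \deqn{S = (1 - f_1 - f_2) e^{-bd} + \sum_i f_i e^{-bd (g^T v_i)^2}}
#' with a single shared diffusivity `d` and unit stick vectors `v_i`
#' parametrized by spherical angles. The analytic gradient with respect
#' to `(f1, f2, d, theta1, phi1, theta2, phi2)` is attached as attribute
#' `"gradient"`.
#'
#' @param f1,f2 stick volume fractions (>= 0, f1 + f2 <= 1).
#' @param d diffusivity (>= 0), units reciprocal to `b`.
#' @param theta1,phi1,theta2,phi2 spherical angles of the sticks.
#' @param b diffusion weighting (scalar, >= 0).
#' @param g unit gradient direction (length 3; required unit for b > 0).
#' @return scalar attenuation in (0, 1].
#' @export
model_ball_two_sticks <- function(f1, f2, d, theta1, phi1, theta2, phi2,
                                  b, g) {
  if (f1 < 0 || f2 < 0 || f1 + f2 > 1 + 1e-12)
    stop_domain("stick fractions must satisfy f1, f2 >= 0 and f1 + f2 <= 1")
  if (d < 0) stop_domain("diffusivity must be >= 0")
  if (b > 0 && abs(sqrt(sum(g^2)) - 1) > 1e-6)
    stop_domain("gradient direction must be unit norm for b > 0")
  p <- c(1, f1, f2, d, theta1, phi1, theta2, phi2)
  val <- ball2sticks_val(p, b, g)
  gr <- ball2sticks_grad(p, b, g)[-1]  # drop amplitude slot
  structure(val, gradient = gr)
}

# internal value/grad with leading amplitude parameter, used by the registry
ball2sticks_val <- function(p, b, g) {
  amp <- p[1]; f1 <- p[2]; f2 <- p[3]; d <- p[4]
  v1 <- stick_vec(p[5], p[6]); v2 <- stick_vec(p[7], p[8])
  a1 <- sum(g * v1); a2 <- sum(g * v2)
  amp * ((1 - f1 - f2) * exp(-b * d) + f1 * exp(-b * d * a1^2) +
           f2 * exp(-b * d * a2^2))
}

ball2sticks_grad <- function(p, b, g) {
  amp <- p[1]; f1 <- p[2]; f2 <- p[3]; d <- p[4]
  th1 <- p[5]; ph1 <- p[6]; th2 <- p[7]; ph2 <- p[8]
  v1 <- stick_vec(th1, ph1); v2 <- stick_vec(th2, ph2)
  a1 <- sum(g * v1); a2 <- sum(g * v2)
  eb <- exp(-b * d); e1 <- exp(-b * d * a1^2); e2 <- exp(-b * d * a2^2)
  S <- (1 - f1 - f2) * eb + f1 * e1 + f2 * e2
  da1_th <- sum(g * c(cos(th1) * cos(ph1), cos(th1) * sin(ph1), -sin(th1)))
  da1_ph <- sum(g * c(-sin(th1) * sin(ph1), sin(th1) * cos(ph1), 0))
  da2_th <- sum(g * c(cos(th2) * cos(ph2), cos(th2) * sin(ph2), -sin(th2)))
  da2_ph <- sum(g * c(-sin(th2) * sin(ph2), sin(th2) * cos(ph2), 0))
  dS_d <- -b * ((1 - f1 - f2) * eb + f1 * a1^2 * e1 + f2 * a2^2 * e2)
  c(S,
    amp * (e1 - eb),
    amp * (e2 - eb),
    amp * dS_d,
    amp * f1 * e1 * (-2 * b * d * a1) * da1_th,
    amp * f1 * e1 * (-2 * b * d * a1) * da1_ph,
    amp * f2 * e2 * (-2 * b * d * a2) * da2_th,
    amp * f2 * e2 * (-2 * b * d * a2) * da2_ph)
}

# Deterministic quasi-uniform hemisphere directions (spherical Fibonacci).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  cbind(gx = sqrt(1 - z^2) * cos(phi), gy = sqrt(1 - z^2) * sin(phi), gz = z)
}

register_builtin_models <- function() {
  register_dynamic_model(
    "glm",
    nparam = function(ncov) ncov,
    fn = function(p, x) sum(p * x),
    grad = function(p, x) x,
    suffixes = function(ncov) paste0("beta", seq_len(ncov) - 1L),
    invert = function(y, X) {
      Xm <- as.matrix(X)
      qr.coef(qr(Xm), y)
    })

  register_dynamic_model(
    "exp",
    nparam = 2L,
    fn = function(p, x) p[1] * exp(-x[["b"]] * p[2]),
    grad = function(p, x) {
      e <- exp(-x[["b"]] * p[2])
      c(e, -x[["b"]] * p[1] * e)
    },
    suffixes = c("amp", "adc"),
    lower = c(-Inf, 0), upper = c(Inf, Inf),
    covariates = "b",
    invert = function(y, X) {
      b <- X$b
      ok <- y > 0
      if (sum(ok) >= 2 && stats::sd(b[ok]) > 0) {
        co <- stats::coef(stats::lm(log(y[ok]) ~ b[ok]))
        c(exp(co[1]), max(0, -co[2]))
      } else c(max(y, 0), 0.1)
    })

  register_dynamic_model(
    "exp_offset",
    nparam = 3L,
    fn = function(p, x) p[1] * exp(-x[["b"]] * p[2]) + p[3],
    grad = function(p, x) {
      e <- exp(-x[["b"]] * p[2])
      c(e, -x[["b"]] * p[1] * e, 1)
    },
    suffixes = c("amp", "adc", "offset"),
    lower = c(-Inf, 0, -Inf), upper = c(Inf, Inf, Inf),
    covariates = "b",
    invert = function(y, X) {
      co <- y[which.max(X$b)]
      a <- y[which.min(X$b)] - co
      c(a, 0.5, co)
    })

  register_dynamic_model(
    "biexp",
    nparam = 4L,
    fn = function(p, x) {
      b <- x[["b"]]
      p[1] * (p[2] * exp(-b * p[3]) + (1 - p[2]) * exp(-b * p[4]))
    },
    grad = function(p, x) {
      b <- x[["b"]]
      e1 <- exp(-b * p[3]); e2 <- exp(-b * p[4])
      c(p[2] * e1 + (1 - p[2]) * e2,
        p[1] * (e1 - e2),
        -b * p[1] * p[2] * e1,
        -b * p[1] * (1 - p[2]) * e2)
    },
    suffixes = c("amp", "frac", "adc1", "adc2"),
    lower = c(-Inf, 0, 0, 0), upper = c(Inf, 1, Inf, Inf),
    covariates = "b",
    invert = function(y, X) {
      c(max(y[which.min(X$b)], 1e-6), 0.5, 1.0, 0.05)
    })

  register_dynamic_model(
    "ball2sticks",
    nparam = 8L,
    fn = function(p, x) ball2sticks_val(p, x[["b"]],
                                        c(x[["gx"]], x[["gy"]], x[["gz"]])),
    grad = function(p, x) ball2sticks_grad(p, x[["b"]],
                                           c(x[["gx"]], x[["gy"]], x[["gz"]])),
    suffixes = c("amp", "f1", "f2", "d", "theta1", "phi1", "theta2", "phi2"),
    lower = c(0, 0, 0, 0, -Inf, -Inf, -Inf, -Inf),
    upper = c(Inf, 1, 1, Inf, Inf, Inf, Inf, Inf),
    covariates = c("b", "gx", "gy", "gz"),
    invert = function(y, X) {
      # coarse grid over stick-direction pairs + mono-exponential d
      b <- X$b
      amp0 <- mean(y[b == min(b)])
      ok <- y > 0 & b > 0
      d0 <- if (sum(ok) >= 2 && stats::sd(b[ok]) > 0)
        max(1e-3, -stats::coef(stats::lm(log(y[ok] / amp0) ~ 0 + b[ok]))[1])
      else 0.3
      dirs <- fibonacci_hemisphere(12)
      best <- NULL; best_sse <- Inf
      fgrid <- c(0.15, 0.35)
      for (i in seq_len(nrow(dirs))) for (jj in i:nrow(dirs)) {
        for (f in fgrid) {
          th1 <- acos(dirs[i, 3]); p1 <- atan2(dirs[i, 2], dirs[i, 1])
          th2 <- acos(dirs[jj, 3]); p2 <- atan2(dirs[jj, 2], dirs[jj, 1])
          p <- c(amp0, f, f, d0, th1, p1, th2, p2)
          pred <- vapply(seq_along(y), function(t)
            ball2sticks_val(p, b[t], c(X$gx[t], X$gy[t], X$gz[t])), 0)
          sse <- sum((pred - y)^2)
          if (sse < best_sse) { best_sse <- sse; best <- p }
        }
      }
      best
    })
}

# ---- hemodynamic response and designs --------------------------------------

#' Glover double-gamma hemodynamic response function
#'
#' \eqn{h(t) = c_1 t^{6} e^{-t/0.9} - 0.35\, c_2 t^{12} e^{-t/0.9}} with
#' each gamma term normalized to unit peak. Peaks near 5.4 s. Zero for
#' `t <= 0`.
#'
#' @param t time in seconds (vectorized).
#' @return HRF value(s).
#' @export
glover_hrf <- function(t) {
  n1 <- 6; n2 <- 12; tau <- 0.9; a2 <- 0.35
  c1 <- (n1 * tau)^n1 * exp(-n1)
  c2 <- (n2 * tau)^n2 * exp(-n2)
  h <- ifelse(t > 0,
              t^n1 * exp(-t / tau) / c1 - a2 * t^n2 * exp(-t / tau) / c2,
              0)
  h
}

#' Build an fMRS GLM design matrix from stimulus blocks
#'
#' Convolves rectangular stimulation blocks with the Glover HRF (sampled
#' on a fine grid), peak-normalizes each stimulation column, and appends
#' a zero-mean linear drift and a constant column.
#'
#' @param onsets list of numeric vectors (one per stimulation regressor)
#'   of block onset times in seconds; a bare numeric vector gives one
#'   regressor.
#' @param durations matching list/vector of non-negative block durations
#'   in seconds.
#' @param n_transients number of transients T.
#' @param tr repetition time (seconds between transients, > 0).
#' @param hrf impulse response function of time in seconds; pass a
#'   narrow indicator kernel for unconvolved boxcars.
#' @param drift include the linear drift column.
#' @return numeric T x R design matrix with named columns
#'   (`stim1..., drift, const`).
#' @export
convolve_design <- function(onsets, durations, n_transients, tr,
                            hrf = glover_hrf, drift = TRUE) {
  if (tr <= 0) stop_domain("tr must be > 0")
  if (!is.list(onsets)) onsets <- list(onsets)
  if (!is.list(durations)) durations <- list(durations)
  if (length(onsets) != length(durations))
    stop_shape("onsets and durations must have equal length")
  run_len <- n_transients * tr
  dt <- tr / 16
  tfine <- seq(0, run_len, by = dt)
  hfine <- hrf(tfine)
  cols <- lapply(seq_along(onsets), function(i) {
    on <- onsets[[i]]; du <- durations[[i]]
    if (any(du < 0)) stop_domain("negative stimulus duration")
    if (any(on < 0 | on + du > run_len))
      stop_domain("stimulus blocks must lie within the run")
    box <- rep(0, length(tfine))
    for (jj in seq_along(on))
      box[tfine >= on[jj] & tfine < on[jj] + du[jj]] <- 1
    conv <- stats::convolve(box, rev(hfine), type = "open")[seq_along(tfine)] * dt
    col <- stats::approx(tfine, conv, xout = (seq_len(n_transients) - 1) * tr,
                         rule = 2)$y
    if (max(abs(col)) > 0) col <- col / max(abs(col))
    col
  })
  X <- do.call(cbind, cols)
  colnames(X) <- paste0("stim", seq_along(cols))
  if (drift) {
    dcol <- seq_len(n_transients) - (n_transients + 1) / 2
    dcol <- dcol / max(abs(dcol))
    X <- cbind(X, drift = dcol)
  }
  cbind(X, const = rep(1, n_transients))
}
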