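#' Spectral parameters of the linear-combination model
#'
#' The forward model for one transient is
#' \deqn{s(\nu) = B(\nu) + e^{-j(\Phi_0 + \nu \Phi_1)}
#'   \sum_k c_k F[m_k(\tau) e^{-\tau(\gamma_{g(k)} + j\epsilon_{g(k)})}]}
#' with `conc` the metabolite concentrations \eqn{c_k}, per-group
#' Lorentzian broadening `gamma` (s^-1) and frequency shift `eps`
#' (rad s^-1), zero- and first-order phase `phi0` (rad) and `phi1` (s,
#' with \eqn{\nu} in Hz), and a complex polynomial baseline \eqn{B} in the
#' frequency axis rescaled to \[-1, 1\] over the fitted window.
#'
#' @param conc numeric vector of K concentrations (basis order).
#' @param gamma,eps numeric vectors, one entry per metabolite group.
#' @param phi0,phi1 scalars.
#' @param baseline complex vector of polynomial coefficients (order
#'   `length(baseline) - 1`), or NULL for no baseline.
#' @return an object of class `spectral_params`.
#' @export
spectral_params <- function(conc, gamma = 0, eps = 0, phi0 = 0, phi1 = 0,
                            baseline = NULL) {
  if (!is.null(baseline) && !is.complex(baseline)) baseline <- baseline + 0i
  structure(list(conc = as.numeric(conc), gamma = as.numeric(gamma),
                 eps = as.numeric(eps), phi0 = phi0, phi1 = phi1,
                 baseline = baseline),
            class = "spectral_params")
}

#' Names of the flat spectral parameter vector for a basis
#' @param basis a [basis_set()].
#' @param baseline_order polynomial order (-1 = no baseline).
#' @return character vector of length K + 2G + 2 + 2(order+1).
#' @export
spectral_param_names <- function(basis, baseline_order = -1) {
  gi <- basis_group_index(basis)
  nb <- baseline_order + 1L
  c(paste0("conc_", basis$names),
    paste0("gamma_", gi$labels),
    paste0("eps_", gi$labels),
    "phi0", "phi1",
    if (nb > 0) c(paste0("b_re_", seq_len(nb) - 1L),
                  paste0("b_im_", seq_len(nb) - 1L)))
}

#' Pack spectral_params into the flat vector used by the optimizer
#' @keywords internal
pack_spectral <- function(params, basis, baseline_order = -1) {
  gi <- basis_group_index(basis)
  G <- length(gi$labels)
  K <- length(basis$names)
  stopifnot(length(params$conc) == K)
  gamma <- rep_len(params$gamma, G)
  eps <- rep_len(params$eps, G)
  nb <- baseline_order + 1L
  bl <- params$baseline
  if (nb > 0) {
    if (is.null(bl)) bl <- complex(real = rep(0, nb), imaginary = rep(0, nb))
    bl <- rep_len(bl, nb)
    base <- c(Re(bl), Im(bl))
  } else base <- numeric(0)
  v <- c(params$conc, gamma, eps, params$phi0, params$phi1, base)
  names(v) <- spectral_param_names(basis, baseline_order)
  v
}

#' Unpack a flat spectral vector into spectral_params
#' @keywords internal
unpack_spectral <- function(v, basis, baseline_order = -1) {
  gi <- basis_group_index(basis)
  G <- length(gi$labels)
  K <- length(basis$names)
  nb <- baseline_order + 1L
  baseline <- if (nb > 0) {
    complex(real = v[K + 2 * G + 2 + seq_len(nb)],
            imaginary = v[K + 2 * G + 2 + nb + seq_len(nb)])
  } else NULL
  spectral_params(conc = v[seq_len(K)],
                  gamma = v[K + seq_len(G)],
                  eps = v[K + G + seq_len(G)],
                  phi0 = v[[K + 2 * G + 1]], phi1 = v[[K + 2 * G + 2]],
                  baseline = baseline)
}

#' Indices of the fitted ppm window, in ascending-ppm order
#' @param grid an [acquisition_grid()].
#' @param ppm_range length-2 numeric (low, high) or NULL for the full axis.
#' @return integer indices into the ascending-ppm spectrum.
#' @export
fit_window <- function(grid, ppm_range = NULL) {
  if (is.null(ppm_range)) return(seq_len(grid$n_points))
  if (ppm_range[1] >= ppm_range[2]) stop_domain("ppm_range low must be < high")
  ppm <- ppm_axis(grid)
  which(ppm >= ppm_range[1] & ppm <= ppm_range[2])
}

#' Baseline polynomial regressors over a window
#' @keywords internal
baseline_regressors <- function(grid, baseline_order, window) {
  nb <- baseline_order + 1L
  if (nb <= 0) return(matrix(0, length(window), 0))
  nu <- freq_axis(grid)[window]
  span <- max(nu) - min(nu)
  x <- if (span > 0) 2 * (nu - min(nu)) / span - 1 else rep(0, length(nu))
  outer(x, 0:(nb - 1L), `^`)
}

# Shared evaluation context: precomputed axes/selection passed to C++.
eval_context <- function(basis, grid, ppm_range = NULL, baseline_order = -1) {
  window <- fit_window(grid, ppm_range)
  shift <- fftshift_indices(grid$n_points)
  list(tau = time_axis(grid),
       nu = freq_axis(grid)[window],
       sel = shift[window] - 1L,           # 0-based into raw fft output
       Breg = baseline_regressors(grid, baseline_order, window),
       window = window,
       gidx = basis_group_index(basis)$index,
       bmat = t(basis$fids),               # n x K for C++
       baseline_order = baseline_order)
}

#' Forward spectral model (Eq. 1-style linear combination)
#'
#' @param params a [spectral_params()].
#' @param basis a [basis_set()].
#' @param grid an [acquisition_grid()] (defaults to the basis grid).
#' @param ppm_range optional fit window; NULL = full spectrum.
#' @param baseline_order polynomial baseline order; defaults to the order
#'   implied by `params$baseline` (-1 when absent).
#' @return complex spectrum over the (windowed) ascending-ppm axis.
#' @export
forward_spectrum <- function(params, basis, grid = basis$grid,
                             ppm_range = NULL, baseline_order = NULL) {
  if (is.null(baseline_order))
    baseline_order <- length(params$baseline %||% numeric(0)) - 1L
  if (length(params$conc) != length(basis$names))
    stop_shape("conc length does not match basis size")
  ctx <- eval_context(basis, grid, ppm_range, baseline_order)
  v <- pack_spectral(params, basis, baseline_order)
  out <- cpp_eval_block(ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel,
                        ctx$Breg, matrix(v, ncol = 1), FALSE)
  drop(out$spec)
}

#' Analytic gradient of the forward model
#'
#' @inheritParams forward_spectrum
#' @return complex matrix (window length x P) with named columns, P the
#'   flat spectral parameter count.
#' @export
spectral_gradient <- function(params, basis, grid = basis$grid,
                              ppm_range = NULL, baseline_order = NULL) {
  if (is.null(baseline_order))
    baseline_order <- length(params$baseline %||% numeric(0)) - 1L
  if (length(params$conc) != length(basis$names))
    stop_shape("conc length does not match basis size")
  ctx <- eval_context(basis, grid, ppm_range, baseline_order)
  v <- pack_spectral(params, basis, baseline_order)
  out <- cpp_eval_block(ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel,
                        ctx$Breg, matrix(v, ncol = 1), TRUE)
  J <- out$jac[, , 1]
  colnames(J) <- spectral_param_names(basis, baseline_order)
  J
}

#' Akaike Information Criterion (Gaussian residual form)
#'
#' `AIC = n ln(RSS / n) + 2 P`, counting real and imaginary residual
#' points separately in `n`.
#'
#' @param rss residual sum of squares (> 0).
#' @param n_data number of (real-valued) data points.
#' @param n_free number of free parameters (1 <= n_free < n_data).
#' @return scalar AIC.
#' @export
aic <- function(rss, n_data, n_free) {
  if (rss <= 0) stop_domain("RSS must be positive")
  if (n_free < 1 || n_data <= n_free)
    stop_domain("need n_data > n_free >= 1")
  n_data * log(rss / n_data) + 2 * n_free
}

#' Transform an FID to a spectrum (unitary DFT, ascending ppm)
#' @param fid complex vector.
#' @return complex spectrum of equal length.
#' @export
fid_to_spectrum <- function(fid) {
  n <- length(fid)
  (stats::fft(fid) / sqrt(n))[fftshift_indices(n)]
}

#' Inverse of [fid_to_spectrum()]
#' @param spec complex spectrum (ascending ppm order).
#' @return complex FID.
#' @export
spectrum_to_fid <- function(spec) {
  n <- length(spec)
  unshift <- order(fftshift_indices(n))
  stats::fft(spec[unshift], inverse = TRUE) / sqrt(n)
}

#' Spectra of all transients of a series (matrix, rows = transients)
#' @param series an [fid_series()].
#' @export
series_spectra <- function(series) {
  t(apply(series$transients, 1, fid_to_spectrum))
}

#' Unit conversions for the Lorentzian parameters
#'
#' `gamma_to_fwhm_hz`: a pure Lorentzian decay `exp(-gamma tau)` has full
#' width at half maximum `gamma / pi` Hz. `eps_to_hz`: shift in Hz is
#' `eps / (2 pi)`.
#' @param gamma broadening in s^-1.
#' @export
gamma_to_fwhm_hz <- function(gamma) gamma / pi

#' @rdname gamma_to_fwhm_hz
#' @param fwhm_hz full width at half maximum in Hz.
#' @export
fwhm_hz_to_gamma <- function(fwhm_hz) fwhm_hz * pi

#' @rdname gamma_to_fwhm_hz
#' @param eps shift in rad s^-1.
#' @export
eps_to_hz <- function(eps) eps / (2 * pi)

#' @rdname gamma_to_fwhm_hz
#' @param hz shift in Hz.
#' @export
hz_to_eps <- function(hz) 2 * pi * hz
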