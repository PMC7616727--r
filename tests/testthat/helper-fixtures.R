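# Shared fixtures and independent oracles for the test suite.

# small two-singlet basis on a coarse grid
toy_basis <- function(n = 256L, lw_hz = 2, offs_hz = c(-40, 30)) {
  grid <- acquisition_grid(1e-3, n, 123.2, 4.65)
  tau <- time_axis(grid)
  fids <- t(vapply(offs_hz, function(f) exp(2i * pi * f * tau - pi * lw_hz * tau),
                   complex(n)))
  basis_set(fids, c("A", "B"), grid)
}

toy_params <- function() {
  spectral_params(conc = c(1.3, 0.7), gamma = c(4, 6), eps = c(3, -5),
                  phi0 = 0.2, phi1 = 1e-4)
}

# central-difference gradient oracle for the spectral forward model
fd_spectral_gradient <- function(params, basis, baseline_order = -1L,
                                 h_rel = 1e-6) {
  v <- mrsdyn:::pack_spectral(params, basis, baseline_order)
  cols <- lapply(seq_along(v), function(i) {
    h <- h_rel * max(1, abs(v[i]))
    vp <- v; vm <- v
    vp[i] <- v[i] + h; vm[i] <- v[i] - h
    (forward_spectrum(mrsdyn:::unpack_spectral(vp, basis, baseline_order),
                      basis, baseline_order = baseline_order) -
       forward_spectrum(mrsdyn:::unpack_spectral(vm, basis, baseline_order),
                        basis, baseline_order = baseline_order)) / (2 * h)
  })
  do.call(cbind, cols)
}

# central-difference oracle for scalar-valued dynamic models
fd_model_grad <- function(fn, p, ..., h_rel = 1e-7) {
  vapply(seq_along(p), function(i) {
    h <- h_rel * max(1, abs(p[i]))
    pp <- p; pm <- p
    pp[i] <- p[i] + h; pm[i] <- p[i] - h
    (fn(pp, ...) - fn(pm, ...)) / (2 * h)
  }, 0)
}

# numeric FWHM (Hz) of an absorption-mode peak by half-max interpolation
# (real part: the magnitude of a one-sided Lorentzian is sqrt(3) wider)
oracle_fwhm <- function(spec, nu) {
  mag <- Re(spec)
  i <- which.max(mag)
  half <- mag[i] / 2
  li <- max(which(mag[1:i] <= half))
  ri <- i - 1 + min(which(mag[i:length(mag)] <= half))
  fl <- nu[li] + (half - mag[li]) * (nu[li + 1] - nu[li]) / (mag[li + 1] - mag[li])
  fr <- nu[ri - 1] + (half - mag[ri - 1]) * (nu[ri] - nu[ri - 1]) / (mag[ri] - mag[ri - 1])
  fr - fl
}
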