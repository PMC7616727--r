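# Synthetic-data generators emulating the simulation case studies:
# two-peak toy fMRS, realistic ~20-metabolite brain fMRS, MEGA-PRESS
# edited pairs, a multi-subject fMRS cohort, multi-direction and multi-b
# diffusion series. A parametric pseudo-basis (fixed Lorentzian line
# lists) stands in for density-matrix simulation; it reproduces the
# overlap structure that drives fitting-strategy comparisons, not true
# multiplet shapes.

#' Brain metabolite pseudo-basis line lists
#'
#' Nominal 3T proton chemical shifts and relative line amplitudes for 20
#' brain metabolites with standard in vivo concentrations (mM-equivalent
#' units). The `on` column modifications emulate MEGA-PRESS editing at
#' 1.9 ppm: the GABA 3.01 ppm multiplet appears as an outer pseudo-
#' doublet in the edit-off condition and refocused (collapsed) in the
#' edit-on condition, the 1.89 ppm GABA resonance is saturated in ON,
#' and the Glx 3.75 ppm resonances are partially co-edited; everything
#' else is condition-independent and cancels in the difference.
#'
#' @return named list of metabolite specs: `conc` (mM), `lines`
#'   (data.frame ppm/amp for edit-off), `lines_on` (edit-on, NULL when
#'   identical).
#' @export
brain_metabolites <- function() {
  L <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(ppm = m[, 1], amp = m[, 2], phase = 0)
  }
  # antiphase variant: three columns (ppm, amp, phase in radians)
  LP <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(ppm = m[, 1], amp = m[, 2], phase = m[, 3])
  }
  # Coupled resonances are spread over J-split sub-line clusters
  # (J ~ 5-8 Hz at 3T) so neighbouring multiplets overlap into the
  # quasi-continuum seen in vivo; singlets stay single. Editing at
  # 1.9 ppm saturates the GABA 1.89 multiplet, refocuses the partially
  # cancelled GABA 3.01 multiplet into a collapsed stronger line, and
  # co-edits the Glx 3.75 resonances, so the edited information lives
  # in the ON - OFF contrast.
  list(
    NAA  = list(conc = 12.0, lines = L(2.008, 3,
                                       2.45, 0.25, 2.49, 0.35, 2.53, 0.25,
                                       2.63, 0.20, 2.67, 0.30, 2.71, 0.20)),
    NAAG = list(conc = 1.5,  lines = L(2.042, 3, 2.68, 0.2, 2.72, 0.3)),
    Cr   = list(conc = 4.5,  lines = L(3.027, 3, 3.913, 2)),
    PCr  = list(conc = 4.5,  lines = L(3.029, 3, 3.930, 2)),
    GPC  = list(conc = 1.0,  lines = L(3.212, 9, 3.58, 0.5, 3.61, 0.5,
                                       3.64, 0.5, 4.31, 1)),
    PCho = list(conc = 0.6,  lines = L(3.209, 9, 3.59, 0.5, 3.61, 0.5,
                                       3.63, 0.5, 4.28, 1)),
    Glu  = list(conc = 10.0, lines = L(1.98, 0.3, 2.04, 0.5, 2.08, 0.5,
                                       2.12, 0.5, 2.20, 0.3, 2.28, 0.4,
                                       2.34, 0.6, 2.40, 0.4,
                                       3.70, 0.4, 3.75, 0.5, 3.79, 0.4),
                lines_on = L(1.98, 0.3, 2.04, 0.5, 2.08, 0.5,
                             2.12, 0.5, 2.20, 0.3, 2.28, 0.4,
                             2.34, 0.6, 2.40, 0.4, 3.75, 1.4)),
    Gln  = list(conc = 3.0,  lines = L(2.09, 0.4, 2.13, 0.5, 2.17, 0.3,
                                       2.42, 0.5, 2.45, 0.6, 2.48, 0.4,
                                       3.73, 0.3, 3.76, 0.4, 3.79, 0.3),
                lines_on = L(2.09, 0.4, 2.13, 0.5, 2.17, 0.3,
                             2.42, 0.5, 2.45, 0.6, 2.48, 0.4, 3.76, 1.1)),
    # at the editing echo time the coupled GABA multiplets are
    # antiphase in the OFF condition (mostly self-cancelled, the reason
    # editing is needed); the ON pulse at 1.9 ppm saturates the 1.89
    # multiplet and refocuses 2.28 and 3.01 into positive lines
    GABA = list(conc = 1.5,
                lines = LP(1.83, 0.30, pi, 1.87, 0.45, 0,
                           1.91, 0.45, 0, 1.95, 0.30, pi,
                           2.24, 0.40, pi, 2.28, 0.55, 0, 2.32, 0.40, pi,
                           2.96, 0.40, pi, 3.01, 0.55, 0, 3.06, 0.40, pi),
                lines_on = L(2.284, 1.5, 3.012, 1.5)),
    Glc  = list(conc = 1.5,  lines = L(3.20, 0.4, 3.23, 0.5, 3.40, 0.5,
                                       3.43, 0.5, 3.47, 0.4, 3.77, 0.4,
                                       3.80, 0.5, 3.83, 0.4)),
    Lac  = list(conc = 0.6,  lines = L(1.29, 1.4, 1.33, 1.4, 4.10, 0.7)),
    Ins  = list(conc = 6.0,  lines = L(3.49, 0.8, 3.52, 1.4, 3.55, 0.8,
                                       3.58, 0.6, 3.61, 1.0, 3.64, 0.6,
                                       4.05, 0.8)),
    Asp  = list(conc = 2.0,  lines = L(2.61, 0.4, 2.65, 0.5, 2.69, 0.4,
                                       2.76, 0.3, 2.80, 0.4, 2.84, 0.3,
                                       3.89, 0.5)),
    Tau  = list(conc = 1.5,  lines = L(3.22, 0.6, 3.25, 0.8, 3.28, 0.6,
                                       3.40, 0.7, 3.42, 0.8, 3.44, 0.7)),
    GSH  = list(conc = 2.0,  lines = L(2.51, 0.4, 2.55, 0.5, 2.59, 0.4,
                                       2.93, 0.6, 2.97, 0.6, 3.77, 0.5)),
    sIns = list(conc = 0.3,  lines = L(3.340, 6)),
    PE   = list(conc = 1.0,  lines = L(3.19, 0.6, 3.22, 0.8, 3.25, 0.6,
                                       3.95, 0.7, 3.98, 0.8, 4.01, 0.7)),
    Asc  = list(conc = 1.0,  lines = L(3.71, 0.4, 3.73, 0.5, 4.01, 0.5,
                                       4.03, 0.4)),
    Ala  = list(conc = 0.5,  lines = L(1.44, 0.8, 1.47, 1.0, 1.50, 0.8,
                                       3.78, 0.6)),
    Gly  = list(conc = 1.0,  lines = L(3.548, 2))
  )
}

# intrinsic linewidth of pseudo-basis lines (Hz); data linewidths are
# reached by adding Lorentzian gamma on top of this floor
PSEUDO_BASIS_LW <- 1.0

lorentz_fid <- function(grid, ppm, amp, lw_hz, phase = 0) {
  tau <- time_axis(grid)
  f <- (ppm - grid$ppm_reference) * grid$spectrometer_freq
  amp * exp(1i * phase + 2i * pi * f * tau - pi * lw_hz * tau)
}

#' Build a parametric pseudo-basis
#'
#' @param grid an [acquisition_grid()].
#' @param mets metabolite spec list as from [brain_metabolites()] (subset
#'   allowed).
#' @param condition `"off"` (default line lists) or `"on"` (use
#'   `lines_on` where present).
#' @param lw_hz intrinsic basis linewidth (Hz).
#' @param groups `"per_metabolite"` (independent shift/broadening per
#'   metabolite) or `"global"` (one shared group, the standard linked
#'   model).
#' @return a [basis_set()].
#' @export
pseudo_basis <- function(grid, mets = brain_metabolites(),
                         condition = "off", lw_hz = PSEUDO_BASIS_LW,
                         groups = c("global", "per_metabolite")) {
  groups <- match.arg(groups)
  nms <- names(mets)
  fids <- t(vapply(mets, function(m) {
    lines <- if (condition == "on" && !is.null(m$lines_on)) m$lines_on
    else m$lines
    if (any(lines$amp < 0)) stop_domain("line amplitudes must be >= 0")
    ppm_rng <- range(ppm_axis(grid))
    if (any(lines$ppm < ppm_rng[1] | lines$ppm > ppm_rng[2]))
      stop_domain("line ppm outside the spectral window")
    ph <- if ("phase" %in% names(lines)) lines$phase else rep(0, nrow(lines))
    Reduce(`+`, lapply(seq_len(nrow(lines)), function(i)
      lorentz_fid(grid, lines$ppm[i], lines$amp[i], lw_hz, ph[i])))
  }, complex(grid$n_points)))
  gmap <- if (groups == "global") stats::setNames(rep("g0", length(nms)), nms)
  else stats::setNames(nms, nms)
  basis_set(fids, nms, grid, groups = gmap)
}

#' Matched-filter singlet SNR
#'
#' SNR of the tallest peak in `ppm_range` after an exponential matched
#' filter (`exp(-pi lw tau)`, matched to a Lorentzian of FWHM `lw_hz`),
#' relative to the spectral noise SD. With `noise_sd` given the noise
#' level is analytic (`noise_sd * sqrt(mean(w^2))` per spectral point
#' under the unitary DFT); otherwise it is estimated from the first
#' eighth of the ppm axis (assumed signal-free).
#'
#' @param fid complex FID (one transient).
#' @param grid an [acquisition_grid()].
#' @param ppm_range window containing the reference singlet.
#' @param lw_hz matched-filter linewidth (Hz).
#' @param noise_sd known time-domain noise SD per real component.
#' @return scalar SNR.
#' @export
measure_snr <- function(fid, grid, ppm_range = c(1.8, 2.2), lw_hz = 5,
                        noise_sd = NULL) {
  w <- exp(-pi * lw_hz * time_axis(grid))
  spec <- fid_to_spectrum(fid * w)
  ppm <- ppm_axis(grid)
  sel <- ppm >= ppm_range[1] & ppm <= ppm_range[2]
  peak <- max(Mod(spec[sel]))
  sig <- if (!is.null(noise_sd)) noise_sd * sqrt(mean(w^2))
  else stats::sd(Re(spec[seq_len(floor(length(spec) / 8))]))
  peak / sig
}

# noise SD per real/imag time-domain component achieving a requested
# matched-filter SNR for a given noiseless FID
noise_sd_for_snr <- function(fid, grid, snr, ppm_range, lw_hz) {
  w <- exp(-pi * lw_hz * time_axis(grid))
  spec <- fid_to_spectrum(fid * w)
  ppm <- ppm_axis(grid)
  sel <- ppm >= ppm_range[1] & ppm <= ppm_range[2]
  peak <- max(Mod(spec[sel]))
  peak / (snr * sqrt(mean(w^2)))
}

add_noise <- function(transients, noise_sd) {
  n <- length(transients)
  transients + complex(real = stats::rnorm(n, 0, noise_sd),
                       imaginary = stats::rnorm(n, 0, noise_sd))
}

# generate a noiseless transient matrix from a plan + truth theta
synth_transients <- function(plan, theta, basis, grid,
                             baseline_order = -1L) {
  ctx <- eval_context(basis, grid, NULL, baseline_order)
  params <- map_all_parameters(plan, theta)
  bpt <- basis_per_t_list(basis, plan$T)
  out <- cpp_eval_block(ctx$bmat, ctx$gidx, ctx$tau, ctx$nu, ctx$sel,
                        ctx$Breg, params, FALSE, bpt)
  t(apply(out$spec, 2, spectrum_to_fid))
}

# ---- CS1 toy: two Lorentzian peaks -----------------------------------------

#' Two-peak toy fMRS series
#'
#' 64 repetitions of two Lorentzian peaks at the given separation; peak B
#' increases in amplitude by 20% during the central 32 repetitions, peak
#' A stays constant. A rectangular stimulation + constant design matrix
#' is returned. Noise is set by the matched-filter SNR of peak A;
#' `snr = Inf` gives a noiseless series.
#'
#' @param separation_ppm peak separation (ppm).
#' @param snr matched-filter singlet SNR of peak A per transient.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param linewidth_hz total Lorentzian FWHM of both peaks (Hz).
#' @param n_transients repetitions (default 64, central half modulated).
#' @return list with `series`, `tvar`, `basis` (per-metabolite groups),
#'   `config` (GLM on concentrations, nuisances fixed), `truth_theta`,
#'   `opts`, `truth` scenario description.
#' @export
gen_two_peak <- function(separation_ppm, snr, seed, linewidth_hz = 5,
                         n_transients = 64L) {
  grid <- acquisition_grid(4e-3, 128L, 123.2, 4.65)
  half_sep <- separation_ppm / 2
  ppm_rng <- range(ppm_axis(grid))
  if (4.65 - half_sep < ppm_rng[1] || 4.65 + half_sep > ppm_rng[2])
    stop_domain("separation outside the spectral window")
  mets <- list(
    A = list(conc = 1, lines = data.frame(ppm = 4.65 - half_sep, amp = 1)),
    B = list(conc = 1, lines = data.frame(ppm = 4.65 + half_sep, amp = 1)))
  basis <- pseudo_basis(grid, mets, groups = "per_metabolite")
  gamma_true <- fwhm_hz_to_gamma(max(linewidth_hz - PSEUDO_BASIS_LW, 0))

  stim <- rep(0, n_transients)
  stim[(n_transients / 4 + 1):(3 * n_transients / 4)] <- 1
  tvar <- time_variable(data.frame(const = 1, stim = stim))
  config <- dynamic_config(list(
    conc = list(model = "glm", covariates = c("const", "stim")),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = -1L)
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  theta["conc_A_beta0"] <- 1; theta["conc_A_beta1"] <- 0
  theta["conc_B_beta0"] <- 1; theta["conc_B_beta1"] <- 0.2
  theta[c("gamma_A", "gamma_B")] <- gamma_true

  tr <- synth_transients(plan, theta, basis, grid)
  set.seed(seed)
  if (is.finite(snr)) {
    sd0 <- noise_sd_for_snr(tr[1, ], grid,
                            snr, c(4.65 - half_sep - 0.1, 4.65 - half_sep + 0.1),
                            linewidth_hz)
    tr <- add_noise(tr, sd0)
  } else sd0 <- 0
  list(series = fid_series(tr, grid), tvar = tvar, basis = basis,
       config = config, truth_theta = theta,
       opts = fit_options(baseline_order = -1L, ftol = 1e-6),
       truth = list(stim_over_baseline = 0.2, noise_sd = sd0,
                    separation_ppm = separation_ppm,
                    linewidth_hz = linewidth_hz))
}

# ---- CS1 extension: realistic fMRS spectrum --------------------------------

#' Realistic single-subject fMRS simulation
#'
#' 60 repetitions of a 20-metabolite 3T brain spectrum; one target
#' metabolite increases by 20% for the central 30 repetitions (rectangular
#' design, two regressors). Linewidths of 6 or 10 Hz are the documented
#' settings.
#'
#' @param target_metabolite name from [brain_metabolites()].
#' @param linewidth_hz Lorentzian FWHM (6 or 10 are the standard cases).
#' @param seed RNG seed.
#' @param snr per-transient NAA matched-filter SNR.
#' @return list as in [gen_two_peak()].
#' @export
gen_fmrs_spectrum <- function(target_metabolite, linewidth_hz, seed,
                              snr = 30) {
  grid <- acquisition_grid(1e-3, 1024L, 123.2, 4.65)
  mets <- brain_metabolites()
  if (!target_metabolite %in% names(mets))
    stop_format(sprintf("unknown metabolite '%s'", target_metabolite))
  basis <- pseudo_basis(grid, mets, groups = "global")
  gamma_true <- fwhm_hz_to_gamma(max(linewidth_hz - PSEUDO_BASIS_LW, 0))
  T_n <- 60L
  stim <- rep(0, T_n); stim[16:45] <- 1
  tvar <- time_variable(data.frame(const = 1, stim = stim))
  config <- dynamic_config(list(
    conc = list(model = "glm", covariates = c("const", "stim")),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed",
    baseline = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = 2L)
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  for (m in names(mets)) {
    theta[paste0("conc_", m, "_beta0")] <- mets[[m]]$conc
    theta[paste0("conc_", m, "_beta1")] <-
      if (m == target_metabolite) 0.2 * mets[[m]]$conc else 0
  }
  theta["gamma_g0"] <- gamma_true
  tr <- synth_transients(plan, theta, basis, grid, baseline_order = 2L)
  set.seed(seed)
  sd0 <- if (is.finite(snr))
    noise_sd_for_snr(tr[1, ], grid, snr, c(1.9, 2.1), linewidth_hz) else 0
  if (sd0 > 0) tr <- add_noise(tr, sd0)
  list(series = fid_series(tr, grid), tvar = tvar, basis = basis,
       config = config, truth_theta = theta,
       opts = fit_options(baseline_order = 2L, ppm_range = c(0.5, 4.4)),
       truth = list(target = target_metabolite,
                    delta = 0.2 * mets[[target_metabolite]]$conc,
                    noise_sd = sd0, linewidth_hz = linewidth_hz))
}

# ---- CS2: MEGA-PRESS editing ----------------------------------------------

#' MEGA-PRESS edited pair simulation
#'
#' Generates one edit-ON / edit-OFF pair (19 metabolites, no
#' macromolecules) from per-condition pseudo-bases, plus an edit-off-only
#' series with half the noise variance (matched total acquisition time).
#' Either `noise_sd` (time-domain SD) or `snr` (NAA matched-filter SNR,
#' the 30-330 grid of the study design) fixes the noise.
#'
#' @param linewidth_hz Lorentzian FWHM; the study grid is
#'   `seq(5, 9, length.out = 4)`.
#' @param seed RNG seed.
#' @param noise_sd time-domain noise SD; overrides `snr`.
#' @param snr NAA singlet SNR (used when `noise_sd` is NULL).
#' @return list with `pair` (T = 2 series, OFF then ON), `off_half`
#'   (T = 1, half noise variance), `basis` (per-condition), `basis_off`,
#'   `basis_diff` (edited metabolites only), `config` (shared
#'   concentrations and nuisances), `truth_theta`, `truth`.
#' @export
gen_mega <- function(linewidth_hz, seed, noise_sd = NULL, snr = NULL) {
  grid <- acquisition_grid(1e-3, 1024L, 123.2, 4.65)
  mets <- brain_metabolites()
  mets <- mets[setdiff(names(mets), "Gly")]  # 19 metabolites
  b_off <- pseudo_basis(grid, mets, condition = "off", groups = "global")
  b_on <- pseudo_basis(grid, mets, condition = "on", groups = "global")
  basis <- basis_set(b_off$fids, b_off$names, grid, groups = b_off$groups,
                     per_timepoint = list(b_off, b_on))
  gamma_true <- fwhm_hz_to_gamma(max(linewidth_hz - PSEUDO_BASIS_LW, 0))

  tvar <- time_variable(data.frame(condition = c(0, 1)))  # OFF, ON
  config <- dynamic_config(list(
    conc = "fixed", gamma = "fixed", eps = "fixed",
    phi0 = "fixed", phi1 = "fixed", baseline = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = 2L)
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  for (m in names(mets)) theta[paste0("conc_", m)] <- mets[[m]]$conc
  theta["gamma_g0"] <- gamma_true

  tr <- synth_transients(plan, theta, basis, grid, baseline_order = 2L)
  set.seed(seed)
  if (is.null(noise_sd)) {
    if (is.null(snr)) stop_domain("give noise_sd or snr")
    noise_sd <- noise_sd_for_snr(tr[1, ], grid, snr, c(1.9, 2.1),
                                 linewidth_hz)
  }
  pair <- add_noise(tr, noise_sd)
  off_half <- add_noise(tr[1, , drop = FALSE], noise_sd / sqrt(2))

  dfids <- b_on$fids - b_off$fids
  keep <- sqrt(rowSums(Mod(dfids)^2)) > 1e-9 * max(sqrt(rowSums(Mod(b_off$fids)^2)))
  basis_diff <- basis_set(dfids[keep, , drop = FALSE], b_off$names[keep],
                          grid,
                          groups = stats::setNames(rep("g0", sum(keep)),
                                                   b_off$names[keep]))
  list(pair = fid_series(pair, grid, labels = c("OFF", "ON")),
       off_half = fid_series(off_half, grid),
       basis = basis, basis_off = b_off, basis_diff = basis_diff,
       config = config, truth_theta = theta, tvar = tvar,
       opts = fit_options(baseline_order = 2L, ppm_range = c(0.5, 4.4)),
       truth = list(conc = vapply(mets, function(m) m$conc, 0),
                    noise_sd = noise_sd, linewidth_hz = linewidth_hz))
}

# ---- CS3: group fMRS cohort ------------------------------------------------

#' Simulated visual-stimulation fMRS cohort
#'
#' Per subject, a stimulation and a control (no effect) condition at 7T:
#' HRF-convolved two-block design plus linear drift and constant (four
#' regressors). Stimulation effects (fraction of baseline concentration):
#' Glu +2%, Lac +4%, Glc -3%, Asp -3%, all others zero; BOLD line
#' narrowing enters as a negative stimulation effect on the shared
#' Lorentzian broadening. Inter-subject variation is Gaussian on the
#' effects (25% of the mean effect) and on baseline concentrations (5%).
#'
#' @param n_subjects number of subjects (default 10).
#' @param seed RNG seed.
#' @param snr per-transient NAA SNR (block-averaged data quality).
#' @param n_transients dynamic points per condition.
#' @param tr seconds per dynamic point.
#' @return list with `subjects` (each: `stim`, `ctrl` [fid_series],
#'   `truth_stim`, `truth_ctrl` theta vectors), `basis`, `tvar`,
#'   `config`, `design`, `effects`, `opts`.
#' @export
gen_fmrs_cohort <- function(n_subjects = 10L, seed, snr = 200,
                            n_transients = 64L, tr = 2) {
  grid <- acquisition_grid(4e-4, 512L, 297.2, 4.65)
  mets <- brain_metabolites()
  basis <- pseudo_basis(grid, mets, groups = "global")
  run <- n_transients * tr
  X <- convolve_design(onsets = list(0.15 * run, 0.6 * run),
                       durations = list(0.2 * run, 0.2 * run),
                       n_transients = n_transients, tr = tr)
  tvar <- time_variable(as.data.frame(X))
  config <- dynamic_config(list(
    conc = list(model = "glm",
                covariates = c("stim1", "stim2", "drift", "const")),
    gamma = list(model = "glm",
                 covariates = c("stim1", "stim2", "drift", "const")),
    eps = "fixed", phi0 = "fixed", phi1 = "fixed", baseline = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = 2L)

  effects <- c(Glu = 0.02, Lac = 0.04, Glc = -0.03, Asp = -0.03)
  gamma_base <- fwhm_hz_to_gamma(9 - PSEUDO_BASIS_LW)
  gamma_stim <- -fwhm_hz_to_gamma(0.3)  # BOLD narrowing, Hz -> s^-1

  set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    conc_s <- vapply(mets, function(m) m$conc, 0) *
      (1 + stats::rnorm(length(mets), 0, 0.05))
    names(conc_s) <- names(mets)
    make_theta <- function(with_effect) {
      theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
      for (m in names(mets)) {
        theta[paste0("conc_", m, "_beta3")] <- conc_s[m]  # const
        eff <- if (with_effect && m %in% names(effects))
          conc_s[m] * stats::rnorm(1, effects[m], 0.25 * abs(effects[m]))
        else 0
        theta[paste0("conc_", m, "_beta0")] <- eff
        theta[paste0("conc_", m, "_beta1")] <- eff
      }
      theta["gamma_g0_beta3"] <- gamma_base
      if (with_effect) {
        theta["gamma_g0_beta0"] <- gamma_stim
        theta["gamma_g0_beta1"] <- gamma_stim
      }
      theta
    }
    th_stim <- make_theta(TRUE)
    th_ctrl <- make_theta(FALSE)
    tr_stim <- synth_transients(plan, th_stim, basis, grid, 2L)
    tr_ctrl <- synth_transients(plan, th_ctrl, basis, grid, 2L)
    sd0 <- noise_sd_for_snr(tr_ctrl[1, ], grid, snr, c(1.9, 2.1), 9)
    list(stim = fid_series(add_noise(tr_stim, sd0), grid),
         ctrl = fid_series(add_noise(tr_ctrl, sd0), grid),
         truth_stim = th_stim, truth_ctrl = th_ctrl, noise_sd = sd0)
  })
  list(subjects = subjects, basis = basis, tvar = tvar, config = config,
       design = X, effects = effects,
       opts = fit_options(baseline_order = 2L, ppm_range = c(0.5, 4.4),
                          ftol = 1e-6))
}

# ---- CS5: multi-direction diffusion ----------------------------------------

#' Multi-direction diffusion-weighted MRS simulation
#'
#' Three metabolites with distinct ball-and-two-sticks ground truths
#' (NAA: two crossing sticks; Ins: ball-dominant, glia-like; Cr: a
#' mixture), acquired at b = 1 and 3 ms/um^2 over `n_dir` deterministic
#' repulsion-style directions plus one b = 0, so T = 2 n_dir + 1. The
#' 60-direction protocol carries 10x the noise variance of the
#' 6-direction one (matched acquisition time).
#'
#' @param n_dir 6 or 60 directions per shell.
#' @param seed RNG seed.
#' @param snr b = 0 NAA matched-filter SNR of the 6-direction protocol.
#' @return list with `series`, `tvar`, `basis`, `config`, `truth_theta`,
#'   `truth` (including per-metabolite stick table), `opts`.
#' @export
gen_dmrs_directions <- function(n_dir, seed, snr = 40) {
  grid <- acquisition_grid(1e-3, 512L, 123.2, 4.65)
  mets <- list(
    NAA = list(conc = 10, lines = data.frame(ppm = 2.008, amp = 3)),
    Cr  = list(conc = 8,  lines = data.frame(ppm = c(3.027, 3.913),
                                             amp = c(3, 2))),
    Ins = list(conc = 6,  lines = data.frame(ppm = c(3.520, 3.610),
                                             amp = c(4, 2))))
  basis <- pseudo_basis(grid, mets, groups = "global")
  dirs <- fibonacci_hemisphere(n_dir)
  tvar <- time_variable(data.frame(
    b = c(0, rep(1, n_dir), rep(3, n_dir)),
    gx = c(1, dirs[, 1], dirs[, 1]),
    gy = c(0, dirs[, 2], dirs[, 2]),
    gz = c(0, dirs[, 3], dirs[, 3])), kind = "bval_bvec")
  config <- dynamic_config(list(
    conc = list(model = "ball2sticks"),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = -1L)

  truth_sticks <- list(
    NAA = c(f1 = 0.35, f2 = 0.35, d = 0.35, theta1 = pi / 2, phi1 = 0,
            theta2 = pi / 2, phi2 = pi / 2),
    Cr  = c(f1 = 0.20, f2 = 0.15, d = 0.32, theta1 = pi / 2, phi1 = 0,
            theta2 = pi / 2, phi2 = pi / 2),
    Ins = c(f1 = 0.08, f2 = 0.05, d = 0.30, theta1 = pi / 2, phi1 = 0,
            theta2 = pi / 2, phi2 = pi / 2))
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  for (m in names(mets)) {
    theta[paste0("conc_", m, "_amp")] <- mets[[m]]$conc
    theta[paste0("conc_", m, "_", names(truth_sticks[[m]]))] <-
      truth_sticks[[m]]
  }
  theta["gamma_g0"] <- fwhm_hz_to_gamma(6 - PSEUDO_BASIS_LW)

  tr <- synth_transients(plan, theta, basis, grid)
  set.seed(seed)
  sd6 <- noise_sd_for_snr(tr[1, ], grid, snr, c(1.9, 2.1), 6)
  sd0 <- if (n_dir >= 60) sd6 * sqrt(10) else sd6
  tr <- add_noise(tr, sd0)
  list(series = fid_series(tr, grid), tvar = tvar, basis = basis,
       config = config, truth_theta = theta,
       truth = list(sticks = truth_sticks, noise_sd = sd0,
                    conc = vapply(mets, function(m) m$conc, 0)),
       opts = fit_options(baseline_order = -1L))
}

# ---- CS6: multi-b diffusion ------------------------------------------------

#' Multi-b-value diffusion-weighted MRS simulation
#'
#' Seven log-spaced b values from 0.02 to 50 ms/um^2; biexponential
#' metabolite decays, mono-exponential macromolecule decay, and an
#' exponential-plus-offset trajectory for the leading baseline
#' coefficient (emulating residual-water baseline roll decaying with b).
#'
#' @param seed RNG seed.
#' @param snr b = 0.02 NAA matched-filter SNR; `Inf` for noiseless.
#' @return list with `series`, `tvar`, `basis`, `config`, `truth_theta`,
#'   `opts`.
#' @export
gen_dmrs_multib <- function(seed, snr = 60) {
  grid <- acquisition_grid(1e-3, 512L, 123.2, 4.65)
  mets <- list(
    NAA = list(conc = 10, lines = data.frame(ppm = 2.008, amp = 3)),
    Cr  = list(conc = 8,  lines = data.frame(ppm = c(3.027, 3.913),
                                             amp = c(3, 2))),
    Ins = list(conc = 6,  lines = data.frame(ppm = c(3.520, 3.610),
                                             amp = c(4, 2))),
    MM  = list(conc = 3,  lines = data.frame(ppm = c(0.91, 1.21),
                                             amp = c(3, 2))))
  basis <- pseudo_basis(grid, mets, lw_hz = 4, groups = "global")
  bvals <- exp(seq(log(0.02), log(50), length.out = 7))
  tvar <- time_variable(data.frame(b = bvals), kind = "custom")
  config <- dynamic_config(list(
    conc = list(model = "biexp"),
    conc_MM = list(model = "exp"),
    b_re_0 = list(model = "exp_offset"),
    gamma = "fixed", eps = "fixed", phi0 = "fixed", phi1 = "fixed",
    baseline = "fixed"))
  plan <- dyn_plan(config, basis, tvar, baseline_order = 1L)
  biexp_truth <- list(
    NAA = c(frac = 0.25, adc1 = 1.10, adc2 = 0.09),
    Cr  = c(frac = 0.30, adc1 = 1.00, adc2 = 0.10),
    Ins = c(frac = 0.35, adc1 = 0.95, adc2 = 0.12))
  theta <- stats::setNames(numeric(plan$n_theta), plan$theta_names)
  for (m in names(biexp_truth)) {
    theta[paste0("conc_", m, "_amp")] <- mets[[m]]$conc
    theta[paste0("conc_", m, "_", names(biexp_truth[[m]]))] <- biexp_truth[[m]]
  }
  theta["conc_MM_amp"] <- mets$MM$conc
  theta["conc_MM_adc"] <- 0.01
  theta["b_re_0_amp"] <- 0.5
  theta["b_re_0_adc"] <- 1.5
  theta["b_re_0_offset"] <- 0.05
  theta["gamma_g0"] <- fwhm_hz_to_gamma(6 - 4)

  tr <- synth_transients(plan, theta, basis, grid, baseline_order = 1L)
  set.seed(seed)
  sd0 <- if (is.finite(snr))
    noise_sd_for_snr(tr[1, ], grid, snr, c(1.9, 2.1), 6) else 0
  if (sd0 > 0) tr <- add_noise(tr, sd0)
  list(series = fid_series(tr, grid), tvar = tvar, basis = basis,
       config = config, truth_theta = theta,
       truth = list(biexp = biexp_truth, mm_adc = 0.01, noise_sd = sd0,
                    bvals = bvals),
       opts = fit_options(baseline_order = 1L))
}
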