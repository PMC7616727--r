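---
title: "Dynamic (2D) MRS fitting: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic (2D) MRS fitting: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsdyn)
```

## The problem

Dynamic (2D) MRS acquires a series of spectra while experimental
conditions change: diffusion weighting, spectral editing, functional
stimulation, relaxation weighting. The conventional pipeline fits every
transient independently and then models the fitted parameters across
time; it discards the knowledge that most spectral parameters are
shared, or smoothly linked, across transients. `mrsdyn` fits the whole
series at once: every spectral parameter may be **fixed** across time,
**variable** (one value per transient), or **constrained by a dynamic
model** of the experimental time variable. Joint fitting reduces the
number of free parameters and, when parameters are mutually correlated
within a single spectrum, reduces the uncertainty of the parameters of
interest.

## The spectral model

One transient is modelled as a linear combination of broadened, shifted,
phased basis spectra plus a complex polynomial baseline:

$$ s(\nu) \;=\; B(\nu) \;+\; e^{-j(\Phi_0 + \nu\,\Phi_1)}
   \sum_k c_k\, \mathcal{F}\!\left[\, m_k(\tau)\,
   e^{-\tau(\gamma_{g(k)} + j\,\epsilon_{g(k)})} \right] $$

* $c_k$ — concentration of metabolite $k$ (arbitrary concentration
  units; the synthetic generators use mM-equivalents),
* $\gamma$ — Lorentzian broadening in s$^{-1}$, per *metabolite group*
  (`gamma_to_fwhm_hz()` converts to the added FWHM $\gamma/\pi$ Hz),
* $\epsilon$ — frequency shift in rad s$^{-1}$; with the literal
  $e^{-j\epsilon\tau}$ convention a positive $\epsilon$ moves a peak by
  $-\epsilon/2\pi$ Hz on the ascending frequency axis,
* $\Phi_0$ (rad), $\Phi_1$ (s) — zero/first-order phase. The model
  equation leaves the units of $\nu$ in the $\nu\Phi_1$ term open; this
  implementation fixes **$\nu$ in Hz** and documents it here,
* $B(\nu)$ — complex polynomial in $\nu$ rescaled to $[-1,1]$ over the
  fitted window; default order 2, `-1` disables it.

The lineshape is purely Lorentzian, matching the model equation; no
Gaussian/Voigt component is fitted. Spectra are indexed in ascending
ppm; the FID-to-spectrum map is the unitary DFT with fftshift-style
centring, and `ppm_reference` maps to the centre bin. Metabolite groups
share $\gamma$ and $\epsilon$: one global group is the standard
("linked") model, per-metabolite groups the "free" model.

All derivatives are analytic, including the chain through dynamic
models, and are verified against central differences in the test suite
(`<= 1e-6` relative).

## Dynamic models

`dynamic_config()` (or a JSON file via `parse_config()`) binds each
spectral parameter, or a parameter class (`conc`, `gamma`, ...), to a
behaviour. Model-bound parameters draw their covariates from the
per-transient time variable. Built-ins:

| model | parameters | use |
|---|---|---|
| `glm` | one $\beta$ per design column | fMRS designs |
| `exp` | amplitude, ADC | mono-exponential diffusion decay |
| `exp_offset` | amplitude, ADC, offset | baseline "roll" vs b-value |
| `biexp` | amplitude, fraction, two ADCs | metabolite diffusion |
| `ball2sticks` | amplitude, $f_1,f_2$, $d$, two stick angles | crossing-fibre dMRS |

The ball-and-two-sticks signal is
$S = (1-f_1-f_2)e^{-bd} + \sum_i f_i e^{-bd (g^\top v_i)^2}$ with a
single shared diffusivity and spherical-angle stick parametrization
($\theta \in [0,\pi]$, $\phi \in [0, 2\pi)$); it is applied as
$c(t) = c_0 S(b_t, g_t)$. Custom models register through
`register_dynamic_model()` before config parsing — the original tool
uses an executable configuration file; this package deliberately uses a
declarative config plus a registration hook, for portability and
safety, while preserving the fixed/variable/model-constrained
semantics.

The hemodynamic response `glover_hrf()` is the double-gamma
$h(t) = c_1 t^{6} e^{-t/0.9} - 0.35\,c_2 t^{12} e^{-t/0.9}$ with each
term normalized to unit peak (numeric argmax near 5.4 s, undershoot
pulls the composite peak to ~5.2 s). The reference implementation the
constants imitate does not print them; these values are this package's
own documented choice. `convolve_design()` builds HRF-convolved,
peak-normalized stimulation columns plus a zero-mean linear drift and a
constant.

## Fitting

The objective is the summed squared residual of real and imaginary
spectral points over a configurable ppm window (default: full
spectrum). The optimizer is a deterministic box-constrained
Levenberg–Marquardt with analytic Jacobians; no stochastic sampling is
used anywhere. Defaults: `max_iter = 200`, relative cost-decrease
tolerance `ftol = 1e-7`, gradient tolerance `gtol = 1e-6` (the
Cr/PCr-type near-degeneracies otherwise produce long, estimate-neutral
tail crawls; estimates shift by well under 1e-3 concentration units
between `ftol = 1e-6` and `1e-9`). Default bounds keep concentrations
and broadenings non-negative; everything else is unbounded.
Non-convergence is a *flag* on the result, never an exception, so Monte
Carlo campaigns complete.

Initialization (`init_spectral()`): phases start at zero, the shift from
the cross-correlation of data and unit-concentration model magnitude
spectra, the broadening from a matched-filter linewidth estimate minus
the basis linewidth (floored at zero), concentrations by non-negative
least squares at those nuisances. For dynamic fits three strategies
exist:

* `"invert"` (default) — independent per-transient fits, then each
  dynamic model least-squares-fitted to the per-transient series
  (linear models in closed form; nonlinear models by bounded LM from a
  coarse deterministic grid — for the sticks model a spherical
  Fibonacci direction grid),
* `"mean"` — one fit of the coherent average, broadcast through the
  same inversion; preferred when per-transient fits are unstable (e.g.
  two unresolved peaks label-swapping between transients, which poisons
  the inverted start),
* `"values"` — user-supplied $\theta_0$ verbatim (the hook for external
  initializers, and for ground-truth initialization in simulations).

The reference publication reports that its own default initialization
failed for the multi-direction sticks problem; the grid-start
refinement used here is this package's own choice and is exercised by a
60-direction noiseless inversion test rather than asserted to be the
original's behaviour.

Uncertainty: $\hat\sigma^2 = \mathrm{RSS}/(n-P)$ and
$\mathrm{Cov} = \hat\sigma^2 (J^\top J)^{-1}$ through a rank-guarded
eigen-pseudo-inverse; degenerate directions are reported. The AIC is
the Gaussian-residual form $n\ln(\mathrm{RSS}/n) + 2P$ with real and
imaginary points both counted.

## Group statistics

First-level contrasts are plain $w^\top\hat\beta$ with
$w^\top \mathrm{Cov}\, w$ variances; ratios (percent change) use the
delta method. Metabolites bound to the same *linear* dynamic model can
be combined (e.g. NAA + NAAG → tNAA) with full cross-covariance
propagation; combination under nonlinear models is refused as
undefined. Group inference is a **variance-weighted fixed-effects GLM**
(weights 1/varcope, residual-based variance, t → z through the normal
quantile map, two-sided p): the original tool wraps a Bayesian
multilevel engine (FLAMEO), which is an external binary; the closed-form
weighted GLM preserves the paired-design semantics — with equal weights
it reduces exactly to the classical paired t-test (verified in the
tests) — and its null calibration is checked empirically (type-I error
within [0.03, 0.07] at $\alpha = 0.05$). Bonferroni correction across
metabolites is available but off by default.

## The synthetic world

The generators reproduce the *statistical structure* of the simulation
case studies, not their exact spectra. The key substitution: basis sets
come from a **parametric pseudo-basis** (fixed Lorentzian line lists per
metabolite) instead of density-matrix simulation. Consequences worth
being explicit about:

* Coupled resonances are emulated as J-split sub-line clusters
  (J ≈ 5–8 Hz) so that multiplets overlap into the quasi-continuum seen
  in vivo. Absolute spectra are not faithful; the overlap/correlation
  structure that drives fitting-strategy comparisons is.
* Editing (MEGA-PRESS) is emulated at the mechanism level: in the
  edit-off condition the GABA multiplets are *antiphase* (largely
  self-cancelled — the physical reason editing is needed at the editing
  echo time), the 1.9 ppm editing pulse saturates the GABA 1.89
  multiplet, refocuses 2.28/3.01 into positive collapsed lines, and
  co-edits the Glx 3.75 resonances. All other metabolites are
  condition-independent and cancel in ON − OFF. The difference basis is
  the per-metabolite ON − OFF, keeping only metabolites with nonzero
  difference. Difference spectra are fitted over the standard edited
  window (2.5–4.2 ppm).
* Noise is i.i.d. complex Gaussian in the time domain. SNR follows the
  matched-filter definition: tallest peak of the exponentially filtered
  spectrum over the filtered spectral noise SD; generators calibrate
  the noise SD numerically against the requested SNR (verified within
  10%).
* Quantities the source text defers to supplementary material are fixed
  here as documented defaults: the toy-series peak SNR levels {10, 20,
  40} and separation grid 0.02–0.2 ppm; standard in vivo concentrations
  for the ~20-metabolite brain list; cohort data quality (per-transient
  NAA SNR 200, representing block-averaged 7 T time courses);
  inter-subject variation (25% of the mean effect on effects, 5% on
  baseline concentrations); BOLD line narrowing −0.3 Hz; diffusion
  truths (NAA two crossing sticks at 90°, f = 0.35 + 0.35; Cr a
  0.20 + 0.15 mixture; Ins ball-dominant; d ≈ 0.3 µm²/ms). Gradient
  direction sets are deterministic spherical-Fibonacci hemispheres (a
  repulsion-style quasi-uniform scheme, chosen for bit-reproducibility).
* The cohort's stimulation effects are the stand-in values Glu +2%,
  Lac +4%, Glc −3%, Asp −3% of baseline. With those effect sizes and
  the stated data quality, the low-concentration targets (Lac 0.6 mM)
  have limited group-level power at n = 10; the group-detection
  acceptance check is expected to fail partly, and that failure is a
  property of the stated effect sizes, not of the inference machinery
  (whose null calibration and recovery accuracy are verified
  separately).

A green test therefore establishes: correctness of the model algebra
and gradients, exact noiseless recovery for every generator, and the
*relative* behaviour of fitting strategies under the emulated overlap
structure. It does not establish agreement with density-matrix-level
spectra, vendor data handling, or in vivo effect sizes.

## Numerical choices

* Unitary DFT both ways; all acquisition grids are powers of two and
  the compiled core uses a cached-twiddle radix-2 FFT (Armadillo's
  per-call planning dominated profile time), falling back to
  `arma::fft` otherwise.
* The dynamic-fit normal equations are accumulated per transient in
  spectral-parameter space and projected through the chain Jacobian
  ($M^\top A M$), which keeps the cost linear in the transient count.
* Monte Carlo child seeds come from a deterministic counter scheme
  (`derive_seed()`); all strategies within one repetition share the
  same data (common random numbers for paired comparisons).
* Ties/degeneracies: the stick model is antipodally symmetric and
  permutation-symmetric; `stick_error()` rectifies signs and matches
  sticks by the error-minimizing permutation. Near-degenerate normal
  matrices are inverted with an eigenvalue-thresholded pseudo-inverse.

## Known limitations

* No Voigt/Gaussian lineshape, spline baselines, or water modelling.
* Dynamic models cannot couple parameters across metabolites (matching
  the original tool's stated limitation).
* The NIfTI-MRS reader/writer is deliberately minimal: singleton
  spatial dimensions, complex data, one JSON header extension. It is a
  convenience, not a conformance implementation.
* No MCMC/posterior sampling; uncertainties are Gauss–Newton
  covariances.
* Per-subject percent-change trace normalization ("relative to the
  middle time point") used in the original figures is not reproduced;
  group inference here works on GLM betas directly.
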