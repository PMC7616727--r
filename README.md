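# mrsdyn — universal dynamic fitting of MR spectroscopy

`mrsdyn` fits **dynamic (2D) MRS** data: series of spectra acquired
while experimental conditions change — functional stimulation (fMRS),
spectral editing (MEGA-PRESS), diffusion weighting (dMRS). Instead of
fitting each transient independently and modelling the noisy parameter
time courses afterwards, `mrsdyn` fits a joint **spectral–temporal
model**: every parameter of the linear-combination spectral model

$$ s(\nu,t) = B(\nu,t) + e^{-j(\Phi_0(t) + \nu\Phi_1(t))}
   \sum_k c_k(t)\, \mathcal{F}\!\left[ m_k(\tau,t)\,
   e^{-\tau(\gamma(t) + j\epsilon(t))} \right] $$

can be *fixed* across transients, *free per transient*, or *constrained
by a dynamic model* of the experimental time variable — a GLM design
matrix for fMRS, b-values and gradient directions for dMRS, shared
concentrations for edited pairs. Joint fitting reduces the free
parameter count and, when spectral parameters are correlated, reduces
the uncertainty of the parameters of interest.

It is intended for MRS methods researchers: it ships the dynamic-model
library (GLM with canonical HRF designs, mono-/bi-exponential and
exponential-plus-offset decays, ball-and-two-sticks diffusion),
analytic gradients throughout, bound-constrained Levenberg–Marquardt
fitting with covariance-based uncertainty and AIC, first-level
contrasts and variance-weighted paired group inference, synthetic-data
generators for the classic simulation case studies, and a Monte Carlo
harness for estimator comparison (RMSE / SD-ratio / bias / stick-error
metrics).

See `vignette("dynamic-mrs-fitting")` for the model, the assumptions,
and every numerical design choice.

## Worked example: a toy functional MRS series

Two Lorentzian peaks, 64 transients; peak B rises by 20% during the
central half. Concentrations are bound to a two-regressor GLM
(baseline + stimulation boxcar), the nuisances are shared across time:

```r
library(mrsdyn)
sim <- gen_two_peak(separation_ppm = 0.1, snr = 20, seed = 42)
fit <- fit_dynamic(sim$series, sim$basis, sim$config, sim$tvar,
                   sim$opts, init = "mean")
fit
#> <results_table> 10 free params, RSS 529.594, AIC -5.621e+04, converged
#>                   estimate           sd
#> conc_A_beta0  1.0079570409 0.0157461778
#> conc_A_beta1 -0.0242233102 0.0156787313
#> conc_B_beta0  1.0029527775 0.0153333635
#> conc_B_beta1  0.1898567046 0.0158260174
#> gamma_A      12.4094066917 0.2789359658
#> ...

100 * fit$par[["conc_B_beta1"]] / fit$par[["conc_B_beta0"]]
#> 18.9   # percent stimulation response; simulated truth is 20
```

`conc_B_beta1` is the stimulation beta of peak B (truth 0.2): the joint
fit recovers it as 0.190 ± 0.016 from a noisy series in which the
per-transient estimates are several times noisier. `gamma_*` is the
fitted Lorentzian broadening in s⁻¹ (12.5 s⁻¹ ≈ 4 Hz of added width on
the 1 Hz basis lines, i.e. the simulated 5 Hz total linewidth), `eps_*`
the frequency shifts in rad s⁻¹, `phi0`/`phi1` the phases. First-level
contrasts and group inference build on the covariance:

```r
cp <- first_level_cope(fit, c(conc_B_beta1 = 1))
#> cope 0.1899, varcope 0.0158^2
```

Other entry points: `fit_independent()` (classical per-transient
fitting), `gen_mega()` / `gen_fmrs_cohort()` / `gen_dmrs_directions()` /
`gen_dmrs_multib()` (case-study simulators), `run_monte_carlo()` with
`mc_scenario_cs1/cs2/cs5()` (strategy comparisons),
`run_cohort_analysis()` (subject fits → paired group GLM), and a file
CLI at `inst/cli/mrsdyn.R` (`simulate`, `fit`, `mc`, `stats`
subcommands) reading/writing the JSON + TSV interchange formats and
minimal NIfTI-MRS.

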