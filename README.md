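# sigmaqe

Chlorophyll-fluorescence analysis linking energy-dependent quenching
(qE) to the functional absorption cross-section of photosystem II
(σPSII), for single-turnover fluorometry of microalgae (FIRe/mini-FIRe
style instruments), with a seeded synthetic generator of a diatom
Lhcx-mutant strain panel so the whole chain can be exercised and tested
without instrument data.

## What it computes

**Induction fitting.** A saturating single-turnover flash closes PSII
centers with one-hit Poisson statistics, so the fluorescence rise is

F(t) = Fo + (Fm − Fo) · (1 − exp(−σPSII·Φ·t)),

with Φ the photon flux (photons Å⁻² s⁻¹; `photon_flux_from_power()`
converts the flash's W cm⁻² at a wavelength). `fit_transient()` recovers
Fo, Fm and σPSII (Å² quanta⁻¹) by bounded nonlinear least squares, with
an optional connectivity parameter p via C(1−p)/(1−pC).

**Quenching calculus.** Per light step of a rapid light curve,
`compute_params()` derives NPQ = Fm/Fm′ − 1 (Fm taken from the first
light step's Fm′), the quantum-yield partition Y(II) + Y(NPQ) + Y(NO)
= 1, qL and 1−qL from the directly measured Fo′ (1 s darkness), and the
absolute electron transport rate E·σPSII′·(Fv′/Fm′)/(Fv/Fm) in
e⁻ PSII⁻¹ s⁻¹. `des()` gives the diadinoxanthin/diatoxanthin
de-epoxidation state Dt/(Dd+Dt).

**σPSII vs Y(NPQ).** `filter_points()` applies per-curve retention
rules (negative Y(NPQ) removed; E > 600 µmol photons m⁻² s⁻¹ removed;
steps where Y(NPQ) rose but σPSII dropped by less than 5% of the
curve's total decrease removed), `fit_sigma_ynpq()` pools everything
into one OLS regression with 95% CIs, and the value at Y(NPQ) = 1 —
all absorbed energy dissipated — estimates the non-quenchable residual
cross-section. `core_cross_section()` computes the pigment-based
counterpart a*·n_chl·M_chl/N_A (defaults 9.8 m² g⁻¹, 70 chl a, 893.5
g mol⁻¹ → 101.8 Å²) for comparison.

**Lifetimes.** `fit_decay()` fits decay histograms by iterative
reconvolution of up to three exponentials with the instrument response
function and reports amplitude- and intensity-weighted average
lifetimes.

## Worked example

```r
library(sigmaqe)

# fit one noisy synthetic single-turnover transient
fl <- flash_spec()                       # 80 us, 1 W/cm2, 450 nm
tr <- simulate_transient(1, 3, 500, 0, fl, noise_rel_sd = 0.01, seed = 2)
fit_transient(tr)
#> Single-turnover induction fit
#>   Fo = 1.007   Fm = 3.001   Fv/Fm = 0.6645
#>   sigmaPSII = 498.6 A^2   p = 0.000
#>   rmse = 0.0307   converged: TRUE (5 iter)

# full pipeline on the default 8-strain panel, both acclimations
cfg <- panel_config(c(default_panel("LL"), default_panel("HL")),
                    n_replicates = 3, noise_rel_sd = 0.02, seed = 1)
run_pipeline(cfg, reference_core_A2 = 112)
#> Pipeline run: 48 curves, 720 points (config 1fc1c0a8, sigmaqe 0.1.0)
#> qE / sigmaPSII report: 48 curves, 720 points (387 retained)
#> sigmaPSII ~ Y(NPQ) pooled linear regression
#>   sigma = 521.4 -397.5 * Y(NPQ)   (r2 = 0.974, n = 387)
#>   95% CI slope: [-404.0, -391.0]  intercept: [519.6, 523.3]
#>   extrapolated sigmaPSII at Y(NPQ)=1: 124.0 A^2 (95% CI [118.7, 129.2])
#>   pigment-based PSII core cross-section: 101.8 A^2
#>   published core reference value: 112.0 A^2
#>   delta (extrapolated - core): +22.2 A^2
```

Reading the output: the true transient cross-section was 500 Å² and the
fit returns 498.6 at 1% noise. In the panel run, 387 of 720 points
survive the qI/irradiance filters; the pooled regression starts at the
dark cross-section (intercept ≈ 521 Å², generative value 525) and falls
by ≈ 398 Å² per unit Y(NPQ). The extrapolated residual cross-section
(124 Å²; generative core 110 Å²) lands near the pigment-based core
value, the comparison at the heart of the analysis — the remaining gap
is the documented noise/qI bias of the long extrapolation (see the
methods vignette). `run_pipeline(cfg, out_dir = "out")` additionally
writes `curves.csv`, `params.csv`, `retention.csv` and `summary.json`.

User-supplied light curves in the same CSV dialect
(`strain,acclimation,replicate,step,E_umol_m2_s,F_prime,Fm_prime,
Fo_prime,sigma_A2,sigma_1s_A2`) go through `read_light_curves()` →
`compute_params()` → `qe_report()` identically.

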