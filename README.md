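# gatedfcs

Time-gated STED-FCS analysis of TCSPC photon streams, with a
physics-based simulator for verifying the whole chain.

## The problem

Fluorescence correlation spectroscopy (FCS) measures molecular mobility
— for example of labelled lipids in a supported bilayer or a cell
membrane — from the temporal autocorrelation of the fluorescence emitted
as single molecules cross a small observation spot. STED microscopy
shrinks that spot below the diffraction limit with a doughnut-shaped
depletion beam, giving access to diffusion on sub-100 nm scales.

On turnkey commercial systems the depletion laser typically runs in
continuous-wave (CW) mode while the excitation is pulsed. Depletion is
then incomplete immediately after each excitation pulse, so the spot
periphery still emits — with a shortened fluorescence lifetime — and the
effective spot acquires a non-Gaussian pedestal. Fitting standard FCS
models to such data produces an artefactual anomaly exponent below one
and hides the true resolution. Because the pedestal photons are exactly
the short-lifetime photons, *time gating* — keeping only photons whose
TCSPC delay after the excitation pulse falls in a window
`[t_start, t_end)` — removes the pedestal, restores Gaussian-spot
behaviour, and lets one measurement be re-analysed at many gate delays
to produce a whole family of observation-spot sizes.

`gatedfcs` is for people who have (or simulate) time-tagged photon data
and want that analysis: photon-stream I/O and gating, photon-mode
multi-tau correlation, FCS model fitting, brightness and spot-size
calibration, gate scans, and a Brownian-dynamics/photophysics simulator
that generates photon streams with known ground truth.

## The model

Correlation curves are fitted with the one-component 2D
anomalous-diffusion model with a single dark state,

    G(t_c) = G(0) * 1/(1 + (t_c/tau_D)^alpha) * (1 - T + T exp(-t_c/tau_T))

(amplitude G(0) in the fluctuation convention, transit time tau_D,
anomaly factor alpha, triplet fraction T, triplet time tau_T), over a
1 µs – 200 ms window by default. Molecular brightness is
`cpm = G(0) * <F>`; free-diffusion fits are screened by the strict
quality window `0.8 < alpha < 1.2`. Spot sizes follow from transit-time
ratios against a confocal reference,

    FWHM(P) = FWHM(0) * sqrt(tau_D(P) / tau_D(0)),

with the confocal FWHM a user-supplied instrument calibration
(default 240 nm). See the vignette `vignettes/gated-sted-fcs.Rmd` for
estimator conventions, simulator physics and numerical choices.

## Worked example

Simulate a confocal reference and a CW-STED measurement, gate, fit, and
convert the transit time into an effective spot size:

```r
library(gatedfcs)

cfg_conf <- simulation_config(duration_s = 4, zeta = 0, seed = 101)
conf <- simulate_photon_stream(cfg_conf)
conf
#> <photon_stream> 563272 photons over 4 s (141 kHz), rep rate 80 MHz
#>   label: sim seed=101 zeta=0

fit_conf <- fit_fcs(correlate(conf), fixed = c(T_trip = TRUE, tau_T = TRUE))
fit_conf
#> <fcs_fit_result> G0=1.298, tau_D=0.001854 s, alpha=0.961 (T=0.000 fixed, tau_T=5e-06 s fixed)
#>   cpm=182.7 kHz, chi2_red=0.000238, qc_pass=TRUE

cfg_sted <- simulation_config(duration_s = 4, zeta = 20, seed = 102)
sted <- simulate_photon_stream(cfg_sted)
gate <- gate_window(2.4, 6.4)            # ns after the excitation pulse
fit_gated <- fit_fcs(correlate(apply_gate(sted, gate)),
                     fixed = c(T_trip = TRUE, tau_T = TRUE))
fit_gated
#> <fcs_fit_result> G0=37.03, tau_D=7.292e-05 s, alpha=0.986 (T=0.000 fixed, tau_T=5e-06 s fixed)
#>   cpm=68.51 kHz, chi2_red=5.17, qc_pass=TRUE

fwhm_from_transit(fit_gated$params$tau_D, fit_conf$params$tau_D, fwhm0 = 240)
#> [1] 47.6                                  # nm
effective_spot_profile(cfg_sted, gate)$fwhm_nm
#> [1] 43.9                                  # simulator ground truth, nm
```

Reading of the numbers: the confocal transit (1.85 ms, alpha close to 1,
amplitude ~1.3 for ~0.7 molecules in the spot) matches free diffusion at
5 µm²/s through a 240 nm spot; gating the depleted measurement shortens
the transit 25-fold, i.e. a ~48 nm effective spot, within 10% of the
analytic ground-truth profile; the fitted anomaly stays near 1 because
gating restored a near-Gaussian spot. The same stream fitted *without*
the gate yields alpha ~ 0.85, the pedestal artefact.

For scans over many gates use `multi_gate_analysis()` /
`gate_scan_report()` with the graded template `default_gate_scan()`. A
command-line front end is installed at
`system.file("scripts", "gatedfcs", package = "gatedfcs")` with
`simulate`, `analyze`, `gatescan` and `fixtures` subcommands.

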