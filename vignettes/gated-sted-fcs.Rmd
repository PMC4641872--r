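---
title: "Gated STED-FCS from photon streams: models, estimators and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated STED-FCS from photon streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedfcs)
```

## The measurement this package models

Fluorescence correlation spectroscopy (FCS) infers molecular mobility from
the temporal autocorrelation of the fluorescence collected from a small
observation spot: labelled molecules diffusing in and out of the spot
produce intensity fluctuations whose correlation decays on the transit
timescale. On a STED microscope the observation spot can be shrunk well
below the diffraction limit by a doughnut-shaped depletion beam.

With a *continuous-wave* (CW) depletion laser and pulsed excitation,
depletion in the spot periphery is incomplete immediately after each
excitation pulse: peripheral molecules fluoresce with a reduced but
nonzero lifetime, producing a pedestal around the depleted spot. The
effective spot is then far from Gaussian, and FCS fits report an
artefactual anomaly (stretching exponent below one). Because the pedestal
photons are precisely the *short-lifetime* photons, discarding photons by
their TCSPC microtime — keeping only a window `[t_start, t_end)` after
the excitation pulse — removes the pedestal, restores a near-Gaussian
spot and, as a bonus, tunes the spot size: later gate delays keep photons
from ever-closer to the doughnut zero, i.e. smaller spots. One
measurement therefore contains a whole family of observation spots.

The package implements that analysis chain for time-tagged photon data
(macrotime + microtime per photon) and pairs it with a
Brownian-dynamics/photophysics simulator detailed below, so every claim
the analysis makes can be checked against known ground truth without a
microscope.

## The FCS model and its estimation

Correlation curves are fitted with the one-component two-dimensional
diffusion model with a single dark state and an anomaly exponent,

$$G(t_c) = G(0)\,\frac{1}{1+(t_c/\tau_D)^{\alpha}}
  \bigl[1 - T + T e^{-t_c/\tau_T}\bigr],$$

with amplitude $G(0)$ (fluctuation convention, $G\to 0$ for uncorrelated
signal), transit time $\tau_D$, anomaly factor $\alpha$, triplet fraction
$T$ and triplet time $\tau_T$. Two conventions deserve emphasis:

* the triplet bracket is used exactly as written, *without* the common
  $1/(1-T)$ prefactor; users converting $G(0)$ into a molecule number
  must divide by $(1-T)$ themselves;
* $\alpha$ multiplies as $(t_c/\tau_D)^\alpha$, so $\alpha = 1$ is free
  diffusion through a Gaussian spot and $\alpha < 1$ the slow-tailed
  decay produced by a pedestal-distorted spot.

Molecular brightness is `cpm = G(0) * <F>` with `<F>` the mean detected
count rate. Note that with the amplitude taken at $t_c \to 0$ (triplet
included) cpm estimates the bright-state brightness; taking the
diffusion-part amplitude (fit with `T_trip` fixed at 0 beyond the triplet
regime) estimates the time-averaged brightness, which is the quantity
that saturates when dark-state dwell grows with excitation power.

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on the curve restricted to a fit window, by
default 1 µs – 200 ms. Bounds: $G_0 \ge 0$, $\tau_D \in [1\,\mu s, 10\,s]$,
$\alpha \in [0.3, 3]$, $T \in [0, 0.99]$, $\tau_T \in [0.1\,\mu s, 1\,ms]$;
cost tolerance $10^{-12}$, at most 5000 evaluations. Initialisation is
derivative-free: $G_0$ from the mean of the first decade of lags in the
window, $\tau_D$ from the first lag below half of that, $\alpha = 1$.
The returned parameters are never worse (in the fitted objective) than
the starting point; non-convergence and degenerate inputs (an all-zero
curve, where $\tau_D$ is unidentifiable) are flagged, never silent.
Residuals are unweighted unless the curve carries segment errors
(`segment_errors()`), in which case `1/G_err` weights are used; the
two-stage gated-STED protocol fixes $T$ and $\tau_T$ at confocal-fitted
values so the STED-stage fit has exactly three free parameters.

Fits of free-lipid calibration data are screened by the strict anomaly
window $0.8 < \alpha < 1.2$ (`qc_filter()`).

## The photon correlator

`correlate()` estimates $G$ directly from photon arrival times on a
multi-tau style quasi-logarithmic grid (16 points per octave by default,
from one macrotime tick — the excitation period — to a tenth of the trace
length). At coarsening $u = 2^\ell$ the photon times are binned to
$\lfloor t/u \rfloor$ and, for a coarse lag $k$,

$$G(k) = \frac{P_k\,(M-k)}{N_L(k)\,N_R(k)} - 1,$$

where $P_k$ counts ordered photon pairs at coarse lag $k$, $M$ is the
coarse trace length and $N_L, N_R$ count photons in the left/right
normalization windows $[0, M-k)$ and $[k, M)$. This symmetric (finite
trace) normalization makes a homogeneous Poisson stream average to
$G = 0$ at every lag and a strictly periodic photon train give exactly
zero. Lags whose normalization windows are empty are undefined and
reported `NA`. Exactly the same estimator is implemented twice: the
multi-tau path (coarsen–merge–two-pointer counting) and
`brute_force_correlate()`, a naive $O(N^2)$ double loop used as the
independent oracle; the test suite requires agreement to $10^{-9}$.

Curve uncertainties come from `segment_errors()`: the trace is cut into
equal segments, each correlated independently, and the per-lag standard
error across segments is attached to the mean curve — the standard FCS
practice for fit weights.

## Spot-size calibration

For free 2D diffusion $\tau_D$ scales with spot area, so the effective
spot diameter follows from transit-time ratios against a confocal
reference,
$\mathrm{FWHM}(P) = \mathrm{FWHM}(0)\sqrt{\tau_D(P)/\tau_D(0)}$.
The confocal FWHM is a user-supplied instrument calibration; the package
default of 240 nm (488 nm excitation, NA 1.4) is a *configurable
assumption*, prominently so, because it scales every derived spot size.
Uncertainties propagate to first order (delta method) from replicate
spread. `aggregate_power_series()` summarises replicate fits across
excitation- or depletion-power series, optionally normalising transit
times to the lowest power.

`select_gate()` encodes the practical gate-choice rule: the gate end sits
where the decay histogram first falls to the background level (later
photons only add noise); the gate start is the largest delay that still
retains a configurable fraction of the photons (default 10%). The
retained-photon fraction is a deliberate, stated proxy for FCS
signal-to-noise; a full FCS noise model is out of scope.
`default_gate_scan()` provides the graded seven-gate template
(1.12–1.36 … 4.8–7.2 ns) whose windows widen with delay to compensate the
decaying intensity.

## The simulator

`simulate_photon_stream()` generates TCSPC photon streams from explicit
physics:

* 2D Brownian motion of `n_molecules` point emitters in a periodic square
  box (minimum-image distances), positions updated every `timestep_s`
  (default 2 µs = 160 pulses at 80 MHz) and frozen between updates;
* pulsed excitation at `rep_rate_hz` with per-pulse excitation
  probability $p(r) = p_0 e^{-2r^2/w_{exc}^2}$;
* a CW depletion doughnut $d(r) = (2e\,r^2/w_d^2)e^{-2r^2/w_d^2}$ (exact
  zero on axis, unit peak at $w_d/\sqrt2$) adding a stimulated decay
  channel, $k_{tot}(r) = k_{fl}(1 + \zeta d(r))$, with the saturation
  $\zeta$ proportional to depletion power — the mW-to-$\zeta$ map is
  instrument-specific, so $\zeta$ is exposed directly;
* microtimes drawn from $\mathrm{Exp}(k_{tot}(r))$, optionally jittered
  by a Gaussian IRF, and wrapped into the excitation period; a photon is
  detected only if the decay was spontaneous (probability
  $k_{fl}/k_{tot}$) and survives the detection efficiency;
* triplet crossing per excitation blocking further excitation for an
  exponential dark dwell; per-excitation photobleaching with the bleached
  molecule replaced at a uniformly random position (a reservoir keeping
  concentration stationary — this damps, but does not remove, the
  bleaching bias, exactly as intended);
* homogeneous Poisson background with uniform microtimes.

The defaults describe a supported-lipid-bilayer calibration measurement:
$D = 5\ \mu m^2/s$ (a fluid DOPC-like bilayer), 240 nm confocal FWHM
($w_{exc} = 204$ nm), fluorescence lifetime 3.5 ns, 80 MHz repetition,
10 s acquisitions, and a labelling density of 5.6 molecules/µm² (200
molecules in a 6 µm box). The depletion doughnut scale (300 nm) is an
analytic choice — the true profile depends on the phase plate and
alignment of a given instrument — and any smooth zero-centred annulus
would serve; with the default scale, $\zeta = 20$ places the gated
working point near 45 nm, in the range the technique is used for.

`effective_spot_profile()` is the independent ground truth: the radial
detection profile
$\eta(r) = p(r)\,\frac{k_{fl}}{k_{tot}}\,
\frac{e^{-k_{tot}t_1}-e^{-k_{tot}t_2}}{1-e^{-k_{tot}P}}$
with FWHM located by bisection. The last factor is the *wrapped*
gate-acceptance probability (the simulator wraps microtimes modulo the
excitation period $P$, so the profile uses the same convention; the
correction is at most a few percent at a 3.5 ns lifetime and 12.5 ns
period). Without depletion the decay rate is position-independent and
gating provably cannot change the spot shape — a property the tests
assert. `microtime_density()` provides the matching quadrature oracle
for the microtime mixture distribution.

### Numerical and design choices

* **Box size.** The box holds a *fixed* number of molecules, so
  occupancy of the spot is slightly anti-correlated at long lags: the
  correlation tail carries a closed-ensemble offset of about
  $-G_0\,\pi w^2/L^2$. An early 3 µm box made this offset comparable to
  the model tail across the 200 ms fit window and biased fitted
  $\alpha$ upward by almost 0.1; the 6 µm default keeps the offset an
  order of magnitude below the tail over the full window. When changing
  `box_um`, keep $\pi w^2 t_{max} / (L^2 \tau_D) \ll 1$.
* **Timestep.** Positions are frozen for 2 µs (160 pulses); the
  validator enforces `timestep_s` at most 1% of the expected confocal
  transit. For deeply-depleted spots the transit can approach 100 µs;
  the residual discretisation affects only the first one or two grid
  points inside the fit window and was not measurable in the anomaly
  checks.
* **Reproducibility and coupling.** All randomness derives from one
  integer seed via splitmix64-seeded xoshiro256++ streams, one
  diffusion/photophysics/bleach triple *per molecule* plus a background
  stream. Identical configs give identical streams. The per-molecule
  split also makes bleach-level comparisons paired: the first uniform of
  a molecule's bleach stream drives a geometric excitations-to-bleach
  counter, so a higher bleach probability bleaches the same molecule
  strictly earlier while all unbleached lifelines reproduce the
  bleach-free trace photon for photon. The photobleaching-bias tests
  rely on this variance reduction; without it the 1e-6-per-excitation
  level is far below desk-scale noise.
* **Far-field stride.** Molecules far outside the excitation cutoff
  (where the chance of any excitation in a step is below $10^{-9}$) take
  one aggregated Gaussian step covering $K$ substeps — identical in law —
  with $K$ capped so that a 6$\sigma$ excursion cannot reach the active
  zone unnoticed. This is a pure speed optimisation (~7x) with no
  statistical consequence.
* **Photon-pair conventions.** Macrotimes live on an integer tick grid
  (one tick = excitation period) so all pair counting is exact integer
  arithmetic; gates are half-open `[start, end)` so disjoint gates
  partition the photons exactly.

### What the simulator does and does not emulate

It reproduces the features the gating method exploits: the
position-dependent lifetime structure under CW depletion, the ungated
pedestal, triplet blinking, power-dependent photobleaching bias,
brightness saturation, and uncorrelated background. It deliberately
omits: axial (3D) structure and z-diffusion, vesicles/domains/binding,
detector afterpulsing and dead time, scattered-laser breakthrough during
the excitation pulse, and photon antibunching. Passing tests therefore
validate the *analysis chain* under the stated physics; they do not
certify performance on real data with detector artefacts, and gated
curves from one stream share photons and are statistically dependent —
the package documents rather than corrects this.

## Scales used by the shipped checks

The automated checks run the full chain at desk scale, chosen so each
completes in minutes on one core: 10 s traces; ~50 molecules for the
confocal anomaly series (five seeds) and the default density elsewhere;
depletion saturations 5/20/50 with the 2.4–6.4 ns gate and the
seven-gate scan; a photobleaching screen at high excitation
(`exc_prob_peak = 0.4`, attenuated detection) with six paired seeds per
bleach level; correlator-oracle cross-checks on streams up to $10^4$
photons. The anomaly recovery acceptance band (mean $\alpha = 1.00 \pm
0.10$) reflects the per-trace scatter of $\alpha$ at these photon
budgets, about 0.07 r.m.s.

## Known limitations

* `cpm` inherits the amplitude convention of the printed model; see
  above for the $(1-T)$ caveat.
* The confocal FWHM is an input, not something the package can measure;
  all absolute spot sizes scale with it.
* `brute_force_correlate()` is quadratic and guarded to $10^5$ photons.
* Segment errors at lags approaching the segment length are noisy;
  the default segment scheme stops at a tenth of the segment.
* The mW-to-$\zeta$ calibration is instrument-specific and out of scope;
  results are reported against $\zeta$.
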