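---
title: "Methods: microbubble dynamics, acoustics and dose-response analysis in sonosim"
author: "sonosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbubble dynamics, acoustics and dose-response analysis in sonosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonosim)
```

# Scope

`sonosim` implements the desk-scale computational chain of a comparative
sonoporation study of clinical ultrasound contrast agents (SonoVue,
Sonazoid, Optison): acoustic pulse synthesis and output metrics, a
shell-model Rayleigh–Plesset simulation swept over bubble size and weighted
by measured size distributions, constant-rate infusion pharmacokinetics,
optical particle-sizing analytics, attenuation and cavitation spectral
analysis with four-parameter logistic (4PL) threshold fitting, and a
"best agent" dose–response map. Because raw laboratory data for such
studies are rarely deposited, the package ships seeded synthetic-data
generators that emulate the statistical structure each analysis stage
assumes; every generator's ground truth is recoverable by the matching
analysis stage, which is what the test suite verifies.

# The bubble model

An encapsulated microbubble of equilibrium radius $R_0$ in a liquid of
density $\rho$ obeys a modified Rayleigh–Plesset equation

$$\ddot R = \frac{1}{\rho R}\Big[-\tfrac{3}{2}\rho\dot R^2
  + p_g\Big(\frac{R_0}{R}\Big)^{3\gamma} + p_v - p_0 - \frac{2\sigma}{R}
  - 2\chi\Big(\frac{1}{R_0}-\frac{1}{R}\Big)
  - \delta_t\,\omega\,\rho R\dot R - p_{ac}(t)\Big],$$

with gas pressure $p_g$, vapour pressure $p_v$, ambient pressure $p_0$,
interfacial tension $\sigma$, shell stiffness $\chi$, polytropic exponent
$3\gamma$, total damping coefficient $\delta_t$, driving angular frequency
$\omega$ and acoustic pressure $p_{ac}(t)$ (compression positive).

Design choices a user should know about:

* **Ambient-pressure closure.** Shell-model RP variants circulating in the
  applied literature sometimes omit the $-p_0$ term, which leaves the
  equation without a physical rest state. `sonosim` includes $-p_0$ and
  closes the gas pressure by the equilibrium condition
  $p_g = p_0 + 2\sigma/R_0 - p_v$, so that `pac = 0` makes $R(t) = R_0$ an
  exact fixed point (verified to $|R-R_0|/R_0 < 10^{-6}$ over 20 µs in the
  tests for all three shipped agents).
* **Damping.** $\delta_t = 4\mu/(\rho\omega R_0^2) + \omega R_0/c$
  (viscous plus acoustic re-radiation). Thermal losses and shell friction
  are deliberately *not* modelled; see *Limitations*.
* **Single $\omega$.** The damping term uses one scalar
  $\omega = 2\pi f_c$ of the driving pulse, even for broadband pulses.
* **Linearized resonance.** Linearizing the implemented right-hand side
  about $R_0$ gives the undamped natural frequency
  $f_0 = \frac{1}{2\pi}\sqrt{(3\gamma p_g - 2\sigma/R_0 + 2\chi/R_0)/(\rho R_0^2)}$;
  note that the shell term $-2\chi(1/R_0-1/R)$ contributes $2\chi/R_0$ to
  the stiffness (a factor 2 smaller than the $4\chi/R_0$ of models whose
  shell term derives from an effective surface tension). `natural_frequency()`
  is the oracle for the low-amplitude resonance test: at 1 kPa drive the
  simulated response peak must sit within 5% of $f_0$.
* **Solver.** `deSolve::lsodar` with a compiled right-hand side, relative
  tolerance $10^{-8}$, absolute tolerance $10^{-12}$ m, automatic
  stiff/non-stiff switching, and the driving pulse linearly interpolated
  as a forcing function. Output is sampled at ≥ 32 points per carrier
  period. A root function halts the integration if $R < R_0/100$; such
  trajectories are flagged `collapsed` and masked in sweeps, never
  reported as converged metrics.

## Agent parameters

The shipped `inst/extdata/agents.json` holds the literature shell
constants used throughout:

| agent | gas | $\chi$ (N/m) | $\gamma$ | $\sigma$ (N/m) |
|---|---|---|---|---|
| SonoVue | SF6 | 0.22 | 1.0934 | 0.052 |
| Sonazoid | C4F10 | 0.53 | 1.0699 | 0.042 |
| Optison | C3F8 | 4.00 | 1.0731 | 0.90 |

The surrounding fluid defaults to mouse blood at 37 °C:
$\rho = 1057$ kg/m³, $\mu = 5.996$ mPa·s, and — not stated anywhere in the
source literature, therefore declared package assumptions, all
overridable — $c = 1570$ m/s, $p_0 = 101{,}325$ Pa, $p_v = 6267$ Pa (water
vapour pressure at 37 °C). The tabulated gas compressibility $\kappa$ is
stored for reference but enters no equation; its intended role in the
source model is unclear and is not guessed.

## Sweeps and distribution weighting

`sweep_radii()` runs the model on a regular $R_0$ grid (default
0.35–10 µm in 50 nm steps, 194 points) and records the oscillation
amplitude — the diameter excursion $D_{max} - D_{min}$, absolute and as a
percentage of the equilibrium diameter $2R_0$ — and the peak radiated
pressures at a 7 µm observation distance (a capillary-wall distance;
$p(r,t) = \rho(R^2\ddot R + 2R\dot R^2)/r$ with $\ddot R$ from the model
right-hand side, so the $1/r$ law is exact). For bubbles whose
instantaneous radius reaches the observation point the radiated-pressure
entries are masked rather than extrapolated.

`weight_sweep()` multiplies a sweep metric (as a function of diameter
$d = 2R_0$) by the count- or volume-occupancy-normalized size
distribution of an agent and sums over histogram bins; because the
weights sum to 1, a constant unit metric has area-under-curve 1 under
either normalization. If more than 1% of the distribution mass falls
outside the sweep's diameter coverage the call fails, naming the amount.

# Acoustic output metrics

`tone_burst()` synthesizes sine bursts with a Tukey ($\alpha = 0.25$ by
default) or rectangular envelope; the Tukey taper limits spectral
splatter while holding the stated peak negative pressure over the flat
three quarters of the burst. `pulse_metrics()` implements the standard
conventions: $MI = PNP[\text{MPa}]/\sqrt{f_c[\text{MHz}]}$,
$I_{SPPA} = \frac{1}{T}\int p^2/(\rho c)\,dt$ and
$I_{SPTA} = I_{SPPA}\cdot\text{duty}\cdot 1000$. The duty cycle defaults
to `duration * prf`, but published setting tables sometimes print duty
values that do not follow from cycles × PRF; `pulse_metrics()` therefore
accepts the duty cycle directly as an input, which is how the package
reproduces tabulated plate-sonicator intensities (3 mW/cm² at MI 0.10 /
0.4% duty; 10 W/cm² pulse-average at MI 0.39 with the plane-wave
$\hat p^2/2\rho c$ using water constants $\rho = 1000$, $c = 1480$).

# Infusion pharmacokinetics

A one-compartment constant-rate infusion:
$C(t) = (k_0/CL)(1 - e^{-k_e t})\,C_{bub}$ with $k_e = \ln 2/t_{1/2}$ and
$CL = k_e V_d$. Defaults describe a mouse protocol: $k_0 = 20$ µL/min,
$V_d = 2.5$ mL. "Steady state" is defined as 99.8% of the plateau
(≈ 9 half-lives), a threshold chosen because it is the fraction at which
a 30 s half-life infusion plateaus at 4.5 min, the behaviour reported
for such protocols; the fraction is an explicit argument. A helper
converts oscillating-pump settings through the 1 mL-syringe flow
multiplier 0.058 (0.4 mL/min → 23 µL/min, nearest integer).

# Particle sizing

`summarize_population()` reproduces the optical-sizing pipeline:
equivalent diameter $2\sqrt{A/\pi}$, roundness = equivalent/maximum
diameter capped at 1, a 0.7 µm minimum-diameter cutoff (the optical
resolution limit), left-closed 0.1 µm histogram bins labelled by centers,
both count and $d^3$ (volume) weighting, percentiles by linear
interpolation of the weighted empirical CDF (no estimator is standard in
the application literature, so the simplest interpolating one is used),
the $d_{90}/d_{10}$ polydispersity index, pooled mean ± SEM, and
concentration = surviving count / imaging volume × dilution (imaging
volume default $6.2\times10^{-6}$ mL). `stability_compare()` reports
percentage changes between fresh and aged summaries plus a Welch t-test
on the diameters; `area_matched_concentration()` rescales a concentration
by the ratio of count-weighted mean squared diameters so that agents
present equal cross-sectional area.

# Spectra and cavitation thresholds

Replicate waveforms are reduced to one-sided rectangular-window
periodograms and averaged in linear power (no taper is applied because
none is standard for this measurement; the choice is module-local and
easy to change). The attenuation spectrum is the dB power deficit of the
bubble measurement relative to the bubble-free baseline divided by the
acoustic path, default 8 cm (twice a 4 cm sample chamber). The bulk
resonance frequency is the in-band attenuation maximum, ties resolving to
the lowest frequency.

Cavitation metrics are background-subtracted: the subharmonic magnitude
is the *peak* (robust to band-edge leakage, versus a band mean) of the dB
difference in 400–600 kHz; the spectral integral is the trapezoidal
integral of the *linear* power difference over 0.2–10 MHz — integrating
dB values is not physically meaningful — reported as
$10\log_{10}(1 + I/I_{ref})$ with $I_{ref}$ the background power in the
same band, so identical spectra sit at a 0 dB floor.

`fit_4pl()` fits $Y = d + (a-d)/(1+(x/c)^b)$ by Levenberg–Marquardt
least squares. The statement that plateaus are "set to equal values"
across datasets is read as a *joint* fit with shared $a, d$ (the reading
$a = d$ would make the curve constant); both readings are available via
`share_plateaus`. The inflection $c$ is the cavitation threshold; its
95% CI comes from the parameter covariance
$\hat\sigma^2(J^\top J)^{-1}$ and is labelled as such (not a
between-repeat CI). Regime boundaries (stable / transitional / inertial)
are the closed-form MIs where the sigmoid completes 5% and 95% of its
transition, $x_q = c\,(q/(1-q))^{1/b}$, which satisfy
$x_{0.05}x_{0.95} = c^2$.

# Dose-response mapping

Calcein response tables are reduced to replicate means per measured
(intensity, concentration) point and interpolated by separable natural
cubic splines — intensity on a linear scale, concentration on log10
(measured concentrations span more than a decade). The interpolant passes
through the knots exactly, is clipped to [0, 100]%, and refuses to
extrapolate. `best_agent_map()` takes the per-cell argmax across agents
and reports the winning margin; exact ties are listed jointly rather than
broken by agent order, because observed differences between the weaker
agents are often not statistically significant.

# Synthetic data: what it emulates and what it does not

* `gen_population()`: lognormal diameters parameterized by median and
  $d_{90}/d_{10}$ (ln-scale sigma $= \ln(\text{psd})/(2 \times 1.2816)$),
  areas back-computed as $\pi d^2/4$, maximum diameter from a
  Beta(45, 3) roundness draw (mean ≈ 0.94, the optically observed range).
  The lognormal family was chosen because it is strictly positive and
  closed under this parameterization; real populations are at best
  approximately lognormal.
* `gen_waveform_set()`: a deterministic broadband Gaussian click
  (default 4 MHz center, 2.5 MHz spectral sigma, 512 samples at 50 MHz —
  a gated ~10 µs pulse-echo window) filtered in the frequency domain so
  the power deficit equals profile × path; per-bin, per-replicate
  Gaussian noise in dB. Real echoes add reverberation, jitter and
  transducer coloration that this generator does not model.
* `gen_mi_response()`: 4PL curve plus Gaussian dB noise per replicate.
* `gen_response_surface()`: Hill-type saturation
  $E_{max}C/(C + EC_{50}(I))$ with $EC_{50}(I) = ec_{50}e^{-gI}$
  decreasing in intensity, Gaussian noise in percentage points, clipped
  to [0, 100].

All generators save and restore the global RNG state, so identical
arguments give bit-identical output and the caller's stream is
undisturbed. Passing tests on these generators demonstrates that the
analysis stages are *correct inverses of their own data model*; it does
not demonstrate performance on laboratory data with un-modelled
artifacts.

# Numerical choices and problem sizes

The test suite runs the full 194-point sweep for all three agents once
(the compiled right-hand side makes one sweep a few seconds of work) and
uses coarser grids (0.5 µm steps), shorter bursts (5–8 µs) and moderate
population sizes (hundreds to $10^5$ particles) elsewhere; the 4PL CI
coverage check uses 200 seeded repeats of 3 replicates × 30 MI levels.
Grid convergence is asserted by halving the solver tolerance and
requiring the percent amplitude to move by less than 0.1 percentage
points on an identical output grid.

# Known limitations

* The damping closure (viscous + re-radiation) excludes thermal losses
  and shell friction. For lipid- and albumin-shelled agents at MHz
  frequencies those omitted channels are substantial, so simulated
  resonance amplitudes are *upper bounds*: a total damping several times
  larger — as shell-friction measurements for such agents suggest —
  scales the peak oscillation amplitude down by the same factor in the
  near-linear regime. Published amplitude figures for shelled agents
  produced with richer damping models are therefore systematically lower
  than this model's output at identical drive; within-model *orderings*
  across agents (which agent responds most, and at which size) are much
  more robust than absolute amplitudes, and the package's own comparative
  conclusions rely on the orderings.
* The model is spherically symmetric, ignores bubble–bubble and
  bubble–wall interaction, buckling/rupture shell regimes, and shock
  emission on collapse (collapse is guarded and flagged instead).
* Cavitation-threshold CIs are parameter-covariance CIs; with few MI
  levels and correlated residuals they can undercover.
* The best-agent map interpolates between a handful of measured
  conditions; cubic splines through 3–4 levels can over/undershoot
  between knots (values are clipped, margins near boundaries are small —
  inspect `margin` before interpreting a single-cell winner).
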