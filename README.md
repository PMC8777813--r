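# sonosim

Which ultrasound contrast agent is best for low-intensity sonoporation?
Answering that requires a chain of desk-scale computations that usually
live in one-off lab scripts: characterizing the acoustic pulses
(mechanical index, I_SPPA, I_SPTA), simulating how differently shelled
microbubbles respond to them, converting infusion settings into
circulating bubble concentrations, reducing optical sizing images to
distributions, extracting resonance frequencies and cavitation thresholds
from echo spectra, and mapping measured calcein dose–response surfaces to
a per-condition "best agent". `sonosim` packages that chain as tested,
reusable R functions, with seeded synthetic-data generators so the whole
pipeline runs and validates without laboratory data.

## The core model

An encapsulated microbubble of equilibrium radius R0 follows a modified
Rayleigh–Plesset equation

    R·R̈ = (1/ρ)[ −(3/2)ρṘ² + p_g(R0/R)^{3γ} + p_v − p_0 − 2σ/R
                  − 2χ(1/R0 − 1/R) − δ_t ω ρ R Ṙ − p_ac(t) ]

with shell stiffness χ, polytropic exponent 3γ, interfacial tension σ,
damping δ_t = 4μ/(ρωR0²) + ωR0/c, and the gas pressure closed by
p_g = p_0 + 2σ/R0 − p_v so the rest radius is an exact equilibrium.
Sweeping R0 (0.35–10 µm, 50 nm steps) under a synthesized treatment
burst, weighting the response by each agent's measured size distribution,
and integrating over diameter ranks the agents by expected mechanical
action on nearby cells. Cavitation thresholds are the inflection point c
of a four-parameter logistic fit Y = d + (a−d)/(1+(x/c)^b) to
MI–response sweeps, with plateaus shared across agents in a joint fit.

The three shipped agents use literature shell constants
(SonoVue χ = 0.22 N/m, Sonazoid χ = 0.53 N/m, Optison χ = 4.0 N/m, with
their gas-specific γ and σ) in mouse blood (ρ = 1057 kg/m³,
μ = 5.996 mPa·s). See `vignettes/sonosim-methods.Rmd` for every
assumption, default and limitation — in particular why the
viscous-plus-reradiation damping makes absolute oscillation amplitudes
upper bounds, while agent *orderings* are robust.

## Worked example

```r
library(sonosim)

## the clinical treatment burst: 1.8 MHz, 20 us, PNP 0.268 MPa
tp <- tone_burst(1.8e6, 20e-6, 0.268e6)
pulse_metrics(tp, duty_cycle = 0.011)
#> <pulse_metrics> PNP 0.268 MPa, MI 0.2, I_SPPA 2.046 W/cm^2,
#>                 I_SPTA 22.51 mW/cm^2 (duty 1.1%)

## infusion kinetics: a 30 s half-life reaches steady state in 4.5 min
m <- infusion_model(t_half_s = 30, cbub_ppml = 2.4e8)
round(time_to_fraction(m, 0.998) / 60, 1)
#> [1] 4.5

## sweep the bubble model over R0 and weight by a synthetic population
sw <- sweep_radii(default_agents()$SonoVue, mouse_blood(), tp)
sw
#> <radius_sweep> SonoVue: 194 R0 points (0.35-10 um),
#>                max osc 172% at R0 = 2.15 um, 0 masked
dist <- summarize_population(gen_population(1.7, 2.46, n = 20000, seed = 2))
weight_sweep(sw, dist, "count")
#> <weighted_summary> SonoVue, count-normalized osc_amp_pct: AUC = 64.46

## cavitation threshold from a noisy synthetic MI sweep (true c = 0.44)
mi <- seq(0.01, 1.2, length.out = 26)
resp <- gen_mi_response(0, -30, 8, 0.44, mi, noise_db = 1, n_reps = 3, seed = 3)
fit_4pl(resp)[[1]]
#> <logistic_fit_4pl> a = -0.08433, d = -30.06, b = 8.179,
#>                    c = 0.4434 (95% CI 0.4384-0.4484)
```

The pulse metrics are the regulatory quantities of the treatment setting
(MI 0.2 at 1.8 MHz); the sweep peak says which bubble size responds most
to that pulse and how strongly (percent of equilibrium diameter); the
weighted AUC folds that response over the sizes actually present in a
vial; and the 4PL fit recovers the generator's cavitation threshold
within its confidence interval. `run_paper_pipeline()` chains pulse →
sweeps → weighting → pharmacokinetics for all three agents and writes a
ranked report plus its resolved configuration, so any run is reproducible
from its own outputs.

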