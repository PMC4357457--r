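---
title: "Rate effects in simulated atrial fibrillation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate effects in simulated atrial fibrillation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afsim)
```

## The question the package addresses

Rate control is the standard pharmacological strategy in permanent atrial
fibrillation (AF), yet there is no firm evidence for which resting heart rate
to target. `afsim` approaches the question in silico: a closed-loop
lumped-parameter (0D) model of the heart and circulation is driven by
stochastic AF-like RR intervals at mean rates of 50, 70, 90, 110 and
130 bpm, and the resulting left-heart hemodynamic and mechano-energetic
indices are compared across rates. Because only the ventricular rate changes
between arms, differences in the outputs are attributable to rate alone.

## The circulation model

The circulation is a network of compliances (C), resistances (R) and
inertances (L): four heart chambers, a systemic arterial and venous
compartment, and a pulmonary arterial and venous compartment. For every
chamber or compartment the model carries

* a **mass conservation** equation, `dV/dt = Q_in - Q_out`;
* an **equation of motion** on inertial branches,
  `L dQ/dt = P_up - P_down - R Q`;
* a **linear state equation** mapping volume to pressure,
  `P = E(t) (V - V_un)` for chambers and `P = (V - V_un)/C` for vessels.

Volumes are the primary states (pressures are derived), so the closed loop
conserves total blood volume *exactly* in the continuous equations; any
numerical drift is a solver diagnostic, and the integrator aborts if it
exceeds one part in 10^6.

**Chambers.** Each ventricle has a time-varying elastance
`E(t) = E_min + a(t) (E_max - E_min)` with a smooth raised-cosine activation
`a(t)` that rises from 0, peaks once, and returns to 0 at the end of
systole. Both atria are held **passive** (`E` constant): this is the model's
representation of AF, where the atrial kick is lost. Ventricular systole
lasts `T_sys = k_sys * rr^alpha_sys`. The default exponent
`alpha_sys = 0.40` is a calibration choice: a sublinear law is required so
that systole occupies a growing fraction of the beat at fast rates (the
classical rate-corrected QT behaviour), and 0.40 reproduced the observed
rate-dependence of the beat-averaged ventricular pressure better than the
square-root law, which remains available (`alpha_sys = 0.5`). Both
ventricles share the activation clock, which is reset at every RR onset.

**Valves.** The aortic, pulmonary and tricuspid valves are ideal
pressure-gated resistive diodes: `Q = max(P_up - P_down, 0)/R_open`, so
regurgitation is impossible and closure is a well-defined instant. The
**mitral valve** additionally carries blood inertance: its flow obeys a
momentum equation `L_mi dQ/dt = P_la - P_lv - R_mi Q` while open, and a
strong one-sided restoring term pins the flow state at zero once it has
decelerated through zero (the mass balance uses the flow clamped at zero, so
no backward volume ever moves). This one deviation from the pure-diode
design is forced by the physiology the model must reproduce: end-diastole is
*defined* as mitral closure, and measured end-diastolic ventricular
pressures exceed the atrial pressure at the same instant and *rise* with
heart rate. With a pure diode the mitral valve closes exactly at the
atrioventricular pressure crossover, which forces `P_lved = P_laed` and a
falling `P_lved`; with inertia, filling is truncated mid-deceleration at
fast rates, closure slips into early contraction, and the end-diastolic
pressure rises with rate, as observed.

**Events and definitions.** End-systole (es) is aortic-valve closure;
end-diastole (ed) is the mitral closure that begins the beat's systole.
Event times are located from the valve-state transitions on the dense output
grid and refined by interpolating the driving quantity (the decelerating
mitral flow, or the transvalvular pressure difference) between bracketing
samples. A beat whose aortic valve never opens is flagged non-ejecting,
excluded from ejection-defined statistics (SV, EF, SW, PE, PVA, CO,
efficiency) and counted; at cv = 0.24 and rates up to 130 bpm such beats are
rare to absent.

## The RR-interval generator

AF RR intervals are drawn from an exponentially modified Gaussian
(exGaussian): the sum of a Gaussian `N(mu_g, sigma_g^2)` and an independent
exponential with mean `tau`, giving the right-skewed histogram typical of
AF. The generator is parameterised by the target mean (60/HR) and the
coefficient of variation, fixed at the AF-typical cv = 0.24 across all
rates. Since mean and cv pin only two moments, the split of the variance
between the Gaussian and exponential components is free; `tau_fraction`
(default 0.5, an equal split) exposes it. The skewness at the default split
is `2 tau^3 / (sigma_g^2 + tau^2)^(3/2) = 0.71`, and sensitivity to the
split is mild: it changes the shape of the tail, not the mean or cv that
drive the hemodynamic averages.

Draws below a physiological floor `rr_min` are redrawn from the same seeded
stream (rejection sampling preserves reproducibility). The default floor is
0.25 s, at the short end of atrioventricular-nodal functional refractoriness.
A floor of 0.3 s was considered and rejected: at 130 bpm it truncates ~5% of
the distribution's mass, biasing the sample mean by +2.3% and the cv to
0.219, which breaks the generator's own moment contract (mean within 2%, cv
within ±0.02); at 0.25 s the residual bias (+0.7% on the mean, -0.008 on cv)
is inside the contract at every rate. With cv = 0 the generator degenerates
to a strictly regular rhythm, used as the sinus-baseline calibration mode.

## Numerical integration

The stiff system (fast valve and arterial time scales against slow venous
filling) is integrated beat-by-beat with `deSolve::lsoda`, an adaptive
multistep solver of the `ode15s` class, with the right-hand side compiled in
C. Defaults: relative tolerance 1e-6, absolute tolerance 1e-8, 200 dense
output samples per beat. Each beat is integrated on its own clock from 0 to
its RR value; the final state seeds the next beat. The first 20 beats are a
warm-up that flushes the synthetic initial condition and is excluded from
every statistic (a regular rhythm settles to a periodic steady state with
beat-to-beat stroke-volume changes below 0.1% within this warm-up; this was
verified against 300- and 1000-beat runs). Halving both tolerances changes
long-run mean stroke volume by well under 0.5%.

## Per-beat indices and aggregation

From each analyzed beat the package derives the tabulated indices: es/ed and
extremal pressures and volumes, beat means (time averages over the full
cycle), and

* `SV = V_lved - V_lves`, `EF = SV/V_lved * 100`;
* `SW` = area of the left-ventricular pressure-volume loop (absolute
  shoelace area of the sampled loop, 1 mmHg mL = 1.33322e-4 J);
* `PE = P_lves (V_lves - V_un)/2 - P_lved (V_lved - V_un)/4` with
  `V_un = 5 mL`, the elastic potential energy stored at end-systole;
* `PVA = PE + SW` (oxygen-consumption surrogate) and efficiency
  `SW/PVA * 100`;
* `CO = SV * HR`, `RPP = P_sas,syst * HR`, `TTI = P_lv,mean * RR` with
  `TTI/min = TTI * HR`, `PVA/min = PVA * HR`.

All "per-minute" indices use the beat's **instantaneous** rate 60/RR and are
averaged per beat afterwards. This convention matters under an irregular
rhythm: by Jensen's inequality `mean(60/RR) > 60/mean(RR)`, so per-beat rate
weighting makes mean CO and RPP exceed the product of the means — exactly
the gap visible in the reference results, which the nominal-rate convention
cannot produce. Aggregation is the arithmetic mean and sample SD over
analyzed beats; EF is the mean of per-beat ratios, not the ratio of means.

## The heart-rate sweep

`run_sweep()` runs the full experiment: for each rate it spawns a
deterministic per-rate seed from the master seed, samples 5000 + 20 RR
intervals, simulates, summarizes and aggregates, then assembles the index
table (29 parameters × rates) with each row's maximum percent variation
against the 50 bpm reference column and a relevance flag at |variation| >
15%. Results are independent of execution order; identical configurations
give bit-identical tables. `render_outputs()` writes the table, per-beat
CSVs, a reproducibility manifest (seeds, solver options, full parameter
set), and four figures (RR densities; ventricular and systemic pressure
versus rate with representative time series; the seven mechano-energetic
indices versus rate). `stationarity_check()` splits a beat series into
halves and flags indices whose half-means differ by more than 3 standard
errors; 5000 beats pass comfortably.

## Parameter provenance and calibration

No parameter table is published for the reference experiment, so the package
ships its own closed-loop set (also in
`inst/extdata/default_params.yaml`). It was calibrated in two stages, in
this order: first the regular-rhythm baseline at 70 bpm was brought into
textbook-normal ranges (EF 55-70%, systolic systemic pressure
100-130 mmHg, mean atrial/pulmonary pressures near 10 mmHg); then the main
levers were set against the published AF means at 50 and 130 bpm — total
stressed volume for the overall pressure level, diastolic ventricular
stiffness and mitral/tricuspid resistances for how strongly filling is
rate-limited, maximal elastance for end-systolic volume, and the
systolic-duration law for the pressure-time integrals. The default set
reproduces the headline values at both ends of the sweep to within a few
percent; absolute values should still be read as model outputs, not
patient predictions.

## What the synthetic data do and do not show

The RR generator emulates the marginal distribution of AF beat intervals
(right-skewed, cv 0.24) but deliberately ignores serial correlation,
atrioventricular-node memory, autonomic modulation and circadian structure.
The analytic fixtures (`make_analytic_beat`, `make_summary_stream`) exist to
pin arithmetic — loop areas, event recovery, aggregation — with exactly
known answers; they are not physiological. Passing tests therefore
demonstrate correctness of the computational pipeline and consistency with
the reference experiment's summary statistics, not validity for any
individual patient. The model also omits, by design, the autonomic nervous
system, coronary circulation, respiratory coupling, valve disease and drug
effects; it simulates a denervated heart whose only between-arm difference
is the RR-interval stream.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at reduced sizes chosen to keep a
complete run within a development iteration: 40-140-beat runs for unit
properties, one 5000-beat run for conservation, a 500-beats-per-rate sweep
for the directionality of all fourteen rate-dependent indices, and two
5000-beat arms (50 and 130 bpm) for the quantitative comparison. The
acceptance script reruns those two arms end-to-end at 5000 beats from a
user-supplied seed.
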