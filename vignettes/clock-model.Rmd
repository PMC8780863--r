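---
title: "A delayed-feedback model of the Neurospora clock under short light-dark cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A delayed-feedback model of the Neurospora clock under short light-dark cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frqclock)
```

## The biological question

The Neurospora crassa circadian clock is a transcription-translation
feedback loop: the White Collar Complex (WCC) activates transcription of
*frq*, FRQ protein accumulates with a lag (translation, progressive
phosphorylation, nuclear translocation) and represses WCC activity, closing
a delayed negative loop with a free-running period near 22 h in constant
darkness. WC-1 is also the blue-light photoreceptor: light converts WCC to
an activated state that drives a strong burst of *frq* transcription, and
the photoreceptor VVD, itself light-induced, feeds back on that activation
(photoadaptation). `frqclock` asks what this architecture does under
symmetric light-dark cycles far shorter than a day — LD12:12 down to
LD30min:30min — where the observed behavior is striking: FRQ expression
follows the external cycle down to roughly LD3:3, but at LD2:2 and below it
escapes the forcing and reverts to a ~22 h free run decorated with small
saw-tooth responses to each light pulse.

## The model

Six state variables: cytosolic *frq* mRNA `M_frq`, nuclear FRQ `F`, *wc-1*
mRNA `M_wc1`, phosphorylated dark-state nuclear WCC `W_dark`, light-activated
WCC `W_light`, and VVD `V`. With `L(t)` the light level in [0, 1] and
`H(F) = K_I^h / (K_I^h + F^h)` the FRQ repression gate,

```
M_frq' = (v_dark W_dark + v_light W_light) H(F) - d_M M_frq
F'     = k_s M_frq(t - tau) - d_F F
M_wc1' = v_w + k_fw F - d_Mw M_wc1
W_dark'= k_w M_wc1 - A(t) + k_rel W_light - d_Wd W_dark
W_light'= A(t) - k_rel W_light - d_Wl W_light
V'     = k_v W_light - d_V V
```

with the VVD-gated activation flux `A(t) = k_act L(t) W_dark / (1 + V/K_V)`.
The lag `tau` lumps translation, multi-site phosphorylation and nuclear
import of FRQ into a single delay of several hours (constrained to 2-8 h),
and is the oscillation-enabling element: at the shortest admissible lag the
dark rhythm collapses or shortens far below 22 h (see the delay-necessity
test). Repression is realized as a Hill gate on *frq* transcription — the
simplest closure of "FRQ represses WCC function" — rather than as an
explicit WCC-inactivation flux; the gate multiplies the dark *and* the
light drive, which is what lets the endogenous loop keep running underneath
strong forcing. A modest FRQ→*wc-1* support term (`k_fw`) reflects the
known positive limb; `k_fw = 0` is a supported configuration. Knockout
flags zero the corresponding synthesis terms (`frq_null → k_s`,
`wc_null → k_w`, `vvd_null → k_v`); the frq7/frq2 period mutants are
mapped to FRQ stability (`d_F` scaled by 0.7 and 1.4), which lengthens and
shortens the free-running period respectively.

Two open structural choices were settled as follows. Nuclear and cytosolic
*frq* mRNA pools are lumped, with export absorbed into `tau`; nothing in
the quantified behaviors distinguishes the pools at this resolution. VVD
inhibition is divisive (`1/(1 + V/K_V)`), the standard competitive form; a
subtractive form changes none of the qualitative conclusions but can go
negative and needs clipping, so the divisive form was preferred.

Units: hours throughout; concentrations are arbitrary units. Light
intensity is normalized linearly so that 5000 lux ≡ 1.0 and 1000 lux ≡ 0.2,
the only two intensities that matter experimentally. Only the blue-light
channel (via WCC) is modeled; red-light inputs do not entrain clock
mutants and are left out.

## Why the entrainment boundary exists

The forcing is multiplicative (light scales transcription through the same
repression gate), so raw drive strength alone cannot quench the endogenous
loop; the boundary arises from frequency-dependent filters in the light
input path. In the calibrated set the light drive dominates
(`v_light/v_dark` ≈ 11) but is rationed by the dark WCC pool: `W_dark`
turns over slowly (`d_Wd` ≈ 0.03/h) and is consumed by light activation
(`k_act` ≈ 3.5/h per unit light) far faster than it is replenished
(`k_w M_wc1`). Each lights-on therefore delivers a *frq* induction spike
that scales with the `W_dark` rebuilt during the preceding dark phase —
large and loop-resetting when dark phases are hours long, a dwindling
ration at very short cycles. This is also what makes the per-cycle mRNA
induction amplitude decrease monotonically as cycles shorten. Downstream,
`F` integrates delayed `M_frq` with time constant `1/d_F`, attenuating the
driven ripple by `d_F / sqrt(w^2 + d_F^2)` at forcing frequency
`w = 2*pi/T`; at LD2:2 the residual 4 h ripple in FRQ is too small to
dominate the waveform, the endogenous relaxation cycle survives the
weakened mean drive, and peak detection sees the circadian envelope — a
free run with saw-tooth superimposition. The same filter is why the
protein/mRNA smoothness ratio falls below 1 at short cycles.

Calibration drove the VVD arm to near-inactivity (`k_v` small, `d_V`
fast): in this realization photoadaptation is carried by depletion of the
slowly-replenished WCC pool rather than by VVD inhibition. The VVD state
and its divisive gate remain in the equations — strengthening `k_v`/`K_V`
re-engages them — but the committed optimum does not rely on them, and the
`vvd` knockout accordingly leaves the committed model's behavior
essentially unchanged.

## Rhythm quantification

All analyses consume plain (`time`, `value`) series, so simulated
trajectories and sparse noisy densitometry go through the same code path.

* **Peaks**: local maxima with topographic prominence of at least a fraction
  (default 0.1) of the series range; plateaus resolve to their first sample
  (ties toward earlier time), endpoints are excluded, and peak times are
  refined by a parabolic fit through the three surrounding samples, which
  matters for 3-hourly densitometry.
* **Period**: mean ± SD of successive peak-to-peak intervals, with a
  spectral cross-check (mean-removed Schuster periodogram over 0.5-48 h at
  0.02 h resolution; series thinned to ≤ 1200 points, far above the Nyquist
  needs of these smooth signals).
* **Phase angle**: per forcing cycle, the offset from lights-on to the
  tallest peak (or trough/mid-range onset) inside that cycle; its SD is
  computed circularly so boundary-wrapping jitter is not inflated. A
  fourth reference, `"fundamental"`, takes the peak time of the cycle's
  least-squares sinusoid at frequency 1/T; on 3-hourly noisy densitometry
  it is far more stable than the raw argmax (sub-sample phase noise instead
  of whole-sample flips), and it is what the classifier uses.
* **Classification**: *entrained* iff (i) the fundamental-based
  peak-to-peak period matches the cycle length T within 5%, (ii) the
  phase-angle SD is at most `max(0.5 h, 0.1 T)`, and (iii) the power at
  1/T is at least the strongest circadian-band (16-32 h, excluding T's own
  5% neighborhood) power, so a small phase-locked saw-tooth riding on a
  dominant free run cannot pass as entrainment; otherwise *free_running*
  if the periodogram has a dominant peak in 16-32 h with at least 3x the
  median power; otherwise *arrhythmic*. The thresholds are declared here
  because the source observations are categorical; the entrainment
  definition deliberately counts driven (masked/hourglass) rhythms as
  entrained, which is the operational usage for these data. A flat
  post-transient series (range below 1e-6 of its level, e.g. a silenced
  knockout) is arrhythmic by construction.
* **Transients**: the first 96 h or 5 forcing cycles, whichever is longer,
  are discarded before any quantification.

A note on the boundary case: the LD3:3 condition is described both as the
last cycling condition ("still exhibits a 6 h oscillation") and as the
first free-running one in different parts of the source material. The
report therefore carries both the forcing-band power ratio and the
free-running-band content, so either reading can be checked against the
same object; the committed calibration follows the figure-level description
(entrained at 3 h, free-running at 2 h half-period).

## Calibration

The model's rate constants are not printed anywhere; they are fixed by a
seeded stochastic search (`calibrate_parameters()`: log-space global draws
plus greedy local refinement) against the printed behavioral constraints:

* C1: dark free-running period 22 h (quadratic loss; the one quantitative
  anchor);
* C2: entrained at half-periods 12, 8, 6, 4 and 3 h (hard penalty);
* C3: free-running at half-period 2 h with dominant period within 22 ± 2 h
  and nonzero forcing-band (saw-tooth) power (hard penalty);
* C4: mRNA light-response amplitude strictly decreasing over half-periods
  12, 6, 3, 1 h;
* C5: protein/mRNA smoothness ratio < 1 at half-periods ≤ 3 h.

Near the entrainment boundary the forced system can spend hundreds of
hours in quasi-periodic transients, and at LD6:6 it can settle into a
period-doubled (24 h-alternating) forced orbit that a short simulation
window misses entirely. Calibration therefore scores each forced condition
twice — once on the standard post-transient window and once on a late
(≥ 400 h) window that has reached the attractor — and adds penalties on
subharmonic (2T) spectral content, so the committed set is entrained in
the asymptotic sense, not merely during a long transient.

Calibration is a one-time developer step; its output is committed as plain
JSON and returned by `default_parameters()`. `constraint_residuals()`
re-evaluates all five constraints on the committed set, and the test suite
keeps that provenance check green. During search, integration runs at a
coarse step and a reduced cycle count; all committed results are verified
at the default resolution below.

## Numerical choices

* **Integrator**: fixed-step classical RK4 by the method of steps, with the
  delayed `M_frq(t - tau)` read from the stored grid by cubic Lagrange
  interpolation, and a constant pre-zero history (default 0.1 a.u. in every
  component). Light forcing is piecewise constant and discontinuous, so the
  step is refined to divide every phase duration exactly (durations are
  resolved to whole seconds): every transition lands on a grid point, each
  RK4 stage sees a constant light level, and no discontinuity error arises.
  A default `dt = 0.01` h resolves the fastest protocol (LD30min:30min)
  with 50 steps per phase; `dt ≤ tau/20` is enforced so the delayed lookup
  stays well inside the known history.
* **Positivity**: RK4 can undershoot zero by O(dt^5) near sharp troughs;
  components are clipped to 0, and the Hill gate additionally guards its
  base. Non-finite states abort with the time of blow-up.
* **Problem sizes**: analysis simulations use 20 post-transient cycles per
  forced condition (with a `max(96 h, 5 T)` transient) and 600 h for
  constant darkness — enough for a dozen free-running cycles after the
  transient while keeping a full T-cycle scan around a minute of CPU.

## Synthetic data

The generators supply every fixture the analyses need, each seeded and
restoring the caller's RNG state.

* `gen_densitometry()` samples a simulated component (default FRQ) at a few-
  hour interval, applies multiplicative log-normal noise — blot intensities
  are positive and their errors scale with signal — and rescales to a
  maximum of 1, as densitometry panels are normalized. The default window
  is 48 h (two LD12:12 cycles) at 3 h sampling; the sampling interval of
  the source panels is not printed, so 3 h is an assumption, adjustable by
  argument. Classifier robustness checks sample the converged forced state
  (a 240 h settle before the sampled window) so that slow entrainment
  transients are not conflated with unstable phase.
* `gen_race_tube()` lays growth-front marks every 24 h at a constant speed
  and places conidiation band centers at integer multiples of the banding
  period through the inverse growth map, both with seeded positional
  jitter. Band timing is driven directly by the forcing period — an
  hourglass read-out — because conidiation banding under LD cycles does not
  require a functional core oscillator; coupling the bands to the FRQ model
  would contradict that observation. "Band position" means band center.
* `gen_morphometry()` draws a two-population aspect-ratio mixture:
  microconidia nearly round (ratio uniform in [1.0, 1.4], width log-normal
  around 2.5 µm) and macroconidia elongated (ratio log-uniform in
  [2.0, 5.0], width around 5 µm). The classified proportion is unbiased for
  the mixture weight.
* `gen_condition_panel()` builds a multi-condition experiment: replicate
  race tubes with a flat growth-speed dependence on cycle length, and a
  microconidium fraction rising with half-period to a maximum at 12 h
  (defaults 0.08 to 0.32), mirroring the reported pattern that LD12:12
  maximizes microconidia while growth shows no systematic cycle-length
  trend. With 300 conidia per condition the per-condition sampling SD
  (~0.025) is small against that 0.24 range, so the Pearson test detects
  the effect with power well above 0.9 at six conditions, while the flat
  model stays non-significant at the nominal rate.

What the generators deliberately do not emulate: band calling from
photographs, gel backgrounds and saturation, unequal mark intervals from
irregular marking, or any coupling of banding to the molecular model.
Passing round-trip tests therefore shows that the analysis code inverts the
stated statistical structure, not that it would survive raw-image
artifacts.

## Phenotype conventions

Growth marks are taken at exact 24 h intervals from inoculation; marking
clock error is absorbed into the generator's jitter. Growth "rate" is
mm/day (marks are daily; ratios and normalized values are unaffected by
the unit). The microconidium criterion is strict: aspect ratio < 1.5, so a
conidium at exactly 1.5 is a macroconidium. Condition-level association
uses Pearson correlation on (cycle length, value) — the source does not
name its statistic, and a rank-based alternative is available via
`method = "spearman"` — and group comparisons use the two-sided Student's
t test (equal variances) with the conventional star labels.

## A worked pass

```{r, eval = FALSE}
params <- default_parameters()
sc <- scan_T(params, c(12, 8, 6, 4, 3, 2))
sc[, c("half_period", "classification", "period", "phase_sd")]
find_boundary(sc)$boundary

dd <- simulate_clock(params, ld_constant(0), 600)
estimate_period(trajectory_series(dd, "F"), discard = 96)
```

## Known limitations

* The realization is one concrete closure of the five stated modeling
  assumptions; the original equation set is not public, so agreement is
  behavioral (periods, classifications, orderings), not parameter-level.
* Entrainment here includes masking by construction; the package does not
  attempt to separate true limit-cycle locking from driven responses, and
  whether the LD3:3 lock is 1:1 or higher-order is left to the recorded
  period ratio.
* No stochastic (molecular-noise) version, no temperature input, no
  conidiation output model, and no second oscillator (the CRY-dependent
  system) — no equations exist for these at this resolution.
* The race-tube generator's hourglass banding is an idealization; real
  tubes show band broadening and merging at very short cycles ("too
  compact to resolve"), which is exactly why the analysis refuses series
  with fewer than two resolvable bands rather than guessing.
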