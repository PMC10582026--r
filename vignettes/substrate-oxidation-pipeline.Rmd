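---
title: "From breath averages to trial statistics: the oxitrain methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From breath averages to trial statistics: the oxitrain methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxitrain)
```

oxitrain analyses treadmill-based weight-management interventions in
adolescents with obesity that are measured by indirect calorimetry: a
ventilated-canopy basal metabolic rate (BMR), a graded walking test that
yields peak oxygen uptake and the fat-oxidation/intensity curve, training
sessions prescribed from that test and equated in energy, and the trial's
group-by-time statistics. This vignette explains the models, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the underlying
conventions leave room.

## Substrate oxidation stoichiometry

Breath-averaged V'O2 and V'CO2 (L min^-1, STPD) are converted to
oxidation rates (g min^-1) by the classic non-protein stoichiometry with
a protein term:

$$\mathrm{fat} = 1.67\,\dot V O_2 - 1.67\,\dot V CO_2 - 0.307\,P_{ox}$$
$$\mathrm{cho} = 4.55\,\dot V CO_2 - 3.21\,\dot V O_2 - 0.459\,P_{ox}$$

with the protein oxidation rate estimated from the convention that
protein supplies about 12% of energy expenditure,
$P_{ox} = EE \times 0.12 / 16.74\ \mathrm{kJ\,g^{-1}}$. Printed versions
of this estimate sometimes carry a typographic minus in place of the
division; a subtraction of 16.74 from a quantity of order 0.5 kJ min^-1
would produce large negative oxidation rates, so `oxitrain` implements
the division and says so in the documentation of
`protein_oxidation_rate()`.

Two conventions around $P_{ox}$ coexist and the package supports both
explicitly:

* **Graded tests** use the *resting* $P_{ox}$, derived from the
  subject's measured BMR (`resting EE` in kJ min^-1 times 0.12/16.74,
  about 0.04 g min^-1 in these cohorts). The coefficients on $P_{ox}$
  are small, so this choice barely moves the fat and carbohydrate
  curves.
* **Submaximal sessions** default to a *self-consistent* $P_{ox}$ in
  which protein supplies 12% of each 5-minute window's own energy
  expenditure. Because the substrate-sum energy rate is linear in
  $P_{ox}$, the fixed point has a closed form
  (`oxitrain:::pox_self_consistent`). This convention — not the resting
  one — is the only one compatible with published session
  energy-partition tables in this population, where protein energy is
  12–13% of a ~1.4 MJ session (≈10 g of protein over ~40 min; a resting
  $P_{ox}$ would predict ≈2 g). An explicit `pox` argument overrides the
  default everywhere.

Raw rates are signed; an RER above 1 makes the raw fat rate negative,
which the package reads as "fat oxidation negligible", so all reported
tables clip at zero while keeping the signed diagnostics (`fat_raw`,
`fat_clipped`).

Energy partitioning multiplies clipped rates by fixed energy densities
(carbohydrate and protein 16.7 kJ g^-1, fat 37.7 kJ g^-1); the total is
the exact sum of the three terms by construction. Resting energy
expenditure uses the Weir equation without protein correction,
$EE = 4.184(3.941\,\dot VO_2 + 1.106\,\dot VCO_2)$ kJ min^-1 — the
standard choice for canopy calorimetry, isolated in
`resting_ee_weir()` so a laboratory using a different equation can swap
one function.

## Graded-test analysis

The default protocol (`default_grad_protocol()`) is 10 min of standing
rest followed by seven 5-min walking stages (0.6 m s^-1 flat up to
1.4 m s^-1 at 12% grade), terminated when heart rate reaches ~180 bpm to
avoid maximal effort in this population. Analysis decisions:

* **V'O2peak** is the mean of the samples in the last 20 s of the
  recording (4 samples at 5-s breath averaging). The window is half-open
  on the left and includes the final sample, which makes the value
  bit-reproducible; a mean rather than a median is used.
* **Stage measurements** average the final 60 s of each *completed*
  stage (half-open windows, so a sample never lands in two stages);
  incomplete stages are excluded, with a warning when data inside a
  reached stage are too sparse.
* **MFO/Fatmax** default to the per-stage maximum of the clipped fat
  rate (`stage_max`), matching per-workload determination; ties break
  toward the lower intensity. A cubic least-squares option (`poly3`)
  maximises the fitted polynomial analytically on the observed intensity
  range for smooth-curve work. The stage grid spaces intensities about
  10.8 percentage points apart, so a stage-max estimate is accurate only
  to that resolution, and under measurement noise the max-selection is
  biased slightly high (about +0.01–0.02 g min^-1 at the default 4% gas
  CV); both effects are visible in the recovery tests and bounded there
  a priori by the grid step.
* **Crossover**: fat oxidation counts as negligible below a threshold
  of 0.05 g min^-1 (configurable; the literature reports the resulting
  intensity, not the threshold). The crossing is linearly interpolated
  on the clipped curve above Fatmax; if never crossed, the highest
  observed intensity is returned flagged.
* Intensity is always expressed relative to the *same* test's V'O2peak,
  so pre- and post-intervention curves are each normalised to their own
  peak.

## Energy-equated prescription

Both session types target the same budget of 20 kJ per kg fat-free mass
(`session_energy_target()`, ≈1.3–1.4 MJ in these cohorts). Predicted
energy uses a fixed gross oxygen energy equivalent of 20.9 kJ per L O2;
the equivalent is an argument (`kj_per_l_o2`) so an RER-dependent value
can be substituted. The combined session is 5 min at 50% V'O2peak, three
2-min bouts at 95% separated by 1-min 50% recoveries, plus a continuous
60% block whose duration is solved in closed form against the budget
(infeasible budgets raise an error rather than a negative duration). The
continuous-only session is one block at 40% V'O2peak by default — in
these cohorts essentially the Fatmax intensity, which is the other
published reading of that prescription; the `intensity` argument leaves
the choice to the user. Heart-rate targets come from linear
interpolation of the test's per-stage (intensity, HR) pairs, linearly
extrapolated to 100% from the top two stages and clamped to
[resting HR, HRpeak].

Only the 95% bouts count as HIIT time in `hiit_fraction`; warm-up and
recoveries are low-intensity volume. At the group design points the
share lands between 0.10 and 0.20 (≈0.15 at the COMB baseline means),
consistent with a polarized ~80/20 design; individual draws scatter a
couple of percentage points around it. Note a bookkeeping subtlety in
the published description of such sessions: the fixed structure plus
"~30 min" continuous block sums to ~43 min, while mean session length is
reported as ~36 min; the solver reproduces the structure and budget and
leaves that discrepancy alone.

## Session analysis

Recorded sessions are analysed in consecutive half-open 5-min windows;
the trailing partial window is kept with its true duration (dropping it
would bias totals low). Totals integrate window rates over window
minutes, and the print method rounds grams and kJ to integers as such
tables are conventionally reported, while the object keeps full
precision so the exactness invariants (total = sum of parts, grams ×
density = energy) hold. Training load uses an HR cut of 85% HRmax to
classify high-intensity time, so recorded and planned sessions are
analysable alike; shares sum to 100 exactly.

## Trial statistics

The design is two groups by two timepoints with repeated measures on
time. `mixed_anova_2x2()` computes the classical sums of squares in
closed form from per-subject means and half-differences (see the source
header for the algebra); this is algebraically identical to the
sequential `aov()` decomposition — the test suite checks agreement to
1e-8 against both `aov()` and an independent normal-equations oracle —
but runs in O(N), which makes the 1000-replicate type-I calibration
cheap. With two within-subject levels the Greenhouse–Geisser epsilon is
identically 1; `gg_epsilon()` is nevertheless implemented generically
(orthonormal-contrast form) so designs with more timepoints can reuse
it.

The Bonferroni post-hoc family is the four cell contrasts actually
reported in such trials — within-group W0 vs W3 (paired) for each group
and between-group at each timepoint (pooled two-sample) — hence a
multiplier of 4; the family is a documented decision, since procedure
descriptions rarely state it. Effect sizes are Hedges' g: pooled-SD
standardized differences of the pre-post changes, corrected by
$1 - 3/(4\,df - 1)$, labelled small below 0.20 and large at or above
0.50.

## The synthetic generator

Every stage is testable without raw recordings because the generator
emulates the three instruments:

* **Canopy BMR**: 45 one-minute samples whose steady state inverts the
  Weir equation exactly to the subject's BMR at RER 0.85, plus a
  quadratic adaptation transient (+25% at the start, exactly zero from
  8 min) so the 5–10-min discard rule is genuinely exercised: a 10-min
  discard recovers BMR to machine precision on noiseless data, a 0-min
  discard is biased high.
* **Graded test**: 5-s samples; stage steady states climb linearly from
  35% to 100% of the subject's true V'O2peak; mono-exponential onset
  kinetics (τ = 40 s) at transitions; HR linear in instantaneous V'O2
  between resting and peak HR, with truncation at the 180-bpm stop
  criterion. The subject's fat-oxidation truth is a beta-shaped unimodal
  curve parameterised by exactly the three published landmarks (Fatmax,
  MFO, crossover intensity) — the family is chosen for positivity and
  single-peakedness, since only the landmarks are published — and V'CO2
  is back-computed by numerically inverting the stoichiometric
  equations, so the analysis pipeline is tested against a known truth.
* **Sessions**: segment-wise steady gas exchange at the planned
  intensities with the same onset kinetics. Segment V'O2/V'CO2 are
  solved so the substrate-sum energy rate equals the plan's predicted
  segment rate (the trial equated sessions by design); the fat rate
  still follows the subject's truth curve at the segment intensity.
  With the calibrated presets, session substrate grams land within the
  published 2-SD bands without any further tuning.
* **Cohorts**: W0 draws from the group presets plus per-subject pre-post
  changes; published change SDs are used where available, otherwise the
  change SD is derived from the marginal SDs under a within-subject
  correlation of 0.8 (exposed as `rho` because ANOVA power depends on
  it). Anthropometrics are independent normals truncated to
  physiological bounds (no BM–FFM covariance beyond FFM ≤ 0.95 BM) —
  a documented simplification.

Noise defaults: 4% multiplicative CV per gas sample, 3 bpm HR noise,
both independent across samples. Real metabolic carts show correlated
and autocorrelated breath noise, drift, and BIA-derived FFM error, none
of which are modelled; passing recovery tests therefore demonstrates the
*pipeline's* correctness and calibration under plausible noise, not
instrument-level realism.

Simulation sizes in the test suite (200 replicates for the graded-test
and BMR recovery checks, 1000 null replicates at 1000 subjects per group
for ANOVA calibration, 400 per group for cohort-mean checks) were chosen
to keep Monte-Carlo error well below the tolerances being asserted while
the whole suite runs in well under a minute on one core.

## Degenerate inputs and numerical choices

Duplicated timestamps and non-monotone time are data errors naming the
offending timestamp; malformed rows are dropped and counted aloud.
All-zero fat curves make Fatmax undefined (flagged, not invented).
Zero pooled SD flags the effect size as undefined. The cubic MFO fit
finds its maximum from the derivative's roots rather than a numeric
optimiser, so a parabola's vertex is recovered to 1e-6. The
gas-exchange/substrate map is inverted with `solve()` on the 2×2
coefficient matrix, never a hand-derived inverse, and round-trips to
1e-10. Window joints are half-open everywhere, which is what makes
"sum of window energies = one-pass energy" exact.

## Known limitations

* Bioimpedance FFM and BMI-for-age standardisation are injection
  points, not implementations: the population-specific coefficients live
  in external references, so the package accepts measured FFM and a
  user-supplied regression (`ffm_from_bia()`).
* No ventilatory-threshold detection, ramp protocols, or plateau-based
  V'O2max criteria — the stop-at-180-bpm submaximal-peak design is
  assumed.
* No EPOC/recovery modelling, accelerometry, or dietary simulation;
  the generator's pre-post changes are drawn, not mechanistically
  produced by the three weeks they represent.
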