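---
title: "Methods: reconstructing radium dial worker doses from historical measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing radium dial worker doses from historical measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrecon)
```

## The problem

An early radium dial painter ingested ²²⁶Ra over a few working years,
dominantly by lip-pointing the brush. What survives is a sparse record:
a handful of in vivo measurements taken decades later, each reporting
either an external whole-body count or a paired radon-breath plus external
count, in μCi. The reconstruction task has four stages, each a module of
this package: measurement correction, forward biokinetic modelling, intake
estimation, and dosimetry. A synthetic-worker generator closes the loop by
producing cases with known ground truth.

## Measurement correction

²²²Rn, the first progeny of ²²⁶Ra, is a noble gas: a fraction *E* of the
radon born in the body diffuses out and is exhaled before decaying (the
*emanating* fraction), and only the complement *R* = 1 − *E* (the
*retained* fraction) supports the ²¹⁴Pb/²¹⁴Bi gamma emissions that external
counters detect. Hence:

* external-only record: burden = measured / *R*, with *R* assumed
  (historically 0.31 for this case series);
* paired record: burden = breath-equivalent + external, assumption-free.

Reported μCi burdens are rounded half-away-from-zero to 3 decimals to match
the presentation of the historical tables; the Bq values (1 μCi =
3.7 × 10⁴ Bq exactly) are kept unrounded. Three of the six external-only
rows of the bundled historical table are *not* the printed measured/0.31
arithmetic (e.g. 0.650/0.31 = 2.097 vs a printed 2.100); the package
reproduces the arithmetic, documents the discrepancy, and makes no attempt
to guess an undocumented correction. Records carrying quality flags (such
as the 1974 note questioning a breath measurement) are parsed normally —
exclusion is an analysis-stage decision, not a parsing-stage one.

## Decay chain

The ²²⁶Ra → ²⁰⁶Pb series is shipped as an editable ten-row table
(half-lives, decay modes, dominant gamma lines, historical "Radium A–G"
aliases), keeping physics constants out of code. The chain is linear;
branches below 1% are ignored. Time-dependent activities use the Bateman
closed form for a linear chain; near-degenerate decay constants (within
10⁻¹² relative) are separated by a 10⁻⁹ relative perturbation before
evaluation, which sidesteps the formula's singularities at a cost far below
the test tolerances. The closed form is cross-checked against an adaptive
ODE integration oracle in the test suite.

## Biokinetic model

The compartment structure is: alimentary contents → blood → {soft tissue,
bone surface} with bone surface ⇄ bone volume exchange, urinary/faecal
excretion from blood and gut, and first-order radon escape from every
compartment to an exhaled-air sink. The emanating fraction is therefore an
*output* (exhaled atoms per radon atom produced), not an assumption; under
the default parameters it evaluates to ~0.5 during and after exposure,
inside the historically reported 0.37–0.75 range.

Key parameter choices (all in the editable YAML file, units 1/d):

* fA = 0.3 at age 15 and 0.2 for adults, entering as an fA-weighted split
  of the alimentary outflow so the absorbed fraction is exactly fA.
* Blood→bone-surface transfer higher at 15 y (9.0) than for the adult
  (6.0), urinary excretion lower (7.0 vs 12.0): adolescents deposit more
  of their systemic radium in the skeleton.
* Slow bone pools: surface→blood 0.003, surface→volume 0.0015 (15 y) /
  0.0005 (adult), volume→blood 2 × 10⁻⁴ (15 y) / 8 × 10⁻⁵ (adult, i.e.
  ~3%/y turnover). These values make the skeletal pools integrate the
  intake over the working years — so dose rates rise to a maximum at the
  lip-pointing cutoff — and give a measured-era body-burden decline
  comparable to the historical series. They are illustrative, documented
  as such, and not a transcription of any reference compendium; the loader
  accepts a user-transcribed reference set with the same schema.

Age dependence is linear interpolation of every coefficient (and fA)
between the 15-y and 25-y reference sets, held constant over sub-intervals
of at most 30 days of age; from 25 y the adult set applies unchanged. The
form of the interpolation is a package choice (the underlying reference
models tabulate discrete ages); linear-with-monthly-steps is the simplest
reproducible option and is configurable through `max_step_d`.

### Solver

Within each sub-interval the system is linear time-invariant, so it is
propagated *exactly* by the matrix exponential of the augmented affine
system (states plus a constant-inflow column). Discretisation error enters
only through the age stepping; the test suite checks the propagation
against adaptive fine-step integration at 10⁻⁶ relative and grid-halving
stability of lifetime doses at 0.1%. Chain members with half-lives under
one hour (²¹⁸Po, ²¹⁴Pb, ²¹⁴Bi, ²¹⁴Po) are reported in secular equilibrium
with in-compartment ²²²Rn rather than propagated — exact on the solver's
timescale and avoids placing a 4 × 10⁸/d rate inside the exponential.
²¹⁰Pb, ²¹⁰Bi and ²¹⁰Po are propagated but decay in place by default
(`independent_kinetics`); a `shared_kinetics` mode assigning all progeny
the radium coefficients is available for sensitivity comparison. ²²⁶Ra
physical decay (1600 y) is retained for uniformity even though it is
negligible over a lifetime.

The internal clock is days since birth, because parameters are age-indexed;
all input/output uses calendar dates with exact calendar arithmetic — a
series spanning 1923–1976 leaves no room for 360-day-year shortcuts.

## Intake schedule and estimation

The two-period schedule places a constant base rate from work start to the
lip-pointing cutoff and 1/100 of it from the cutoff to work end. The exact
cutoff date within 1926/27 is not historically fixed; the default is
1927-01-01 and it is a configuration field. Degenerate configurations are
defined, not rejected: cutoff at or after work end gives a single-period
schedule, cutoff at or before work start a single reduced-rate period, and
a zero-length work period an empty schedule with zero intake.

Each measurement yields a scaling factor (measured burden / unit-model
burden at that date). Factors are averaged arithmetically — matching the
"mean and standard deviation of the factors" convention — with a log-space
(geometric) option off by default; the SD uses the n − 1 sample estimator
(n is small, 8 here; the convention is not dictated by the source
material). The uncertainty band is multiplicative: (mean ± SD) × unit
curve. Total ingestion is the exact calendar integral of the scaled
schedule, so the identity "total = ∫ schedule" holds to the last bit in
the emitted reports. A legacy single-measurement mode anchors to one
record (by default the most recent, selected by `"latest"` or a 1-based
index) with SD reported as NA, and a parameter-driven power-law retention
function supports comparison with historical assessments whose exact
coefficients are caller-supplied rather than hard-coded.

## Dosimetry

S-coefficients are assembled as Σ(energy × yield × absorbed fraction) /
target mass, converted to Gy/d per Bq. The shipped emission table carries
one charged-particle line per chain member (alpha energies, mean beta
energies); the absorbed-fraction table is deliberately small and labelled
illustrative: bone-surface and bone-volume sources irradiating endosteum
and red marrow, blood contributing to marrow, and soft-tissue
self-irradiation of brain, lung, heart wall and breast. Pairs absent from
the table contribute no dose *by explicit omission*; a direct S-coefficient
lookup for an absent pair raises an error rather than silently returning
zero, and a compartment carrying activity without a source mapping is
likewise an error. The absorbed fractions were chosen once so that, with
the default biokinetics, the documented qualitative structure holds:
skeletal targets dominate, every dose rate peaks at the intake cutoff, and
rates fall more than tenfold over the following 45 years. Absolute dose
values under these illustrative tables are order-of-magnitude only;
reproducing published per-organ doses would require transcribing reference
absorbed-fraction datasets, which is out of scope. Lifetime doses are
trapezoidal integrals on the solver grid up to the configured death date.
External radiotherapy appears only as report metadata. The legacy
comparison block reports a user-supplied historical bone dose alongside the
endosteal estimate with the caveat that the two refer to different targets.

## Synthetic workers

The generator emulates the historical study conditions: the default case
works 1923-08-01 to 1927-08-01 with cutoff 1927-01-01, base rate
10⁴ Bq/d, eight measurements uniformly placed in 1957–1975, external-only
counting before 1970 and paired counting after (the era split mirrors how
instrumentation evolved), a per-case emanating fraction uniform on
[0.37, 0.75], and multiplicative lognormal noise with geometric SD 1.2.
The noise model is a package choice — no measurement-error model survives
in the records — motivated by the positivity and scale-invariance of
counting measurements; GSD 1.2 represents "good but not modern" counting
practice and is configurable. External rows report retained × burden ×
noise; paired rows split the burden into emanating and retained portions
with independent noise per channel. Cohort members derive sub-seeds
deterministically from a master seed, and the unit forward model is solved
once per study condition and shared across replicates by linearity.

What passing tests show — and do not show. Recovery tests (noise-free
round trips exact to solver tolerance; median |relative error| of the
recovered rate below 5% at GSD 1.2 with 8 measurements over 200
replicates; errors tightening as schedules densify from 2 to 8) validate
the estimator under the generator's assumptions: correctly specified
retained fractions, lognormal noise, a correct forward model. Real
records add transcription ambiguity, unknown true emanating fractions
(the mis-specification test quantifies exactly this: assuming retained
0.31 when the truth is 0.69 inflates the recovered intake by 0.69/0.31,
a direct consequence of pipeline linearity), detector-geometry effects,
and biokinetic model error — none of which the synthetic cohort emulates.

## Numerical choices and problem sizes

* Bateman degeneracy threshold 10⁻¹² relative, perturbation 10⁻⁹.
* Secular-equilibrium cutoff: half-life < 1 h (configurable).
* Age/coefficient stepping ≤ 30 d; propagators cached per (step, rate,
  age) so the adult post-exposure era costs one matrix exponential.
* Solution grids in the shipped analyses span birth + work start (1923)
  to death (1976) at monthly resolution (~650 points, ~35 states); test
  cohorts use 200 replicates per condition. The full suite runs in well
  under a minute on one core.
* Ties in peak-finding resolve to the earliest grid point (`which.max`).
* Tiny negative values from the exponential (below 10⁻⁹ relative) are
  clamped to zero before validity checks.

## Limitations

* The bundled transfer coefficients and absorbed fractions are simplified
  defaults: structurally faithful, quantitatively illustrative.
* No radiation-damage-modified skeletal kinetics, no systemic radon
  transport model (radon escapes or decays in place), no sex-specific
  osteoporosis kinetics.
* The uncertainty treatment stops at the mean ± SD band of the scaling
  factors; no formal error propagation.
* Photon cross-fire between distant organs is only what the absorbed-
  fraction table encodes; the default table encodes none.
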