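---
title: "Analysing serial-transfer adaptation with evoadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing serial-transfer adaptation with evoadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoadapt)
library(dplyr)
```

## The measurement problem

High-throughput adaptive laboratory evolution (ALE) on solid media propagates
thousands of microbial colony populations through repeated batch cycles: a
colony expands from a bottleneck inoculum of roughly 5 × 10^4 cells to 2–4
million cells over ~3 days, is robotically subsampled, and re-deposited on a
fresh stressor plate. Each cycle therefore contributes log2(final/initial) ≈
5.3–6.3 population doublings, and a 19-cycle experiment accumulates on the
order of a hundred generations. Fitness is phenotyped continuously: each
colony's population size is scanned at 20-minute intervals, giving one growth
curve per colony per cycle.

evoadapt turns those raw curves into the quantities that matter for
evolutionary inference:

* **D** — the population doubling time (hours), from the steepest slope of
  log2 population size vs time (µ~max~, doublings/hour; D = 1/µ~max~);
* **G** — generations per cycle, log2 of the final/initial population sizes;
* **A~g~** — the adaptation milestone: hours of doubling-time reduction
  achieved by cumulative generation g, read from a LOESS fit of D against
  cumulative generations (defaults g = 25, 50, 75);
* the **fitness → adaptation regression** across strains, its outliers, and
  the **diminishing-return (global) epistasis** slope of reconstructed
  mutations across genetic backgrounds.

Because the real deposited datasets are large and instrument-specific, the
package ships a serial-transfer simulator that generates complete synthetic
experiments — lineage dynamics, plates, gradients, noisy curves — with known
ground truth, so every stage of the analysis is testable end to end.

## Growth-curve processing

The per-curve chain is `qc_curve()` → `remove_spikes()` →
`smooth_gaussian()` on log2 counts → `estimate_mu_max()`, with
`count_generations()` on the despiked (not Gaussian-smoothed) series:

```{r curves}
t <- seq(0, 72, by = 1 / 3)                      # 20-min cadence, 72 h
cells <- pmin(5e4 * 2^(pmax(0, t - 2) / 2.5), 3e6)  # lag 2 h, D = 2.5 h
ds <- remove_spikes(cells)$series
sm <- 2^smooth_gaussian(log2(ds), sigma = 1.5)
estimate_mu_max(t, sm)
count_generations(ds)
```

Numerical choices worth knowing:

* **All smoothing and regression happen on log2(cells)**, so exponential
  growth is a straight line and the window slope is directly doublings/hour.
* **µ~max~ windows.** Ordinary least squares over every run of 5 consecutive
  points; the maximum slope wins, earliest window on ties (ties are compared
  with a 1e-9 relative guard so floating-point jitter cannot reorder exact
  ties). A maximum slope ≤ 0 flags the curve `no_growth` and leaves D
  undefined rather than returning a negative doubling time.
* **Spike handling.** A plain rolling median applied to an exponential ramp
  does not return the original points around a spike: the median of a
  monotone window containing a spike is a *neighbouring* value, so the
  filter time-shifts a few samples by one step and the max-of-windows
  estimator reliably latches onto the artificial double-step it leaves
  behind, inflating µ~max~ far beyond any useful tolerance. The pipeline
  therefore uses
  the median filter for *detection* — points deviating from their windowed
  median by more than 0.5 doublings are spikes — and excises only those,
  log-linearly interpolating across the gap (`remove_spikes()`). Detection
  windows shift to full width at the series boundaries so a spike on the
  first or last sample is still seen against real neighbours. The plain
  rolling median (`despike_median()`, shrinking symmetric windows at the
  edges) remains available and is what the QC spike-fraction statistic is
  defined against.
* **Gaussian smoothing** uses a discrete kernel truncated at ±4σ,
  renormalized where it overhangs the boundary (σ default 1.5 samples). The
  renormalized edge kernel is asymmetric and biases the first/last few
  points of a ramp; the µ~max~ window essentially never sits there because
  edge slopes are flattened, not steepened.
* **QC thresholds** (≥10 points, ≥1 doubling of dynamic range, ≤20% spiked
  points, endpoints not decreasing by >0.2 doublings) are package choices —
  screening rules of this kind are internal to colony-phenomics platforms
  and not published; they are all exposed as arguments.

## Spatial plate normalization

Non-evolving wild-type reference colonies occupy the (even row, even col)
member of every 2×2 quartet — one reference per four positions. Their
doubling times sample the plate's environmental field. `fit_reference_surface()`
bilinearly interpolates log2 reference D over the reference grid (nearest
reference beyond the outermost reference rows/columns; failed references
imputed from their four nearest usable neighbours) and expresses the surface
as offsets from the plate-set reference median; `normalize_plate()` subtracts
the offsets in log2, i.e. divides out the local multiplicative distortion and
re-centres every plate on a common level. Corrections are multiplicative on D
because environmental effects on growth act multiplicatively.

Bilinear interpolation was chosen over 2-D LOESS smoothing for determinism
and because it is exact at the references: after normalization the reference
colonies sit exactly on the plate-set median, which is also what makes
normalization idempotent. The cost is that reference measurement noise passes
into the surface unsmoothed; with the reference density of these layouts
(one in four positions) that trade is acceptable, and the normalization
recovery tests quantify it.

## Adaptation trajectories and milestones

`assemble_trajectories()` places each cycle's normalized D at the cumulative
generations accumulated through that cycle. Generations of QC-failed cycles
still elapse — time passes even when the measurement is lost — but contribute
no point. Populations with fewer than 4 usable cycles are dropped and logged.

`fit_adaptation_loess()` fits a tricube-weighted local polynomial of D on
cumulative generations: `loess()`'s own default span of 0.75 is meant for
generic scatter, but adaptation curves saturate — a steep early decline
followed by a plateau — and local-*linear* fits at any usable span flatten
that curvature enough to miss milestone values by several hundredths of an
hour or more on noiseless saturating test functions. The defaults are
therefore **span 0.4, degree 2**,
with the symmetric (biweight) family and 2 robustness iterations, and the
exact `"direct"` loess surface so fits are deterministic and evaluable
anywhere. Short trajectories (< 7 points) drop to degree 1 and widen the
neighbourhood so each local fit keeps more points than parameters.

`extract_milestones()` reads the preadaptation doubling time as the fit
evaluated at generation 0 *clamped to the fit's support*: real trajectories
have their first point at the end of cycle 1 (~5–6 generations), and
extrapolating a local quadratic below its support systematically inflates
the boundary value and with it every milestone; clamping keeps the milestone
bias on simulated cohorts inside the 0.05 h bound the test suite asserts.
A~g~ is then fit(0) − fit(g), in hours of doubling-time reduction
(positive = adapted), and milestones beyond the trajectory's generation span
are `NA` — undefined, never silently zero. `milestone_table()` maps this over
all populations; replicate milestones are averaged per strain by
`summarize_strains()` (fit per replicate, average after — replicates are
independent evolutionary experiments, not technical repeats). The
preadaptation estimator is switchable to the first measured cycle's D
(`preadaptation = "first_cycle"`), which is the natural alternative when the
first-cycle measurement itself is trusted.

## Fitness → adaptation statistics

`regress_adaptation()` is OLS of strain-mean adaptation on strain-mean
preadaptation D. Under diminishing-return epistasis the relationship is
linear with positive slope: strains that start slower gain more hours.
`call_outliers()` tests, per strain, the replicate-level residuals from that
regression against zero (two-sided one-sample t), then applies
Benjamini–Hochberg across strains at q = 0.05; significant strains are
labelled `better`/`worse` by residual sign, with median deviation magnitudes
per direction. The regression is *not* refit leaving each tested strain out;
with hundreds of strains a single strain's leverage on the fit is negligible
relative to the residual noise being tested. `replicate_repeatability()`
estimates the measurement ceiling by correlating random half-split replicate
means across strains (seeded; an exhaustive pairwise mode is exposed), and
`overlap_test()` gives observed/expected overlap of two strain sets with a
two-sided Fisher exact p.

## Diminishing-return epistasis from reconstructions

For a mutation reconstructed in many backgrounds, `mutation_effects()`
computes the stress-specific benefit as a difference of differences:

Δ = (D^stress^~bg~ − D^basal^~bg~) − (D^stress^~mut~ − D^basal^~mut~)

Working in hours (not ratios) makes any basal-growth cost of the mutation
cancel exactly — it enters both terms of the second bracket — so Δ isolates
the stress-specific effect; a ratio mode is exposed for sensitivity checks.
`fit_diminishing_return()` regresses Δ on the background's stress doubling
time (the deficit, differing only by the basal offset, is the exposed
alternative predictor). When benefits are generated as a fraction φ of each
background's remaining deficit, the slope of this regression estimates φ —
which is exactly how the simulator parameterizes its mutation classes, so
slope recovery is a closed-loop parameter-recovery test. Mutating a gene the
background already lacks is a structural zero: the record is marked
inapplicable and excluded, not treated as a measured zero effect.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: basal doubling time
2.27 h; stress deficits uniform on 0.5–4 h across 300 strains × 12
replicates; 19 cycles from a 5 × 10^4 bottleneck to 2–4 × 10^6 cells; three
mutation classes with rescue fractions φ = 0.9, 0.3, 0.6 (rates 10^-6,
10^-6, 5 × 10^-7 per division) so the strongest and weakest classes produce
mean benefits near a 3:1 ratio; curves sampled every 20 min for 72 h with a
2 h lag, 2% log-normal multiplicative noise, 1% isolated spikes; plate
gradients up to ±10% on D (random plane plus low-frequency sinusoid, drawn
fresh per plate and cycle since each cycle runs on a freshly poured plate);
0.15 h additive measurement noise on doubling-time estimates.

Within a cycle, lineages grow deterministically and exponentially at their
own rates until the colony total reaches the drawn final size; mutants are
seeded by a Poisson supply proportional to each lineage's divisions, placed
uniformly along the division count; the transfer is a multinomial sample of
the bottleneck size. Drift therefore acts only at the bottleneck — at colony
sizes above 5 × 10^4 that is where it matters, and a division-by-division
agent simulation would buy nothing but cost. Mutation benefits compose as
successive removal of a fraction of the *remaining* deficit, which makes the
composed doubling time independent of acquisition order and bounded below by
the basal doubling time. End-of-cycle lineage sizes are rescaled so the
colony total equals the drawn final size exactly (new mutant cells descend
from divisions already counted), keeping realized generations strictly
inside log2(final/bottleneck) bounds. Realized generations are emergent:
19 cycles × 5.3–6.3 doublings gives ~100–120 generations, and the simulator
reports what happened rather than forcing a narrower printed range.

Deliberately not modelled: sequence-level mutation (classes are abstract
labels), diploidy/mating/recombination (the regime is haploid and asexual),
scanner image processing and pixel-to-cell calibration (the curve table is
the interface), and between-replicate environmental covariance beyond the
plate gradient. Passing tests on this generator therefore validate the
statistical machinery — estimator accuracy, bias, error control, parameter
recovery — not instrument-specific artefacts of any particular platform.

Two generator entry points exist because full curve rendering is only needed
when the curve-processing stage is under study: `simulate_experiment()`
renders every colony × cycle curve on plates with reference colonies and
gradient fields; `simulate_cohort()` stops at per-cycle doubling times with
measurement noise. Both share the same lineage simulator and ground-truth
tables.

## Problem sizes and determinism

The test suite exercises the statistical properties at sizes chosen to make
the checks sharp while keeping a full run comfortable on a single CPU:
300 strains × 12 replicates for the epistasis-emergence regression and
outlier operating characteristics (20 seeds for rates), 140 backgrounds × 20
seeds per rescue fraction for slope recovery, 100 plates for gradient
removal, 1,000 random series against each brute-force oracle, and a rendered
24-strain × 3-replicate × 19-cycle experiment for the byte-identical
end-to-end rerun. All randomness flows from explicit seeds; rerunning any
pipeline with the same inputs and seed reproduces identical result tables.

## Known limitations

* The bilinear reference surface extrapolates by nearest reference beyond
  the outermost reference rows/columns, so the last odd row/column carries a
  residual of about one gradient step; a 2-D LOESS surface option would
  trade determinism for smoother edges.
* Preadaptation D is a fit boundary value; its variance is higher than
  interior milestone values, and with fewer than ~6 usable cycles the
  clamped evaluation equals the (noisier) first-point fit.
* The outlier t-test assumes approximately normal replicate residuals;
  heavy-tailed measurement error would be better served by a rank test,
  which the replicate-level tables make easy to bolt on.
* The simulator's noise is independent across cycles and positions apart
  from the plate gradient; persistent position effects (e.g. neighbour
  shading) are exactly what the reference normalization is for, but they are
  not generated, so their residual impact on real data is not measured here.
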