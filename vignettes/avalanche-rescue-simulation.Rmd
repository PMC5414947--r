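---
title: "Monte Carlo optimization of avalanche rescue strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo optimization of avalanche rescue strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avrescue)
```

## The problem

Avalanche rescue is a race against asphyxiation: a completely buried subject
with an obstructed airway is unlikely to survive much beyond 35 minutes, and
rescue resources in the critical first half hour are almost always scarce.
Two recurring allocation decisions have no obvious answer because they trade
speed against accuracy, or one patient's chances against another's:

* **Probing depth.** A probe line that penetrates 2.5 m finds nearly every
  buried subject but advances slowly; one that probes 0.5 m moves an order of
  magnitude faster but misses the majority of victims outright.
* **CPR duration.** A lone rescuer with one extricated pulseless patient and
  one still-buried subject must decide how long to resuscitate before
  digging: resuscitation success rises saturating-exponentially with CPR
  time, while every CPR minute extends the second subject's burial.

Neither expectation can be evaluated in closed form, because the key inputs —
burial depth and deposit area — are only available as empirical registry
distributions. `avrescue` therefore estimates each expectation by Monte
Carlo: resample the empirical inputs, evaluate the deterministic rescue
physics per draw, and average, for every value of the decision variable on a
grid. The optimizer is a plain grid argmax under the
"greatest good for the greatest number" criterion (maximize mean survival,
respectively expected survivors).

## Model ingredients and their parameters

**Burial-depth and deposit-area distributions.** An
`empirical_distribution` is an ordered multiset of positive values resampled
uniformly (probability 1/n each) — a bootstrap of the raw registry column,
deliberately free of any parametric fit. Quantiles use linear interpolation
between order statistics (R's type 7); the convention matters only for
reporting, not for the simulations, which never use fitted quantiles.

**Survival curve** `S(t)`: probability that a completely buried subject is
alive when extricated after `t` minutes. The shipped default
(`default_survival_curve()`, version tagged in every result) is a seven-knot
piecewise-linear digitization of the published Swiss accident-data curve
shape: a plateau near 0.9 for the first ~10 min, a steep asphyxiation decline
to about one third by 35 min, and a slowly decaying tail. Piecewise-linear
interpolation is chosen over splines because it preserves monotonicity
exactly; beyond the last knot the last value holds. The knots live in a YAML
config (`inst/extdata/survival_curve_default.yaml`) so users can substitute
their own digitization; since the source is a published *figure*, not a
table, the default is approximate by construction, and results that depend on
its fine structure (e.g. the exact location of flat optima) should be read
with that in mind.

**Probing-speed model** `v(D)`: strip-metres per minute per rescuer at
probing depth `D`, for a 1.5 m search-strip width. The two published anchor
points for slalom probing are 13 m/min at 0.5 m and 1.5 m/min at 2.5 m; the
default connects them with a power law `v(D) = 13 · (0.5/D)^β`,
`β = ln(13/1.5)/ln 5 ≈ 1.34`, reflecting that stroke time grows faster than
linearly with depth. A tabulated curve can be supplied instead. Depths
outside [0.5, 2.5] m are clamped (with a warning) because the law is anchored
only inside that range.

**Digging speed** `v_dig = 0.15` m of burial depth per minute, the standard
V-shaped conveyor-belt shovelling figure. Excavation time is
`d / v_dig`.

**ROSC model** `p1(t) = a · (1 − exp(−0.07 · t^1.3))`: probability of return
of spontaneous circulation after `t` minutes of CPR, rising from 0 toward the
ceiling `a`. The ceiling encodes the hypoxic insult before the arrest and is
looked up from a sparse clinical table (0.62, 0.25, 0 at initial burial times
of 12, 20, 35 min). Lookup is exact-match only — the table is too sparse to
justify interpolation, so other burial times require an explicit user-chosen
ceiling.

**Search time for the second subject**: Gaussian, mean 2 min, sd 1 min,
negative draws censored to zero (about 2.3 % of the mass).

**Scenario geometry (probe line).** The subject's position is uniform along
a single concatenated strip of length `area / 1.5 m`; `n` rescuers multiply
the effective line speed, giving `t_search = x / (v(D) · n)`. Lateral misses
are not modelled: a subject shallower than (or exactly at) the probing depth
is found with certainty, one deeper is missed on this passage and scored as
zero survival. The equality tie counts as found — the physically sensible
limit of the two strict rules. The default rescuer policy in area sweeps is 5
rescuers (companion party) up to 1000 m² and 20 (organized rescue) above.

**Decision grids.** Probing depth: 21 values, 0.5–2.5 m in 0.1 m steps. CPR
duration: integers 0–30 min. Optima break ties toward the smaller decision
value (the faster line; the shorter CPR, favouring the still-buried patient
when indifferent).

## Numerical and design choices

* **Common random numbers.** Within a grid evaluation, one draw set of
  victims (position fraction, burial depth, search time) is shared across
  all grid points, and across areas or burial-time cases within a sweep.
  Grid points are thereby compared on the same sampled victims, which removes
  between-cell sampling noise from the comparison and makes the structural
  monotonicities exact in the output rather than approximate: the miss
  fraction is non-increasing in probing depth by construction, and each extra
  CPR minute lengthens every sampled burial, so `mean_p2` is non-increasing
  in `t_CPR`. The alternative — an independent sub-stream per grid cell —
  leaves those invariants true only within Monte Carlo error, which is the
  wrong property for an argmax on a flat ridge.
* **Problem sizes.** 10,000 runs per grid evaluation is the package default;
  a half-versus-full-sample delta is recorded per grid point as a convergence
  diagnostic, and the test suite checks that doubling the run count moves
  grid means by less than three pooled standard errors. At these sizes a full
  six-area sweep takes well under a second.
* **Reproducibility.** Every driver takes an integer seed; sweep cells derive
  sub-seeds by hashing the root seed with the cell labels, so a single cell
  can be re-run in isolation. The command-line interface writes a manifest
  (resolved configuration, seed, package and curve versions, input
  fingerprint) with every result.
* **`p1` is deterministic** given `t_CPR` — the ROSC formula has no random
  inputs — so only patient 2's survival is Monte Carlo averaged; combined
  statistics (`p1 + mean_p2`, `p1 · mean_p2`,
  `1 − (1 − p1)(1 − mean_p2)`) use the independence of the two patients and
  hold as exact identities of the output table.
* **Units are fixed at ingest**: registry depths arrive in centimetres and
  are converted to metres once; all computation is in metres and minutes.
  Missing cells are represented as absent, never zero — a zero depth would
  silently corrupt the resampled distribution.
* **Degenerate inputs** are first-class: point-mass depth distributions and
  zero-variance search times collapse every output to a closed form, which
  the tests exploit as oracles against independent quadrature.

## The synthetic data generator

`generate_records()` emulates the statistical structure the simulations
assume: positive, strongly right-skewed burial depths and deposit areas,
drawn from log-normal laws parameterized by median and log-sd, with
independent missingness per field and a guarantee that every record keeps at
least one field. Defaults (depth median 1.0 m, log-sd 0.6; area median
7200 m², log-sd 1.2) are chosen as realistic registry scales: full-burial
depths concentrate below ~1.5 m with a multi-metre tail, and deposit areas
span several decades around a few thousand square metres. The family and all
parameters are configuration, not assertions about any particular registry.

`synthetic_s1_table()` is a stand-in for a specific registry snapshot of
fully buried subjects whose raw table is not redistributed with the package.
It reproduces the snapshot's *published summary structure* exactly — 1555
rows of which 1490 carry a depth, 541 an area, 477 both, and one anomalous
row carries neither (the reader drops and reports such rows rather than
resolving them); sample median deposit area 7200 m²; exactly 1043/1490
(70.0 %) of depths exceeding 0.5 m — by deterministically rescaling
log-normal draws (depth median 0.7 m before pinning, the typical full-burial
scale). What it cannot reproduce is the registry's fine histogram shape,
spatial or temporal correlations, or any depth–area dependence (fields are
generated independently). Results that pass tests on the stand-in therefore
validate the *machinery* and the published marginal facts, not conclusions
about the real registry's joint distribution.

## Limitations

* The survival curve is a figure digitization; optima that sit on flat
  ridges of the survival surface can shift by a grid step or two under a
  different plausible digitization, which is why the tests assert interval
  and monotonicity properties rather than exact optimum locations.
* No cooling or hypothermia model: survival depends on burial time only,
  which is defensible within the first hour of burial but not beyond.
* One buried subject per probe scenario, one rescuer and two patients in the
  triage scenario; no lateral probing misses; rescuer count scales line speed
  exactly linearly (real lines pay a regrouping overhead).
* The ROSC curve derives from non-avalanche cardiac-arrest patients; if the
  true avalanche curve rises more steeply, the optimal CPR duration shortens.
* The optimizer returns grid optima of *expected* survival; it says nothing
  about variance across accidents, and maximizing expected survivors does not
  maximize each individual's survival probability.
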