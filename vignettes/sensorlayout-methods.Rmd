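---
title: "Designing multi-modal electro-physiological sensor layouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-modal electro-physiological sensor layouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorlayout)
```

## The problem

Skin-surface electrodes for electromyography (EMG), electrodermal activity
(EDA) and electrocardiography (ECG) are conventionally placed by hand,
following per-modality heuristics: EMG pairs belong on the muscle line, away
from innervation zones, at moderate inter-electrode distance; EDA pairs must
cover enough sweat glands; ECG electrodes on the forearm only work well at a
few discrete locations. Packing electrodes for several modalities into one
compact wearable patch while keeping all of these rules satisfied is a
geometric optimization problem, not something a designer can iterate by
trial and error.

`sensorlayout` treats the anterior forearm as a 2-D scene reconstructed from
four body measurements, scores any candidate electrode layout on a common
cost scale, and searches the placement space with simulated annealing under
hard spacing and containment constraints. A window-sweep protocol maps the
whole quality/size trade-off and extracts two named designs from it: the
smallest layout with any usable signal (AREA-OPTIMIZED) and the smallest
layout whose predicted quality stays at or above 0.95 (QUALITY-OPTIMIZED).

## The anatomical model

`build_forearm_model()` scales a normalized template by the measurements
`f1` (wrist-to-elbow length) and `f2`, `f3`, `f4` (anterior-surface widths
at the wrist, mid-forearm and elbow). The template is declarative JSON — the
outline polygon, five muscle lines (FCR, BR, PL, PQ, FCU) with
innervation-zone polygons, three candidate ECG pairs with relative SNR, an
EDA anchor and the sweat-gland density — so real guide-derived coordinates
can be swapped in without touching code. The shipped `default_template()`
is **synthetic**: published placement guides are not reproduced, so the
default coordinates are plausible inventions laid out so that the
rule-based baseline placement is geometrically valid and scores perfectly
in every modality, which the real guides intend. Axes: origin at the
wrist-crease midpoint, `+v` toward the elbow (scaled by `f1`), `+u` toward
the radial side (scaled by the width, interpolated piecewise-linearly
wrist → mid → elbow). The demo measurements (250, 55, 70, 85 mm) are a
typical adult forearm.

## The cost model

Every modality cost is normalized to [0, 1] with 0 best, so costs can be
mixed in one objective.

**EMG** (per muscle): hard pre-checks first — an electrode centre more than
10 mm from the muscle line, or an electrode disk overlapping an innervation
zone, scores 1 outright. Otherwise the cost is
`alpha * omega(theta) + (1 - alpha) * nu(d)`, with `alpha = 0.5` by
default. `omega(theta) = 0.0057 theta + 0.000181 theta^2` up to 60 degrees
and 1 beyond; the angle is *axial* (folded into [0, 90] degrees), because a
bipolar pair has no orientation sign — without folding, a perfectly aligned
but reversed pair would score worst. `nu(d)` is a fitted quadratic on
5 < d <= 25 mm, 0 on the ideal 25–60 mm band, and 1 beyond 60 mm; below
5 mm, where the fitted curve does not apply and electrodes nearly touch, it
is pinned at 1 so that scoring arbitrary layouts stays total (the 12 mm
spacing constraint makes that branch unreachable in valid layouts). The
overall EMG cost is the unweighted mean over selected muscles — the EMG
priority weight is applied exactly once, in the global objective.

**EDA**: the pair covers `N_s = (pi r^2 + 2 r d) D_s` sweat glands
(`r = 5 mm`, forearm density `D_s = 1.08 /mm^2`, i.e. 108 per cm²). Fewer
than 140 glands, or a separation beyond the recommended 60 mm, scores 1;
otherwise the cost is `1 - N_s / N_max` with `N_max` the coverage at 60 mm
(≈ 733 glands on the forearm).

**ECG**: a discrete keypoint model. The pair is matched to the nearest
candidate pair (minimizing summed centre-to-keypoint distance over both
matchings) and costs `1 - SNR/SNR_max` there, so the upper-forearm pair
scores 0 and the wrist pair (relative SNR 0.25) scores 0.75. Because the
annealer moves electrodes continuously while the underlying SNR data are
discrete, a capture radius (20 mm per electrode) bounds the assignment:
beyond it the cost is 1. The mid-forearm pair's relative SNR is not pinned
by published data available here; the default is 0.6 and it is a template
field.

**Area**: the convex hull area of the measurement-electrode centres
(Graham scan + shoelace), normalized by the hull of the rule-based baseline
layout. Layouts with fewer than three electrodes are degenerate and score
0. Reference electrodes (at most two: one shared by EMG, one for ECG) sit
off the forearm and take part in neither costs nor constraints.

The global objective is `O = w1 O1 + w2 O2 + w3 O3 + w4 O4`, with enabled
modality weights summing to 1 in the weight scheme. A bound scheme replaces
(or, in the hybrid scheme, supplements) the modality weights with
exponential penalties `p (exp(max(O_k - l_k, 0)) - 1)` for exceeding a
per-modality cost ceiling `l_k`; the prose and formula of the source
disagree about the direction of this bound, and the formula's
`max(O_k - l_k, 0)` is taken as authoritative: `l_k` is a ceiling on cost,
i.e. a floor on quality. Reported *quality* is `1 -` the weight-normalized
modality aggregate; the area term is a size metric, not signal quality, and
is excluded from quality on purpose.

## The optimizer

Simulated annealing over electrode centres. A proposal moves one uniformly
chosen electrode; validity (pairwise centre spacing >= 12 mm, which also
guarantees non-overlap for the shipped electrode radii, and containment of
every centre in the search region and forearm outline) is enforced by
outright rejection — invalid layouts are never scored. Valid proposals are
accepted with probability `min(1, exp(-delta/T))`, and the temperature
cools geometrically (`T0 = 1`, factor 0.95, 100 moves per level). The
candidate budget defaults to 15,490 proposals, and the best-so-far layout
is returned.

Two choices here were genuinely open and deserve their rationale:

* **Move kernel.** The EMG term is *flat at its worst value* everywhere
  outside the 10 mm muscle corridors, so purely local steps (10 mm) must
  random-walk across a zero-gradient plateau and, in experiments with this
  package, routinely failed to discover one or more corridors within the
  candidate budget (sweep aggregates stalling near 0.67 on three-muscle
  runs). Moves are therefore a mixture: with probability 0.75 a local step
  (direction uniform, magnitude uniform on (0, 10] mm), and with
  probability 0.25 a long-range translation whose target is either uniform
  over the region or biased toward the moved electrode's own anatomical
  guide (its muscle line, or the ECG keypoint band), half and half. The
  biased component changes only the proposal distribution — the objective
  and acceptance rule are untouched — and with it whole-forearm
  multi-modal runs reach aggregates of order 0.01 within budget.
* **Schedule scaling.** When the candidate budget is reduced (tests and
  examples do this for runtime), the moves-per-temperature should be
  reduced proportionally so the *temperature trajectory completes*;
  truncating the schedule instead leaves the system too hot to refine and
  was the dominant failure mode in scaled-down runs.

Determinism: one RNG stream seeded from the configuration, consumed in a
fixed documented order, makes designs bit-reproducible; per-window sweep
seeds derive from the base seed and window height.

## The sweep protocol

`bounding_box_sweep()` grows a wrist-anchored rectangle in 1 mm increments
(configurable) to the full forearm and anneals inside each window,
recording infeasible windows (too small to pack the roster at 12 mm
spacing) as markers. AREA-OPTIMIZED is the design at the smallest window
whose modality aggregate is below 1; QUALITY-OPTIMIZED is the smallest hull
among designs with aggregate at most 0.05. One upward sweep serves both
selections — the published protocol sweeps downward for the quality design,
but the selection rules only consult the recorded list, so a direction flag
is kept for fidelity runs rather than run twice.

The sweep's aggregate excludes the area term (area is exactly what the
window is trading), but the in-window objective keeps a modest area weight
(`w4 = 0.2` in the examples): without it, the annealer has no incentive to
be compact inside a window that is larger than strictly necessary, and the
selected designs sprawl.

## What the synthetic world does and does not establish

The generator's defaults are the stated conditions of the underlying
measurement models: 50 mm² EMG/ECG and ≈ 0.785 cm² EDA electrodes, 12 mm
spacing, 10 mm line tolerance, 140-gland minimum, 60 mm recommended EDA
distance, 108 glands/cm², wrist ECG SNR at one quarter of the best site,
and the 15,490-candidate budget. A green test establishes that the cost
model reproduces its printed values and that the optimizer and protocol
behave as specified *on the synthetic template*. It does not establish
anatomical validity of the shipped coordinates, nor signal quality on a
real arm — the model ignores subcutaneous fat, skin moisture and
electrode–skin impedance, and the published human-subject comparison
percentages depend on participant measurements that are not public.

One model property worth knowing when reading results: the 10 mm line
tolerance is penalty-free, so an optimizer under area pressure may slide
several electrode pairs toward each other into a narrow strip between
near-parallel muscle lines, producing convex hulls far smaller than a
practitioner would draw. That is a faithful consequence of the cost model,
not an artifact of the search.

## Numerical choices

* Boundary points count as inside for containment (permissive: layouts may
  touch the sketched outline); ray casting with an explicit boundary check
  is the algorithm of record, winding numbers the test oracle.
* Hull degeneracy (fewer than 3 electrodes, or collinear centres) yields
  area 0 rather than an error when scoring, since two-electrode (EDA-only)
  configurations are legitimate.
* IZ membership means the electrode *disk* overlaps the IZ polygon, the
  conservative reading of "falls within".
* All distances are centre-to-centre, matching the non-overlap rule's
  formulation.
* Selection ties: equal-height AREA candidates by smaller hull;
  equal-area QUALITY candidates by smaller window.

## Worked example

```{r example, eval = FALSE}
model <- build_forearm_model(forearm_measurements(250, 55, 70, 85))
cfg <- design_config(
  modalities = c("EMG", "EDA", "ECG"),
  weights = c(EMG = 1 / 3, EDA = 1 / 3, ECG = 1 / 3, area = 0.2)
)
design <- anneal(model, cfg, anneal_config(seed = 1))
glance(design)
autoplot(design, model)

sweep <- bounding_box_sweep(model, cfg, anneal_config(seed = 20), increment = 5)
autoplot(sweep)
select_quality_optimized(sweep)
```

## Limitations

The model is 2-D (an unrolled anterior surface), single-site, and
electrode-type agnostic. The ECG model is discrete by construction; a
continuous forearm SNR model, if one becomes available, would slot into the
template as a denser candidate set. The annealer offers no optimality
certificate — mixed-integer formulations could provide bounds but are out
of scope.
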