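# sensorlayout

Computational design of compact multi-modal electro-physiological sensor
layouts for the anterior forearm.

Placing skin electrodes for surface EMG, electrodermal activity (EDA) and
ECG is normally done by hand from per-modality heuristics: EMG pairs aligned
with the muscle line and clear of innervation zones, EDA pairs covering
enough sweat glands, ECG electrodes at the few forearm sites with usable
SNR — all while no two electrodes come closer than 12 mm. Packing the 14
measurement electrodes of a full three-modality patch into a small footprint
under all of these rules at once is a geometric optimization problem. This
package is for wearable-device designers and physiological-computing
researchers who want that search automated and reproducible.

## The model

Every modality is scored on a common cost scale, 0 (best) to 1 (worst):

* **EMG**, per selected muscle *i* (of FCR, BR, PL, PQ, FCU):

  O₁ᵢ = α·ω(θ) + (1−α)·ν(|e⃗|), or 1 outright if an electrode is > 1 cm
  from the muscle line or overlaps an innervation zone, with
  ω(θ) = 0.0057·θ + 0.000181·θ² (θ ≤ 60°, else 1) and ν a fitted quadratic
  on 5–25 mm, 0 on the ideal 25–60 mm band, 1 beyond. O₁ is the mean over
  selected muscles; α = 0.5 by default.
* **EDA**: the pair covers N_s = (πr² + 2rd)·D_s sweat glands
  (r = 5 mm, D_s = 1.08 /mm² on the forearm); cost 1 if N_s ≤ 140 or
  d > 60 mm, else 1 − N_s/N_max with N_max ≈ 733 at the recommended 60 mm.
* **ECG**: discrete candidate pairs (wrist / mid-forearm / upper forearm)
  with relative SNR 0.25 / 0.6 / 1.0; cost 1 − SNR/SNR_max at the nearest
  candidate, so the best pair scores 0 and the wrist pair 0.75.
* **Area**: convex-hull area of the electrode centres, normalized by the
  rule-based baseline layout's hull.

The global objective is O = Σ w_k·O_k (weights over enabled modalities
summing to 1, plus an area weight), optionally with exponential penalties
p·(e^max(O_k−ℓ_k,0) − 1) for per-modality cost ceilings. A simulated
annealer searches electrode positions under the 12 mm spacing and
containment constraints; a wrist-anchored bounding-box sweep maps the
quality/size trade-off and selects the **AREA-OPTIMIZED** (smallest window
with any usable signal) and **QUALITY-OPTIMIZED** (smallest hull with
predicted quality ≥ 0.95) designs.

The shipped anatomical template is synthetic (published placement-guide
coordinates are not reproduced); it is a JSON file, so guide-derived
coordinates can be swapped in.

## Worked example

```r
library(sensorlayout)

model <- build_forearm_model(forearm_measurements(250, 55, 70, 85))
cfg <- design_config(weights = c(EMG = 1/3, EDA = 1/3, ECG = 1/3, area = 0.2))
design <- anneal(model, cfg, anneal_config(seed = 1))
design
#> <electrode_design> 14 measurement electrodes; EMG+EDA+ECG
#>   objective 0.0826  quality 0.9963  hull area 2625.4 mm^2
glance(design)
#> # A tibble: 1 × 10
#>   n_electrodes objective      O1      O2    O3    O4 modality_aggregate quality
#>          <int>     <dbl>   <dbl>   <dbl> <dbl> <dbl>              <dbl>   <dbl>
#> 1           14    0.0826 0.00724 0.00392     0 0.395            0.00372   0.996
```

The design places all 14 measurement electrodes with every EMG pair aligned
on its muscle (O₁ = 0.007), the EDA pair near the recommended 60 mm
separation (O₂ = 0.004), the ECG pair on the best candidate site (O₃ = 0),
and a hull of 2625 mm² — about 40 % of the rule-based baseline's footprint
(O₄ = 0.395) at essentially baseline signal quality (0.996).

`tidy(design)` returns the electrode table (role, centre in mm);
`autoplot(design, model)` draws the layout over the forearm;
`save_design()` / `export_svg()` write the JSON design file and a printable
layout or punch-hole stencil (1 SVG unit = 1 mm). A command-line wrapper
with `fixture`, `optimize`, `score`, `sweep` and `export` subcommands is
installed at `inst/cli/sensorlayout`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantity from
scratch — it rebuilds the forearm model from the demo measurements and
evaluates the EDA gland-coverage model at the recommended electrode
distance — and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/sensorlayout-methods.Rmd`) documents the
cost model's assumptions, the annealer's move kernel and schedule, what the
synthetic template does and does not establish, and known limitations.
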