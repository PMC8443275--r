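---
title: "Quantifying mechanical cell competition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mechanical cell competition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcompr)
```

`cellcompr` quantifies the readouts of cell-competition experiments in
human pluripotent stem cell (hPSC) cultures: spatial crowding of the
losing subline, apoptosis near a confrontation border, mechanosensitive
marker localisation, single-cell stiffness, and culture-level growth
suppression. This vignette explains each model, the tunable parameters
and their defaults, what the synthetic generators emulate, and the
numerical choices made where the design was genuinely open.

## Delaunay local density

Nuclei centroids (x, y in micrometres) are triangulated; the triangles
incident to a nucleus tile its immediate neighbourhood, so their areas
`A(i), i = 1..n` measure how much space the cell commands. Two readings
of the per-cell statistic circulate and differ whenever `n > 1`:

* `inverse_of_sum` (default): `rho = 1 / sum(A(i))` — the reciprocal of
  the total incident area;
* `sum_of_inverses`: `rho = sum(1 / A(i))`.

Both are implemented; every output row records which variant produced
it, so the choice is auditable. The default follows the unambiguous
prose reading ("the inverse of this sum"); the alternative is the
literal typeset formula. Both scale as length^-2 and order crowding the
same way, so direction-of-effect conclusions are variant-independent
(the test suite asserts scale equivariance and monotonicity under
contraction for both).

The triangulation itself is a Bowyer-Watson incremental construction in
compiled code. Design details:

* **Degenerate triangles** below `1e-12` square micrometres are removed
  (a message reports how many); exact duplicate points are deduplicated
  with a warning, and the per-cell output maps duplicates back to their
  retained copy.
* **Convex-hull cells** keep a density value but are flagged: their
  incident fan is truncated by the field of view, which biases `rho`
  downward, so group comparisons exclude them by default. The
  correctness of every produced triangulation is property-tested
  against a brute-force empty-circumcircle oracle at tolerance `1e-9`.
* Coordinates are real-valued micrometres in a y-down image frame;
  densities are reported in `um^-2`.

Group distributions are compared with the two-sample
Kolmogorov-Smirnov statistic `D = sup |F1 - F2|`, computed exactly by a
sorted merge walk, with the standard asymptotic tail probability. The
native implementation is cross-checked against `stats::ks.test` in the
tests.

## Confrontation-border profiling

In a confrontation assay the two populations grow toward each other
across a 500-micrometre insert gap (the generator's default
`gap_width`) and meet at a near-straight interface. Each cell's
positional identity is its perpendicular signed distance to that line,
positive into loser territory. When no annotated line is supplied, the
interface is estimated as the midpoint between the opposing 5th/95th
percentile fronts along x — robust to straggler cells that have
crossed the line.

Apoptosis is profiled as the caspase-positive fraction in contiguous
distance bins (default `bin_width` 50 um; no bin geometry is standard,
so widths are uniform and configurable). The profile obeys exact
count-weighted aggregation: merging bins reproduces the coarse-bin
fractions identically, which the suite asserts.

The generator's positivity model for loser cells is
`p(d) = base + amplitude * exp(-d / L)` with defaults
`base = 0.05`, `amplitude = 0.4`, `L = 100 um` — a baseline apoptosis
rate with a border-localised elevation decaying into loser territory;
winners sit at `base`. Recovery is tested by refitting `L` with a
binomial maximum-likelihood fit (Nelder-Mead on logit/log-transformed
parameters).

A design note on the recovery check: with 5,000 loser cells the MLE of
`L` carries an irreducible sampling SD of about 11% — a Cramér-Rao
calculation over candidate field geometries bottoms out near 11.4% at
a loser-territory depth of ~600 um, which is the depth the recovery
tests use (1200 x 2000 um field, border at 600 um). Because a single
field can therefore miss a 20% band by sampling noise alone, the
recovery checks summarise five replicate fields (each at n = 5,000) by
their median.

Front displacement over a time course is the per-timepoint interface
estimate minus the estimate at first contact, signed so that winners
advancing into loser territory is positive; timepoints missing one
population are flagged rather than fatal.

## Nuclear/cytoplasmic quantification

Nuclei are segmented from the Hoechst channel by a global Otsu
threshold, connected components and a minimum-area filter; touching
nuclei can optionally be split by a distance-transform watershed (the
automated stand-in for manual splitting — enabling it is the user's
logged choice). Per nucleus, two masks follow:

* **inner nucleus** — erosion by a Euclidean disc of `radius_px`
  pixels (default 15);
* **cytoplasm ring** — dilation by the same disc, minus the union of
  *all* nuclei, so cytoplasm is never contaminated by an adjacent
  nucleus.

Morphology is computed via exact Euclidean distance transforms
(erosion keeps pixels farther than `radius_px` from background;
dilation keeps pixels within `radius_px` of the nucleus), which is the
isotropic disc structuring element in distance form. Ring pixels
claimed by several dilations go to the nearest nucleus, ties to the
lowest label, and the cells involved are flagged `contested_ring`; the
per-pixel partition is verified against an exhaustive assignment
oracle. Cells whose nucleus erodes away (`empty_inner`), whose
dilation leaves the frame (`edge_cell`), or whose ring is empty or
zero (`zero_cytoplasm`) are excluded from ratios but keep whatever
means are defined.

`nc_ratio = nuclear_mean / cytoplasm_mean` on the raw channel; no
background subtraction is applied by default, with an optional
constant-offset subtraction behind the `background` argument.

The synthetic image renders nuclei as unit discs and the marker
additively per cell: `nc_partition x cyto_intensity` over the nuclear
disc, `cyto_intensity` over an annulus out to twice the nuclear radius,
on a constant background, plus Gaussian noise (`noise_sd` in marker
units; the nuclei channel receives the same relative noise). With the
default 8-um nuclei at 0.5 um/pixel, the 15-pixel ring (7.5 um) stays
inside the 16-um annulus, so the measured ratio should equal
`nc_partition` exactly in the noise-free limit — which the recovery
tests confirm across partitions 0.5-4 and at 5% noise within 10%.

## Hertz stiffness fitting

For a rigid sphere of radius `R` indenting an incompressible elastic
half-space by `delta`, the classical Hertz model gives

```
F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)
```

with `nu = 0.5` (incompressible) and `R = 2.5 um` (a 5-um polystyrene
bead) as defaults; inputs are um/nN, the modulus is reported in Pa,
and the unit constant is centralised and unit-tested against a
hand-converted SI value.

Instrument software treats the contact point opaquely; here it is
explicit and testable: initialisation at the first sample exceeding
three baseline standard deviations (baseline = first fifth of the
curve), then refinement as a free parameter of the Levenberg-Marquardt
least squares. Only post-contact indentations up to `fit_fraction`
(default 0.5) of the maximum are fitted, where the small-indentation
approximation holds; on model-generated curves halving the window
moves the estimate by under 1%, and noise-free self-consistency is at
machine precision. Flat or non-positive curves return
`converged = FALSE` with a diagnostic instead of a number.

Because sessions take several curves per cell and several cells per
experiment, summaries are strictly hierarchical: cell value = mean of
its converged fits, experiment value = mean of cell values. Raw fits
are never pooled across cells, so an unevenly measured cell cannot
dominate an experiment mean.

## Competition metrics and the growth model

The synthetic growth model is the simplest density-coupled pair: each
subline grows exponentially; in co-culture the loser's per-capita rate
is reduced by `coupling x` current winner density,

```
dW/dt = r_W W,    dL/dt = (r_L - c W) L,
```

integrated in closed form (the tests also check it against an
independent fine-step ODE solver). Defaults emulate the standard
experiment: plating `4.4e4 cells/cm^2`, 50:50 mix, 3 days of
competition after day 0. Rates `r_W = 1.1`, `r_L = 0.9` per day give
doubling times of 15-18 h, typical of hPSC sublines with the winner
slightly faster; `c = 3e-6 cm^2/cell/day` was chosen once so that the
integrated suppression over 3 days is strong but not eliminative
(~80% loser deficit), matching the qualitative severity of the
phenotype. No quantitative effect size is published for these
curves, so the coupling is a free generator parameter, not a
calibrated one.

Culture-level readouts: log-linear doubling times (undefined, not
infinite or zero, for flat counts); subline ratios in both published
conventions, always labelled, with the winner share obeying
`s = r/(1+r)` row by row; caspase fractions with exact Clopper-Pearson
intervals (endpoints verified against the defining binomial tail
equations); and density titrations over the standard
`3,750-45,000 cells/cm^2` range summarised by a Spearman rank
correlation between plating density and relative loser growth — a
flat (uncoupled) response is reported as correlation 0 rather than
undefined.

Routine hypothesis tests used alongside these readouts (t, ANOVA,
multiple-comparison corrections) are deliberately left to standard
statistical software; only the KS statistic and the binomial CI are
package-native.

## Relative copy number (2^-ddCq)

With Cq triplicates of a target and a reference assay in a test sample
and a karyotypically diploid calibrator:
`dCq = mean(Cq_target) - mean(Cq_ref)` per sample,
`ddCq = dCq_sample - dCq_calibrator`, `RQ = 2^-ddCq`, and the copy
number estimate is `2 RQ` under the single-reference diploid-calibrator
assumption (multi-reference averaging is out of scope). Triplicates
with SD above 0.5 cycles are flagged but still computed, since a
flagged estimate is more useful than a missing one. Calibration
points: `ddCq = 0, -1, -0.585` give `RQ = 1, 2, 1.5` — diploid, full
single-copy gain, and the heterozygous-gain signature of a 3-copy
locus.

## What the synthetic tests do and do not show

The generators reproduce the *statistical structure* the analyses
assume — homogeneous vs clustered point processes, a half-plane
confrontation with distance-dependent positivity, disc nuclei with a
known intensity partition, exact Hertzian curves with additive noise,
exponential growth with multiplicative coupling. Passing recovery
tests therefore demonstrates that the estimators are correct and
well-conditioned under their own model assumptions. They do not
demonstrate robustness to what real data adds: irregular nucleus
shapes and segmentation errors, curved or ragged confrontation fronts,
spatially varying background and uneven illumination, viscoelastic or
tilted force curves, or counting noise in growth assays. Parameters
estimated from real images should be read with those caveats; the QC
flags (hull, edge, contested, empty-inner, high-SD) are the designed
entry points for auditing them.

## Problem sizes and determinism

Every stochastic routine consumes a named seed through a local RNG
scope, so identical seeds give bit-identical outputs without touching
the caller's RNG state. The test and acceptance runs use deliberately
modest sizes — 100 patterns of up to 50 points for the oracle
equivalence, 100 seeds of 500-point fields for the corralling
direction, five 5,000-cell fields for the decay refit, twelve-nucleus
images at 0.5 um/pixel, and 100 force curves — sizes at which every
recovery proof runs in seconds while the Monte-Carlo margins remain
comfortable.
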