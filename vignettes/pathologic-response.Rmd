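---
title: "Quantifying pathologic response: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pathologic response: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprct)
```

## The estimand and the two estimators

After neoadjuvant therapy, the tumor bed — the region the tumor occupied
before treatment — is decomposed on every histologic slide into three
components that sum to 100%: viable tumor, necrosis, and stroma (fibrosis
plus inflammation). The quantity of clinical interest is the percentage of
the whole bed that is still viable tumor; major pathologic response (MPR)
is declared at or below a threshold (10% by default) and pathologic
complete response (pCR) requires no viable tumor cells anywhere, including
sampled regional lymph nodes.

Two per-case summaries of the slide values $V_i$ are in circulation:

* the **unweighted mean** $\bar V_u = \tfrac1n \sum_i V_i$, the historical
  definition under which MPR was established, and
* the **area-weighted mean**
  $\bar V_w = \sum_i \tfrac{l_i w_i}{T} V_i$, with $T = \sum_i l_i w_i$,
  which weights each slide by its measured bed rectangle $l_i \times w_i$.

When every slide carries a similar amount of bed the two coincide; when a
large-area slide is nearly tumor-free and a small slide is nearly all
tumor, they diverge — the weighted mean is the consistent estimator of the
bed-wide viable fraction, which is exactly what the simulator verifies.
The package computes and reports both for all three components, and the
classification **basis defaults to the unweighted mean** because the
outcome evidence behind the 10% cutoff was accumulated under plain
averaging; switching to `basis = "weighted"` is a single argument. Whether
the distinction changes labels materially is itself an open clinical
question, which is why reports always carry both.

Stroma is never entered: it is derived as $100 - V - N$, with the blank
form defaulting to 100% stroma only when viable and necrosis are both
explicitly zero-entered — a truly blank cell is a `MISSING_FIELD` finding,
keeping "assessed as 0" distinct from "not assessed".

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mpr_threshold` | 10 (%) | MPR cutoff, boundary inclusive; histology-specific values (e.g. 65 for adenocarcinoma in one retrospective series) are supported |
| `basis` | `"unweighted"` | which mean drives the MPR label |
| `tolerance_factor` | 1.2 | slack on gross-footprint plausibility checks |
| `slab_thickness_cm` | 0.5 | gross section thickness |
| `cassette_area_cm2` | 4 | tissue footprint of one cassette in the legacy-sampling model |
| `cell_size_cm` | 0.05 | simulator grid resolution |
| `noise_sd` | 0 | observer reading noise (percentage points) |

Dimensions are in cm, areas in cm²; converting ocular-micrometer or
field-diameter readings is the caller's responsibility. Percentages live on
the 0–100 scale throughout. Strict mode enforces whole-number percentages
(the form accepts any whole number between 0 and 100); lenient mode admits
decimals — needed for simulator output — and downgrades `NON_INTEGER` to a
warning.

## Validation safeguards

Findings are returned, never thrown, so a batch of cases can be triaged in
one pass. The rule registry is closed: `MISSING_FIELD`, `SUM_GT_100`,
`RANGE`, `NON_INTEGER`, `DUPLICATE_SLIDE_ID`, `AREA_RANGE`, `EMPTY_CASE`.
Two choices deserve a note. First, `SUM_GT_100` only fires when both
percentages are individually in range, so each defect maps to exactly one
rule. Second, the plausibility check against the gross dimensions is not
specified anywhere as arithmetic, so the package defines it explicitly:
a warning when any single slide's bed rectangle exceeds
`tolerance_factor × gross_length × gross_width`, or when the total bed
area exceeds `tolerance_factor × n_slides ×` that footprint. Both the
per-slide and the total comparison are reported, the severity is a warning
and computation is never blocked: gross and microscopic measurements
legitimately disagree, and the tool's job is to flag, not to reject.

## Sampling strategy and the legacy comparison

The proposed plan is rule-based and exact: tumors at most 3 cm in greatest
diameter, or any tumor with suspected pCR, are submitted entirely; larger
tumors contribute at least 50% of the bed from alternate sections, and the
absence of viable tumor in those sections escalates to complete
examination to confirm pCR. Alternate sections are the odd-indexed slabs
(1st, 3rd, ...) with a selectable offset, for determinism.

`standard_proportion()` quantifies the legacy one-section-per-centimeter
approach. Its published arithmetic is not available, so the package states
its own geometric model: the tumor is a sphere cut into 0.5 cm slabs; full
submission needs `ceiling(area / cassette_area)` cassettes per slab at the
mid-slab cross-section; the legacy approach takes `ceiling(diameter)`
cassettes, and the examined proportion is their ratio, capped at 1 and
exactly 1 at or below 3 cm (such tumors are submitted whole by rule). With
the defaults this yields `standard_proportion(7)` = 7/98 ≈ 7.1%, a steeply
diminishing proportion as diameter grows. The slab thickness and cassette
area are exposed so the model can be recalibrated if a different gross
protocol is in use. Because of the `ceiling` terms the proportion is
monotone on centimeter-scale grids but can wiggle at millimeter steps
around integer diameters; the interface documents the model rather than
hiding the granularity.

## The simulator

`simulate_bed()` builds a circular bed on a square grid and assigns labels
by **exact quota**: the cavity count first (as a fraction of the
footprint), then viable and necrosis as fractions of the remaining bed
cells, remainder stroma. Ground truth is therefore known to the cell and
stored as the *realized* fractions — a requested 20% realizes to the
nearest achievable quota, within one cell of the request — so estimator
error comes only from sectioning and the observer model, never from label
sampling noise. Heterogeneity patterns order the bed cells by distance
from the centroid: `central` places viable tissue nearest the center,
`peripheral` farthest (residual tumor along the lesion periphery is the
reported tendency), `random` uniformly; necrosis occupies the adjacent
positions in the same ordering. Distance ties among symmetric cells are
broken by a seeded jitter three orders of magnitude below one cell area.
The bed is 2-D — a single gross cut face — because slides are planar and
the weighted estimator is area-based; a 3-D bed adds parameters without
changing the estimand.

`section_bed()` cuts vertical slabs (slab thickness must be a multiple of
the cell size) and records each retained slab the way a pathologist would:
`l, w` are the best-fitted rectangle around the slab's bed footprint, the
percentages are label fractions among bed cells, and cavity cells —
which meet no component's criteria — are excluded from the denominator.
The rectangle inevitably overhangs the curved bed edge, so the slide also
carries `excluded_area_cm2` = rectangle minus bed-tissue area (cavity plus
overhang), and the weighted mean uses the effective area `l·w − excluded`
as the weight. This is the same subtraction the tissue rules prescribe for
empty cystic cavities and bronchial lumina, applied uniformly; it makes
full sectioning plus the weighted mean an exact identity for the grid
truth, which the test suite asserts at 1e-9.

Three schemes are provided. `all` is complete submission. `alternate` is
the proposed ≥ 50% strategy. `one_per_cm` models the legacy standard for
tumors over 3 cm as the **single slab at the maximum dimension** — the
most representative cross-section, which is what the legacy protocol
actually examines microscopically — so its examined fraction shrinks with
diameter just as the geometric model predicts (about 9% of bed cells at
7 cm). An evenly-spaced-slab reading of "one per centimeter" was rejected:
with 0.5 cm slabs it retains the same ~50% of the bed as the alternate
scheme at every diameter, which contradicts the diminishing-proportion
behavior the scheme exists to represent and erases the contrast the
benchmark is designed to measure.

`apply_observer()` adds truncated Gaussian reading noise (viable first,
then necrosis clipped so the sum stays ≤ 100, stroma re-derived — the
decomposition is conserved by construction) and optionally rounds by the
reporting convention: values below 5% to the nearest whole percent,
otherwise to the nearest multiple of 10, **half-up** (15 → 20), chosen so
that repeated analyses round identically.

`evaluate_strategies()` is a seeded Monte-Carlo loop over
bed → sectioning → (observer) → estimator → classification, reporting
bias, RMSE, MPR misclassification against the exact truth, and the mean
fraction of bed examined. Replicate seeds are derived deterministically
from the master seed.

What the simulator does *not* emulate: irregular (non-circular) bed
outlines, multifocal beds, correlation between slide thickness and
measurement error, inter-observer systematic bias (only symmetric noise),
and any histology-level texture. Passing benchmarks therefore demonstrate
estimator behavior under controlled spatial heterogeneity, not performance
on real slides.

## Tissue rules

Morphologically ambiguous elements are categorized by a versioned data
table rather than code branches, so a future revision of the conventions
can be swapped in: extracellular mucin → stroma (extended to colloid
carcinoma), neoplastic cells within mucin → viable tumor (the mucin stays
stroma), fibrovascular cores → stroma, fibrosis and inflammation → stroma
with no native-versus-regression distinction attempted, necrotic foci →
necrosis, empty cystic cavities and bronchial lumina → excluded from the
bed denominator (their area is recorded, not interpreted), direct nodal
extension → viable tumor bed, and an encapsulated nodal metastasis →
outside the primary bed — with a breached capsule reclassifying it as
direct extension. The three in-bed categories are exactly the components
of the 100% decomposition.

## Agreement statistics

The ICC is fixed to the two-way random-effects, single-measurement,
**absolute-agreement** form, ICC(2,1): pathologists are interchangeable
and systematic reader shifts should count against agreement. It is
computed from the two-way ANOVA mean squares; the suite checks it against
an `aov()`-based oracle at 1e-9 and its invariance to constant shifts.
Bland–Altman limits are mean ± 1.96 SD of paired differences, with the
observed proportion inside the limits reported (≈ 0.95 under Gaussian
differences, verified by simulation at n = 10,000). Cohen's kappa on the
MPR dichotomy uses the closed form; a unanimous-but-identical table is
defined as kappa 1 and unanimous-but-different as 0, since the chance
correction is degenerate there. Rounded-versus-continuous comparisons are
produced by piping `apply_observer()` output into these functions; no
special-cased code path exists. No acceptable-discordance range is
hard-coded: none has been established.

## Numerical and degenerate-input choices

* Slides with zero bed area are retained in records but excluded from both
  means; a case whose every slide lacks bed raises an undefined-computation
  error, as does a zero total area for the weighted mean.
* Bed dimensions accept two-decimal cm precision; nothing forbids finer
  input, but the form convention is ruler-scale measurement.
* JSON reports serialize numbers at 17 significant digits so a
  write-read cycle is bit-exact; CSV round-trips are lossless for valid
  files and the decimal separator is always a period.
* All simulation entry points take an explicit integer seed; identical
  seeds reproduce grids, slides and reports identically.

## Problem sizes

The shipped checks use what one CPU handles in seconds: 105 simulated beds
(diameters 2–8 cm, all three patterns) for ground-truth recovery, 10,000
random slides for conservation, 500 Monte-Carlo replicates per sectioning
scheme at 7 cm for the misclassification benchmark, and n = 10,000 for the
limits-of-agreement coverage simulation. Larger runs scale linearly and
are a matter of passing bigger `n_reps`.

## Known limitations

The package quantifies; it does not adjudicate. It has no concept of
histologic subtype beyond the configurable threshold, does not estimate
viable tumor size in cm, does not correlate with imaging, and the legacy
sampling model is a declared geometric stand-in, not a reconstruction of
any particular laboratory's practice. The simulator's cavities are single
contiguous blobs; multifocal cavitation would require a straightforward
extension of the placement routine.
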