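# mprct

Quantifying pathologic response in non-small cell lung cancer (NSCLC)
resected after neoadjuvant therapy.

After neoadjuvant treatment, the percentage of residual viable tumor in the
tumor bed is the basis of two trial endpoints: **major pathologic response
(MPR)**, at most 10% viable tumor, and **pathologic complete response
(pCR)**, no viable tumor cells at all (including sampled regional lymph
nodes). How that percentage is measured varies between studies — how much of
the bed is sampled, whether slide percentages are averaged plainly or by
tumor-bed area, and whether values are recorded continuously or rounded to
10% increments. `mprct` implements a standardized pipeline for pathologists
and trial data managers:

* **Per-slide capture and validation.** Each slide records the tumor-bed
  length `l_i` and width `w_i` (cm), percent viable tumor `V_i` and percent
  necrosis `N_i`; percent stroma is always derived as
  `S_i = 100 − V_i − N_i`. Safeguards flag missing cells, sums over 100%,
  out-of-range values, duplicate slide IDs and bed areas implausible against
  the gross dimensions.
* **Unweighted and area-weighted means.** The unweighted mean viable tumor
  is `mean(V_i)` over slides with bed present. The weighted mean,

  ```
  V̄_w = Σ_i (l_i · w_i / T) · V_i,    T = Σ_i l_i · w_i,
  ```

  weights each slide by its bed area, so slides carrying a lot of tumor bed
  dominate. The two can differ substantially when large-area slides carry
  low viability.
* **Classification.** MPR at a configurable threshold (default 10%,
  boundary inclusive; histology-specific cutoffs such as 65% are supported),
  pCR when every slide has `V_i = 0` and nodes are negative.
* **Sampling plans.** The proposed strategy: submit the entire tumor bed
  when the diameter is ≤ 3 cm or pCR is suspected; at least 50% from
  alternate sections otherwise, escalating to full examination when no
  viable tumor is found. A geometric model quantifies how little the legacy
  one-section-per-centimeter approach examines as tumors grow.
* **Simulation.** A seeded 2-D tumor-bed generator with exact ground truth
  and central / peripheral / random heterogeneity, virtual sectioning, an
  observer noise-and-rounding model, and a Monte-Carlo benchmark of
  sampling strategies (bias, RMSE, MPR misclassification).
* **Interobserver agreement.** Bland–Altman limits of agreement, two-way
  absolute-agreement ICC(2,1), and Cohen's kappa on the MPR dichotomy.

## Worked example

Two slides: a small one (2 × 1 cm) almost entirely viable, a large one
(4 × 3 cm) almost free of tumor.

```r
library(mprct)
slides <- slide_measurements(
  slide_id = c("A1", "A2"),
  bed_length_cm = c(2, 4), bed_width_cm = c(1, 3),
  pct_viable = c(90, 5), pct_necrosis = c(0, 10)
)
fit <- mprct(slides)
summary(fit)
```

```
Pathologic response (case case, 2 slide(s), bed area 14 cm^2)
  mean viable tumor: 47.5% unweighted, 17.14% weighted
  classification (unweighted basis, threshold 10%): NO_MPR

Component means (%):
           viable necrosis stroma
unweighted  47.50     5.00  47.50
weighted    17.14     8.57  74.29

Reported with 10%-increment rounding (viable): 50 20
```

The unweighted mean (47.5%) treats both slides equally; the weighted mean
(240/14 ≈ 17.14%) recognizes that six-sevenths of the examined bed sits on
the nearly tumor-free slide. Neither reaches MPR here, but near the 10%
cutoff the choice of basis can flip the label — which is why both are always
reported. `write_report(fit)` emits the full JSON report;
`plan_sampling(5)` prints the sampling instructions for a 5 cm bed:

```
Sampling plan for 5 cm tumor bed
  submit: 50% of tumor bed, alternate sections (>= 5 sections)
  if no viable tumor in initial sections: examine remaining bed completely to confirm pCR
```

A thin command-line front end with subcommands `compute`, `validate`,
`plan`, `simulate`, `agree` and `rules` is installed at
`inst/cli/mprct.R`.

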