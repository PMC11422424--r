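# emadtw

Subgrouping participants of ecological momentary assessment (EMA) studies
by the temporal course of their psychotic-symptom ratings.

EMA prompts participants several times a day to rate momentary experiences
— here five psychotic-symptom items ("I hear voices", "I see things", "I
feel that others dislike me", "I feel suspicious", "I feel that others
intend to harm me") on a 1–7 Likert scale over seven days. The package
turns these irregular, incomplete beep-level ratings into per-person
symptom trajectories and asks, without using diagnostic labels, whether the
cohort splits into stable trajectory subgroups:

1. ratings are harmonized onto a 7 × 6 grid of daily two-hour slots
   (within-slot duplicates averaged; participants answering < 1/3 of beeps
   excluded);
2. the grid is completed by iterative random-forest imputation (per item,
   sweeps stop when the relative change over imputed cells starts to
   increase) and the five items are averaged into a composite trajectory;
3. trajectories are compared pairwise by dynamic time warping under a
   Sakoe–Chiba band |i−j| ≤ w (w = 2, 4, 8, 16) with the symmetric step
   pattern g(i,j) = min(g(i−1,j−1) + 2d, g(i−1,j) + d, g(i,j−1) + d),
   d = |x_i − y_j|;
4. the distance matrix is clustered by Ward.D2 and by k-means on its rows
   for k = 2..10;
5. cluster stability is measured by reclustering B = 1000 random 50%
   subsamples and averaging best-match Jaccard indices per cluster; the
   smallest k whose clusters all exceed 0.85 is selected;
6. the resulting subgroups are characterized with Welch t-tests, one-way
   ANOVA and Pearson chi-square tests, with Benjamini–Hochberg FDR applied
   within variable families.

A synthetic-cohort generator with a planted latent high-symptom class
(concentrated among patients) makes every stage testable without access to
study data.

## Worked example

```r
library(emadtw)

sim <- simulate_ema_cohort(cohort_spec(seed = 1))   # 25 HC / 20 RE / 55 PD
fit <- ema_clust(sim$records, windows = c(2, 4, 8, 16), B = 200, seed = 1)
print(fit)
#> EMA symptom-trajectory clustering (banded DTW)
#>   participants: 100 (excluded: 0)
#>   windows: 2, 4, 8, 16; primary window: 2
#>   selected k = 2 (hierarchical), cluster sizes: 86/14
#>   selected k per window: 2, 2, 2, 2
```

The fit selects a two-cluster solution at every band width: a small
high-symptom cluster (here 14 participants, mostly patients) against a
large low-symptom cluster. `summary(fit)` adds the study-group composition
by cluster with its chi-square, the mean composite rating per cluster with
a Welch t-test, and the corrected rating variance (trajectory variance
divided by its mean); `plot(fit, type = "stability")` draws the minimum
clusterwise Jaccard against k for both algorithms with the 0.85 threshold.
Against the generator's planted classes this solution has adjusted Rand
index 1.0 (`adjusted_rand_index()`).

Lower-level entry points (`build_slot_grids()`, `rf_impute()`,
`pairwise_dtw()`, `clusterwise_stability()`, `characterize_clusters()`, ...)
expose each stage separately, and `run_pipeline(ema_config(...), out_dir)`
writes all intermediates plus a manifest.

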