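# batchbench

Batch effects — systematic, non-biological variation shared by microarray
samples processed at the same site over a short period — can rival or exceed
the biological signal in gene-expression studies. Several adjustment
algorithms exist, each with a different model of what a "batch" does to the
data. **batchbench** is a simulation-based benchmarking framework for
comparing them: it generates log2 expression matrices with *known* batch
effects and differential expression, applies five adjustment algorithms, and
scores every one with the same panel of variance-attribution, precision,
accuracy and overall-performance metrics. It is aimed at analysts deciding
which adjustment to trust for a multi-batch expression study, and at
methodologists who want a controlled test bed with full ground truth.

## The model

Data are simulated under a location/scale (L/S) batch model. For gene *g*,
sample *j* in batch *i*:

```
Y_ijg = alpha_g + X_j * beta_g + gamma_ig + delta_ig * eps_jg,   eps_jg ~ N(0, sigma_g^2)
```

* `alpha_g` — baseline log2 expression, drawn N(7, 2²) across genes;
* `beta_g` — group effect, i.e. the nominal log2 fold change;
* `gamma_ig ~ N(0, gamma_sd²)` — additive batch effect (location shift);
* `delta_ig² ~ InverseGamma(8, 8.05)` — multiplicative batch effect
  (noise rescaling, mean delta² ≈ 1.15);
* `sigma_g` — per-gene noise, set so a two-sample test on batch-free data
  sees each DE gene at about 3.3 standard errors.

Three study designs are built on this engine:

* **VAS** (variation assessment): 100 samples (65 Profile 1 / 35 Profile 2),
  1000 genes all DE, generated twice as technical duplicates — once in a
  single batch, once split over two batches.
* **AAS** (accuracy assessment): 10,000 genes in 100 cases and 100 controls;
  exactly 1,200 DE genes, 100 at each of the 12 nominal log2 fold changes
  ±{0.14, 0.26, 0.58, 1, 1.32, 1.58}; batches with reversed case/control
  imbalance.
* **Confounded**: the AAS design with all cases in one batch and all
  controls in the other — the design no adjustment can rescue.

The adjustment methods are gene-wise per-batch mean-centering
(`mean_center`), geometric ratio-to-reference scaling (`ratio_g`),
parametric and non-parametric empirical-Bayes location/scale adjustment
(`combat`), and surrogate-variable adjustment by residual SVD with a
permutation stopping rule (`sva_adjust`). Scoring uses principal variance
component analysis (`pvca`), per-gene replicate Pearson/ICC correlations
with Fisher z, fold-change Spearman r² and signal-detection slope, per-gene
Welch tests with Benjamini–Hochberg correction, ROC-AUC with a paired
DeLong comparison, and the Matthews correlation coefficient.

## Worked example

```r
library(batchbench)
sim <- simulate_aas(seed = 1)
sim
#> Accuracy-assessment simulation: 10000 genes x 200 samples; 1200 DE genes over 12 log2 fold-change levels
#>   batches: B1 40, B2 40, B3 40, B4 40, B5 40

report <- run_benchmark("aas", methods = c("unadjusted", "mean_center",
                                           "ratio_g", "combat_p"), seed = 1)
report
#> Batch-adjustment benchmark -- aas design, seed 1
#>       method pvca_batch_fraction fc_r2 slope   auc   mcc note
#>   unadjusted            3.57e-01 0.925 1.010 0.871 0.526
#>  mean_center            1.00e-03 0.943 0.905 0.962 0.610
#>      ratio_g            6.15e-04 0.935 1.010 0.952 0.684
#>     combat_p            4.15e-10 0.947 1.000 0.967 0.740
```

Reading the rows: before adjustment, batch explains ~36% of the overall
variance (PVCA) and the Welch-test ranking separates DE from null genes
with AUC 0.871. Every method removes essentially all batch-attributable
variance, but they differ elsewhere: mean-centering attenuates fold changes
(slope 0.905) because in batches with imbalanced case/control ratios part
of the biological signal sits in the batch means it subtracts; the
empirical-Bayes adjustment removes the batch effect while protecting the
group signal and gives the best AUC and MCC.

```r
pvca(simulate_vas(seed = 1)$expr_batched, simulate_vas(seed = 1)$sheet)
#> PVCA:34PCs retained (60.2% of overall variance, threshold 60%)
#>   resid                  56.0%
#>   batch                  29.8%
#>   group                  14.2%
#>   batch:group             0.0%
```

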