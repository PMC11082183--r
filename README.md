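# phosphonet

Signaling-network dissection and kinase/phosphatase activity inference from
sparse phosphoproteomic data.

Bottom-up phosphoproteomics yields a phosphopeptide × sample log2-abundance
matrix riddled with value-dependent missingness: peptides below their limit
of detection (LOD) simply vanish. phosphonet is for computational biologists
who want to turn such a matrix into (a) a de-novo kinase/phosphatase
(KP-enzyme) → substrate network and (b) per-sample enzyme activity scores,
without external training data.

## The method in brief

* **hpMI** — mutual information between two censored rank profiles is
  estimated by a hybrid partition: the sample plane is split into four
  quadrants by joint observedness, the 2×2 observed/missing table
  contributes its plug-in MI (missingness is informative under LOD
  censoring), and the jointly observed points contribute their
  adaptive-partitioning MI weighted by n11/N — an exact chain-rule
  decomposition, so complete data reduce to ordinary adaptive-partitioning
  MI. Significance comes from a row-permutation null (missing values
  permuted along with values) with Šidák family-wise control,
  `1 − (1 − α)^(1/m)`, and an exponential tail fit.
* **stDPI** — indirect edges are pruned by the data processing inequality,
  restricted to information triangles whose intermediary is a kinase: a
  path through a phosphatase inverts the sign of the effect on the
  substrate, so those triangles cannot explain a sign-consistent edge.
* **Bootstrap consensus** — 200 run-resampled networks are combined; each
  edge's support k is scored by the upper-tail Poisson probability at the
  mean support rate, Benjamini–Hochberg adjusted.
* **Signalons** — each regulator's substrate set with probabilistic weights
  (MI / network max, optionally prior-weighted), a mode-of-regulation sign
  from a three-Gaussian mixture over Spearman correlations, trimming by
  cumulative squared normalized weight (cap 500), and a minimum size of 5.
* **mNES** — per-sample differential signatures (row-min + noise
  imputation, z vs a reference set, normal-quantile ranks) are scored by a
  calibrated two-part rank-enrichment z-statistic; crosstalk between
  signalons sharing substrates is corrected via
  `CDE = log10(pB) − log10(pA)` penalized by `CDE^(CI/NT)` (CI = 20);
  phosphostate- and activity-level passes are integrated by Stouffer's
  method, `z = (z_PL + z_AL)/√2`.

A fully seeded synthetic-data generator (`simulatePhospho()`,
`simulatePerturbation()`) with known ground truth makes every stage
testable offline; `recoveryReport()` and `prRoc()` score results against
the truth.

## Worked example

```r
library(phosphonet)

sim  <- simulatePhospho(simConfig(nSamples = 150, seed = 7))
sim$phospho
#> PhosphoSet: 328 sites x 150 runs, 60.0% observed

spec <- candidateSpec(kinases = sim$truth$kinases,
                      phosphatases = sim$truth$phosphatases)
net  <- dissect(sim$phospho, spec, dpi = "stdpi", nBoot = 100, seed = 1)
head(net, 3)
#>          regulator            target         mi support       pvalue       rho
#> 1 KIN1:P00001:S100 SUB001:Q00001:S10 0.10531196      61 2.296687e-35 0.3487804
#> 2 KIN1:P00001:S100 SUB002:Q00002:S10 0.11402409      73 4.573692e-47 0.1136486
#> 3 KIN1:P00001:S100 SUB004:Q00004:S10 0.07645915      30 1.642895e-10 0.2891552

sl <- buildSignalons(net, seed = 1)
sl[[1]]
#> Signalon for KIN1:P00001:S100 [phosphostate:site, default]: 23 targets
#>   mode range [0.67, 1.00], max weight 0.638

am <- measureActivity(sim$phospho, sl, nullSize = 100, seed = 1)
round(nes(am)[1:4, 1:4], 2)
#>                  run001 run002 run003 run004
#> KIN1:P00001:S100   2.43  -0.64  -0.92   1.34
#> KIN2:P00002:S100  -0.88   1.17  -0.18  -0.53
#> KIN3:P00003:S100  -1.06  -0.31   0.11   0.75
#> KIN4:P00004:S100   0.17   2.18   0.92   0.27

recoveryReport(net, sim$truth, am)[c("precision", "recall",
                                     "medianActivitySpearman")]
#> $precision              [1] 0.983
#> $recall                 [1] 0.528
#> $medianActivitySpearman [1] 0.854
```

The consensus network recovers about half of the planted edges at 98%
precision on this 40%-censored cohort, and the per-sample NES track the
latent enzyme activities at a median Spearman correlation of 0.85. Positive
NES means the enzyme's substrate program is up in that sample relative to
the cohort centroid (increased activity for a kinase); the paired
`pvalue` assay holds two-tailed empirical p-values from the bootstrapped
null.

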