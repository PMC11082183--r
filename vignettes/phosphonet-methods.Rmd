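---
title: "Dissecting signaling networks and inferring enzyme activity from sparse phosphoproteomes"
author: "phosphonet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting signaling networks and inferring enzyme activity from sparse phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphonet)
```

## The problem

Bottom-up phosphoproteomics measures the abundance of phosphopeptides
across samples, but the quantities of biological interest are the
*activities* of the kinases and phosphatases (KP-enzymes) that write and
erase those phosphosites. phosphonet reconstructs KP-enzyme → substrate
networks de novo from a phosphopeptide abundance matrix and then infers
per-sample enzyme activity from the phosphorylation state of each enzyme's
inferred substrate set (its *signalon*, the signaling analog of a
transcription factor's regulon).

Two properties of phosphoproteomic data shape every design choice in the
package:

1. **Censoring.** Peptides below their limit of detection (LOD) are not
   observed. Missingness is therefore *value-dependent* (MNAR) and carries
   information: a peptide that disappears exactly when its kinase's
   phosphosite disappears is evidence of co-regulation, not a nuisance.
   Typical matrices are 20--80% missing.
2. **Sign structure.** Kinase abundance must correlate positively with
   substrate phosphorylation, phosphatase abundance negatively. This
   constrains both the candidate edge set and which information-theoretic
   pruning steps are biochemically valid.

## Mutual information under censoring (hpMI)

Edges are scored by mutual information between rank-transformed abundance
profiles. For complete pairs we use recursive adaptive partitioning of the
rank plane (`adaptivePartitionMI()`): a cell is split at its midpoint while
the chi-square statistic over its four sub-cells exceeds 7.815 (chi-square
with 3 df at alpha 0.05, the convention of adaptive-partitioning MI
estimators); each leaf contributes $(n_c/N)\log[(n_c/N)/(w_x w_y)]$ nats.

With missing values, the sample plane decomposes into four quadrants by
joint observedness. `hpMI()` combines them by the exact chain rule for
mutual information with "missing" as one marginal bin per axis:

$$\widehat{I}(X;Y) \;=\; I_{2\times2}(\text{observed/missing table})
  \;+\; \frac{n_{11}}{N}\, \widehat{I}_{AP}(X, Y \mid \text{both observed})$$

so that every term sits on the single $1/N$ probability scale and the
estimate reduces *exactly* to the adaptive-partitioning value when nothing
is missing. This combination rule is a design choice of this package: the
decomposition is the unique one that is additive in the quadrants and
consistent with the plug-in estimator; it is isolated in one function so the
convention can be swapped. The estimator is symmetric, nonnegative, and,
under co-censoring, strictly gains power over complete-case MI ("dMI") and
over low-intensity-noise imputation followed by complete MI ("iMI") — the
package's acceptance suite verifies this ordering on censored synthetic
cohorts.

**Significance.** The null is built by permuting each feature row of the
matrix *including its missing values*, preserving the missingness rate of
every feature. Family-wise control over $m$ candidate pairs converts the
FWER to a per-test level $1-(1-\alpha)^{1/m}$ (Šidák); because this level
is far below what raw permutation counts can resolve, the upper tail of the
pooled null is extrapolated with an exponential fit to its top 1%
(mean-excess estimate). `nullMIThreshold()` errors rather than guessing
when the pooled null is too small.

## Network dissection

`dissect()` runs the full pipeline: threshold selection, `nBoot` bootstrap
rounds (runs resampled with replacement; per-round seeds derived from the
master seed and the round index, so results are order-independent and
reproducible), per-round DPI pruning, and a Poisson consensus.

**DPI and stDPI.** In an information triangle $R_1\to R_2$, $R_2\to T$,
$R_1\to T$, the data processing inequality removes $R_1 \to T$ when its MI
is the strict minimum (additive `tolerance`, default 0). The
signal-transduction variant (stDPI) only assesses triangles whose
intermediary is a **kinase**: a path through a phosphatase inverts the sign
of the effect on the substrate, so kinase-phosphatase-substrate and
phosphatase-phosphatase-substrate triangles cannot represent a sign-
consistent indirect route and are never pruned. stDPI therefore always
retains a superset of plain DPI's edges; the advantage materializes in
incoherent feed-forward motifs (a kinase that activates a phosphatase while
both directly regulate shared substrates — e.g. a kinase inducing its own
negative regulator), where plain DPI deletes genuine direct edges. Note a
feasibility fact that the synthetic benchmark respects: a sign-consistent
phosphatase-intermediary triangle with pairwise correlations
$(+r_{KP}, +r_{KS}, -r_{PS})$ requires a positive-semidefinite correlation
matrix, which caps all three magnitudes near 0.5; such triangles therefore
live in the mid-range of the edge-strength spectrum.

**Consensus.** Each edge's bootstrap support $k$ is scored by the
upper-tail Poisson probability with rate $\lambda$ equal to the mean
support over all edges ever detected, then Benjamini--Hochberg adjusted at
alpha 0.05. This rate convention follows adaptive-partitioning network
tools; it presumes the candidate space contains many weakly supported
edges (true in any genome-scale run; degenerate candidate lists of only
strong edges should be scored with decoys).

Candidate restriction supports three modes: a plain enzyme list, a signed
enzyme list (kinase edges must have positive Spearman correlation on
jointly observed points, phosphatase edges negative; enforced at
consensus), and a reference network with optional per-edge priors in
$[0,1]$.

## Signalons

`buildSignalons()` converts the consensus network into per-regulator target
sets:

* **Weight**: MI normalized by the maximum MI across the entire network;
  optional priors are normalized by the per-regulator maximum prior and
  multiplied in (a zero prior drops the target).
* **Mode of regulation**: a three-component Gaussian mixture over all
  network Spearman correlations, components representing repressed,
  non-monotone, and activated targets. The middle component's mean is
  pinned at 0 and the outer means are sign-constrained; this keeps the
  components identifiable when one enzyme class dominates the network.
  The fit is seeded EM with 10 restarts (best log-likelihood wins, ties by
  restart index); with fewer than 10 correlations the mixture is unstable
  and a linear ramp $\mathrm{sign}(\rho)\min(1,|\rho|/0.5)$ is used
  instead. The mode is the posterior activated-minus-repressed
  probability.
* **Trimming**: targets sorted by weight accumulate
  $s_k=\sum_{i\le k}(w_i/w_1)^2$ until a stopping threshold (default 50)
  is reached, hard-capped at 500 substrates. The threshold form treats the
  published trimming sum as a stopping rule on the cumulative squared
  normalized weights; this reading is configurable (`tTarget`) because the
  published description leaves the role of the constant open.
* **Minimum size**: signalons with fewer than `M = 5` substrates are
  excluded from inference. Activity-level networks over a handful of
  regulators can never reach 5 targets, so `hierarchicalMeasure()` exposes
  `alMinSize` for small systems; genome-scale runs keep the default.

`optimizeSignalons()` picks, per regulator, the candidate signalon (across
datasets/sites/priors) with the highest **median** absolute NES over a
signature ensemble — a single winner per regulator keeps downstream
bookkeeping simple, and an incorrect signalon can only lower the
enrichment. `deduplicateSignalons()` removes redundant site-level signalons
of one phosphopeptide by greedily dropping the signalon with the largest
mean absolute activity correlation until no pair exceeds the cutoff
(default 0.5).

## Activity inference

A per-sample **signature** is the z-statistic of the sample against a
reference set, computed feature-wise after imputing missing entries as the
row minimum plus uniform noise whose range is the gap between the two
lowest observed values (ties broken by the noise), then rank-mapped through
the normal quantile function. Because the signature is rank-based, a large
coordinated shift of one enzyme's targets slightly depresses the scores of
everything else (a compositional effect shared by all rank-enrichment
methods); the crosstalk simulation below is designed with enough features
that this drift stays small.

**Enrichment.** `enrichmentNES()` uses a two-part rank statistic: a
directional component $S_1=\sum_i w_i\,\mathrm{mode}_i\,q^{(2)}_i$ over
two-tailed normal quantiles and a magnitude component
$S_2=\sum_i w_i(1-|\mathrm{mode}_i|)\,q^{(1)}_i$ over one-tailed quantiles
of the absolute scores, folded together as
$\mathrm{ES}=\mathrm{sign}(S_1)(|S_1|+S_2^+)$. The two quantile maps are
uncorrelated under the null (one is odd, the other even in the signature
score), giving the exact null standard deviation
$\sqrt{s_1^2+\tfrac{2}{\pi}s_1 s_2+\tfrac{1}{2}s_2^2}$ used to scale ES to
a z-score; when modes are near $\pm1$ (the usual case) the statistic is
exactly standard normal under target permutation, and the acceptance suite
checks Kolmogorov–Smirnov agreement with N(0,1) at $\alpha=0.01$ over 1000
null draws. Negating all modes negates the NES exactly.

**Empirical null.** With `nullSize > 0`, reference runs are resampled into
null signatures; each regulator's NES is rescaled by its null mean and
standard deviation and a two-tailed empirical p-value with floor $2/(B+1)$
is attached.

**Crosstalk correction.** For every ordered pair of regulators sharing
targets, both significant in a sample (p < 0.05), the weaker signalon's
shared-target weights are multiplied by
$\min(1, \mathrm{CDE}^{CI/NT}/\mathrm{CDE}_{\max})$ where
$\mathrm{CDE}=\log_{10}p_B-\log_{10}p_A \ge 0$, $CI=20$, $NT$ is the number
of pairs the signalon participates in, and $\mathrm{CDE}_{\max}$ is the
sample's largest CDE (defined as full nullification when all CDEs are 0,
matching the equal-p limit). Ties in p (e.g. both regulators at the
empirical-null floor) are broken by $|NES|$. The mapping from the penalized
quantity onto target weights is a documented design choice of this package;
note that with analytically unbounded p-values the factor saturates at 1
once the two significance levels differ by more than an order of
magnitude, so the correction is most active under the bootstrapped null
model, whose p-value floor keeps CDE small — the recommended configuration.

**Hierarchical two-level inference.** `hierarchicalMeasure()` first infers
phosphostate-level (PL) activities for every run, then dissects an
activity-level (AL) network from the PL activity matrix using **plain DPI**
(the second pass abstracts the system functionally, where the
phosphatase-intermediary argument no longer applies), infers AL activities,
and integrates the two levels by Stouffer's method,
$z=(z_{PL}+z_{AL})/\sqrt2$, with equal weights and a fall-back to the
single available level. The AL pass is what rescues enzymes whose own
phosphopeptides are not measured (classically tyrosine kinases): given a
whole-protein abundance row as a weak proxy, the enzyme's downstream
kinases' PL activities carry most of the recoverable signal.

## The synthetic-data generator

`simulatePhospho()` draws latent enzyme activities (standard normal around
a basal level of 1), builds substrate log2 intensities as signed scaled
sums of parent activities plus Gaussian noise — the scale chosen so a
planted edge's expected Spearman correlation equals `effectRho`, via
$r = 2\sin(\pi\rho/6)$ — and censors each feature below the `lodQuantile`
of its marginal (value-dependent MNAR by construction). Optional structure:
regulatory chains/trees with per-link strength, incoherent co-regulation
for kinase-parent/phosphatase-child links, per-substrate effect-size
spread, batch mean-shifts, whole-protein (`PA`) proxy rows for enzymes
whose phosphopeptides are censored out, and a perturbation time-series
generator with matched vehicle controls and an optional adaptive rebound.
Fixed seeds give bit-identical output, and perturbed and control series
share all noise draws, so they differ only through the intervention.

What the generator does **not** emulate: peptide-level identification
errors, retention-time or ratio-compression artifacts, nonlinear
saturation, correlated noise across substrates, and shared-peptide
ambiguity. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not performance on any
particular instrument's output.

## Simulation-study conditions

The test suite and `scripts/acceptance.R` use these fixed conditions,
chosen once as representative of the regimes the method targets:

* **Default cohort** (end-to-end recovery): 150 samples, 5 kinases + 3
  phosphatases, 40 substrates each, effect strength 0.5, 40% censoring.
* **Weak-edge censoring benchmark** (estimator ordering): effect 0.3, 80%
  censoring, 300 samples, the regime the hybrid estimator is designed for.
* **Chain benchmark** (DPI correctness): two chained kinases at strength
  0.9, 10% censoring, 200 samples.
* **Mixed-network PR benchmark** (stDPI vs DPI vs noDPI): 2 kinases + 6
  phosphatases with a two-level tree, incoherent co-regulation near the
  correlation-feasibility limit (loadings 21/22.5 at base effect 0.35 with
  spread 0.15), kinase-kinase links at 0.9, kinase-phosphatase links at
  0.53, 25% censoring, 400 samples; precision read at 25% recall, median
  of 10 replicates, edges ranked by bootstrap support plus MI.
* **Crosstalk pair**: 400 features, 30 reference runs, the active
  regulator's 40 targets shifted by 2.5, the inactive one sharing 20 of
  them plus 10 null targets, bootstrapped null of size 60.
* **Proxy-rescue cohort**: 8 kinases, a 5-child hierarchy under the first
  kinase whose phosphopeptide is removed and replaced by a protein-
  abundance proxy at correlation 0.85, chain strength 0.75.

Bootstrap counts in the simulation studies (30–60) are smaller than the
production default (200) because the studies average over replicates; the
default is kept for single-dataset analyses.

## Numerical choices and degenerate inputs

* MI is reported in nats; ties receive midranks; constant vectors give MI 0
  with a warning; all-missing vectors are an error; fewer than 4 jointly
  observed points zero the quadrant-1 term.
* Quantile normalization is missingness-aware (observed values only, tied
  quantiles averaged) and is followed by row-centering over observed
  entries; centering is row-wise because the downstream estimators are
  row-rank-based, so column-centering would be a no-op for them.
* Protein normalization keeps the phospho value where the protein value is
  missing, so already-sparse rows are not destroyed; unmatched sites pass
  through with a reported count.
* Precision with zero predicted edges is reported as missing, not 0 or 1.
* All stochastic steps consume explicit seeds; a fixed seed yields
  byte-identical network and activity exports.

## Known limitations

* The Poisson consensus rate degenerates when the candidate list contains
  only saturated edges (every candidate in every bootstrap); genome-scale
  candidate spaces avoid this automatically.
* The crosstalk weight mapping saturates for widely separated analytic
  p-values (see above).
* The AL pass can only recover regulators that have at least some proxy
  row at the PL stage; a regulator invisible at PL stays invisible.
* The mixture-based mode of regulation assumes the network's correlation
  distribution is a mixture of a near-zero and two displaced components;
  heavily attenuated correlations (strong censoring) shrink all components
  toward zero and flatten the modes.
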