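---
title: "Models and methods behind atacmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atacmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical models the package implements, the
choices made where the procedures leave room, and what the synthetic
generators do and do not emulate. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` compute themselves.

## 1. Per-nucleus quality control

A droplet-based single-nucleus ATAC-seq library assigns Tn5 fragments to
barcodes; a barcode is worth keeping only if its fragments look like they
came from one intact nucleus. Three families of filters are implemented.

**TSS enrichment.** Open chromatin concentrates at transcription start
sites. `tss_metrics()` counts, per nucleus, fragments overlapping any
TSS ± 1 kb window (default pass: ≥ 1,000), the fraction of such fragments
(typical thresholds 7.5% or 15% depending on library quality, hence the
per-sample threshold support in `qc_thresholds()`), and the ratio of per-bp
Tn5 insertion rates near versus far from TSS. Each fragment contributes two
insertions — its two ends. The near window is [TSS − 25, TSS + 25] (51 bp)
and the far window the two flanks at 1,900–2,000 bp (202 bp in total); both
counts are divided by their window widths so the ratio is scale-free, and
nuclei pass at ratio ≥ 4. When the far window is empty but the near window
is not, the ratio is reported at a cap of 10⁶ rather than infinity.

**Chromosome deviation.** The fraction of a nucleus's fragments on each
chromosome should track chromosome length. Free DNA from lysed nuclei
contaminating a droplet breaks this. The nuclei × chromosome proportion
matrix is column-standardized and the score is the row sum of absolute
z-values; nuclei at score ≥ 40 are removed. With a rat-like karyotype
(21 chromosomes informing the synthetic genome default), a nucleus sitting
2 SD off on ~20 chromosomes hits the threshold. A zero-SD column is
uninformative about contamination and contributes 0 — the alternative
(dropping the column) would make scores incomparable across cohorts.

**Fragment-size periodicity.** Nucleosome-bound DNA shelters ~147 bp, so
healthy libraries show a ~200 bp periodicity in fragment sizes.
`fragment_size_spectrum()` histograms sizes on 1-bp bins over [1, 1000],
mean-subtracts, and scores each nucleus by the periodogram power at periods
of 100–300 bp *as a share of total spectral power*. The relative form is
deliberate: the absolute band power of any sharp feature of the size
distribution (e.g. a single narrow peak) is large regardless of
periodicity, whereas the band share is maximal (1) for a pure 200-bp-period
comb and small for localized spikes. It is also invariant to scaling all
counts, so sequencing depth does not leak into the score. Nuclei in the
within-sample tails are flagged by a rank rule — the ⌈αn⌉ smallest and
largest scores at α = 0.01 — which removes exactly one nucleus per tail per
100 nuclei and avoids interpolation ambiguities of percentile definitions.

Doublet calls and ploidy classes (e.g. an 8n multiplet class) are upstream
inputs, not computations; `apply_qc_filters()` honours them as extra
boolean removal columns. All filters are conjunctive, so their order is
irrelevant.

## 2. LSI embedding and two-pass clustering

The binary site × nucleus matrix *f* is treated as a term–document matrix.
Weights:

* IDF per site: $g_i = \log_2(n / \sum_j f_{ij})$ — rarely open sites are
  informative;
* site filter: keep sites with IDF-weighted variance
  $g_i^2 p_i (1-p_i) > $ threshold (0.4 for 500-bp tiles, 0.1 for peaks;
  the variance of a weighted Bernoulli row, bounded by 1);
* document norm per nucleus: $d_j = 1/\sum_i f_{ij}^2$, i.e. the
  reciprocal open-site count for binary data. The conventional LSI norm is
  the reciprocal *L2* norm ($1/\sqrt{\cdot}$); both are supported
  (`document_norm(norm = "l2")`) and the reciprocal-count form is the
  default. Which is scientifically right is not settled; for binary data
  the difference is a per-nucleus power of the open-site count that the
  subsequent row-centring and SVD largely absorb.

**Batch correction.** Library conditions (notably the Tn5:DNA ratio) shift
the average normalized accessibility of a site between samples. For
nucleus *j* of sample *s*, the factor on site *i* is the ratio of the mean
of $d \cdot f$ on site *i* over all nuclei to the mean over sample-*s*
nuclei; with coarse cell-type labels both means restrict to the nucleus's
type, which prevents composition differences between samples from
masquerading as batch effects. A zero denominator yields a factor of 1, and
each nucleus's factors are capped at Q3²/Q2 of their own quartiles — an
asymmetric cap that tolerates moderate up-scaling but stops the inflation a
near-zero denominator would cause.

**Two passes.** Since cell types are unknown at first, the pipeline runs:
sample-only correction → 30-component SVD → outlier removal on the top-2
coordinates (sum of squared distances to the 5 nearest neighbours, flagging
above the 99.5th percentile — the procedure defines the score; the
percentile is our conservative default since no threshold is canonical) →
re-embedding at 10 components → SNN-Leiden clustering → agglomeration into
coarse clusters → cell-type-aware correction → re-embedding at 8
components → final clustering. The retained component counts (10 and 8) are
defaults observed to sit past the noise floor in data of this kind and are
configurable. Coarse agglomeration merges fine clusters whose top-2
centroid distance is below a configurable fraction (default 0.25) of the
global coordinate spread; a manual override map is accepted because the
coarse level is ultimately a judgement call.

The SNN graph uses k = 20 nearest neighbours, Jaccard edge weights, and
pruning below 1/15; Leiden optimizes modularity at resolution 1. All are
configurable. One behaviour worth knowing: Leiden never merges communities
across disconnected graph components, so the resolution → 0 limit yields
one cluster per connected component, not one cluster overall. Cell-type
assignment scores each cluster by the mean standardized accessibility of
marker-gene panels (a liver panel ships as the default) and labels a
cluster "ambiguous" when the top two types are within 10⁻⁹.

## 3. Reference-based deconvolution

Indices: *i* peaks, *j* cell types, *k* samples. From QC-passed nuclei,
pseudo-bulk counts $u_{ijk}$ over $a_{jk}$ nuclei are quantile normalized —
jointly, with the reference distribution (mean of sorted vectors) stored so
bulk samples, even singletons, can later be mapped to the same scale.
Tied values receive the mean of the reference values across their rank
span, which preserves column totals exactly. Because quantile normalization
is nonlinear, the nuclei content of a normalized library is tracked as
$b_{jk} = (\sum_i v_{ijk}/\sum_i u_{ijk}) a_{jk}$ and factorized as
$b_{jk} \approx c_j d_k$ by OLS on $\log b$ (identified by $d_1 = 1$).

**Ploidy.** A cell type with doubled DNA content (tetraploid hepatocytes
being the motivating case) emits twice the counts per nucleus, so its
fitted $c_j$ comes out at roughly *half* the level of a diploid type — the
synthetic validation asserts exactly this. `factorize_b()` also exposes an
explicit per-type divisor for workflows that prefer to encode the
adjustment manually; applying it on top of data that already carry the
ploidy effect would double-count, so it is off by default.

**Marker peaks and the reference.** Per type, peaks are ranked by Welch
t-statistics of that type's samples against the rest (fold-change ranking
as fallback under two samples); for each candidate per-type count *m* in a
grid (default 20–200 by 20 — the grid is explicit because the upstream
tool's internal bounds are not public), the pooled signature's condition
number is computed and the minimizing set kept. The signature is
$w_{ij} = \text{mean}_k \tilde v_{ijk}$ with per-peak error variance
$e_i^2 = \text{mean}_j \text{var}_k$, capped into [Q1²/Q2, Q3²/Q2] for use
as regression weights (the uncapped copy is retained).

**Platform factors.** For samples assayed on both platforms, the
single-nucleus side predicts the one-nucleus mixture
$x_k = \sum_j \frac{a_{jk}}{\sum_{j'} a_{j'k}} \frac{1}{c_j} w_j$, and
$f_i = \exp(\text{mean}_k \log (y_{ik}/x_{ik}))$ captures the per-peak
measurement distortion between platforms, capped like $e^2$ to avoid
overcorrection. Non-positive pairs are excluded pairwise; peaks with no
usable pair get $f_i = 1$.

**Estimation.** $F^{-1}y_k = W\theta_k + \varepsilon$,
$\varepsilon_i \sim N(0, e_i^2\sigma^2)$, solved by Huber M-estimation
(tuning constant 1.345, MAD scale; bisquare and an NNLS variant are
available) with weights $1/e_i^2$; all-zero $e^2$ means equal weights, and
a numerically exact fit short-circuits to weighted OLS because a zero MAD
scale would stall the M-estimator. Negative coefficients are clamped to
zero after fitting, as the procedure prescribes — not via constrained
least squares — and the composition is $C\hat\theta / \sum_j c_j
\hat\theta_{jk}$. Conditions are compared per cell type by OLS on condition
indicators with the Bonferroni threshold $0.05/(\text{types} \times
\text{non-reference conditions})$.

**Bulk normalization modes.** Whether bulk vectors should be quantile
normalized to the stored pseudo-bulk reference or independently is
genuinely open; the package normalizes to the stored reference by default.
A `"scale"` mode (linear total-mass matching) exists because quantile
normalization of a *mixture* against *pure-type* references is inherently
nonlinear: no parameter setting can make the default chain exactly linear,
so exact-recovery checks of the regression machinery use the linear mode.

## 4. Activity matrices

Gene scores count Tn5 insertions (both fragment ends) in the gene body
± 2 kb, unweighted — deliberately simpler than distance-decay models, since
only "gene body and vicinity" is well supported and the window is
configurable. The processing chain is fixed in order: median library-size
scaling; kNN smoothing of zeros in 10-dimensional PCA space (k = 15) with a
floor of 0.001; removal of genes at the floor in ≥ 1% of nuclei; log₂;
quantile normalization; subtraction of the rank-2 SVD approximation, which
absorbs the dominant sample batch signal (and unavoidably some cell-type
signal — acceptable because downstream comparisons are within cell type).

Motif deviations follow the accessibility-deviation idea: the observed
count of open motif-carrying peaks per nucleus versus its expectation under
the nucleus depth and peak popularity, standardized against 50 random peak
sets matched on accessibility deciles (GC matching is not performed; motif
matches are an input, not a computation). The z-matrix then receives the
same quantile + SVD-subtraction treatment as the gene scores, in that
order.

Differential activity uses the continuity-corrected normal approximation of
the Wilcoxon rank-sum statistic with tie correction — a deliberately robust
stand-in, since imputed activity scores are far from normal. The gene-set
test is a sample-permutation procedure: per gene a moderated |t| (pooled
variance shrunk toward the mean with 4 prior degrees of freedom), per set
the mean of weighted member |t| with the overlap down-weight
$w_g = 1 + \sqrt{(\max f - f_g)/(\max f - \min f)}$, and a permutation
count of max(10,000 × scale, 20 × number of sets). The `scale` argument
trades permutation resolution for runtime; tests use scaled-down counts and
state so here rather than in the test names.

## 5. TF regulation modules

For each gene, a regression random forest (ranger backend, 100 trees by
default, √p candidate predictors per split) predicts its activity from all
TF deviations plus condition indicator rows. Importance is the per-predictor
total variance reduction, floored at zero and normalized so the per-gene
column sums to the forest's out-of-bag R² (floored at zero) — making the
entries interpretable as shares of explained variance. The test suite pins
these semantics with an oracle that walks every stored tree with its in-bag
counts and re-sums the split variance reductions. Condition rows
participate in the factorization (they are part of the printed matrix) but
are excluded from membership reporting and gene-set universes.

The matrix is factorized by multiplicative updates minimizing generalized
KL divergence (the Brunet variant), compiled in C++ because rank sweeps
with 100 restarts dominate runtime. Convergence: relative objective change
below 10⁻⁶ (checked every 10 iterations) or 2,000 iterations. Rank
selection fits a consecutive grid (default 2–10, 20 reduced starts) and
takes the *inflection* of the residual curve, operationalized as the
maximum discrete second difference of the **log** residuals — equivalently
the rank after which the relative improvement collapses. The raw-scale
second difference is dominated by the curve's overall level and picks the
steepest early segment rather than the elbow; the log form is scale-free
and selects the planted rank on block-structured data. Ties break toward
the smaller rank; a curve with no positive curvature returns the smallest
rank with a warning. Whether KL or Frobenius residuals define the curve is
not canonical; the fit objective (KL) is used.

Module membership reporting: regulators/genes ranked within the top 5 *and*
above half the module's top weight. Gene-set characterization uses Welch t
(member vs non-member weights) with a max-statistic gene-name permutation
null per module — 100 permutations, FWER-adjusted
p = (1 + #exceedances)/101, significance at < 0.05.

Split-half consistency halves the nuclei at random, recomputes the
importance matrix in each half, approximates each by NMF at the chosen
rank, and correlates the two approximations; the noise floor repeats this
five times with the gene-matrix nucleus labels permuted (motif matrix
intact). An importance matrix with no signal can come back all zero; its
consistency is defined as 0.

## 6. Gene-set activity and core genes

The activity of a gene set in single nuclei is the first right-singular
vector of the stack of standardized member rows (TF deviations over gene
scores; a symbol present in both matrices contributes both rows) — the
single-cell analogue of a pathway-level principal component. The singular
vector's sign is arbitrary; it is fixed by positive correlation with the
mean standardized member row, so the score reads as "activity of a
representative member". Significance permutes the TF-weight and gene-weight
vectors independently within their blocks (a joint mode exists behind a
flag, since the procedure wording is ambiguous) 100 times and compares
first singular values. Condition shifts are summarized by Mann–Whitney
AUROC with flags at 0.75 and 0.9 (and mirrored flags for decreases).

Core genes combine two signals: |correlation| of a symbol's row with the
activity score at a default threshold of 0.3 (the one printed correlation
threshold in the motivating analysis, configurable), and a total PPI score
to the set's members (self-edges excluded, absent symbols 0) within the top
5% across all scored symbols. The 5% boundary uses dense ranking — all
symbols tying the boundary value are included. Core symbols outside the set
are the novel candidates.

## 7. The synthetic generators

The generators define the study conditions for every test:

* `generate_fragments()` — a 21-chromosome genome with decreasing lengths
  and a TSS every 100 kb (the smallest structure exercising per-chromosome
  and TSS logic at a rat-like chromosome count); per nucleus ~2,000
  fragments with a configurable TSS-proximal fraction (default 0.5);
  fragment sizes from a sub-nucleosomal exponential plus Gaussians at 200
  and 400 bp (periodic weight 0.5 by default); contaminated nuclei are
  planted at an exact count (round of the nominal fraction) with
  per-chromosome proportion shifts of ±3 multinomial SDs using balanced
  signs — unbalanced signs would be partially undone by the proportion
  renormalization, making the planted deviation smaller than declared.
* `generate_binary_matrix()` — per-type site-open profiles as a shared
  Beta(2, 20) baseline plus +0.3 on a 10% marker subset, per-sample
  log-normal depth multipliers (log-SD 0.3 by default), independent
  Bernoulli entries.
* `generate_mixture_experiment()` — per-peak base intensities
  Gamma(2, 0.02) shared across cell types with log-normal type modulation
  (log-SD 0.8). The shared base matters: real ATAC peak intensities are
  strongly correlated across cell types, and with fully independent
  profiles the bulk mixture's marginal distribution would differ in shape
  from the pure-type references, so quantile normalization would distort
  the mixture in a way real data does not show. True proportions are
  Dirichlet(1), realized as nucleus counts; bulk vectors carry log-normal
  platform factors (log-SD 0.3) and Poisson noise at ~20× one-nucleus
  depth. One cell type is double-ploidy (2× counts per nucleus). The
  noise-free mode returns expectations *and* draws the type profiles as
  permutations of one common multiset, which makes quantile normalization
  exactly linear on the pure types and enables machine-precision recovery
  tests.
* `generate_regulatory_dataset()` — per-nucleus latent module factors with
  condition-shifted means (effect 1 SD), TF/gene rows as loading × factor +
  N(0, 0.5), gene sets covering 60% of each module's genes plus 20%
  decoys, matched-size decoy sets, and PPI scores ~0.9 within modules
  versus ~0.05 background.
* `simulate_regulator_matrix()` — a planted block nonnegative matrix for
  factorization tests that do not need the random-forest stage.

What the generators do **not** emulate: sequence content (no reads, no
motif scanning), doublets beyond a labelled flag, fragment-level
overdispersion, spatially structured peaks, or realistic gene-set overlap
topology. Passing tests therefore demonstrate correctness of the
estimators under the stated noise families — Poisson counts, log-normal
multiplicative distortions, Gaussian residuals — not robustness to every
artefact of real libraries.

## 8. Problem sizes, tolerances, determinism

The test suite runs the pipelines at desk scale, chosen as the smallest
sizes at which the checked properties are statistically stable: clustering
at ~800–1,000 nuclei × ~1,200 tiles; deconvolution at 1,000 peaks × 7
types × 5 samples (the acceptance script averages 10 simulations);
rank-selection recovery over 20 replicates of 50 TFs × 300 genes with 3
starts per rank; error-control checks over 20 replicates with 100–1,000
permutations; split-half consistency at 30 TFs × 80 genes × 300 nuclei
with 40-tree forests. Machine-precision claims (oracle equivalence,
noise-free recovery) are asserted at 10⁻¹² and 10⁻⁶ respectively;
statistical claims use the margins stated in the tests.

Every stochastic routine takes an explicit seed; generators set the seed
from their config, and per-gene forest seeds derive from the base seed so
results are reproducible regardless of iteration order.

## 9. Known limitations

* The marker-peak selection reimplements the idea of t-test ranking under
  condition-number minimization with an explicit grid; it is not a
  re-implementation of any specific tool's internals.
* The kNN zero-imputation is a deliberate simplification of model-based
  imputation; its interface is pluggable.
* The DGE statistic (Wilcoxon z) is a documented choice, not a claim about
  how any particular published analysis computed theirs.
* Modularity-based Leiden clustering inherits the resolution limit: very
  large homogeneous clusters can split at resolution 1 (see Section 2).
* AUROC flags and core-gene calls are descriptive summaries, not
  inferential statements with error control.
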