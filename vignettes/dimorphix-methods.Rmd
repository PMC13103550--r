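---
title: "Methods: multi-omic sex-dimorphism analysis with dimorphix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic sex-dimorphism analysis with dimorphix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`dimorphix` analyses sex-dimorphic molecular signatures in case/control
cohorts profiled across several omic layers: region-summarized DNA
methylation (promoter and gene-body fractions), RNA-seq counts, and a
log2-scale protein panel (NPX units). The motivating application is systemic
lupus erythematosus (SLE), where disease is strongly female-biased but more
severe in males, and where aberrant expression of the X-inactivation lncRNA
XIST in male patients, together with X-chromosome hypermethylation and
X-linked transcript downregulation, suggests an XCI-like silencing process
in male immune cells.

The package provides five analysis layers and a synthetic-cohort generator
used to validate every one of them end to end:

1. **QC and normalization** — LOD-based protein filtering, low-expression
   sample exclusion, a count filter, log-CPM, quantile normalization,
   mean-variance precision weights, methylation region summarization, and a
   read-depth sex QC.
2. **Factorial differential analysis** — per-feature linear models with the
   coding (intercept, sex, disease, sex:disease), empirical-Bayes variance
   moderation, BH-FDR, and fold-change-gated significance calls.
3. **XIST bimodality** — Hartigan's dip statistic with a Monte-Carlo
   uniform-reference null, Sheather-Jones bandwidth selection, KDE trough
   thresholding into XIST-high/XIST-low, and a Brown-Forsythe variance
   comparison.
4. **Chromosome-level enrichment** — preranked GSEA against chromosome gene
   sets (with a pseudoautosomal "PAR" set), hypergeometric
   over-representation, X-linked fraction summaries and an XCI-panel
   silencing summary.
5. **Deconvolution and clinical screens** — TPM, NNLS/OLS reference-based
   proportions benchmarked against flow cytometry, interferon signature
   scoring, and Wilcoxon/chi-square/Spearman covariate screens with
   family-wise BH correction.

# The factorial model

For each feature $g$ the model is
$y_{gs} = \beta_0 + \beta_1\,\mathrm{male}_s + \beta_2\,\mathrm{SLE}_s +
\beta_3\,\mathrm{male}_s\,\mathrm{SLE}_s + \varepsilon_{gs}$, with
female = 0 / male = 1 and HC = 0 / SLE = 1. Under this coding,
$\beta_2$ is the female SLE−HC contrast, $\beta_2+\beta_3$ the male SLE−HC
contrast, and $\beta_3$ the sex-by-disease interaction
([male SLE − male HC] − [female SLE − female HC]), the quantity that
isolates disease effects that differ by sex after accounting for baseline
sex differences.

Residual variances are moderated with a scaled-inverse-chi-square prior
fitted by moment matching on $\log s^2_g$ (digamma/trigamma equations,
Newton inversion of the trigamma function). The moderated $t$ uses the
posterior variance $(d_0 s_0^2 + d_g s^2_g)/(d_0+d_g)$ on $d_0+d_g$ degrees
of freedom (capped at the pooled residual degrees of freedom when the prior
is effectively infinite, matching standard practice). $d_0 = 0$ reproduces
the ordinary $t$-test exactly — asserted to machine precision in the tests —
and the full pipeline is cross-checked against limma's empirical-Bayes fit.

Significance is called at FDR ≤ 0.1 and |FC| > 1.5 (i.e. |LFC| > log2 1.5).
**Methylation fold changes** are not defined on the fraction scale; region
fractions are clamped to $[10^{-4}, 1-10^{-4}]$ and logit-transformed, and
"LFC" for methylation means a logit-scale difference. A `methylation_scale`
config switch ("logit", default, vs "log2" of the fraction) isolates this
choice.

Subgroup contrasts within males (XIST-high vs HC, XIST-low vs HC, high vs
low) reuse the same machinery with a one-way three-level design; no new
mathematics.

# XIST bimodality and classification

The dip statistic is the sup-norm distance between the sample ECDF and the
closest unimodal distribution function, computed with the iterative greatest
convex minorant / least concave majorant algorithm on the sorted sample. It
is validated against a from-scratch linear-programming minimizer over
unimodal CDFs (convex piece, optional atom at the mode, concave piece; mode
at any data value or midpoint) for all sample sizes up to 8. The test's
p-value is Monte Carlo against uniform(0,1) reference samples (the classical
least-favourable unimodal null), $p = (1+\#\{D_0 \ge D\})/(n_{mc}+1)$.
Because the null depends only on $n$, `dipNullDistribution()` lets
replicate-heavy simulations share one null table; `dipTest()` draws a fresh
null otherwise.

Classification of male SLE samples uses a Gaussian KDE with the
Sheather-Jones solve-the-equation bandwidth (`stats::bw.SJ`, with a flagged
Silverman fallback if the fixed-point equation has no root) evaluated on a
fixed 512-point grid spanning the data range ± 3 bandwidths. The threshold
is the minimum of the density strictly between the leftmost and rightmost
strict local maxima — the literal global minimum of a KDE lies at the grid
boundary and cannot be the intended rule — with ties broken leftmost.
Samples missing qPCR are classified by an independently derived trough on
the RNA-seq values, and the source of each call is recorded. The qPCR and
RNA-seq thresholds are derived independently per source; whether they should
be derived jointly is not determined by the application, and independent
thresholds are the simpler, reproducible choice.

qPCR expression is normalized by the delta-delta-Ct convention:
$\Delta Ct = Ct_{XIST} - Ct_{GAPDH}$, relative expression
$2^{-(\Delta Ct - \overline{\Delta Ct}_{HC})}$ anchored at sex-matched
healthy controls, so an average control sample has relative expression 1.
The exact anchoring arithmetic is a documented choice; any strictly
monotone transform leaves the classification invariant (tested).

One caveat surfaced by the simulations: when an extreme outlier forms its
own small density bump beyond the high mode, the trough rule can place the
threshold between the high mode and the outlier bump and misclassify that
replicate. This is a property of the published rule, not of the
implementation; the classifier-recovery test averages over replicates and
the mean agreement stays above 95% under the study conditions.

# Chromosome-level enrichment

Genes map to gene sets "1".."22", "X", "Y", "MT" plus "PAR"; a gene is "PAR"
iff its TSS falls in a pseudoautosomal interval (GRCh38 PAR1/PAR2 by
default, configurable). TSS membership rather than span overlap is used
because a single unambiguous rule is preferable for set construction;
coordinates are 0-based half-open throughout, with the TSS of a − strand
gene at `end − 1`.

Preranked GSEA ranks features by LFC (ties by ascending p, then id), uses
the weighted running-sum statistic (hit increments $|s|^w$ normalized over
in-set scores, $w=1$ by default; miss decrements $1/(N-N_h)$), and a
gene-label permutation null: NES is ES over the mean |null ES| of the same
sign, p is the one-sided add-one permutation fraction, and FDR is BH across
the reported sets (simpler than the original GSEA FDR; documented). The
running-sum implementation is checked against a naive full-cumsum oracle
and against fgsea on random instances. Sign convention: with methylation
ranked by logit-scale LFC, positive NES means enriched hypermethylation;
for transcripts/proteins negative NES means enriched downregulation. The
convention is recorded in the scan output.

A note on negative controls: the gene-label permutation null assumes
exchangeable genes. When many features of one set carry a shared planted
effect, permuting *sample* labels leaves those features correlated — their
estimated LFCs all contain the same random group-imbalance term — so the
set still drifts coherently to one end of the ranking and single-modality
set significance under permuted labels occurs far more often than the
nominal level. This anticonservativeness under inter-gene correlation is a
well-known property of preranked GSEA. The package's negative control
therefore checks that label permutation abolishes the *detection event*
(positive NES with FDR ≤ 0.1 simultaneously in both methylation
modalities), which it does in ~95% of permuted replicates, rather than
expecting uniform single-set p-values.

# Deconvolution benchmark

Counts are TPM-normalized (`count/length`, rescaled per sample to $10^6$).
NNLS (Lawson-Hanson, via `pracma::lsqnonneg`) and OLS (negatives clipped,
raw coefficients retained) estimate per-sample cell-type weights against a
genes × cell-types reference on the shared-gene intersection; weights are
renormalized to proportions. The benchmark scores each (reference, method)
pair by the mean of the Pearson correlations of B-cell and NK-cell
proportions with flow cytometry, ties broken by the B-cell correlation —
an operationalization of "high concordance with B and NK proportions".
Other deconvolution algorithms (dtangle, SVR, quadratic programming,
robust regression) are deliberately out of scope; the
`proportionEstimate` structure is the plug-in interface.

In the recovery tests the generating reference competes against a
gene-shuffled panel and a heavily noised panel (elementwise
$2^{N(0,2)}$ factors). Mildly noised references that preserve the marker
structure deconvolve almost as well as the truth; no benchmark can — or
should — distinguish references that are statistically equivalent, so the
competitors are degraded beyond the benchmark's resolution, as genuinely
different reference panels are in practice. A shuffled reference often
yields constant (all-zero) estimates; such pairs are excluded from scoring
with a warning, mirroring how methods that fail to produce estimates are
dropped from real benchmark grids.

# The synthetic cohort generator

`simulateCohort()` emulates the study conditions: a 679/77/41/7
female-SLE / female-HC / male-SLE / male-HC cohort; an XIST-like X-linked
transcript that is bimodal in male SLE with $\pi_{high} = 0.54$ of males in
the high mode and a planted mean interaction LFC of 4.71 (the high-mode
shift is $4.71/0.54 \approx 8.7$, consistent with the reported
XIST-high-vs-HC effect); X hypermethylation (+1.0 logit units on half of
the non-PAR X features, male SLE only); a modest X transcript down-shift
(−0.4 log2 on half of the X genes, SLE of both sexes); interferon-gene
upregulation (+2 log2, SLE of both sexes, 6 named IFN genes plus an
unnamed module); and a 2434-assay protein panel with 66 X-linked assays.
Where the study conditions do not pin a value (within-mode XIST spread,
noise SDs, marker structure), defaults were chosen once as field-plausible:
mode separation 6 within-mode SDs (classification ground truth essentially
unambiguous; power tests vary it), NB dispersion 0.1, log-normal library
sizes with CV 0.3 (so CPM normalization is non-trivial), logit-normal
methylation with SD 0.5.

RNA baselines come from a five-cell-type mixture model: a genes × cell-types
reference with 20% marker genes, per-cell-type totals equalized on the
length-normalized (TPM) scale so that bulk TPM is linear in the mixing
proportions; per-sample proportions are logistic-normal, and the female
neutrophil share co-varies negatively with the XIST latent so the
stratified correlation screens have known signal. Flow columns are the true
proportions plus measurement noise. Clinical variables are noisy monotone
transforms of latent disease activity and the XIST class (SLEDAI-like
score, IgG, alkaline phosphatase, mobility, disease duration), plus
pure-noise numeric and categorical variables for null calibration.
Karyotype anomalies (one XXY male, one XO female by default) surface only
through the read-depth simulator, mirroring how such samples are caught in
practice.

With `noise = 0` the generator emits the deterministic mean field: group
means equal planted values exactly on the methylation/NPX scales, latent
classes are assigned deterministically (`round(0.54·41)` = 22 high / 19
low), and RNA "counts" are the exact expectations — hence non-integer; the
container therefore enforces non-negativity, with integrality a property of
stochastic draws only.

Two aspects of real data are deliberately not emulated: read-level
sequencing artifacts (coverage is simulated at region/chromosome level
only) and between-assay batch structure. Passing recovery tests therefore
demonstrates correctness of the estimators under the planted model, not
robustness to alignment or batch pathologies.

# Numerical and scale choices

* **CPM compositionality.** The XIST-like transcript is so strongly
  expressed in XIST-high males that, in small synthetic gene universes, it
  occupies a visible fraction of the library; log-CPM differences then
  under-estimate planted absolute changes, and quantile normalization maps
  the top-ranked gene onto shared order statistics, distorting it further.
  The pipeline therefore takes single-gene XIST values from plain log-CPM
  (pre-quantile-normalization), and the recovery tests use a 2000-gene
  universe where the compositional bias is well below the assessment
  tolerance. At transcriptome scale (≥ 20k genes) both effects are
  negligible.
* **Residual variances** of exactly zero are floored at $10^{-12}$ before
  moderation. Trigamma inversion is Newton with analytic derivatives.
* **Dip-test power** is assessed at the stated condition — two Gaussian
  components 6 SDs apart with a fixed 20/21 split at $n=41$. Random
  (Bernoulli) splits occasionally produce very unbalanced mixtures whose
  dip is genuinely smaller; power against those is lower, which is a
  property of the statistic.
* **Wilcoxon paths.** The exact-enumeration and normal-approximation paths
  agree closely in relative terms except in the extreme tail
  (p < 0.01), where the normal approximation is known to diverge
  relatively; path-agreement checks exclude that region.

# Problem sizes used by the test-suite and acceptance script

Simulation-heavy checks run at reduced, fixed sizes chosen as the package's
own assessment conditions: interaction-model recovery uses 50 replicates of
the 679/77/41/7 cohort with 2000 genes; the X-silencing scan uses 20
replicates with 1000 methylation features and 500 permutations per set
(plus 10 label-permuted negative controls); classifier recovery uses 100
replicates at $n=41$; the dip size simulation shares one 10000-draw null
table across 1000 replicates; the deconvolution benchmark uses 20
replicates of a 117-sample cohort with 2000 genes; end-to-end determinism
re-runs a 239-sample, 600-feature pipeline twice and compares file digests.
The acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities at comparable sizes from a user-supplied seed.

# Known limitations

* The moderated tests assume (weighted) Gaussian errors per feature;
  NB-distributed counts with a very small cell (7 male HC) show mild
  tail inflation, visible as an empirical FDR slightly above nominal in
  the null-calibration test (within its stated bound).
* The trough rule is sensitive to outlier bumps (above).
* The benchmark scores only B and NK cells against flow; mapping of other
  populations to flow gates is configuration, not inference.
* The pipeline's input mode expects the same TSV layouts the generator
  writes; it does not parse vendor formats.
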