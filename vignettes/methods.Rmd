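---
title: "Models and methods in omicstrata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in omicstrata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(omicstrata)
```

`omicstrata` implements an integrative subtyping workflow for multi-omics
tumor cohorts. This vignette is the package's own account of the statistics
it computes: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. Preprocessing rules

**CNV segments.** Segments supported by fewer than 5 probes are dropped.
Within a sample and chromosome, segments are merged when their *reciprocal*
overlap — overlap length divided by the length of each interval, both
ratios — reaches 50%. The reciprocal form is the stricter, standard CNV
convention; a one-sided rule would fold short focal events into long
arm-level segments. Merging is transitive (connected components of the
pairwise relation), the merged value is the probe-count-weighted mean, and
probe counts add. Gene-level values are then the *unweighted* mean of all
merged segments overlapping the gene body, per sample; weighting is used
for the merge (robustness to poorly supported segments) but not for the
gene combination, where the per-segment averaging rule is explicit.
Coordinates are 1-based inclusive on disk (SEG/MAF convention).

**Methylation.** Probes missing in more than 70% of samples are removed;
the remaining missing entries are KNN-imputed over probe rows: distance is
the mean squared difference over the samples both probes observe, the
imputed value is the mean of the k = 10 nearest probes' values in that
sample, ties at the neighbourhood boundary break by probe id so the result
is deterministic, and imputed values are clipped to [0, 1]. Observed
entries are never altered. Promoter aggregation keeps probes in the
strand-aware window TSS − 2000 bp to TSS + 200 bp and averages probes per
gene. Only the downstream extent (200 bp) is externally fixed; the 2 kb
upstream span follows common TSS1500-style array annotation practice and is
a configurable parameter.

**Expression and mutations.** Genes are kept only when the fraction of
samples with FPKM exactly 0 is strictly below 0.5 (the boundary is
removed). Mutation records classified Intron or Silent
(case-insensitively; the synonym list is a parameter) are removed.

## 2. Event concordance

Per-entry events use strict thresholds: gain = log-ratio > 0.3, loss
< −0.3, hypermethylation β > 0.8, hypomethylation β < 0.2; boundary values
are non-events, and missing entries are never counted. Event frequencies
are raw per-sample counts (the feature universe is identical across samples
after preprocessing, so denominators cancel). All six unordered pairs among
{gain, loss, hyper, hypo} are tested with Pearson correlation and a
two-sided p from the t transform on n − 2 degrees of freedom; the labels
follow the r-sign + p < 0.01 rule. A constant count vector yields an `NA`
correlation with a warning rather than an error, because a degenerate layer
should not abort a report.

## 3. Correlation screening and the prognostic screen

For each gene, Pearson r links the omics value (CNV log-ratio, or promoter
β) to log2(FPKM + 1) expression over complete pairs. The log transform is a
design choice (the source recipe names no transform); it stabilizes
variance and is the standard scale for FPKM. The Fisher transform
z = ln((1 + r)/(1 − r)) = 2 artanh(r) is reported per gene, and the
screening p-value comes from the exact t transform rather than the normal
approximation on z — at n in the tens to hundreds the two differ in the
extreme tails where the 1e−5 threshold operates, and the t form is exact
under bivariate normality. Genes with p < 1e−5, any sign, form CNV-G /
MET-G. No multiple-testing correction is applied by default, matching the
recipe's raw thresholds; `stats::p.adjust` can be applied to the returned
table by callers who want BH.

The prognostic screen splits samples at the median of expression (ties to
the low group), tests the two groups by log-rank, and calls a gene adverse
when the high-expression group has more observed than expected events.
Expression was chosen as the splitting variable (the grouping layer was an
open question); it is the layer common to both gene sets.

## 4. NMF consensus subtyping

The factorization is the classical KL-divergence ("brunet") multiplicative
update. One deliberate addition: each run screens `n_init = 3` seeded
initializations for `init_iter = 30` burn-in updates and continues only the
candidate with the lowest divergence. Multiplicative updates cannot leave a
basin in which a basis column has died; on cleanly separable data roughly
one run in ten otherwise converges to a merged-cluster local minimum, which
would contaminate the consensus matrix. Screening by the objective is the
same remedy k-means takes with `nstart`.

"50 iterations" in the source recipe is read as 50 random-restart *runs*
feeding the consensus (the R NMF package's `nrun` semantics), not 50
multiplicative-update steps; per-run updates stop at relative divergence
change < 1e−6 or 2000 iterations. The consensus matrix holds co-assignment
frequencies (samples assigned by dominant H row per run); the final
assignment is average-linkage hierarchical clustering of 1 − consensus cut
at the candidate rank. Rank selection over 2–10 uses the cophenetic
correlation (CPCC) between the dendrogram's cophenetic distances and
1 − consensus, with ties broken by mean silhouette (on 1 − consensus), then
by the smaller rank; any rank whose smallest cluster falls below 10 members
is inadmissible. The dispersion index mean((2(C − ½))²) is reported but not
used for selection. A constant off-diagonal consensus makes CPCC undefined;
it is returned as `NA` with a warning.

## 5. Integrative latent-variable clustering

The joint model is `X_t = W_t Z + eps_t` for data types t (CNV,
methylation, expression), with shared latent positions `Z` (columns
standard Gaussian of dimension k − 1), diagonal type-specific noise, and a
lasso penalty per type. The E-step gives the posterior mean and covariance
of Z from the stacked data (Woodbury identities keep everything in the
(k − 1)-dimensional space); the M-step soft-thresholds the unpenalized
loading update at `lambda_t × max |unpenalized loading of type t|` — the
[0, 1] lambda scale is thereby meaningful across types of different
dimension and scale — and updates noise variances from residual moments
with a floor of 1e−3. The floor is a Heywood-case guard: inputs are
row-standardized, so a residual variance below 1e−3 carries no statistical
information but makes EM crawl (the log-likelihood keeps creeping as
variances decay geometrically). At lambda = 0 the iteration is exact EM and
the observed-data log-likelihood is non-decreasing; this is asserted in the
tests. Default stopping: relative log-likelihood change < 1e−6 or 2000
iterations (EM iterations are cheap at these sizes and slow convergence at
high signal-to-noise is normal).

Clusters come from seeded k-means (20 restarts) on the posterior latent
means. Lambda tuning evaluates 101 vectors from a shifted Halton design
over [0, 1]^T — the source recipe fixes the budget of 101 points but not
the selection criterion, so the package maximizes the mean silhouette of
the latent-space clustering, a criterion computable without external data;
ties break toward the smaller lambda L1 norm. The recipe's printed lambda
vectors are shipped as documented presets (`icluster_lambda_presets()`),
not defaults. Stability for K ∈ {2, 3, 4} is the mean pairwise adjusted
Rand index over 20 seeded refits, with the medoid refit used for the
optional survival read-out; the report ranks K but never auto-selects,
because the reference analysis itself reports a tension between the
stability-preferred K and the K it ultimately interprets.

Beta values are logit-transformed (clipped to [0.001, 0.999]) before row
standardization; the logit scale is where the Gaussian noise assumption is
least wrong for proportions.

## 6. Subtype characterization

**Exact contingency tests.** CNV states (Gain/Loss/Normal) and methylation
states (Hyper/Hypo/Normal) reuse the event thresholds. The 2 × C test is
the probability-ordering (Freeman–Halton) exact test: full enumeration of
first-row compositions when the table total is ≤ 200, otherwise a seeded
Monte-Carlo estimate from Patefield's algorithm (1e5 tables, add-one
estimator). The same machinery serves the 2 × 2 mutation-frequency
contrasts (always enumerated). BH is applied across features; the mutation
test additionally flags genes at raw p < 0.05, matching the recipe.

**Differential expression.** A full shrinkage-based NB pipeline is
deliberately *not* re-implemented; the contract here is "negative binomial
test + two-fold + FDR < 0.05". The package uses median-of-ratios size
factors, a per-gene method-of-moments NB dispersion pooled within groups
(floored at 1e−8), and a Wald test on the log2 fold change of normalized
group means with a delta-method standard error and a t reference on
n_A + n_B − 2 degrees of freedom. No dispersion or LFC shrinkage is
applied. Type-I calibration of this test is asserted empirically in the
acceptance suite ([0.03, 0.07] at nominal 0.05). Note one structural
consequence of the compound significance rule: for a gene whose true fold
change is exactly 2, the estimated |log2FC| exceeds the threshold only
about half the time regardless of sample size, so detection sensitivity is
a property of the Wald p-value, not of the compound flag.

**Survival.** Kaplan–Meier tables and log-rank tests use the `survival`
package, with a guard for the fully degenerate single-event-time case
(statistic 0 by definition; `survdiff`'s variance matrix is singular
there). With two groups the global statistic equals the pairwise one.
Marker cascades split samples into within-cohort expression tertiles
L1/L2/L3 by rank (heavy ties fall back to a seeded jitter with a warning —
the tertile boundaries are otherwise undefined); the trend is adverse when
the per-tier observed/expected event ratio rises monotonically from L1 to
L3. Tertiles are a package definition: the source recipe never defines the
cascade cut.

**Scores and enrichment.** External per-sample scores (immune-cell
abundances, stromal/immune scores) are *consumed, not computed*:
Kruskal–Wallis across subtypes plus pairwise rank-sum tests with BH.
Enrichment is a one-sided hypergeometric over-representation test against
user GMT collections with BH across terms.

## 7. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the cohort scale of the reference data (defaults: 159 samples, 3 subtypes,
2000 genes, ~30% censoring):

- **Subtype blocks.** 10% of genes are copy-number-coupled and a disjoint
  10% methylation-coupled; each coupled gene belongs to one subtype's
  block and its CNV value (respectively logit-β) shifts by `block_effect`
  (default 0.8 log-ratio units; × 4 on the logit scale so the β-scale
  shift near 0.5 is comparable) in that subtype. The default magnitude was
  chosen once so that recovery is feasible at n = 159 — the reference
  analysis reports no effect sizes, so the defaults encode "clearly
  present subtype structure", not measured effect magnitudes.
- **Couplings.** Expression signal for a coupled gene is built as
  `r · scale(driver) + sqrt(1 − r²) · noise` with r = 0.6 (CNV) or −0.6
  (methylation), so the planted correlation is exact by construction;
  negative-binomial counting noise (dispersion 0.1, log-normal library
  sizes, FPKM = counts rescaled by fixed gene lengths) attenuates the
  observed correlation to roughly 0.54 at the default depth.
- **Event burden.** A log-normal per-sample burden factor multiplies the
  rate at which large focal CNV events and methylation excursions are
  planted, on a mid-range methylation baseline; this is what makes all
  four CNV–methylation event-frequency pairs positively correlated. The
  first design iteration used a low (promoter-realistic) β baseline and
  burden-scaled spread, which *inverted* the hypomethylation correlations
  — a sample already below the hypo threshold loses events as its spread
  grows — and was replaced by explicit event planting.
- **Survival.** Exponential event times with per-subtype hazard ratios
  (default 3 / 1.7 / 1, worst prognosis in subtype 1) raced against an
  independent exponential censoring time calibrated to the target
  censoring fraction. Exponential-vs-exponential racing keeps log-rank
  power analytically checkable.
- **Plumbing for the filters.** Decoy segments with < 5 probes, probes
  outside promoter windows, ~2% scattered missing β entries plus 1% of
  probes missing in 75% of samples, 5% near-silent genes, and a tail of
  Silent/Intron mutation calls exist solely to exercise the preprocessing
  rules.

What the generator does **not** emulate: realistic segmentation processes
(each gene sits on exactly one true segment), array probe-level noise,
tumor purity, linkage between neighbouring genes, or clinically realistic
covariate structure. A green recovery test therefore establishes that the
pipeline recovers the structure it assumes when that structure is present
at the stated strength — not that it would find the reference cohort's
subtypes.

## 8. Determinism and seeds

Every stochastic component takes a seed; child seeds are derived
arithmetically (kept below 2³¹). Matrices are written with 17 significant
digits so a written bundle reads back bit-identically, and the end-to-end
determinism of the pipeline (identical config + seed ⇒ identical file
hashes) is an acceptance criterion.

## 9. Known limitations

- The NB Wald test is honest but unshrunken; at very small n its
  dispersion estimates are noisy and the t reference only approximately
  calibrated (the calibration band is asserted at 20 vs 20).
- KNN imputation is O(missing-rows × probes × samples); at array scale
  (450k probes) it would need blocking or an index, which is out of scope
  at cohort sizes targeted here.
- The lasso EM treats the soft-threshold as a per-iteration operation; the
  converged nonzero-count is monotone in lambda only per update, not
  guaranteed across full EM paths (the acceptance grid on the default
  world is monotone).
- Lambda tuning optimizes silhouette, which favours compact latent
  clusters; with strongly non-spherical latent structure a
  likelihood-based criterion could choose differently.
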