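# omicstrata

Integrative multi-omics subtyping of tumor cohorts in R.

## The problem

Tumor cohorts profiled on several molecular layers — DNA copy number (CNV),
promoter DNA methylation, RNA expression, somatic mutations, clinical
follow-up — often hide subgroups that no single layer reveals. `omicstrata`
implements a complete, tested version of a widely used analysis recipe for
discovering and characterizing such subgroups:

1. **Preprocess** raw inputs: merge CNV segments by reciprocal overlap
   (default 50%, probe-count ≥ 5), map segments to genes, drop methylation
   probes missing in > 70% of samples, KNN-impute the rest, aggregate
   promoter probes (TSS − 2000 bp … TSS + 200 bp), drop genes with FPKM = 0
   in ≥ 50% of samples, and remove Intron/Silent mutation calls.
2. **Event concordance**: call per-entry events (gain: log-ratio > 0.3;
   loss: < −0.3; hypermethylation: β > 0.8; hypomethylation: β < 0.2),
   count them per sample, and test all six pairwise Pearson correlations of
   the counts (r sign + p < 0.01 labels).
3. **Gene stratification**: per gene, Pearson r between the omics layer and
   log2(FPKM + 1) expression, Fisher z = ln((1 + r)/(1 − r)), and a
   p < 1e−5 screen defines the copy-number-driven (CNV-G) and
   methylation-driven (MET-G) gene sets; a univariate median-split log-rank
   screen (p < 0.05) marks prognostic members, with set intersection.
4. **NMF consensus subtyping** on each gene set's expression: "brunet"
   KL-divergence multiplicative updates, 50 seeded restarts, consensus
   matrix, rank 2–10 selected by cophenetic correlation (CPCC) with
   dispersion/silhouette tie-breaks and a minimum subclass size of 10.
5. **Integrative clustering** of CNV + methylation + expression restricted
   to CNV-G/MET-G: a lasso-penalized Gaussian latent-variable model
   `X_t = W_t Z + eps_t` fitted by EM, with a 101-point seeded
   low-discrepancy lambda design, K ∈ {2, 3, 4}, and 20-repeat stability
   (mean pairwise adjusted Rand index).
6. **Characterization** of the resulting subtypes: Freeman–Halton exact
   tests of CNV/methylation state distributions, a negative-binomial Wald
   test for differential expression (|log2FC| ≥ 1 and FDR < 0.05),
   Fisher exact mutation-frequency contrasts, Kaplan–Meier/log-rank
   survival, L1/L2/L3 expression-tertile marker cascades, rank tests for
   external per-sample scores, and hypergeometric enrichment against GMT
   gene sets.

Everything runs on a built-in **synthetic multi-omics generator** that
plants subtypes, dosage–expression couplings (positive for CNV, negative
for promoter methylation), a shared per-sample event-burden factor, and
subtype-dependent exponential survival — so the whole pipeline is testable
offline, with known ground truth.

## Worked example

```r
library(omicstrata)

cfg    <- simulation_config(n_samples = 120, n_genes = 800, seed = 7)
bundle <- generate_multiomics(cfg)
bundle
#> <synthetic_bundle: 120 samples, 800 genes, 2400 probes, K=3 planted subtypes>

counts <- classify_events(bundle$cnv_gene, bundle$beta_matrix)
event_frequency_correlations(counts)
#>         pair    r       p   n    label
#> 1  gain~loss 0.65 9.2e-16 120 positive
#> 2 gain~hyper 0.60 6.4e-13 120 positive
#> 3  gain~hypo 0.25 7.0e-03 120 positive
#> 4 loss~hyper 0.50 4.7e-09 120 positive
#> 5  loss~hypo 0.22 1.5e-02 120       ns
#> 6 hyper~hypo 0.15 1.0e-01 120       ns

cc    <- correlate_omics_expression(bundle$cnv_gene, bundle$expression_fpkm, "cnv")
cnv_g <- select_correlated_genes(cc, alpha = 1e-5)
length(cnv_g)   # 79 of the 80 planted coupled genes recovered

V  <- log2(unclass(bundle$expression_fpkm)[cnv_g, ] + 1)
cr <- consensus_cluster(V, 3, n_runs = 20, seed = 1, max_iter = 300, tol = 1e-5)
cr$cophenetic   # 0.997

truth <- setNames(bundle$truth$samples$subtype, bundle$truth$samples$sample)
adjusted_rand_index(cr$assignment$labels[names(truth)], truth)  # 1

km_logrank(bundle$clinical, cr$assignment)$global_p  # 0.00449
```

Reading: per-sample event burdens are mutually correlated across the CNV
and methylation layers (the planted burden factor), the p < 1e−5 screen
recovers essentially all coupled genes, consensus NMF at the true K is
maximally stable (CPCC ≈ 1) and reproduces the planted subtypes exactly,
and the subtypes separate in survival (log-rank p ≈ 0.004; the planted
hazard ratios are 3 / 1.7 / 1).

## Full pipeline

```r
cfg <- pipeline_config(out_dir = "run1", seed = 11,
                       simulate = list(n_samples = 159, n_genes = 2000))
run_pipeline(cfg)   # simulate → preprocess → events → stratify → nmf → icluster → characterize
```

Each stage writes TSV outputs under `run1/<stage>/` and a manifest with
md5 hashes; identical config + seed reproduces every file byte-for-byte.
A thin CLI wrapper is installed at `inst/exec/omicstrata`
(`omicstrata run --config config.json`).

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the models, the
tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the package's numerical design choices.
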