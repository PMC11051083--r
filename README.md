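# tricoat

Progression-specific disease subtyping from baseline multimodal data
with a tri-modal co-attention transformer.

## What this package is for

Alzheimer's disease declines at very different rates across patients.
`tricoat` implements a complete workflow for defining and predicting
*progression-specific subtypes* — slow, intermediate and fast cognitive
decliners — from **baseline-only** data in three modalities:

* **imaging** — 72 cortical ROIs x 4 FreeSurfer-derived morphometric
  traits (cortical thickness average and SD, surface area, volume);
* **genetics** — allele dosages at 70 AD-associated SNPs, each with
  GWAS odds ratio, rare-allele frequency, intergenic flag and
  chromosome;
* **clinical** — 7 cognitive scores (LDELTOTAL, DIGITSCOR, TRABSCOR
  and the four RAVLT summaries).

Subtype labels come from k-means (k = 3) on baseline-anchored MMSE
trajectory deltas at 6/12/24 months, with clusters ordered by their
24-month centroid decline.  Classification uses a tri-modal
co-attention transformer: per-modality tokenizers (one token per ROI /
SNP / score), pre-LayerNorm transformer encoders

$$F'_l = \mathrm{MHA}(\mathrm{LN}(F_{l-1})) + F_{l-1}, \qquad
  F_l = \mathrm{FF}(\mathrm{LN}(F'_l)) + F'_l,$$

and a single-head co-attention block in which imaging and genetics
supply the queries and the clinical sequence supplies keys and values,

$$\mathrm{CoAttn}(\{G,I\},C) =
  \mathrm{softmax}\!\left(\frac{Q_{\{G,I\}}K_C^{\top}}{\sqrt{d_k}}\right)V_C ,$$

so the phenotype-proximal clinical representation is re-weighted by the
other modalities.  The two co-attended class tokens feed an MLP that
outputs the three subtype logits.  The package also ships every
standard comparison model (single-modality ablations, early / late /
stage-wise fusion, SVM-RBF, random forest), a nested 10x5 stratified
cross-testing harness with Hand-Till one-vs-one AUROC and paired
t-tests, co-attention interpretation (averaged attention tables, chord
plot edge lists), and a synthetic-cohort generator with planted,
tunable cross-modal class structure so everything runs without
controlled-access data.  The networks, including backpropagation and
Adam, are implemented in base R matrix code and verified against
finite differences and explicit-loop oracles in the test suite.

## Worked example

```r
library(tricoat)

# 1. simulate a cohort: 95 subjects, signal planted in the clinical scores
sim <- simulate_cohort(cohort_spec(n_per_class = c(40, 40, 15), n_roi = 16, n_snp = 16,
                                   effect_size = c(imaging = 0, genetics = 0, clinical = 1)),
                       seed = 42)

# 2. derive progression subtypes from the MMSE trajectories
labeling <- cluster_subtypes(compute_deltas(sim$cohort), seed = 42)
glance(labeling)
#> # A tibble: 1 x 7
#>   n_slow n_intermediate n_fast d24_slow d24_intermediate d24_fast tot_withinss
#>    <int>          <int>  <int>    <dbl>            <dbl>    <dbl>        <dbl>
#> 1     41             34     20    0.415            -4.06    -8.15         618.
labels <- tidy(labeling)

# 3. stratified train / validation / test split, leakage-safe scaling
set.seed(43)
parts <- lapply(split(labels$subject_id, labels$subtype), function(ids) {
  ids <- sample(ids); n <- length(ids)
  split(ids, rep(c("test", "val", "train"), c(round(n/4), round(n/5), n - round(n/4) - round(n/5))))
})
ids <- function(role) unname(unlist(lapply(parts, `[[`, role)))
scaled <- apply_scaler(sim$cohort, fit_scaler(sim$cohort, c(ids("train"), ids("val"))))

# 4. train the co-attention model (reduced configuration)
cfg <- tricoat_config(k = 32, n_layers = 2, n_heads = 4, mlp_hidden = 32,
                      lr = 1e-3, epochs = 15, batch_size = 16, seed = 7)
fit <- fit_tricoat(scaled, labels, ids("train"), ids("val"), cfg)

# 5. held-out performance and cross-modal associations
out <- predict(fit, scaled, ids("test"), attention = TRUE)
y_test <- labels$subtype[match(ids("test"), labels$subject_id)]
auroc_ovo(y_test, as.matrix(out$prob[, 2:4]))
#> [1] 0.818
head(export_chord_edges(average_attention(out$attention), top_k = 3), 6)
#> # A tibble: 6 x 3
#>   from     to              value
#>   <chr>    <chr>           <dbl>
#> 1 rs000001 RAVLT_immediate 0.365
#> 2 rs000008 RAVLT_immediate 0.365
#> 3 rs000011 RAVLT_immediate 0.362
#> 4 ROI016   RAVLT_learning  0.267
#> 5 ROI004   RAVLT_immediate 0.257
#> 6 ROI005   RAVLT_learning  0.244
```

The clustering recovers three trajectory groups whose 24-month mean
deltas (+0.4 / −4.1 / −8.2 MMSE points) bracket the planted class
means; the trained model separates held-out subjects at OvO AUROC 0.82
from a clinical-keyed signal; and the exported edge list ranks the
cross-modal attention associations (`from` = ROI or SNP, `to` =
clinical score, `value` = mean attention weight) ready for a chord
diagram.

The full protocol — nested 10-fold cross-testing with 5 inner
validation folds, 50 evaluations per method, paired t-tests — runs
through `make_fold_plan()` / `run_cross_testing()`, or end to end
(simulate → label → evaluate → interpret) through `run_pipeline()` and
the thin CLI at `inst/cli/tricoat.R`.

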