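# rarelasso

Gene-level collapsing of rare sequence variants with L1-penalized
multimarker regression, for association studies where single-marker
tests are underpowered.

Rare variants (minor-allele frequency ≤ 5% here; ≤ 1% optionally) carry
too few carriers per site to test individually. `rarelasso` collapses a
gene's rare variants into one per-individual burden score by three
schemes —

* **PROP** — carrier proportion: fraction of the gene's rare sites at
  which an individual carries ≥ 1 minor allele;
* **DAS** — data-adaptive sum: dosage sum after flipping the coding
  (`x → 2 − x`) of sites whose marginal effect is significantly
  negative;
* **WS** — weighted sum: `Σ_j x_ij / w_j` over *all* the gene's
  variants with `w_j = sqrt(n q_j (1 − q_j))`,
  `q_j = (m_j + 1)/(2 n_u + 2)` estimated in the unaffected group for
  disease traits —

and fits, per phenotype replicate, the multimarker model

```
g(μ_i) = β0 + E_i' β_E + Σ_{v ∈ CV} x_iv β_v + Σ_l c_il β_l
```

maximizing `ℓ(β) − Σ_j λ_j |β_j|` with covariates `E` unpenalized
(identity link for quantitative traits, logit for disease). Collapsing
nonsynonymous and synonymous variants separately allows *differential*
penalties `(λ_ns, λ_s)`, both chosen by within-replicate
cross-validation. Methods are compared across replicates by selection
consistency `C = Σ_{j∈F} n_j(R − n_j)/R`, cross-replicate prediction
error (MSE / AUC vs a covariates-only baseline), and ROC/AUC of
replicate selection counts against a causal truth set.

A built-in simulator generates mini-exome style data (fixed genotypes,
R phenotype replicates, rare-dominated frequency spectrum, liability-
threshold disease, all causal variants nonsynonymous) so the entire
pipeline runs self-contained. The coordinate-descent solver (C++, with
covariance updates for Gaussian fits and IRLS for logistic fits)
returns exact zeros and verifiable KKT conditions.

## Worked example

```r
library(rarelasso)

g     <- simulate_genotypes(400, 50, list(mean = 6), seed = 101)
truth <- simulate_truth(g, h2 = list(Q2 = 0.3),
                        n_causal_genes = list(Q2 = 4), seed = 102)
reps  <- simulate_phenotypes(g, truth, R = 20, seed = 103)
g
#> genotype_set: 400 individuals x 296 variants in 50 genes (134 ns / 162 s)
#>   MAF: median 0.0075, 89% rare at the 5% threshold

fits <- fit_all_replicates(g, reps, "Q2", collapse_config("PROP"),
                           seed = 104)
consistency_score(selection_matrix(fits))
#> [1] 125.6
cross_replicate_prediction(fits, reps, "Q2")
#> [1] 0.1248   # genetics reduce out-of-replicate MSE by 0.125

rr <- rank_and_roc(fits, truth$Q2)
rr$auc
#> [1] 1
head(rr$top_features, 5)
#>     feature count
#> 37     G004    20
#> 63     G030    20
#> 33 G050_V01    20
#> 80     G047    18
#> 42     G009     5
```

The three 20/20-count features are exactly the causal genes G004 and
G030 and the common causal variant in G050 (truth genes: G004 G030
G047 G050); a selection-count threshold separates causal from null
features perfectly here (AUC = 1). The positive prediction improvement
says the selected genetic features generalize across phenotype
replicates; for the covariates-only trait Q4 the same number comes out
at or below zero.

`compare_methods()` runs every method × trait combination and returns
the consistency / improvement / AUC summary table plus ROC and
top-feature details; `run_pipeline()` drives the whole analysis from a
configuration object or yaml file and writes tab-delimited reports
(see `inst/scripts/run-pipeline.R` for a command-line wrapper).
`write_dataset()` / `read_dataset()` round-trip a simulated study
through VCF (with `GENE=`/`ANNO=` INFO tags) and delimited tables.

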