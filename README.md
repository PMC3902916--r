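# sigmakin

Kinetic inference of sigma-factor-controlled transcriptional networks from
dense expression time series.

During spore germination a bacterium rebuilds its transcriptome within a
few hours, and sigma factors — the subunits that direct RNA polymerase to
promoter classes — orchestrate that program. Given a replicated two-channel
microarray time series over germination, `sigmakin` asks, for each sigma
factor and each gene or kinetic gene cluster, whether the sigma factor's
expression profile can kinetically explain the target's profile under the
sigmoid transcription-control model

    dy/dt = k1 / (1 + exp(-(w R(t) + b))) - k2 y

where `R(t)` is the regulator profile, `k1` the maximal production rate,
`k2` the degradation rate, `w` the regulator weight and `b` a reaction
delay. Parameters are fitted per regulator–target pair by multi-restart
simulated annealing minimizing `F = 1 - c`, with `c` the Pearson
correlation between measured and simulated target; a relation is accepted
at `c > 0.8` (or `c > 0.65` when ChIP/literature priors support the pair).

The full pipeline: per-array median/MAD normalization with 2% quantile
trimming → replicate outlier rejection (Dixon Q / Peirce) and profile
averaging → expression-level and CV gene filters → consensus k-means
clustering under Spearman distance with 50% cores and a jackknife elbow
scan → kinetic screening of sigma factors against cluster cores, genes and
each other → GEXF network export (edge thickness ∝ w) → Fisher-exact
functional enrichment of clusters and sigma-to-function linkage.

A synthetic-data generator (`generate_fixture()`) reproduces the structure
of such an experiment — kinetic regulons, dim noisy background genes,
replicated arrays with channel bias and gross outliers, planted functional
enrichment — with full ground truth, so every stage is validated against
known answers.

## Worked example

```r
library(sigmakin)

ds  <- generate_fixture(synthetic_spec(), seed = 1)     # synthetic study
res <- run_pipeline(ds$arrays, ds$sigma_ids,
                    annotation = ds$annotation, priors = ds$priors,
                    n_clusters = 7, seed = 7)

length(res$cores)
#> [1] 6

head(res$edges_genes[res$edges_genes$accepted,
                     c("regulator_id", "target_id", "w", "correlation")])
#>   regulator_id target_id        w correlation
#> 1      sigma01  gene0016 6.273735   0.7057618
#> 2      sigma02  gene0021 3.029264   0.9583489
#> 3      sigma02  gene0022 3.440273   0.8902393
#> 4      sigma02  gene0023 7.669504   0.9874595
#> 5      sigma02  gene0024 4.493503   0.9691824
#> 6      sigma02  gene0025 2.596549   0.9277347

edge_recovery(res$edges_genes, ds$truth,
              candidate_targets = res$clustered_ids)[c("recall", "precision")]
#> $recall
#> [1] 0.84375
#> $precision
#> [1] 0.5869565

head(res$significant[, c("cluster_id", "class", "k", "p_value", "fold_change")])
#>    cluster_id   class  k      p_value fold_change
#> 5         CL1 class05 16 1.055862e-10    4.780952
#> 12        CL2 class03  9 4.251767e-04    3.245690
#> 22        CL3 class04 16 1.341238e-11    5.312169
#> 28        CL4 class01  9 1.320458e-04    3.591415
#> 47        CL6 class02 14 1.706732e-09    5.020000
```

Clustering at n = 7 (five planted regulons plus headroom for background
genes) yields six consensus cores, five of them matching the regulons. The
accepted sigma→gene edges carry the fitted regulator weight `w` and fit
correlation — the first row is a prior-supported pair accepted at the
lower 0.65 threshold. Recall/precision compare accepted edges against the
planted regulons, and the enrichment table flags the functional class
planted in each cluster (P < 0.05, fold change > 2, k > 7).

The same stages run as a narrated workflow in `analysis/01_simulate.R` …
`analysis/06_enrich.R`, writing tables under `results/`.

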