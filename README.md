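# arnfkb

Tools for the expression side of a recurring question in prostate-cancer
biology: do androgen-receptor (AR) and NF-kB transcriptional programs act
as opposing forces in tumors, and does the balance — tracked by GSK-3
isoform expression — carry prognostic information? The package is aimed at
computational biologists who want the full analysis chain as tested,
reusable functions: microarray chip QC, reference-based signature scoring,
tumor stratification, permutation-null gene-set enrichment, derivation of
an "AR-repressed NF-kB target" gene set, and survival analysis of
signature-defined groups. A synthetic cohort generator with the assumed
statistical structure makes every stage testable without external tumor
accessions.

## The core statistics

**Summed Z-score signature scoring.** For gene $g$ and tumor $s$,
$Z_{gs} = (x_{gs} - \bar{x}^{ref}_g)/s^{ref}_g$ with mean and sd ($n-1$)
taken over normal-prostate reference samples; a tumor's signature score is
$\sum_{g \in S} Z_{gs}$. Tumors in the top/bottom third of the AR-signature
score are "high"/"low AR signature"; tumors with both GSK3A and GSK3B
$Z > 0.5$ (resp. both $< -0.5$) are "high" (resp. "low") GSK3.

**Running-sum enrichment with a phenotype-permutation null.** Genes are
ranked by the pooled-variance two-sample t statistic (high vs low group).
Walking the ranked list, the running sum gains
$|t_g|^w / \sum_{hits}|t|^w$ at members of the tested set and loses
$1/(N - N_h)$ elsewhere; the enrichment score (ES) is the signed maximum
deviation, in $[-1, 1]$. The null re-shuffles the group labels (sizes
preserved); $p = (1 + \#\{\text{same-sign null} \ge |ES|\}) /
(1 + \#\{\text{same-sign null}\})$ and NES divides ES by the mean
magnitude of same-sign null scores. The negative leading edge of the
NF-kB-target enrichment in the high-vs-low-AR contrast is the derived
"AR-repressed NF-kB target" set.

**Survival.** Tumors split at the median of the derived-set summed Z-score
are compared by Kaplan-Meier curves and the log-rank test, with follow-up
administratively truncated at 100 and 220 months.

Chip QC uses relative log expression (RLE): per chip, the median deviation
from gene-wise medians; chips beyond $1.5 \cdot IQR$ outside the quartiles
of the per-chip metric are discarded. Bench-assay helpers quantitate
protein/DNA binding-array membranes (negative controls as blank,
positive-control row as scale) and qPCR tables by delta-delta-Ct against
36B4 with quadrature error propagation.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (100 tumors, 20 normals, 2000 genes, AR/NF-kB anticorrelation 0.6).
In R, the same chain in miniature:

```r
library(arnfkb)

co  <- simulate_cohort(sim_config(seed = 1))
z   <- zscore_vs_reference(co$expression)            # vs normal prostates
ar  <- summed_zscore(z, gene_set("AR_signature", co$truth$ar_genes))
lab <- stratify_extremes(ar, fraction = 1/3)         # tertile extremes
enr <- permutation_test(co$expression, lab,
                        gene_set("NFKB_targets", co$truth$nfkb_genes),
                        n_permutations = 1000, seed = 1)
enr
#> <enrichment_result> NFKB_targets: es=-0.9746, nes=-1.787, p=0.001957
#>   (1000 permutations); leading edge 30 genes
```

The negative ES with p < 0.01 says the NF-kB target program is depleted
among genes elevated in high-AR-signature tumors — the planted inverse
correlation, recovered. Continuing:

```r
derived <- derive_repressed_targets(enr, "AR_repressed_NFkB_targets")
sc  <- summed_zscore(z, derived)
grp <- group_by_signature(sc, "median")
md  <- co$metadata[match(names(grp), co$metadata$sample_id), ]
logrank_test(data.frame(time = md$time_months, event = md$event,
                        group = unname(grp)), horizon_months = 100)
#> <logrank_result> chi-square = 20.24 on 1 df, p = 6.824e-06 (at 100 months)
```

Tumors with high expression of the derived AR-repressed NF-kB targets do
significantly worse — the cohort was generated with hazard riding on the
NF-kB score, and the chain recovers it. The published 29-gene derived set
ships as a fixture: `ar_repressed_nfkb_targets()`.

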