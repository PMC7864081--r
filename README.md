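# pathcoact

Are two signaling pathways transcriptionally *coactivated* across a tumor
cohort? `pathcoact` answers this for bulk RNA-seq count matrices by scoring
per-sample pathway activity with single-sample GSEA (ssGSEA) and testing the
cross-sample correlation of two pathways' activities against a bootstrap
null of random size-matched gene signatures. It was built around one
concrete biological question — whether up-regulation of G12/13 signaling
(Gα12/13 → RhoGEF → Rho GTPase) travels together with YAP/TAZ
transcriptional output in bladder cancer — and ships both signatures
(8 genes and 24 genes respectively) as frozen built-ins, but every step
works for any signature pair on any gene-by-sample count matrix.

## The method

For each sample, genes are ranked by expression (ascending ranks
`r_g`, average ties). The ssGSEA enrichment score of a signature `S` walks
genes from highest to lowest expression and integrates the difference
between the weighted in-set and unweighted out-of-set rank ECDFs:

    ES = Σ_i [ P_in^w(i) − P_out(i) ],   w_g = r_g^α,  α = 0.25

Coactivation of a reference and a target signature is the Pearson
correlation `r` of their score vectors across samples. Its significance is
the add-one empirical p-value against the correlations between the
reference scores and `B` random signatures of the target's size drawn from
the matrix's gene universe:

    p = (1 + #{b : r_b ≥ r_obs}) / (1 + B),   floor 1/(1+B)

A negative-binomial cohort simulator with two planted latent-driven gene
modules (configurable latent correlation ρ) provides ground truth for
validating the whole chain.

## Worked example

The `analysis/` scripts run the full study on a simulated 400-sample ×
5,000-gene cohort with a planted latent correlation of 0.7:

```sh
Rscript analysis/01_simulate.R          # write the synthetic cohort
Rscript analysis/02_score_pathways.R    # normalize + ssGSEA scores
Rscript analysis/03_coactivation_test.R # correlation + bootstrap null
Rscript analysis/04_null_calibration.R  # p-value behavior when rho = 0
```

Output of the first three steps:

```
Realized latent activity correlation: r = 0.7173
ssGSEA module-A score vs latent A activity: r = 0.9790
ssGSEA module-B score vs latent B activity: r = 0.9892
Cross-module score correlation: r = 0.6820 (latent truth 0.7173)

Observed coactivation: r = 0.6820 over 400 samples
Bootstrap null: mean r = -0.0012, sd = 0.1117 (B = 10000)
Empirical p = 0.0004 (greater; floor at this B is 0.0001)
```

Reading this: the ssGSEA scores track the hidden per-module activities
almost perfectly (r ≈ 0.98), the cross-module score correlation (0.682)
recovers the realized latent correlation (0.717) with a small attenuation
from count noise, and the observed correlation sits far outside the
bootstrap null (sd ≈ 0.11), giving an empirical p near the estimator's
floor. Equivalent one-call interface:

```r
library(pathcoact)
ds <- simulate_coactivation(synthetic_spec())           # or read_counts("counts.tsv")
res <- run_coactivation_pipeline(ds$counts,
                                 reference = ds$signature_a,
                                 target = ds$signature_b,
                                 B = 10000, seed = 1,
                                 output_dir = "results/run")
res$observed_r; res$p_empirical
```

`run_coactivation_pipeline()` also accepts the built-in signatures
(`builtin_signature("G12_13")`, `builtin_signature("YAP_TAZ")`), GMT files
via `read_gmt()`, an Ensembl-to-symbol mapping table (`map_gene_ids()`),
and a sample subset (e.g. primary tumors only). To run the original
bladder-cancer analysis, download the TCGA-BLCA STAR/HTSeq count matrix
through the GDC client, restrict to primary-tumor barcodes, and pass the
matrix plus the two built-ins.

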