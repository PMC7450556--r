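# neo3d — neoantigen prioritization from 3D genome structure

Sequence-based peptide-MHC predictors rank candidate neoantigens while
ignoring where in the genome the underlying mutation sits. Yet the DNA loci
of immunogenic (immuno-positive) MHC class I epitopes cluster in the
three-dimensional organization of the nucleus. `neo3d` operationalizes that
signal for anyone prioritizing tumor neoantigen candidates from a Hi-C
contact matrix and a curated epitope set:

1. **Curation** — per-assay T-cell records are filtered (human, MHC-I,
   9-mers) and merged per (peptide, allele); the positive rate *r* of each
   group labels it immuno-positive (*r* > 0.8), immuno-negative
   (*r* < 0.2), or drops it. Loci come from a peptide→(chrom, position)
   mapping table.
2. **Compartment degree** — per chromosome, the Hi-C matrix is transformed
   to observed/expected; the leading eigenvector of its Pearson correlation
   matrix is the per-bin chromatin-activity score (A/B compartment degree).
3. **Polymer reconstruction** — one bead per 500-kb bin, one chain per
   chromosome. Each bead *i* gets a target radius *t(i)* decreasing
   linearly in the rank of its compartment degree (active chromatin sits
   near the nuclear center), and conformations minimize the bias potential

       E = k_bond * Σ_bonds (d - b)²  +  k_rad * Σ_beads (|r_i| - t_i)²

   from seeded random walks (gradient descent, adaptive step, monotone in
   energy). An ensemble of independently seeded replicas (default 300)
   averages out individual structures.
4. **KNN vote and combined score** — for a target locus, the k = 10 nearest
   same-chromosome training epitopes (by replica-averaged Euclidean
   distance) vote; the KNN score is their positive fraction. The final
   score is `baseline − knn_score`, where the baseline is an external
   pMHC binding score rescaled to [0, 1], lower = stronger binder; sort
   ascending to prioritize.
5. **Spatial statistics & evaluation** — per-chromosome and genome-wide
   contact-frequency comparisons of pos-pos / neg-neg / pos-neg epitope
   pairs (Mann-Whitney, with an exact permutation option), and
   leave-one-out ROC / precision-recall comparison of combined versus
   baseline-only scoring with bootstrap intervals.

A synthetic-data module generates Hi-C matrices with planted compartment
checkerboards, epitope sets with spatially clustered positives, and
baseline scores of tunable AUC, so the whole pipeline is testable offline.

## Worked example

Simulate a study (three toy chromosomes, 80 positive / 320 negative
epitopes whose positives cluster in the A compartment, baseline AUC 0.70),
write it as pipeline-ready files, and run the full pipeline:

```r
library(neo3d)
sim <- simulate_study(seed = 1)
fix <- write_study_fixture(sim, "demo")
res <- run_pipeline("demo/chrom.sizes", "demo/hic_triplet.txt",
                    "demo/epitope_assays.tsv", "demo/peptide_mapping.tsv",
                    "demo/baseline_scores.tsv",
                    n_replicas = 20, seed = 1, quiet = TRUE)
print(res$comparison$table, digits = 3, row.names = FALSE)
#>    method   auc auc_lo auc_hi  aupr aupr_lo aupr_hi
#>  combined 0.742  0.684  0.799 0.439   0.345   0.558
#>  baseline 0.699  0.636  0.760 0.360   0.278   0.471
```

Adding the 3D-genome KNN vote lifts the leave-one-out AUC from 0.699
(baseline alone — by construction ≈ 0.70) to 0.742, and the AUPR from 0.360
to 0.439; the bootstrap columns are 95% percentile intervals. The top of
the priority list (most negative combined score = strong predicted binder
in a positive-rich spatial neighbourhood):

```r
head(res$scores[order(res$scores$combined_score),
     c("peptide", "knn_score", "baseline_score", "combined_score", "label")], 5)
#>       peptide knn_score baseline_score combined_score    label
#> 271 HQKSMPHMQ       0.7     0.09774436     -0.6022556 negative
#> 57  KSRMTPGPG       0.6     0.02005013     -0.5799499 positive
#> 7   LLCYAHSIW       0.6     0.03007519     -0.5699248 positive
#> 12  PTMMVQHHH       0.5     0.04010025     -0.4598997 positive
#> 42  MFQFPFQLS       0.6     0.17042607     -0.4295739 positive
```

`intra_chromosome_summary()` and `inter_chromosome_distributions()` give
the per-chromosome and genome-wide pair contact-frequency comparisons;
`plot_curves()` and `plot_intra_cf()` draw the ROC/PR curves and the
starred per-chromosome bar chart.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/neo3d simulate --out demo --seed 1
Rscript inst/cli/neo3d predict --chrom-sizes demo/chrom.sizes \
    --hic demo/hic_triplet.txt --epitopes demo/epitope_assays.tsv \
    --mapping demo/peptide_mapping.tsv --baseline demo/baseline_scores.tsv \
    --replicas 20 --seed 1 --out demo_run
```

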