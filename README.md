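# kinsdr

Modeling protein kinase target specificity and finding the kinase-domain
residues that determine it.

Serine/threonine kinases recognize a short motif around the
phosphoacceptor (substrate positions −5..+5, position 0 = the
phosphorylated S/T). `kinsdr` is an R package for the full analysis
chain that connects those motifs to kinase sequence:

1. **Specificity models** — 20×11 position weight matrices (PWMs) of
   relative amino-acid frequencies, built from kinase–phosphosite windows
   after duplicate, activation-segment and 85%-identity redundancy
   filtering; quality-controlled by 10-fold cross-validation of a
   matrix scoring function (models with mean AUC < 0.60 are excluded).
2. **Preference clustering** — affinity propagation over single PWM
   columns (similarity = negative Euclidean distance between 20-vectors)
   with refinement rules: drop nonspecific clusters (top-two mean weight
   < 0.30), merge same/similar residue preferences, drop clusters with
   < 6 kinases, rescue false negatives above the 40th-percentile member
   weight, purge members whose own preference leaves the cluster top-3.
3. **SDR detection** — for each specificity class, a binary partition of
   the kinase-domain alignment is scored per column by three independent
   methods (GroupSim-style similarity contrast, two-class Relief, and a
   SPEER-style entropy + physicochemical score); specificity-determining
   residues (SDRs) are the columns ranked in the top 15 by *all three*
   methods.
4. **Specificity classifiers** — two-class naive Bayes over the residues
   at SDR columns (prior fixed at 0.5, Laplace 0.5 over 21 symbols
   including the gap), positives labeled by ≥ 3× fold enrichment over the
   proteome background, feature subsets chosen by exhaustive LOOCV; R-3
   uses separate CMGC / non-CMGC models.
5. **Evolution** — Frobenius distances between PWMs with a subsampled
   (n = 23) within-kinase null, divergence calls against the median
   random-pair distance, per-category sequence conservation, mean
   classifier posterior across ortholog groups (divergent < 0.5), and
   catalytic-triad (K30/D123/D141) pseudokinase flagging.
6. **Mutation enrichment** — per-kinase per-site mutation fractions
   averaged across kinases, Mann–Whitney contrasts of SDR vs catalytic,
   regulatory and other domain positions, and per-site frequency
   contrasts between specificity classes.

A first-class synthetic-data module generates every input with planted
ground truth (archetype PWMs, phosphosite samples, alignments with
planted determinant columns, ortholog families, enriched mutation
tables), so the whole pipeline is testable end to end without any
database access.

## Worked example

Build a synthetic cohort of 24 kinases (12 proline-directed at +1, 12
arginine-directed at −3), cluster their preferences, and recover planted
SDRs from a synthetic domain alignment:

```r
library(kinsdr)

coh <- simulate_pwm_cohort(c("P+1", "R-3"), 12, 0.7, n_sites = 50, seed = 42)
cluster_preferences(coh$pwms, positions = c(-3, 1))
#> # A tibble: 2 × 8
#>   position label exemplar n_members top2_sum ...
#> 1       -3 R-3   R3_K11          12    0.687
#> 2        1 P+1   P1_K12          12    0.722

sim <- simulate_alignment(seed = 42)   # 30+90 sequences, 250 columns,
res <- detect_sdrs(sim$alignment, sim$labels, seed = 43)  # 3 planted SDRs
res
#> <sdr_result> 250 columns scored, 4 SDR call(s) at top-15 intersection
#>   columns: 49, 62, 65, 229
sim$sdr_columns
#> [1]  49  65 229

sel <- loocv_select(sim$alignment, sim$labels, res$sdr_columns)
sel$columns; round(sel$auc, 3)
#> [1]  49 229
#> [1] 1
```

The clustering recovers both planted preference classes with their full
memberships and labels them by their top mean residue (`R-3`, `P+1`);
`top2_sum` is the summed mean weight of the two most preferred residues
(the ≥ 0.30 specificity criterion). The SDR ensemble recovers all three
planted determinant columns (49, 65, 229) plus one false call (62), and
LOOCV feature selection builds a perfect sequence-based classifier from a
subset of them.

Every result object has broom-style `tidy()`/`glance()` methods and a
ggplot2 `autoplot()`.

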