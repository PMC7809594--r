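---
title: "Modeling kinase target specificity and its determining residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinase target specificity and its determining residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsdr)
library(dplyr)
```

## The scientific problem

Serine/threonine protein kinases recognize a short linear motif around the
phosphoacceptor — conventionally positions −5..+5, with 0 the
phosphorylated S/T. A kinase's preference (proline at +1, arginine at −3,
leucine at −5, ...) is encoded by a small number of kinase-domain residues
near the substrate groove, the *specificity-determining residues* (SDRs).
`kinsdr` implements a pipeline that (i) models each kinase's preference as
a position weight matrix (PWM) estimated from its known phosphosites,
(ii) groups kinases that share a positional preference, (iii) locates the
alignment columns that discriminate such a group from all other kinases,
(iv) turns those columns into naive Bayes classifiers that predict
specificity from sequence alone, and (v) uses the classifiers and PWM
distances to study conservation of specificity across orthologs and the
burden of cancer mutations on SDR positions.

All domain coordinates are 1-based Pfam PF00069 match-state positions;
substrate coordinates are the integers −5..+5. The Pfam map is a required
input: running an HMM aligner is deliberately outside this package's scope,
so alignments and column→domain-position maps are consumed as prepared
files.

## Specificity models (PWMs)

A PWM is a 20×11 column-stochastic matrix of relative amino-acid
frequencies. Construction follows three filters before counting:

* exact duplicate (kinase, substrate, site) records are dropped;
* phosphosites in the substrate's activation segment are dropped, because
  activation-loop sites conform poorly to active-site preferences;
* per kinase, a greedy redundancy filter keeps a window only if its
  identity to every previously kept window is ≤ 0.85 (matches/11; the
  terminus padding character `_` never matches). The filter is greedy in
  input order, which makes it deterministic and order-documented; it
  approximates, but does not reproduce, CD-HIT clustering.

A kinase needs at least 10 usable sites (`min_sites`); matrices built from
fewer sites are refused because they are dominated by sampling noise. The
pseudocount defaults to 0; scoring adds ε = 1e-4 inside logarithms instead.

Model quality is assessed by 10-fold cross-validation: held-out positives
and an equal-sized seeded sample from a user-supplied negative window pool
are scored with the min–max-normalized log-frequency score of
`match_score()`, and the fold AUC is the Mann–Whitney U statistic (ties
0.5). Models with mean AUC < 0.60 should be excluded from downstream
analysis. Two choices here are the package's own: the concrete match-score
normalization (AUCs depend only on the ranking, so any monotone variant
gives identical AUCs — a property the tests assert), and the negative-set
construction (the caller supplies the pool; the synthetic module provides
background-sampled windows), which keeps the AUC balanced and reproducible.
Kinases whose sites are mostly tyrosine-acceptor (> 50% Y) are flagged by
`tyrosine_type_kinases()` and are meant to be excluded from S/T analyses.

## Position-wise preference clustering

At each flanking position, each kinase contributes one PWM column
(a 20-vector); affinity propagation clusters these vectors with similarity
equal to the *negative Euclidean distance* (the negative *squared*
distance, the default of common AP implementations, is available behind a
flag). The self-preference is the median off-diagonal similarity; messages
are damped at 0.9 for up to 1000 iterations and convergence requires 100
iterations of a stable exemplar set. Affinity propagation is symmetric
under exactly tied inputs, so a deterministic, index-ordered offset of
order 1e-9 of the similarity spread is applied to the preferences; if no
exemplar emerges at all (all vectors identical) the result is a single
cluster. Both choices trade a formally arbitrary tie-break for exact
reproducibility.

Raw clusters are refined in a fixed order: (1) drop clusters whose top-two
mean residue weights sum below 0.30 (nonspecific); (2) merge clusters
preferring the same residue or residues of the same chemical group — the
groups used are {R,K}, {D,E}, {I,L,V,M}, {F,Y,W}, {S,T}, a concrete
instantiation since "similar residues" is not enumerated anywhere
authoritative; (3) drop clusters with fewer than 6 members; (4) rescue
false negatives: a non-member joins when its own weight for the cluster's
preferred residue exceeds the 40th percentile (linear interpolation) of
the member weights — reading "the 40th percentile of the top cluster
preference" as a threshold on the members' weights for that residue;
(5) purge false positives whose own argmax residue is outside the
cluster's top-3 mean residues. Size and specificity are re-checked after
rescue and purge, so every surviving cluster satisfies both invariants.
The order of rules and the rescue interpretation were genuinely open;
they are fixed as above and the refinement is idempotent on
well-separated cohorts (tested). A kinase may belong to clusters at
several positions simultaneously — an R-3 kinase can also be P+1.

## Ensemble SDR detection

Given a binary partition of a trimmed kinase-domain alignment (cluster
members vs all others), three independent column scorers are computed.
They are deliberately simplified, faithful instantiations of three
well-known SDR-detection families rather than ports of the published
tools — the ensemble consumes only ranks, and the package's validation is
planted-signal recovery, not bit-compatibility:

* **GroupSim-style**: `score = ((W_pos + W_neg)/2) · (1 − B)` with `W`
  the mean pairwise residue similarity within a class and `B` across
  classes. Similarity is BLOSUM62 min–max-normalized over the 20×20 block
  and then rescaled by `sim(a,b)/√(sim(a,a)·sim(b,b))` so that identical
  residues score exactly 1 (gap pairs score 0). The rescaling is the
  package's choice: it makes a fully conserved column score exactly 0,
  which plain min–max normalization does not (e.g. K/K would score 0.6),
  and the same unit-diagonal similarity is reused for ortholog
  conservation so "all sequences identical" means conservation 1.
* **Relief**: classic two-class Relief over columns; in each seeded
  iteration a random sequence's nearest same-class hit and other-class
  miss (Hamming distance over all columns, ties to the lowest sequence
  index) update each column by `δ(x, miss) − δ(x, hit)`. The structural
  ("3D") weighting of the original multi-class tool needs structures and
  is out of scope.
* **SPEER-style**: the across-column z-scores of (i) the symmetrized
  Kullback–Leibler divergence between class residue distributions
  (pseudocount 0.5 over the 21-symbol alphabet) and (ii) the
  between-class distance of mean physicochemical vectors
  (z-normalized Kyte–Doolittle hydropathy, net charge at pH 7 with
  histidine neutral, van der Waals volume; gap = zero vector), scaled by
  the pooled within-class standard deviation of the projections onto the
  between-class direction (+1e-6). Columns with equal class means get
  component (ii) = 0; with a single column, z-scores are defined as 0.

Columns with more than 20% gaps are removed first (strictly greater, so a
column at exactly 20% survives). Each method ranks columns by descending
score with ties broken by ascending column index, and the SDR call is the
intersection of the three top-15 lists. Ranks are computed over retained
alignment columns; Pfam positions are attached afterwards where mapped.

## Specificity classifiers

For each preference, kinases are labeled positive when the summed PWM
frequency of the preferred residue(s) at the preference position is at
least 3× (alternatively 4× or 5×) the proteome background. A two-class
naive Bayes model over the residues at the SDR columns is trained with a
fixed class prior of 0.5 — so a prediction is not biased by how many
positives the training set happens to contain — and a Laplace correction
of 0.5 over a 21-symbol alphabet that includes the gap, so orthologs with
gapped SDRs remain scorable. Leave-one-out cross-validation over every
non-empty subset of the candidate columns (exhaustive search; the shipped
feature sets have at most 4 columns, and the cap is 8) selects the subset
maximizing the pooled held-out AUC, with ties resolved toward fewer
features and then lexicographic column order.

The shipped per-preference feature sets (`default_feature_sets()`) are,
in domain coordinates: P+1 {159, 188, 196}; P-2 {82, 162, 188}; R-2
{127, 162, 189}; R-3 non-CMGC {82, 86, 127, 162}; R-3 CMGC
{86, 127, 189}; L-5 {86, 189}. R-3 is modeled separately for CMGC and
non-CMGC kinases because the two groups bind the −3 arginine differently;
`predict_specificities()` routes each query by its group label and errors
if an R-3 query lacks one. R-2 retains the cooperative pair 127/189 by
configuration even though single-column scorers cannot detect it. A
specificity is *called* when the posterior strictly exceeds 0.9.

One numerical caveat: with Laplace smoothing, a feature column that is
constant across the training data contributes identical likelihoods to
both classes only when the class sizes are equal; the
uninformative-feature invariance is therefore validated on balanced
cohorts.

## Ortholog conservation and divergence

Specificity distance between two kinases is the Frobenius distance of
their PWMs. The within-kinase null subsamples n = 23 sites (the median
model size in curated data) 100 times — without replacement when enough
sites exist, with replacement otherwise — and takes all pairwise
distances. An ortholog pair is called divergent when its distance strictly
exceeds the median distance of random kinase pairs. Sequence conservation
per alignment column is the mean pairwise unit-diagonal BLOSUM62
similarity described above, averaged over SDR / Catalytic / Domain
position categories; specificity conservation of an ortholog group is the
mean classifier posterior across the group's sequences, with divergence
declared below 0.5. Pseudokinases are flagged by substitutions (or gaps)
at the catalytic triad — K30, D123, D141 in domain coordinates; the
canonical residues are inferred from standard kinase catalytic
architecture.

## Mutation enrichment

Per kinase with at least one domain mutation, the fraction of its
mutations at each domain position is computed; per-site means across
kinases (not pooled counts) prevent hotspot kinases from dominating.
Sites are grouped as Catalytic (18 printed positions), Regulatory (22),
SDR (10 substrate-proximal positions) and Other, and every category pair
is compared by a two-sided Mann–Whitney test with normal approximation
and tie correction; when every observation ties across both groups the
test statistic has zero variance and the p-value is defined as 1.
Positions 157 and 158 appear in both the regulatory and SDR literature
lists; a two-group test needs disjoint categories, so they default to SDR
(they are substrate-proximal) and can be flipped with
`domain_categories(sdr_overlap = "Regulatory")`. The per-site frequency
contrast between two called specificity classes (`specificity_contrast()`)
lets a kinase called for both classes contribute to both axes.

## The synthetic-data generators

Every pipeline stage is validated on generated inputs with planted ground
truth; all generators are pure functions of their arguments and a
mandatory seed.

* `make_archetype_pwm()` mixes a preference residue into a background at
  a chosen strength: the preferred cell gets `strength + (1−strength)·b`,
  the rest `(1−strength)·b`. `sample_sites()` draws windows
  column-independently, forcing S/T at position 0 (ratio 0.7).
* `simulate_pwm_cohort()` samples 50 sites per kinase from its class
  archetype and rebuilds the empirical PWM, giving realistic within-class
  noise for clustering tests.
* `simulate_alignment()` draws each column's residue profile from a
  symmetric Dirichlet (concentration 0.5, giving strongly conserved
  columns with visible spread in null scores); at planted columns the
  background is drawn over the 19 non-determinant residues, positives
  carry the determinant with probability q, and negatives draw from the
  background — so the planted columns are the only systematically
  class-discriminating columns and ground truth is well defined. The
  default conditions are 30 positives, 90 negatives, 250 columns, 3
  planted columns, q = 0.9.
* `simulate_orthologs()` uses a star phylogeny: each ortholog mutates
  independently from the reference at a per-site rate, with SDR positions
  held fixed or flipped to a specified residue with a given probability.
  No tree shape is modeled because no downstream statistic uses branch
  structure.
* `simulate_mutations()` distributes a fixed per-kinase mutation count
  multinomially with SDR positions upweighted by an enrichment factor.

What the generators do **not** emulate: phylogenetic correlation between
kinases (real kinases are not exchangeable draws), compositional bias of
real proteomes, alignment errors, correlated (cooperative) SDR pairs such
as 127/189, and database-specific curation noise. Passing the planted
benchmarks therefore demonstrates that the machinery is correct and
calibrated, not that the real-data headline findings would reproduce from
arbitrary inputs.

## Validation problem sizes

The packaged checks run at these sizes, chosen to match the defaults
above while keeping the suite quick: 50 planted-alignment replicates for
SDR recovery (all planted columns in the top-15 intersection with at most
2 false calls per replicate); 10 replicates of LOOCV classifier recovery
(AUC ≥ 0.95); 5 clustering cohorts at archetype strength 0.5 (Rand index
≥ 0.95); 20 null cross-validation replicates (mean AUC within 0.5 ± 0.12);
1000 category-label permutations for the Mann–Whitney type-I error
(0.05 ± 0.02); 200-kinase mutation cohorts at 3× SDR enrichment
(p < 0.01); and 10 ortholog groups per substitution/flip condition.

## Known limitations

* The three column scorers are single-column methods; cooperative SDR
  pairs are invisible to them and enter only via configured feature sets.
* The published real-data AUCs and ortholog divergence fractions depend
  on curated phosphosite corpora, TCGA mutation tables and Compara
  ortholog sets that this package does not download; with equivalent
  user-supplied tables the pipeline reproduces the analysis design, and
  those numbers serve as regression values only.
* Affinity propagation's cluster count is sensitive to the
  self-preference; the median off-diagonal similarity is the standard
  default but can over- or under-split borderline cohorts.
* Structure-based analyses (contact profiling, homology models, molecular
  dynamics) and phylogeny/ancestral reconstruction are out of scope.
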