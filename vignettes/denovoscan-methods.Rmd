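---
title: "Methods: identifying and characterizing de novo gene candidates"
author: "denovoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing de novo gene candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoscan)
```

# The problem

A de novo gene is a protein-coding gene born from previously non-genic
DNA. Claiming de novo birth for a gene in a focal genome (the motivating
system is *Drosophila melanogaster* inside a ladder of increasingly
distant relatives) requires two kinds of evidence at once: orthologous
sequence in closer relatives showing where the gene *is* present, and
orthologous **non-coding** sequence in more distant relatives showing the
ancestral, non-genic state. `denovoscan` implements that identification
logic, the score calibration it depends on, and the downstream
characterization statistics (protein foldability, structural-ensemble
convergence, expression specificity, stage clustering, sequence
features), all exercisable on synthetic data with planted ground truth.

# Identification model

Species are grouped into branches `1..n` by their split from the focal
taxon (branch 1 = closest). For each query gene and each branch, the
syntenic region lifted from a whole-genome alignment is classified:

* **annotated ortholog** — the region overlaps an annotated gene whose
  reciprocal blastp E-value is `< 0.05`;
* **ambiguous** — annotated overlap but E-value `>= 0.05`. Such a region
  is genic yet of unclear homology, so it supports neither an ortholog
  call nor non-genic ancestry (a deliberate design choice; treating it
  either way would let weak evidence decide a candidate's fate);
* **unannotated ortholog** — an unannotated region whose gene-structure
  prediction score is significantly above random expectation
  (calibrated p `<= 1e-6`, see below);
* **non-genic** — an unannotated region whose coding potential is
  indistinguishable from random sequence;
* **no alignment** — nothing lifted.

The origination branch `Br_i` is the *furthest* branch carrying an
ortholog. Patchy profiles (ortholog at branches 2 and 7, non-genic in
between) are read as secondary losses, not contradictions: the inferred
branch is still 7. A candidate additionally requires (i) at least one
non-genic hit in a branch beyond `Br_i`, (ii) no arthropod-outgroup
homolog at blastp E `< 0.05`, (iii) no "reliable" distant homolog — the
same subject species in at least two independent searches (blastp,
iterative jackhmmer with and without manual profile pruning) at
E `<= 0.001`, after discarding profile-search rows whose best-1-domain
E-value exceeds `1e-5` — and (iv) no validated unannotated outgroup
homolog from tblastn follow-up (canonical start and stop, no
frameshifts, exon count matching the query or one of its orthologs).
Filters run in that order and the first failing stage is recorded, so
the funnel counts are auditable per stage.

A gene with no ortholog in any branch gets branch index 0 (focal-lineage
only). The deepest branch of a ladder has no outgroup, so a gene whose
orthologs reach it can never satisfy requirement (i) — the real study
resolves this with outgroup taxa beyond the deepest branch.

Genomic context is classified as **intragenic** when the gene span
overlaps any other annotated gene span on either strand (0-based
half-open intervals; abutting spans do not overlap), else **intergenic**.

# Score calibration against random expectation

Unannotated syntenic regions are judged by a spliced-alignment score of
the query protein against the region's DNA. To decide what score is
"significant", the package builds a null distribution: for each protein
length `N` on a grid (default 15, 20, 25, 50, 75, 100, 200, 500, 1000),
it scores many independent random protein/DNA pairs — the protein drawn
i.i.d. from proteome amino-acid frequencies, the DNA of length
`3*(N+300)` drawn at coding GC content — and records the per-length mean
and SD. Both summaries are then fitted as functions of `N` by a
two-phase exponential decay

$$S(N) = S_0 + \mathrm{SpanFast}\,e^{-K_\mathrm{fast}N}
             + \mathrm{SpanSlow}\,e^{-K_\mathrm{slow}N},$$

with $\mathrm{SpanFast} = (S_0 - S_\mathrm{min})\cdot
\mathrm{PercentFast}/100$ and $\mathrm{SpanSlow} = (S_0 -
S_\mathrm{min})\cdot(1-\mathrm{PercentFast}/100)$, under the constraints
$K_\mathrm{fast} \ge K_\mathrm{slow} \ge 0$ and $0 \le
\mathrm{PercentFast} \le 100$. Because the null mean *rises* with `N`
toward its plateau $S_0$, the fitted spans are negative, i.e.
$S_\mathrm{min} > S_0$ in this parameterization; the package therefore
does not constrain the sign of $S_0 - S_\mathrm{min}$. The objective is
multimodal in the rate constants, so the Levenberg–Marquardt solver
(`minpack.lm`) is restarted from a grid of log-spaced starting values
with the constraint enforced by the substitution $K_\mathrm{slow} =
K_\mathrm{fast}\cdot r$, $r \in [0,1]$; the best residual sum of squares
wins. Exactly flat data short-circuits to the degenerate exact solution.

An observed score `S` for a query of length `N` is converted to the
upper-tail probability of a Gaussian with the predicted mean and SD
(SD floored at `1e-6` to keep p-values defined for degenerate tables);
the region is called genic at p `<= 1e-6`, with the boundary inclusive.
Tests use 40–1000 replicates per length rather than the production-scale
10,000, with CLT-scaled tolerances; the acceptance checks use 1000
replicates per grid length and verify that the fitted mean is monotone
in `N` and that fresh random pairs essentially never reach the genic
threshold.

## The surrogate spliced-alignment scorer

External gene-structure predictors report a spliced-alignment score that
includes splice-site penalties; the calibration framework, not the
external tool, is the method's contribution, so the package ships a
self-contained scorer with the same character. It is a local dynamic
program over (protein residues consumed, DNA bases consumed) with four
moves: codon match (BLOSUM62 of the residue against the translated
codon; aligning to a stop codon scores −6), protein-only gap and
DNA-codon gap (both affine, open −11 / extend −1), and an intron — a
flat −8 penalty for skipping any `>= 40` nt of DNA. Cells floor at zero
and the score is the global maximum (the empty alignment scores 0).
The intron move is computed with per-row prefix maxima, so the whole DP
is `O(N·M)` and is implemented in C++. There is no GT..AG splice-site
sequence requirement — the penalty stands in for the splice model. The
implementation is verified against exhaustive enumeration of all move
sequences on small instances (N ≤ 8, DNA ≤ 60 nt).

# Foldability and structure metrics

From a per-residue confidence profile (pLDDT, 0–100), a protein is

* **well folded** if mean pLDDT `> 80` *and* the fraction of confident
  residues (pLDDT `> 70`) is `> 0.90`;
* else **partially folded** if `> 30%` of residues, or a run of more
  than 50 consecutive residues, are confident;
* else **not folded**.

All thresholds are strict, so a mean of exactly 80 or a run of exactly
50 falls to the lower class. The classifier is monotone: raising any
residue's score never demotes the class.

Structural similarity uses the TM-score with the standard normalization
distance `d0 = max(0.5, 1.24*(L-15)^(1/3) - 1.8)` (floored for `L <=
21`, where the cube-root expression turns non-positive). Residues are
paired by index — ensembles share one sequence — so no alignment search
is needed. Superposition is least-RMSD Kabsch (SVD with reflection
correction); the TM sum is then refined by re-superposing on the subset
of residues with deviation `< d0` until the subset stabilizes (at most
20 rounds), and the best score over rounds is reported. **Ensemble
convergence** is the mean pairwise TM-score over all model pairs,
multiplied by 100 to sit on the pLDDT scale; when energies are present
the 20 lowest-energy models are selected first (ties broken by model
id), and ensembles supplied without energies are used whole.

Conformations are clustered by density peaks on the pairwise
backbone-RMSD matrix (the clustering metric is a package choice; the
source procedure clusters MD conformations without naming one): density
`rho_i` counts neighbors within a cutoff `d_c` (default the 2nd
percentile of off-diagonal distances), separation `delta_i` is the
distance to the nearest higher-density point (ties in `rho` broken by
index; the global peak takes the maximum distance), centers maximize
`rho * delta`, and remaining points inherit the label of their nearest
higher-density neighbor in decreasing-density order. Representatives
are the cluster centers ordered by cluster size; the refined model is
the center of the largest cluster. A model whose maximum TM-score
against a reference set is strictly below 0.5 is flagged as a potential
novel fold.

# Expression statistics

FPKM converts to TPM per tissue column, `TPM_i = FPKM_i / sum_j FPKM_j
* 1e6`; the converted matrix is tagged and re-normalization is refused.
Genes are kept when their maximum TPM strictly exceeds 0.1. Male
specificity is `z = (TPM_male - TPM_female) / sqrt(sd_male^2 +
sd_female^2)` over whole-body replicate SDs, min-max normalized to
[0, 1] across genes. Tissue specificity is tau, `sum_i (1 - x_i/x_max) /
(N - 1)`, computed on the raw (not log) TPM vector — no log transform is
applied because none is part of the source procedure. Both normalized z
and tau are invariant under positive rescaling of the expression values.

Testis stage profiles over the six spermatogenesis stages (early/late
spermatogonia, spermatocytes, spermatids) are row-standardized ("scaled"
is interpreted as per-gene standardization, the standard choice for
expression heat-map clustering: it makes cluster archetypes
amplitude-free), reduced to three principal components
(column-centered SVD), and clustered by k-means with k-means++-style
restarts (50 random starts, fixed seed stream; the initialization is a
package choice). Clusters are renumbered 1..4 by the
expression-weighted mean stage index of their centroids so cluster 1
peaks earliest in spermatogenesis.

Gene-age trends are two-sided rank correlations of a per-gene property
against the origination branch index: Kendall's tau-b (tie-corrected —
branch indices are heavily tied, plain tau-a would be misleading) and
Spearman's rho, via `stats::cor.test`.

# The synthetic-data generator

The generator's defaults *are* the study conditions under which the
pipeline is validated; they are fixed here and not revisited:

* 9 outgroup branches, 500 genes, 30% planted de novo. Origination
  branches are uniform over branches 1–8 and zero at branch 9: the
  deepest branch of the ladder has no outgroup, so a gene planted there
  could never carry the required non-coding evidence (in the real design
  that evidence comes from taxa beyond the deepest branch).
* 20% of ortholog hits are left unannotated (the true
  annotated/unannotated split is not published; this is an exposed
  knob), carrying genic p-values drawn log-uniform from 1e-30..1e-8;
  non-genic hits draw p uniform on 0.01..1; outgroup species lack any
  alignment 10% of the time, with at least one non-genic outgroup hit
  forced for plantable candidates.
* True homolog E-values are log10-uniform on [−30, −6]; spurious rows
  occur for 5% of unrelated genes with log10 E-values on [−2, +2] —
  unrelated searches mostly return nothing, as real homology searches
  do below their reporting cutoffs.
* pLDDT archetypes: well — every residue N(88, 4); partial — one
  contiguous segment of 60..0.75·L residues at N(80, 4), remainder
  N(45, 8); none — N(40, 8); all clipped to [0, 100]. The archetype
  means sit several SDs from the classification thresholds, so the
  planted classes are unambiguous. Archetype weights (6/54/40%)
  approximate the observed well/partial/none proportions.
* Structure ensembles: an ideal α-helix CA trace (rise 1.5 Å, 100° turn,
  radius 2.3 Å) under 0.5 Å Gaussian noise and random rigid motion, vs.
  an independent self-avoiding random walk per model (3.8 Å steps).
* Expression: 27 fly-atlas-like tissues from per-gene gamma weight
  profiles (broad for ancient genes, concentrated for de novo genes,
  testis-loaded for male-biased genes); male-biased genes have a true
  male/female ratio of 4–10×; whole-body replicate SDs are 10% of the
  mean, and observed means carry one replicate-level noise draw. Stage
  profiles draw from four standardized Gaussian-bump templates peaking
  at stages 1, 2.8, 4.6 and 6 (width 1.1) plus N(0, 0.15) noise — a
  noise level chosen once as realistic for averaged single-cell stage
  profiles and comfortably within the clustering's recovery range.
* Protein lengths are uniform on 90..250 residues (short, as de novo
  genes are); CDS are ATG + random non-stop codons + stop at coding GC.

All randomness flows from one master seed; each generator derives a
fixed substream, and per-gene draws use per-gene substream seeds drawn
once, so outputs are reproducible gene-by-gene. What the generator does
*not* emulate: sequence evolution under a substitution model, alignment
blocks, assembly artifacts, expression count noise, or correlated
evidence errors across branches. Passing the planted-recovery tests
therefore demonstrates the correctness of the decision logic and
statistics, not robustness to the full error structure of real
comparative data.

# Numerical choices and degenerate inputs

* Decay fit: 8 multi-starts; flat input short-circuits to the exact
  degenerate solution; the fitted SD curve is floored at 1e-6 score
  units when predicting.
* Stage-profile scaling floors the row SD at 1e-12, so constant rows map
  to zeros rather than NaN.
* PCA below the requested rank zero-pads coordinates with a warning.
* Density peaks breaks all ties (density, gamma, center order) by index,
  which keeps the clustering deterministic; under exact ties the labels
  are therefore not permutation-equivariant, but generic inputs are.
* Kabsch on degenerate (collinear) point sets warns and returns a
  best-effort rotation.
* k-means uses 50 restarts under a fixed seed; ORF records below 75 nt
  (stop included) are dropped — "longer than 75 nt (coding 25 amino
  acids)" is read inclusively, with the threshold exposed as an
  argument; nested ORFs share the parent stop and are deduplicated by
  (start, strand, frame).
* Problem sizes in the shipped tests (replicates per length, simulated
  gene counts, Monte-Carlo draws) are scaled to complete a full run in
  minutes on one CPU while leaving the statistical margins of every
  check intact.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
cal <- build_calibration(n_reps = 200)        # null-score calibration
cfg <- simulation_config(n_genes = 200, seed = 42)
sim <- simulate_dataset(cfg)                  # planted ground truth
res <- run_pipeline(sim)
res$funnel                                    # identification funnel
head(res$report)                              # per-gene characterization
```

# Known limitations

The surrogate scorer is not Genewise/Spaln: absolute score scales
differ, so calibration tables are only meaningful for scores produced by
the same scorer. The one-tailed Gaussian is an approximation to the
null score distribution; its extreme tail (1e-6) is checked empirically
only down to the resolution a few thousand null draws allow. The
density-peaks `d_c` heuristic (2nd percentile) can be inappropriate for
very small ensembles — it is exposed as an argument. Branch inference
collapses each branch to one evidence slot; with several species per
branch, an ortholog in any species marks the branch orthologous and any
non-genic species provides outgroup support.
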