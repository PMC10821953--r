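# denovoscan

Identification and characterization of **de novo gene candidates** —
protein-coding genes born from previously non-genic DNA — in a focal
genome embedded in a ladder of outgroup species, for researchers in
molecular evolution and comparative genomics.

A candidate call needs two kinds of evidence at once: orthologs
(annotated or predicted) in the branches up to the origination branch
`Br_i`, and orthologous **non-coding** sequence beyond `Br_i` showing the
ancestral state, with distant-homolog filters guarding against missed
annotation. The package implements that decision funnel together with
the statistics around it:

* **Score calibration.** Gene-structure prediction scores for
  unannotated syntenic regions are judged against a simulated null:
  random protein/DNA pairs are scored with a spliced local aligner
  (codon matches under BLOSUM62, affine gaps, flat intron penalty for
  skips ≥ 40 nt), and the null mean and SD are fitted as functions of
  protein length N by a two-phase exponential decay

  `S(N) = S0 + SpanFast·exp(−KFast·N) + SpanSlow·exp(−KSlow·N)`,

  `SpanFast = (S0−Smin)·PercentFast/100`, `SpanSlow =
  (S0−Smin)·(1−PercentFast/100)`, `KFast ≥ KSlow ≥ 0`. A region is
  called genic when its upper-tail Gaussian p-value under the predicted
  mean/SD is ≤ 1e-6.
* **Branch inference and filters.** Per-branch syntenic hit classes →
  furthest-ortholog branch → outgroup non-genic support → arthropod
  exclusion (E < 0.05) → two-search consensus homolog filter
  (E ≤ 0.001, best-domain pre-filter 1e-5) → validated unannotated
  homolog filter; every stage outcome is recorded so the funnel is
  auditable.
* **Foldability.** pLDDT profiles classify as well folded
  (mean > 80 and P(confident) > 0.90), partially folded (> 30% confident
  residues or a > 50-residue confident run), or not folded; TM-score
  (with Kabsch superposition and subset refinement), ensemble
  convergence (mean pairwise TM-score × 100), density-peaks conformation
  clustering, and a novel-fold flag (max TM against references < 0.5).
* **Expression.** FPKM→TPM, male-specificity z-scores (raw and min-max
  normalized), tissue-specificity tau, stage-profile scaling, PCA,
  k-means stage clusters renumbered by developmental timing, and
  Kendall/Spearman gene-age trend tests.
* **Sequence features.** GC content, per-amino-acid codon GC, optimal
  codons, optimal-codon fractions, six-frame ORF scanning with nested
  ORFs, and ATAC peak proximity (±500 bp windows).
* **Synthetic data.** A generator that plants origination branches,
  foldability archetypes, expression archetypes and male bias with known
  ground truth, so the whole pipeline is testable end to end without
  external downloads.

## Worked example

```r
library(denovoscan)

# a synthetic dataset with planted ground truth
cfg <- simulation_config(n_genes = 200, seed = 42)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim)
res$funnel
#>                  total                aligned       nongenic_support
#>                    200                    200                     63
#> after_arthropod_filter  after_homolog_filters             candidates
#>                     63                     63                     63
#> attr(,"by_branch")
#>  1  2  3  4  5  6  7  8
#> 13  6  7  3  5  9 14  6

# how many planted candidates came back with their true branch?
m <- merge(sim$truth[sim$truth$origin == "de_novo", ], res$calls,
           by = "gene_id")
mean(m$status == "candidate" & m$branch == m$true_branch)
#> [1] 1

head(res$report[, c("gene_id", "status", "branch", "fold_class", "tau")])
#>   gene_id                       status branch       fold_class       tau
#> 1   g0001 rejected_no_nongenic_support      9 partially_folded 0.5217182
#> 2   g0002                    candidate      2 partially_folded 0.9769642
#> 3   g0003                    candidate      4      well_folded 0.8817999
#> 4   g0004 rejected_no_nongenic_support      9 partially_folded 0.6146938
#> 5   g0005 rejected_no_nongenic_support      9       not_folded 0.7456270
#> 6   g0006                    candidate      1       not_folded 0.9083958
```

The funnel counts the genes surviving each identification stage (always
non-increasing), with per-branch candidate counts attached; `report`
joins the candidate calls with per-gene foldability, expression
specificity (z-score, tau), GC content and peak proximity. All 63
planted candidates in this run are recovered with their exact planted
branch; the "rejected" genes are the planted ancient ones, which have
orthologs in every branch and thus no outgroup non-coding support.

Null-score calibration and the genic call:

```r
set.seed(1)
cal <- build_calibration(n_reps = 200)   # default grid 15..1000
predict_mean_sd(cal, 120)                # null mean/SD for a 120-residue query
p <- sim$sequences$protein[["g0003"]]    # a query protein
d <- sim$sequences$cds[["g0003"]]        # a DNA target
sc <- spliced_align_score(p, d)
genic_pvalue(sc$score, sc$protein_length, cal)
```

## Package layout

* `R/` — synthetic generator, alignment scorer (+ `src/` C++ DP),
  calibration, homology pipeline, structure metrics, expression metrics,
  sequence features, orchestration.
* `tests/testthat/` — unit and property tests per module, with
  independent oracles (exhaustive alignment enumeration, quaternion
  superposition, quadratic interval scans, O(n²) rank statistics), plus
  the end-to-end acceptance checks.
* `vignettes/denovoscan-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, degenerate-input behavior and
  limitations.
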