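# Syntenic hit classification, branch inference, filters, and the
# candidate-calling funnel, checked against a direct rule evaluator.

test_that("syntenic hits classify by the annotated/unannotated rules", {
  expect_equal(classify_syntenic_hit(annotated_evalue = 1e-10),
               "annotated_ortholog")
  expect_equal(classify_syntenic_hit(annotated_evalue = 0.2), "ambiguous")
  expect_equal(classify_syntenic_hit(genic_pvalue_value = 0.3), "nongenic")
  expect_equal(classify_syntenic_hit(genic_pvalue_value = 1e-8),
               "unannotated_ortholog")
  expect_equal(classify_syntenic_hit(aligned = FALSE), "no_alignment")
  expect_error(classify_syntenic_hit(annotated_evalue = 1e-3,
                                     genic_pvalue_value = 0.5),
               "malformed")
  expect_error(classify_syntenic_hit(), "malformed")
})

test_that("furthest ortholog branch follows the max rule, tolerating gaps", {
  prof <- c(rep("annotated_ortholog", 4), rep("nongenic", 5))
  expect_equal(infer_furthest_ortholog_branch(prof), 4L)
  patchy <- c("no_alignment", "annotated_ortholog", rep("nongenic", 4),
              "unannotated_ortholog", "nongenic", "nongenic")
  expect_equal(infer_furthest_ortholog_branch(patchy), 7L)
  expect_equal(infer_furthest_ortholog_branch(rep("nongenic", 9)), 0L)
  expect_error(infer_furthest_ortholog_branch(character(0)), "empty")
})

test_that("outgroup non-genic support requires a nongenic branch beyond Br_i", {
  prof <- c(rep("annotated_ortholog", 4), "no_alignment", "nongenic",
            rep("no_alignment", 3))
  expect_true(has_outgroup_nongenic_support(prof, 4))
  prof2 <- c(rep("annotated_ortholog", 4), rep("no_alignment", 5))
  expect_false(has_outgroup_nongenic_support(prof2, 4))
  expect_false(has_outgroup_nongenic_support(rep("annotated_ortholog", 9), 9))
  expect_error(has_outgroup_nongenic_support(prof, 10), "range")
})

test_that("consensus filter needs two searches at the cutoff", {
  ev <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    d
  }
  two <- ev(subject_species = "X", search = c("blastp", "jackhmmer_a"),
            evalue = c(1e-4, 5e-4),
            best_domain_evalue = c(NA, 1e-7))
  expect_true(consensus_homolog_filter(two)$reliable)
  one <- ev(subject_species = "X", search = "blastp", evalue = 1e-20,
            best_domain_evalue = NA)
  expect_false(consensus_homolog_filter(one)$reliable)
  weak <- ev(subject_species = "X", search = c("blastp", "jackhmmer_a"),
             evalue = c(0.01, 0.01), best_domain_evalue = c(NA, 1e-7))
  expect_false(consensus_homolog_filter(weak)$reliable)
  # profile rows with poor best-domain E-value are discarded first
  drift <- ev(subject_species = "X",
              search = c("jackhmmer_a", "jackhmmer_b"),
              evalue = c(1e-6, 1e-6), best_domain_evalue = c(1e-3, 1e-3))
  expect_false(consensus_homolog_filter(drift)$reliable)
})

test_that("unannotated homolog validation applies all three criteria", {
  expect_true(validate_unannotated_homolog(TRUE, TRUE, 0, 2, query_exons = 2))
  expect_false(validate_unannotated_homolog(TRUE, TRUE, 1, 2, query_exons = 2))
  expect_false(validate_unannotated_homolog(FALSE, TRUE, 0, 2, query_exons = 2))
  # exon count may match an ortholog instead of the query itself
  expect_true(validate_unannotated_homolog(TRUE, TRUE, 0, 3,
                                           query_exons = c(2, 3)))
  expect_error(validate_unannotated_homolog(TRUE, NA, 0, 2, 2), "malformed")
})

test_that("genomic context is any-strand span overlap under half-open coords", {
  ann <- data.frame(gene_id = c("a", "b", "host"),
                    contig = "chr2L",
                    start = c(1000L, 20000L, 500L),
                    end = c(2000L, 21000L, 5000L),
                    stringsAsFactors = FALSE)
  expect_equal(classify_genomic_context(ann[1, ], ann), "intragenic")
  expect_equal(classify_genomic_context(ann[2, ], ann), "intergenic")
  # abutting end-to-start spans do not overlap
  ab <- data.frame(gene_id = c("x", "y"), contig = "c",
                   start = c(100L, 200L), end = c(200L, 300L),
                   stringsAsFactors = FALSE)
  expect_equal(classify_genomic_context(ab[1, ], ab), "intergenic")
})

make_hits <- function(profiles) {
  # profiles: named list gene_id -> class vector
  do.call(rbind, lapply(names(profiles), function(id) {
    data.frame(gene_id = id, branch = seq_along(profiles[[id]]),
               class = profiles[[id]], stringsAsFactors = FALSE)
  }))
}

test_that("candidate decisions equal the rule evaluator on all 3-branch profiles", {
  classes <- denovoscan:::HIT_CLASSES
  grids <- expand.grid(b1 = classes, b2 = classes, b3 = classes,
                       stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(grids)), function(i) unlist(grids[i, ]))
  names(profiles) <- sprintf("p%03d", seq_along(profiles))
  calls <- call_de_novo_candidates(make_hits(profiles))
  for (i in seq_along(profiles)) {
    want <- oracle_branch_decision(profiles[[i]])
    row <- calls[calls$gene_id == names(profiles)[i], ]
    expect_equal(row$status, want$status, info = paste(profiles[[i]], collapse = ","))
    if (!is.na(want$branch)) expect_equal(row$branch, want$branch)
  }
})

test_that("candidate decisions match the rule evaluator on sampled 5-branch profiles", {
  set.seed(99)
  classes <- denovoscan:::HIT_CLASSES
  profiles <- lapply(1:300, function(i) sample(classes, 5, replace = TRUE))
  names(profiles) <- sprintf("q%03d", seq_along(profiles))
  calls <- call_de_novo_candidates(make_hits(profiles))
  for (i in seq_along(profiles)) {
    want <- oracle_branch_decision(profiles[[i]])
    row <- calls[calls$gene_id == names(profiles)[i], ]
    expect_equal(row$status, want$status)
  }
})

test_that("arthropod and distant homolog evidence reject candidates", {
  prof <- list(g1 = c(rep("annotated_ortholog", 2), rep("nongenic", 3)))
  hits <- make_hits(prof)
  base <- call_de_novo_candidates(hits)
  expect_equal(base$status, "candidate")
  arth <- data.frame(gene_id = "g1", evalue = 1e-30)
  expect_equal(call_de_novo_candidates(hits, arthropod = arth)$status,
               "rejected_arthropod_homolog")
  weak_arth <- data.frame(gene_id = "g1", evalue = 0.5)
  expect_equal(call_de_novo_candidates(hits, arthropod = weak_arth)$status,
               "candidate")
  ev <- data.frame(gene_id = "g1", subject_species = "Z",
                   subject_branch = Inf,
                   search = c("blastp", "jackhmmer_a"),
                   evalue = c(1e-5, 1e-5), best_domain_evalue = NA,
                   stringsAsFactors = FALSE)
  expect_equal(call_de_novo_candidates(hits, evidence = ev)$status,
               "rejected_distant_homolog")
  # homolog within Br_i does not count against the candidate
  near <- transform(ev, subject_branch = 2)
  expect_equal(call_de_novo_candidates(hits, evidence = near)$status,
               "candidate")
  val <- data.frame(gene_id = "g1", validated = TRUE)
  expect_equal(call_de_novo_candidates(hits, validated = val)$status,
               "rejected_distant_homolog")
})

test_that("adding distant evidence never promotes toward candidate; deeper orthologs never lower Br_i", {
  set.seed(17)
  classes <- denovoscan:::HIT_CLASSES
  for (rep in 1:40) {
    prof <- sample(classes, 6, replace = TRUE)
    hits <- make_hits(list(g = prof))
    before <- call_de_novo_candidates(hits)
    arth <- data.frame(gene_id = "g", evalue = 1e-10)
    after <- call_de_novo_candidates(hits, arthropod = arth)
    expect_false(before$status != "candidate" && after$status == "candidate")
    # upgrade a random branch to ortholog: inferred branch is non-decreasing
    b <- sample(6, 1)
    prof2 <- prof; prof2[b] <- "annotated_ortholog"
    expect_gte(infer_furthest_ortholog_branch(prof2),
               infer_furthest_ortholog_branch(prof))
  }
})

test_that("mismatched evidence keys are rejected with offenders listed", {
  hits <- make_hits(list(g1 = c("annotated_ortholog", "nongenic")))
  bad <- data.frame(gene_id = "ghost", evalue = 1e-9)
  expect_error(call_de_novo_candidates(hits, arthropod = bad), "ghost")
})

test_that("classify_hit_table matches per-record classification", {
  set.seed(23)
  n <- 200
  kind <- sample(c("ann", "pred", "none"), n, replace = TRUE)
  tab <- data.frame(
    gene_id = sprintf("g%03d", 1:n), branch = sample(9, n, TRUE),
    annotated_evalue = ifelse(kind == "ann", 10^runif(n, -30, 2), NA),
    genic_pvalue = ifelse(kind == "pred", 10^runif(n, -12, 0), NA))
  out <- classify_hit_table(tab)
  for (i in seq_len(n)) {
    want <- classify_syntenic_hit(
      annotated_evalue = tab$annotated_evalue[i],
      genic_pvalue_value = tab$genic_pvalue[i],
      aligned = kind[i] != "none")
    expect_equal(out$class[i], want)
  }
})
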