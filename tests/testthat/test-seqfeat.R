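# GC content, codon usage, ORF scanning (vs brute-force oracle), peak
# proximity (vs quadratic oracle).

test_that("gc_content matches direct counting and ignores N", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNNNN"), 0.5)
  expect_error(gc_content("NNN"), "undefined")
  expect_error(gc_content("ATXG"), "outside")
})

test_that("gc_content is invariant under reversal and complementation", {
  set.seed(40)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    expect_equal(gc_content(denovoscan:::revcomp(s)), gc_content(s))
    expect_equal(gc_content(paste(rev(strsplit(s, "")[[1]]), collapse = "")),
                 gc_content(s))
  }
})

test_that("per-amino-acid codon GC equals a brute-force tally", {
  expect_equal(unname(codon_gc_by_aa(paste(rep("GGC", 5), collapse = ""))["G"]), 1.0)
  expect_equal(unname(codon_gc_by_aa(paste(rep("AAA", 4), collapse = ""))["K"]), 0.0)
  set.seed(41)
  cds <- replicate(5, {
    body <- sample(c("CTG", "TTA", "GGC", "AAA", "ATG", "GAT"), 20,
                   replace = TRUE)
    paste(c("ATG", body, "TAA"), collapse = "")
  })
  got <- codon_gc_by_aa(cds)
  # oracle: tally every codon occurrence by translated amino acid
  gcode <- Biostrings::GENETIC_CODE
  all_cods <- unlist(lapply(cds, function(s) {
    n <- nchar(s)
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    cods[-length(cods)]
  }))
  aa <- unname(gcode[all_cods])
  gcfrac <- sapply(strsplit(all_cods, ""),
                   function(b) mean(b %in% c("G", "C")))
  want <- tapply(gcfrac, aa, mean)
  expect_equal(unname(got[names(want)]), as.numeric(want),
               tolerance = 1e-12)
})

test_that("codon usage finds optimal codons with alphabetical tie-breaks", {
  cds <- paste(c("ATG", rep("CTG", 5), rep("TTA", 2), "TAA"), collapse = "")
  tab <- suppressWarnings(build_codon_usage(cds))
  expect_equal(unname(tab$optimal["L"]), "CTG")
  expect_equal(unname(tab$optimal["M"]), "ATG")
  tie <- paste(c("ATG", rep("CTG", 3), rep("TTA", 3), "TAA"), collapse = "")
  tab2 <- suppressWarnings(build_codon_usage(tie))
  expect_equal(unname(tab2$optimal["L"]), "CTG")  # alphabetically first
})

test_that("codon-usage table rebuilt from biased synthetic CDS recovers the bias", {
  set.seed(42)
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[gcode != "*"]
  # plant one preferred codon per amino acid, used 80% of the time
  planted <- vapply(split(sense, gcode[sense]),
                    function(cods) sample(cods, 1), character(1))
  cds <- replicate(40, {
    aas <- sample(names(planted), 50, replace = TRUE)
    cods <- vapply(aas, function(a) {
      if (runif(1) < 0.8) planted[[a]]
      else sample(sense[gcode[sense] == a], 1)
    }, character(1))
    paste(c(cods, "TAA"), collapse = "")
  })
  tab <- suppressWarnings(build_codon_usage(cds))
  expect_equal(tab$optimal[names(planted)], planted)
})

test_that("optimal codon fraction counts exact matches", {
  cds_ref <- paste(c(rep("CTG", 5), rep("AAA", 5), "TAA"), collapse = "")
  tab <- suppressWarnings(build_codon_usage(cds_ref))
  all_opt <- paste(c("CTG", "AAA", "TAA"), collapse = "")
  expect_equal(optimal_codon_fraction(all_opt, tab), 1.0)
  none_opt <- paste(c("TTA", "AAG", "TAA"), collapse = "")
  expect_equal(optimal_codon_fraction(none_opt, tab), 0.0)
  mixed <- paste(c(rep("CTG", 6), rep("TTA", 4), "TAA"), collapse = "")
  expect_equal(optimal_codon_fraction(mixed, tab), 0.6)
})

test_that("ORF scanner equals the brute-force scanner on random sequence", {
  set.seed(43)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
    got <- find_orfs(s)
    want <- oracle_orf_scan(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$length, want$length)
    # contract: length >= 75, divisible by 3, ATG..stop content
    expect_true(all(got$length >= 75 & got$length %% 3 == 0))
  }
})

test_that("ORF boundary length is kept at exactly 75 nt and dropped below", {
  body <- paste(rep("GCT", 23), collapse = "")
  s75 <- paste0("ATG", body, "TAA")                    # 75 nt
  expect_equal(nchar(s75), 75L)
  expect_equal(nrow(find_orfs(s75)), 1L)
  s72 <- paste0("ATG", paste(rep("GCT", 22), collapse = ""), "TAA")
  expect_equal(nrow(find_orfs(s72)), 0L)
})

test_that("nested ORFs are reported and flagged", {
  inner_off <- paste(rep("GCT", 10), collapse = "")
  s <- paste0("ATG", inner_off, "ATG", paste(rep("GCT", 30), collapse = ""),
              "TAA")
  orfs <- find_orfs(s)
  plus <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_true(any(plus$nested))
  expect_equal(sum(!plus$nested), 1L)
  # both share the same stop
  expect_equal(length(unique(plus$end)), 1L)
})

test_that("ORF coordinates mirror under reverse complement", {
  set.seed(44)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  a <- find_orfs(s)
  b <- find_orfs(denovoscan:::revcomp(s))
  n <- nchar(s)
  b_mapped <- data.frame(start = n - b$end, end = n - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"),
                         length = b$length)
  b_mapped <- b_mapped[order(b_mapped$start, b_mapped$end, b_mapped$strand), ]
  expect_equal(a$start, b_mapped$start)
  expect_equal(a$end, b_mapped$end)
  expect_equal(a$strand, b_mapped$strand)
  expect_equal(a$length, b_mapped$length)
})

test_that("peak proximity equals the quadratic oracle", {
  set.seed(45)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30), contig = "c1",
                      start = sort(sample.int(100000, 30)),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:3000, 30, replace = TRUE)
  peaks <- data.frame(contig = "c1",
                      start = sort(sample.int(105000, 80)),
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 200L
  peaks$score <- round(rexp(80, 0.1), 2)
  got <- peak_proximity(genes, peaks)
  want <- oracle_peak_proximity(genes, peaks)
  expect_equal(got$n_peaks, want$n_peaks)
  expect_equal(got$nearest_distance, want$nearest_distance)
  expect_equal(got$mean_intensity, want$mean_intensity)
})

test_that("peak proximity handles the worked interval cases", {
  genes <- data.frame(gene_id = "g", contig = "c", start = 1000L,
                      end = 2000L, stringsAsFactors = FALSE)
  near <- data.frame(contig = "c", start = 2100L, end = 2200L, score = 5)
  r <- peak_proximity(genes, near)
  expect_equal(r$n_peaks, 1L)
  expect_equal(r$nearest_distance, 100)
  over <- data.frame(contig = "c", start = 1500L, end = 1600L, score = 1)
  expect_equal(peak_proximity(genes, over)$nearest_distance, 0)
  off <- data.frame(contig = "cX", start = 10L, end = 20L, score = 1)
  r3 <- suppressWarnings(peak_proximity(genes, off))
  expect_equal(r3$n_peaks, 0L)
  expect_equal(r3$nearest_distance, Inf)
  expect_warning(peak_proximity(genes, off), "cX")
})
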