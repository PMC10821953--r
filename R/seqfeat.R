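# Sequence composition, codon usage, ORF scanning, and ATAC peak proximity.

#' GC content of a DNA sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator.
#'
#' @param seq character scalar over the alphabet ACGTN (case-insensitive).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains letters outside ACGTN")
  }
  acgt <- sum(chars != "N")
  if (acgt == 0) stop("all-N sequence: GC content undefined")
  sum(chars %in% c("G", "C")) / acgt
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# split a set of CDS into codons + amino acids, dropping the terminal stop
# and skipping untranslatable records with a warning
cds_codon_table <- function(cds_set) {
  out_cod <- character(0); out_aa <- character(0)
  for (i in seq_along(cds_set)) {
    res <- tryCatch({
      cod <- split_codons(cds_set[i])
      aa <- translate_codons(cod)
      if (any(is.na(aa))) stop("ambiguous codon")
      n <- length(cod)
      if (aa[n] == "*") { cod <- cod[-n]; aa <- aa[-n] }
      if (any(aa == "*")) stop("internal stop codon")
      list(cod = cod, aa = aa)
    }, error = function(e) {
      warning(sprintf("skipping CDS %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      out_cod <- c(out_cod, res$cod)
      out_aa <- c(out_aa, res$aa)
    }
  }
  data.frame(codon = out_cod, aa = out_aa, stringsAsFactors = FALSE)
}

#' Per-amino-acid GC content of the codons actually used
#'
#' For each amino acid, the GC fraction pooled over every occurrence of its
#' codons in the CDS set (terminal stop codons excluded).
#'
#' @param cds_set character vector of CDS sequences (lengths divisible by
#'   3, no internal stops; offending records are skipped with a warning).
#' @return named numeric vector, one entry per observed amino acid.
#' @export
codon_gc_by_aa <- function(cds_set) {
  tab <- cds_codon_table(cds_set)
  if (nrow(tab) == 0) stop("no translatable codons in input")
  gc_of <- vapply(strsplit(tab$codon, ""), function(b) sum(b %in% c("G", "C")) / 3,
                  numeric(1))
  vapply(split(gc_of, tab$aa), mean, numeric(1))
}

#' Build a codon-usage table with per-amino-acid optimal codons
#'
#' The optimal codon of an amino acid is its most frequently used codon in
#' the CDS set (ties broken alphabetically).
#'
#' @inheritParams codon_gc_by_aa
#' @return object of class `codon_usage`: list with `counts` (named codon
#'   counts), `optimal` (named per-amino-acid codon), `missing_aa`
#'   (amino acids never observed).
#' @export
build_codon_usage <- function(cds_set) {
  tab <- cds_codon_table(cds_set)
  if (nrow(tab) == 0) stop("no translatable codons in input")
  counts <- table(tab$codon)
  optimal <- vapply(split(tab$codon, tab$aa), function(cods) {
    ct <- table(cods)
    nm <- names(ct)[ct == max(ct)]
    sort(nm)[1]
  }, character(1))
  missing_aa <- setdiff(AA20, names(optimal))
  if (length(missing_aa)) {
    warning("amino acids never observed: ", paste(missing_aa, collapse = ", "))
  }
  structure(list(counts = counts, optimal = optimal, missing_aa = missing_aa),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage over %d codons; optimal codons:\n", sum(x$counts)))
  print(x$optimal)
  invisible(x)
}

#' Fraction of codons that are optimal for their amino acid
#'
#' @param cds one CDS sequence.
#' @param table a [build_codon_usage()] result (typically built from the
#'   whole-genome CDS set).
#' @return fraction in `[0, 1]` (single-codon amino acids count).
#' @export
optimal_codon_fraction <- function(cds, table) {
  stopifnot(inherits(table, "codon_usage"))
  tab <- cds_codon_table(cds)
  if (nrow(tab) == 0) stop("untranslatable CDS")
  opt <- table$optimal[tab$aa]
  mean(!is.na(opt) & tab$codon == opt)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# single-strand ORF scan; returns 0-based half-open coordinates on the
# given strand's own sequence
scan_orfs_strand <- function(seq, min_len, include_nested) {
  n <- nchar(seq)
  rows <- list()
  for (frame in 0:2) {
    starts_at <- seq(1 + frame, n - 2, by = 3)
    if (length(starts_at) == 0) next
    cods <- substring(seq, starts_at, starts_at + 2)
    stop_idx <- which(cods %in% STOP_CODONS)
    atg_idx <- which(cods == "ATG")
    if (length(atg_idx) == 0) next
    nxt_stop <- function(i) {
      s <- stop_idx[stop_idx >= i]
      if (length(s)) s[1] else NA_integer_
    }
    prev_stop_end <- -Inf  # codon index of last consumed stop, for nesting rule
    for (a in atg_idx) {
      s <- nxt_stop(a)
      if (is.na(s)) next
      if (!include_nested) {
        # keep only the first ATG after the previous stop in this frame
        if (a <= prev_stop_end) next
        prev_stop_end <- s
      }
      len <- (s - a + 1L) * 3L
      if (len >= min_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts_at[a] - 1L, end = starts_at[s] + 2L,
          frame = frame, length = len,
          nested = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0),
                      nested = logical(0)))
  }
  do.call(rbind, rows)
}

#' Scan a DNA sequence for ORFs on both strands
#'
#' An ORF runs from an ATG to the next in-frame stop (stop included in the
#' length); all six frames are scanned and, with `include_nested`, every
#' internal in-frame ATG starts its own record (nested ORFs share the
#' parent's stop).  Records shorter than `min_len` nucleotides are dropped.
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param seq DNA sequence (ACGT).
#' @param min_len minimum ORF length in nt, stop codon included
#'   (default 75).
#' @param include_nested emit nested ORFs (default TRUE).
#' @return data.frame with `start`, `end`, `strand`, `frame`, `length`,
#'   `nested`, sorted by `(start, end, strand)`.
#' @export
find_orfs <- function(seq, min_len = 75L, include_nested = TRUE) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 3)
  n <- nchar(seq)
  fwd <- scan_orfs_strand(seq, min_len, include_nested)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- scan_orfs_strand(revcomp(seq), min_len, include_nested)
  if (nrow(rev)) {
    # map coordinates on the reverse strand back to forward coordinates
    s <- n - rev$end
    e <- n - rev$start
    rev$start <- s; rev$end <- e; rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length = integer(0), nested = logical(0)))
  }
  # mark nesting: an ORF is nested when another record in the same frame and
  # strand shares its stop but starts earlier
  key_stop <- ifelse(out$strand == "+", out$end, out$start)
  grp <- paste(out$strand, out$frame, key_stop)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      lens <- out$length[idx]
      out$nested[idx] <- lens < max(lens)
    }
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak proximity statistics for gene spans
#'
#' For each gene, counts ATAC peaks overlapping the window
#' `[start - window, end + window)` (clamped at 0), the mean peak intensity
#' in that window, and the distance to the nearest peak (0 when a peak
#' overlaps the gene span itself; `Inf` when the contig carries no peak).
#' All intervals are 0-based half-open.
#'
#' @param genes data.frame with `gene_id`, `contig`, `start`, `end`.
#' @param peaks data.frame with `contig`, `start`, `end`, optional `score`
#'   (BED-style intensity).
#' @param window flank size in bp (default 500).
#' @return data.frame with `gene_id`, `n_peaks`, `mean_intensity`,
#'   `nearest_distance`.
#' @export
peak_proximity <- function(genes, peaks, window = 500L) {
  stopifnot(all(c("gene_id", "contig", "start", "end") %in% names(genes)),
            all(c("contig", "start", "end") %in% names(peaks)))
  unknown <- setdiff(unique(peaks$contig), unique(genes$contig))
  if (length(unknown)) {
    warning("peaks on contigs without genes skipped: ",
            paste(unknown, collapse = ", "))
    peaks <- peaks[!(peaks$contig %in% unknown), , drop = FALSE]
  }
  has_score <- "score" %in% names(peaks) && !all(is.na(peaks$score))
  gw <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(pmax(genes$start - window, 0L) + 1L, genes$end + window))
  gspan <- GenomicRanges::GRanges(genes$contig,
                                  IRanges::IRanges(genes$start + 1L, genes$end))
  pk <- GenomicRanges::GRanges(peaks$contig,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(gw, pk, ignore.strand = TRUE)
  n_peaks <- GenomicRanges::countOverlaps(gw, pk, ignore.strand = TRUE)
  mean_int <- rep(NA_real_, nrow(genes))
  if (has_score) {
    sums <- tapply(peaks$score[S4Vectors::subjectHits(ov)],
                   factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(genes))),
                   mean)
    mean_int <- as.numeric(sums)
  }
  dist <- rep(Inf, nrow(genes))
  if (length(pk)) {
    dn <- GenomicRanges::distanceToNearest(gspan, pk, ignore.strand = TRUE)
    dist[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance
  }
  data.frame(gene_id = genes$gene_id, n_peaks = as.integer(n_peaks),
             mean_intensity = mean_int, nearest_distance = dist,
             stringsAsFactors = FALSE)
}
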