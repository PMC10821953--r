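# Identification workflow: classify syntenic hits per (gene, species),
# infer the origination branch Br_i as the furthest branch carrying an
# annotated or unannotated ortholog, require non-genic evidence in the
# outgroups of Br_i, and filter against distant/arthropod homologs.

HIT_CLASSES <- c("annotated_ortholog", "unannotated_ortholog", "nongenic",
                 "ambiguous", "no_alignment")
ORTHO_CLASSES <- c("annotated_ortholog", "unannotated_ortholog")
SEARCH_NAMES <- c("blastp", "jackhmmer_a", "jackhmmer_b", "tblastn")
CANDIDATE_STATUSES <- c("candidate", "rejected_no_nongenic_support",
                        "rejected_distant_homolog",
                        "rejected_arthropod_homolog", "not_aligned")

#' Classify one syntenic hit
#'
#' A lifted syntenic region overlapping an annotated gene is an
#' `annotated_ortholog` when the reciprocal blastp E-value is below
#' `blastp_evalue`, otherwise `ambiguous` (a genic region of unclear
#' homology supports neither an ortholog call nor non-genic ancestry).  An
#' unannotated region is an `unannotated_ortholog` when its gene-structure
#' prediction score is significantly above the random expectation
#' (p <= `genic_p`), otherwise `nongenic`.  A gene with no lifted region in
#' the species is `no_alignment`.
#'
#' @param annotated_evalue blastp E-value of an overlapping annotated gene,
#'   or `NA` if the region is unannotated / absent.
#' @param genic_pvalue_value precomputed genic p-value of the unannotated
#'   region, or `NA`.
#' @param score,protein_length raw prediction score and query length; used
#'   with `calibration` only when `genic_pvalue_value` is `NA`.
#' @param aligned logical: was any syntenic region lifted at all?
#' @param calibration optional [build_calibration()] result for score ->
#'   p-value conversion.
#' @param blastp_evalue annotated-ortholog E-value cutoff (default 0.05).
#' @param genic_p genic significance cutoff (default 1e-6, inclusive).
#' @return one of `"annotated_ortholog"`, `"unannotated_ortholog"`,
#'   `"nongenic"`, `"ambiguous"`, `"no_alignment"`.
#' @export
classify_syntenic_hit <- function(annotated_evalue = NA_real_,
                                  genic_pvalue_value = NA_real_,
                                  score = NA_real_,
                                  protein_length = NA_integer_,
                                  aligned = TRUE,
                                  calibration = NULL,
                                  blastp_evalue = 0.05,
                                  genic_p = 1e-6) {
  if (!aligned) return("no_alignment")
  has_annot <- !is.na(annotated_evalue)
  has_pred <- !is.na(genic_pvalue_value) || !is.na(score)
  if (has_annot && has_pred) stop("malformed record: both annotated and unannotated evidence")
  if (!has_annot && !has_pred) stop("malformed record: aligned hit with neither evidence kind")
  if (has_annot) {
    if (annotated_evalue < 0) stop("E-value must be >= 0")
    return(if (annotated_evalue < blastp_evalue) "annotated_ortholog" else "ambiguous")
  }
  p <- genic_pvalue_value
  if (is.na(p)) {
    if (is.null(calibration)) stop("score given without p-value or calibration")
    p <- genic_pvalue(score, protein_length, calibration)
  }
  if (is_genic(p, genic_p)) "unannotated_ortholog" else "nongenic"
}

#' Infer the furthest ortholog branch (origination branch Br_i)
#'
#' @param profile character vector of hit classes, element `b` for branch `b`
#'   (1 = closest outgroup split).
#' @return the largest branch index whose class is an annotated or
#'   unannotated ortholog, or `0L` when no branch carries an ortholog.
#' @export
infer_furthest_ortholog_branch <- function(profile) {
  if (length(profile) == 0) stop("empty hit-class profile")
  if (!all(profile %in% HIT_CLASSES)) stop("unknown hit class in profile")
  idx <- which(profile %in% ORTHO_CLASSES)
  if (length(idx) == 0) 0L else max(idx)
}

#' Is there non-genic evidence in the outgroups of Br_i?
#'
#' True when at least one branch more distant than `br_i` carries a
#' `nongenic` hit -- the ancestral non-coding evidence a de novo candidate
#' requires.  When `br_i` is the deepest branch there is no outgroup and the
#' answer is vacuously `FALSE`.
#'
#' @param profile per-branch hit classes as in
#'   [infer_furthest_ortholog_branch()].
#' @param br_i origination branch index (0 allowed: no ortholog anywhere).
#' @export
has_outgroup_nongenic_support <- function(profile, br_i) {
  if (length(br_i) != 1L || is.na(br_i) || br_i < 0 || br_i > length(profile)) {
    stop("br_i out of range")
  }
  if (br_i >= length(profile)) return(FALSE)
  any(profile[(br_i + 1):length(profile)] == "nongenic")
}

#' Consensus distant-homolog filter
#'
#' A reliable distant homolog requires the same subject species to appear in
#' at least two distinct searches, each at E <= `consensus_evalue`.
#' Profile-search rows (jackhmmer) whose best-1-domain E-value exceeds
#' `best_domain_evalue` are discarded first as probable profile drift.
#'
#' @param evidence data.frame with columns `subject_species`, `search`,
#'   `evalue`, and optionally `best_domain_evalue`; rows must already be
#'   restricted to subjects more distant than Br_i.
#' @param consensus_evalue per-search E-value cutoff (default 0.001).
#' @param best_domain_evalue profile-search pre-filter (default 1e-5).
#' @return list with `reliable` (logical) and `supporting` (the rows of the
#'   supporting subject/search pairs).
#' @export
consensus_homolog_filter <- function(evidence, consensus_evalue = 0.001,
                                     best_domain_evalue = 1e-5) {
  empty <- list(reliable = FALSE,
                supporting = evidence[0, , drop = FALSE])
  if (is.null(evidence) || nrow(evidence) == 0) return(empty)
  if (!all(evidence$search %in% SEARCH_NAMES)) stop("unknown search name")
  keep <- rep(TRUE, nrow(evidence))
  if (!is.null(evidence$best_domain_evalue)) {
    prof <- evidence$search %in% c("jackhmmer_a", "jackhmmer_b")
    keep <- !(prof & !is.na(evidence$best_domain_evalue) &
                evidence$best_domain_evalue > best_domain_evalue)
  }
  ev <- evidence[keep & evidence$evalue <= consensus_evalue, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  n_searches <- tapply(ev$search, ev$subject_species,
                       function(s) length(unique(s)))
  hits <- names(n_searches)[n_searches >= 2]
  list(reliable = length(hits) > 0,
       supporting = ev[ev$subject_species %in% hits, , drop = FALSE])
}

#' Validate a predicted unannotated homolog (tblastn follow-up)
#'
#' The predicted gene structure must have a canonical start and stop, no
#' frameshifts, and the same exon count as the query or any of the query's
#' recorded orthologs.
#'
#' @param has_start,has_stop logicals from the gene-structure prediction.
#' @param frameshifts integer count of frameshifts in the prediction.
#' @param exons predicted exon count.
#' @param query_exons exon count(s) of the query and optionally its
#'   orthologs.
#' @export
validate_unannotated_homolog <- function(has_start, has_stop, frameshifts,
                                         exons, query_exons) {
  if (any(is.na(c(has_start, has_stop, frameshifts, exons))) ||
      length(query_exons) == 0 || any(is.na(query_exons))) {
    stop("malformed prediction record: missing fields")
  }
  isTRUE(has_start) && isTRUE(has_stop) && frameshifts == 0 &&
    exons %in% query_exons
}

#' Classify a gene's birthplace as intergenic or intragenic
#'
#' Intragenic when the gene span overlaps any other annotated gene span on
#' either strand; else intergenic.  Intervals are 0-based half-open, so
#' abutting spans do not overlap.
#'
#' @param gene list or one-row data.frame with `contig`, `start`, `end`
#'   (0-based half-open) and `gene_id`.
#' @param annotation data.frame of annotated gene spans with columns
#'   `gene_id`, `contig`, `start`, `end`.
#' @return `"intergenic"` or `"intragenic"`.
#' @export
classify_genomic_context <- function(gene, annotation) {
  others <- annotation[annotation$gene_id != gene$gene_id, , drop = FALSE]
  if (nrow(others) == 0) return("intergenic")
  g <- GenomicRanges::GRanges(gene$contig,
                              IRanges::IRanges(gene$start + 1L, gene$end))
  a <- GenomicRanges::GRanges(others$contig,
                              IRanges::IRanges(others$start + 1L, others$end))
  n <- GenomicRanges::countOverlaps(g, a, ignore.strand = TRUE)
  if (n > 0) "intragenic" else "intergenic"
}

#' Re-derive hit classes for a whole syntenic-hit table
#'
#' Vectorized application of the [classify_syntenic_hit()] rules to a table
#' with raw evidence columns: rows with neither an `annotated_evalue` nor a
#' `genic_pvalue` are `no_alignment`; annotated overlaps split into
#' `annotated_ortholog` / `ambiguous` at `blastp_evalue`; unannotated
#' regions split into `unannotated_ortholog` / `nongenic` at `genic_p`.
#'
#' @param hits data.frame with `annotated_evalue` and `genic_pvalue`
#'   columns (NA where absent).
#' @param blastp_evalue,genic_p thresholds as in [classify_syntenic_hit()].
#' @return the table with a recomputed `class` column.
#' @export
classify_hit_table <- function(hits, blastp_evalue = 0.05, genic_p = 1e-6) {
  stopifnot(all(c("annotated_evalue", "genic_pvalue") %in% names(hits)))
  has_ann <- !is.na(hits$annotated_evalue)
  has_p <- !is.na(hits$genic_pvalue)
  if (any(has_ann & has_p)) {
    stop("malformed records: both annotated and unannotated evidence")
  }
  cls <- rep("no_alignment", nrow(hits))
  cls[has_ann] <- ifelse(hits$annotated_evalue[has_ann] < blastp_evalue,
                         "annotated_ortholog", "ambiguous")
  cls[has_p] <- ifelse(hits$genic_pvalue[has_p] <= genic_p,
                       "unannotated_ortholog", "nongenic")
  hits$class <- cls
  hits
}

#' Call de novo gene candidates from syntenic and homology evidence
#'
#' Applies the identification funnel in order: alignment presence ->
#' furthest-ortholog-branch inference -> outgroup non-genic support ->
#' arthropod homolog exclusion -> consensus distant-homolog filter ->
#' validated-unannotated-homolog (tblastn-style) filter.  The first failing
#' stage is recorded per gene.
#'
#' @param hits data.frame of per-(gene, branch) hit classes with columns
#'   `gene_id`, `branch`, `class` (one row per gene x branch; class one of
#'   the five hit classes).
#' @param evidence data.frame of distant-homolog search rows (columns
#'   `gene_id`, `subject_species`, `subject_branch`, `search`, `evalue`,
#'   optional `best_domain_evalue`); `subject_branch` is the branch index of
#'   the subject species (larger = more distant), `Inf` allowed for
#'   non-ladder species.
#' @param arthropod data.frame of arthropod blastp rows (columns `gene_id`,
#'   `evalue`).
#' @param validated data.frame of validated unannotated outgroup homolog
#'   flags (columns `gene_id`, `validated` logical), e.g. from
#'   [validate_unannotated_homolog()] applied to tblastn hits in the
#'   outgroups of Br_i; may be `NULL`.
#' @param annotation optional gene-span table for genomic-context labels
#'   (columns `gene_id`, `contig`, `start`, `end`).
#' @param arthropod_evalue arthropod-homolog exclusion cutoff (default 0.05).
#' @param consensus_evalue,best_domain_evalue see
#'   [consensus_homolog_filter()].
#' @return data.frame of class `candidate_calls`: one row per gene with
#'   `gene_id`, `status`, `branch` (inferred Br_i; NA when unaligned),
#'   `context`, and logical stage columns `aligned`, `has_ortholog_profile`,
#'   `nongenic_support`, `no_arthropod_homolog`, `no_distant_homolog`,
#'   `no_validated_outgroup_homolog`.
#' @export
call_de_novo_candidates <- function(hits, evidence = NULL, arthropod = NULL,
                                    validated = NULL, annotation = NULL,
                                    arthropod_evalue = 0.05,
                                    consensus_evalue = 0.001,
                                    best_domain_evalue = 1e-5) {
  stopifnot(all(c("gene_id", "branch", "class") %in% names(hits)))
  bad <- setdiff(unique(hits$class), HIT_CLASSES)
  if (length(bad)) stop("unknown hit classes: ", paste(bad, collapse = ", "))
  for (tab in list(evidence, arthropod, validated)) {
    if (!is.null(tab) && nrow(tab) > 0) {
      extra <- setdiff(unique(tab$gene_id), unique(hits$gene_id))
      if (length(extra)) {
        stop("evidence keys absent from the hit table: ",
             paste(head(extra, 5), collapse = ", "))
      }
    }
  }

  genes <- unique(hits$gene_id)
  n_br <- max(hits$branch)
  out <- data.frame(gene_id = genes,
                    status = NA_character_,
                    branch = NA_integer_,
                    context = NA_character_,
                    aligned = FALSE,
                    has_ortholog_profile = FALSE,
                    nongenic_support = FALSE,
                    no_arthropod_homolog = NA,
                    no_distant_homolog = NA,
                    no_validated_outgroup_homolog = NA,
                    stringsAsFactors = FALSE)

  hit_split <- split(hits, hits$gene_id)
  ev_split <- if (!is.null(evidence) && nrow(evidence)) split(evidence, evidence$gene_id) else list()
  arth_split <- if (!is.null(arthropod) && nrow(arthropod)) split(arthropod, arthropod$gene_id) else list()
  val_map <- if (!is.null(validated) && nrow(validated)) {
    tapply(validated$validated, validated$gene_id, any)
  } else NULL

  for (g in seq_along(genes)) {
    id <- as.character(genes[g])
    h <- hit_split[[id]]
    profile <- rep("no_alignment", n_br)
    profile[h$branch] <- h$class

    aligned <- any(profile != "no_alignment")
    out$aligned[g] <- aligned
    if (!aligned) { out$status[g] <- "not_aligned"; next }

    br <- infer_furthest_ortholog_branch(profile)
    out$branch[g] <- br
    out$has_ortholog_profile[g] <- TRUE

    support <- has_outgroup_nongenic_support(profile, br)
    out$nongenic_support[g] <- support
    if (!support) { out$status[g] <- "rejected_no_nongenic_support"; next }

    arth <- arth_split[[id]]
    arth_hit <- !is.null(arth) && any(arth$evalue < arthropod_evalue)
    out$no_arthropod_homolog[g] <- !arth_hit
    if (arth_hit) { out$status[g] <- "rejected_arthropod_homolog"; next }

    ev <- ev_split[[id]]
    if (!is.null(ev)) ev <- ev[ev$subject_branch > br, , drop = FALSE]
    cons <- consensus_homolog_filter(ev, consensus_evalue, best_domain_evalue)
    out$no_distant_homolog[g] <- !cons$reliable
    if (cons$reliable) { out$status[g] <- "rejected_distant_homolog"; next }

    val_hit <- !is.null(val_map) && isTRUE(val_map[[id]])
    out$no_validated_outgroup_homolog[g] <- !val_hit
    if (val_hit) { out$status[g] <- "rejected_distant_homolog"; next }

    out$status[g] <- "candidate"
  }

  if (!is.null(annotation)) {
    for (g in seq_along(genes)) {
      row <- annotation[annotation$gene_id == genes[g], , drop = FALSE]
      if (nrow(row) == 1) {
        out$context[g] <- classify_genomic_context(row, annotation)
      }
    }
  }
  class(out) <- c("candidate_calls", "data.frame")
  out
}

#' Funnel summary of a candidate-call table
#'
#' Reconstructs the identification funnel: genes aligned, with outgroup
#' non-genic support, surviving the arthropod filter, surviving the
#' distant-homolog filters, and final candidates.  Counts are
#' non-increasing along the funnel.
#'
#' @param calls a `candidate_calls` table.
#' @return named integer vector of stage counts plus per-branch candidate
#'   counts in attribute `by_branch`.
#' @export
funnel_summary <- function(calls) {
  stopifnot(inherits(calls, "candidate_calls"))
  aligned <- sum(calls$aligned)
  support <- sum(calls$nongenic_support, na.rm = TRUE)
  arth <- sum(calls$nongenic_support & calls$no_arthropod_homolog, na.rm = TRUE)
  dist <- sum(calls$nongenic_support & calls$no_arthropod_homolog &
                calls$no_distant_homolog &
                (is.na(calls$no_validated_outgroup_homolog) |
                   calls$no_validated_outgroup_homolog), na.rm = TRUE)
  cand <- sum(calls$status == "candidate")
  res <- c(total = nrow(calls), aligned = aligned,
           nongenic_support = support, after_arthropod_filter = arth,
           after_homolog_filters = dist, candidates = cand)
  br <- table(calls$branch[calls$status == "candidate"])
  attr(res, "by_branch") <- br
  res
}

#' @export
print.candidate_calls <- function(x, ...) {
  cat(sprintf("De novo candidate calls: %d genes, %d candidates\n",
              nrow(x), sum(x$status == "candidate")))
  print(table(x$status))
  invisible(x)
}
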