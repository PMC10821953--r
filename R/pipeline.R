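# End-to-end orchestration: candidate identification followed by per-gene
# characterization (foldability, expression specificity, GC content), with
# a funnel report and plain-text reporting.

#' Default pipeline thresholds
#'
#' The constants used throughout the identification and characterization
#' stages: genic p-value 1e-6 (inclusive), annotated-ortholog blastp
#' E-value 0.05, arthropod exclusion E-value 0.05, consensus homolog
#' E-value 0.001, best-1-domain E-value 1e-5, expressed-gene TPM floor 0.1,
#' foldability thresholds (mean pLDDT 80, confident residue 70, confident
#' fraction 0.90, partial fraction 0.30, partial run 50), four stage
#' clusters, and a 500 bp peak window.
#'
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(genic_p = 1e-6, blastp_evalue = 0.05, arthropod_evalue = 0.05,
       consensus_evalue = 0.001, best_domain_evalue = 1e-5,
       tblastn_evalue = 1.0, min_tpm = 0.1,
       plddt_mean = 80, plddt_confident = 70, p_confident = 0.90,
       partial_fraction = 0.30, partial_run = 50,
       k_stage_clusters = 4L, peak_window = 500L)
}

#' Run the identification and characterization pipeline on a dataset
#'
#' Applies the candidate-identification funnel to the syntenic/homology
#' evidence, then joins per-gene characterization: foldability class from
#' the pLDDT profiles, male-specificity z-scores (raw and normalized), tau
#' over the tissue panel, GC content of the CDS, and peak proximity.
#'
#' @param dataset a [simulate_dataset()] result, or any list with the same
#'   components (`hits`, `evidence`, `arthropod`, `annotation`, optionally
#'   `plddt`, `expression`, `sequences`, `peaks`).
#' @param thresholds list from [pipeline_thresholds()] (entries may be
#'   overridden).
#' @param seed seed for the stage-clustering stage.
#' @return list of class `denovo_pipeline` with `calls`, `funnel`,
#'   `report` (per-gene data.frame), `stage_clusters` (for male-biased
#'   genes, when stage profiles are present), and `thresholds`.
#' @export
run_pipeline <- function(dataset, thresholds = pipeline_thresholds(),
                         seed = 1L) {
  th <- utils::modifyList(pipeline_thresholds(), thresholds)

  hits <- dataset$hits
  if (all(c("annotated_evalue", "genic_pvalue") %in% names(hits))) {
    # re-derive hit classes from the raw evidence columns
    hits <- classify_hit_table(hits, blastp_evalue = th$blastp_evalue,
                               genic_p = th$genic_p)
  }
  calls <- call_de_novo_candidates(
    hits = hits, evidence = dataset$evidence,
    arthropod = dataset$arthropod, validated = dataset$validated,
    annotation = dataset$annotation,
    arthropod_evalue = th$arthropod_evalue,
    consensus_evalue = th$consensus_evalue,
    best_domain_evalue = th$best_domain_evalue)
  funnel <- funnel_summary(calls)

  report <- calls[, c("gene_id", "status", "branch", "context")]

  if (!is.null(dataset$plddt)) {
    fold <- t(vapply(dataset$plddt, function(p) {
      f <- classify_foldability(p, mean_cutoff = th$plddt_mean,
                                p_confident_cutoff = th$p_confident,
                                confident_cutoff = th$plddt_confident,
                                partial_fraction = th$partial_fraction,
                                partial_run = th$partial_run)
      c(class = f$class, mean_plddt = sprintf("%.4f", f$mean_plddt),
        p_confident = sprintf("%.4f", f$p_confident))
    }, character(3)))
    fold_df <- data.frame(gene_id = rownames(fold),
                          fold_class = fold[, "class"],
                          mean_plddt = as.numeric(fold[, "mean_plddt"]),
                          p_confident = as.numeric(fold[, "p_confident"]),
                          stringsAsFactors = FALSE)
    report <- merge(report, fold_df, by = "gene_id", all.x = TRUE, sort = FALSE)
  }

  stage_clusters <- NULL
  if (!is.null(dataset$expression)) {
    ex <- dataset$expression
    tpm <- fpkm_to_tpm(ex$tissue_fpkm)
    spec <- specificity_scores(tpm, ex$whole_body$male_mean,
                               ex$whole_body$female_mean,
                               ex$whole_body$male_sd, ex$whole_body$female_sd)
    report <- merge(report, spec, by = "gene_id", all.x = TRUE, sort = FALSE)

    if (!is.null(ex$stages)) {
      biased <- if (!is.null(dataset$truth)) {
        dataset$truth$gene_id[dataset$truth$male_biased]
      } else {
        spec$gene_id[spec$zscore_norm > 0.9]
      }
      biased <- intersect(biased, rownames(ex$stages))
      if (length(biased) >= th$k_stage_clusters) {
        scaled <- scale_stage_profiles(ex$stages[biased, , drop = FALSE])
        pca <- pca_reduce(scaled, 3L)
        lab <- kmeans_stage_clusters(pca$coordinates,
                                     k = th$k_stage_clusters, seed = seed)
        stage_clusters <- data.frame(
          gene_id = biased,
          cluster = order_clusters_by_stage(lab, scaled),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (!is.null(dataset$sequences)) {
    gc <- vapply(dataset$sequences$cds, gc_content, numeric(1))
    report <- merge(report,
                    data.frame(gene_id = names(gc), gc = unname(gc),
                               stringsAsFactors = FALSE),
                    by = "gene_id", all.x = TRUE, sort = FALSE)
  }

  if (!is.null(dataset$peaks)) {
    genes <- dataset$annotation[dataset$annotation$gene_id %in% report$gene_id, ]
    pp <- peak_proximity(genes, dataset$peaks, window = th$peak_window)
    report <- merge(report, pp, by = "gene_id", all.x = TRUE, sort = FALSE)
  }

  report <- report[order(report$gene_id), , drop = FALSE]
  rownames(report) <- NULL
  structure(list(calls = calls, funnel = funnel, report = report,
                 stage_clusters = stage_clusters, thresholds = th,
                 seed = seed),
            class = "denovo_pipeline")
}

#' @export
print.denovo_pipeline <- function(x, ...) {
  cat("De novo identification pipeline\n")
  cat("Funnel:\n")
  print(x$funnel)
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits the per-gene master table (TSV), the candidate calls (TSV), a
#' JSON funnel summary, and a run log listing every threshold used.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory.
#' @return invisibly, the vector of written paths.
#' @export
write_report <- function(result, outdir) {
  stopifnot(inherits(result, "denovo_pipeline"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(outdir, "per_gene_report.tsv"),
             calls = file.path(outdir, "candidate_calls.tsv"),
             funnel = file.path(outdir, "funnel.json"),
             log = file.path(outdir, "run_log.txt"))
  write.table(result$report, paths["report"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(result$calls), paths["calls"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  funnel <- as.list(result$funnel)
  funnel$by_branch <- as.list(attr(result$funnel, "by_branch"))
  jsonlite::write_json(funnel, paths["funnel"], auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    sprintf("denovoscan %s", as.character(utils::packageVersion("denovoscan"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", result$seed),
    "thresholds:",
    vapply(names(result$thresholds),
           function(k) sprintf("  %s = %s", k,
                               format(result$thresholds[[k]])),
           character(1)))
  writeLines(log_lines, paths["log"])
  invisible(paths)
}
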