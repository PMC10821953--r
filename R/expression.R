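# Expression normalization and specificity statistics: FPKM -> TPM, the
# male-specificity z-score and its min-max normalization, the tissue
# specificity index tau, testis stage-profile scaling / PCA / k-means
# clustering, and gene-age rank-correlation trend tests.

#' Convert an FPKM matrix to TPM
#'
#' Per tissue column, `TPM_i = FPKM_i / sum_j FPKM_j * 1e6`, so every
#' column sums to one million.
#'
#' @param mat genes x tissues matrix (or data.frame) of FPKM values.
#' @param unit current unit tag; must be `"FPKM"` (re-normalizing a TPM
#'   matrix is refused).
#' @return matrix of TPM values with attribute `unit = "TPM"`.
#' @export
fpkm_to_tpm <- function(mat, unit = attr(mat, "unit") %||% "FPKM") {
  if (identical(unit, "TPM")) stop("matrix is already TPM; refusing to re-normalize")
  m <- as.matrix(mat)
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  tot <- colSums(m)
  if (any(tot == 0)) stop("all-zero tissue column: normalization undefined")
  out <- sweep(m, 2, tot, "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop genes without appreciable expression
#'
#' Keeps genes whose maximum TPM across tissues is strictly larger than
#' `min_tpm`.
#'
#' @param mat genes x tissues TPM matrix.
#' @param min_tpm strict threshold (default 0.1).
#' @export
filter_expressed <- function(mat, min_tpm = 0.1) {
  m <- as.matrix(mat)
  keep <- apply(m, 1, max) > min_tpm
  out <- m[keep, , drop = FALSE]
  attr(out, "unit") <- attr(mat, "unit")
  out
}

#' Male-specificity z-score
#'
#' `z = (TPM_male - TPM_female) / sqrt(sd_male^2 + sd_female^2)`, with the
#' SDs taken over whole-body replicates.
#'
#' @param male_mean,female_mean whole-body mean expression.
#' @param male_sd,female_sd replicate SDs (nonnegative, not both zero).
#' @return numeric z-score(s).
#' @export
male_specificity_zscore <- function(male_mean, female_mean, male_sd, female_sd) {
  if (any(male_sd < 0 | female_sd < 0)) stop("SDs must be nonnegative")
  denom <- sqrt(male_sd^2 + female_sd^2)
  if (any(denom == 0)) stop("both replicate SDs are zero: z-score undefined")
  (male_mean - female_mean) / denom
}

#' Min-max normalize a z-score vector to [0, 1]
#'
#' @param z numeric vector with at least two distinct values.
#' @return `(z - min) / (max - min)`.
#' @export
normalize_zscores <- function(z) {
  rng <- range(z)
  if (diff(rng) == 0) stop("constant z-score vector: normalization degenerate")
  (z - rng[1]) / diff(rng)
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over `N` tissues: 0 for
#' uniform expression, 1 for single-tissue expression.
#'
#' @param x nonnegative expression vector over >= 2 tissues with a positive
#'   maximum.
#' @return tau in `[0, 1]`.
#' @export
tau_specificity <- function(x) {
  if (length(x) < 2) stop("tau needs at least 2 tissues")
  if (any(x < 0)) stop("expression must be nonnegative")
  mx <- max(x)
  if (mx == 0) stop("all-zero expression vector: tau undefined")
  sum(1 - x / mx) / (length(x) - 1)
}

#' Row-standardize stage expression profiles
#'
#' Per gene (row): subtract the row mean and divide by the row SD (floored
#' at 1e-12, so constant rows map to zeros).
#'
#' @param mat genes x stages matrix.
#' @return scaled matrix of the same shape.
#' @export
scale_stage_profiles <- function(mat) {
  m <- as.matrix(mat)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  sweep(sweep(m, 1, mu), 1, pmax(s, 1e-12), "/")
}

#' Principal-component reduction of scaled stage profiles
#'
#' Column-centered SVD; returns the projections on the leading components
#' and the per-component explained-variance fractions.  If the matrix rank
#' is below `n_components` the missing coordinates are zero-padded with a
#' warning.
#'
#' @param mat genes x stages (scaled) matrix.
#' @param n_components number of components to keep (default 3).
#' @return list with `coordinates` (genes x n_components),
#'   `explained_variance` (all components), `rotation`.
#' @export
pca_reduce <- function(mat, n_components = 3L) {
  m <- as.matrix(mat)
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  coords <- p$x[, seq_len(k), drop = FALSE]
  if (k < n_components) {
    warning("rank below n_components; padding coordinates with zeros")
    coords <- cbind(coords, matrix(0, nrow(coords), n_components - k))
  }
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coordinates = coords, explained_variance = ev,
       rotation = p$rotation)
}

#' Cluster stage profiles by k-means on PCA coordinates
#'
#' Standard k-means with many random restarts; deterministic for a fixed
#' seed.
#'
#' @param coordinates genes x d coordinate matrix (typically the first
#'   three PCs).
#' @param k number of clusters (default 4).
#' @param seed RNG seed for initialization.
#' @param nstart random restarts (default 50).
#' @return integer cluster labels in `1..k`.
#' @export
kmeans_stage_clusters <- function(coordinates, k = 4L, seed = 1L, nstart = 50L) {
  m <- as.matrix(coordinates)
  if (nrow(m) < k) stop("fewer observations than clusters")
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  km$cluster
}

#' Renumber stage clusters by developmental timing
#'
#' Clusters are renumbered `1..k` by the ascending expression-weighted mean
#' stage index of their centroid profiles (shifted to be nonnegative), so
#' cluster #1 peaks earliest in spermatogenesis and cluster #k latest.
#' Centroid argmax stage breaks ties.
#'
#' @param labels integer cluster labels.
#' @param scaled genes x stages scaled profile matrix.
#' @return relabeled integer vector.
#' @export
order_clusters_by_stage <- function(labels, scaled) {
  m <- as.matrix(scaled)
  ks <- sort(unique(labels))
  stages <- seq_len(ncol(m))
  centroid <- t(vapply(ks, function(k) colMeans(m[labels == k, , drop = FALSE]),
                       numeric(ncol(m))))
  w <- centroid - min(centroid)           # nonnegative weights
  mean_stage <- as.vector((w %*% stages) / pmax(rowSums(w), 1e-12))
  peak <- apply(centroid, 1, which.max)
  new_of_old <- integer(max(ks))
  new_of_old[ks[order(mean_stage, peak)]] <- seq_along(ks)
  new_of_old[labels]
}

#' Gene-age trend tests for a property
#'
#' Two-sided rank correlations between a per-gene property and the
#' origination branch index: Kendall's tau-b (tie-corrected) and Spearman's
#' rho.
#'
#' @param table data.frame with a `branch` column and the property column.
#' @param property name of the property column.
#' @return list with `kendall_tau`, `kendall_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
age_trend_tests <- function(table, property) {
  stopifnot("branch" %in% names(table), property %in% names(table))
  d <- table[, c("branch", property)]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 genes with branch and property")
  x <- d$branch; y <- d[[property]]
  if (length(unique(y)) < 2 || length(unique(x)) < 2) {
    stop("constant property or branch: correlation undefined")
  }
  kt <- suppressWarnings(cor.test(x, y, method = "kendall",
                                  alternative = "two.sided"))
  sp <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  list(kendall_tau = unname(kt$estimate), kendall_p = kt$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = nrow(d))
}

#' Specificity scores for an expression table
#'
#' Convenience wrapper: computes the raw male-specificity z-score, its
#' min-max normalization across genes, and tau over the tissue columns.
#'
#' @param tissue_tpm genes x tissues TPM matrix.
#' @param male_mean,female_mean,male_sd,female_sd per-gene whole-body
#'   summaries (vectors aligned with `rownames(tissue_tpm)`).
#' @return data.frame with `gene_id`, `zscore`, `zscore_norm`, `tau`.
#' @export
specificity_scores <- function(tissue_tpm, male_mean, female_mean,
                               male_sd, female_sd) {
  z <- male_specificity_zscore(male_mean, female_mean, male_sd, female_sd)
  data.frame(gene_id = rownames(tissue_tpm) %||% seq_len(nrow(tissue_tpm)),
             zscore = z,
             zscore_norm = normalize_zscores(z),
             tau = apply(as.matrix(tissue_tpm), 1, tau_specificity),
             stringsAsFactors = FALSE)
}
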