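# Structural characterization: pLDDT foldability classes, Kabsch
# superposition, TM-score with iterative subset refinement, ensemble
# convergence, and density-peaks clustering of conformations.

#' Classify protein foldability from a per-residue confidence profile
#'
#' A protein is `well_folded` when its mean pLDDT exceeds 80 AND the
#' fraction of confidently predicted residues (pLDDT > 70) exceeds 90%;
#' otherwise `partially_folded` when more than 30% of residues, or a run of
#' more than 50 consecutive residues, are confident; otherwise
#' `not_folded`.  All thresholds are strict inequalities, so boundary
#' profiles fall to the lower class.
#'
#' @param plddt numeric vector of per-residue confidence scores in
#'   `[0, 100]`.
#' @param mean_cutoff,p_confident_cutoff well-folded thresholds
#'   (defaults 80 and 0.90).
#' @param confident_cutoff per-residue confidence threshold (default 70).
#' @param partial_fraction,partial_run partially-folded thresholds
#'   (defaults 0.30 and 50 residues).
#' @return list of class `foldability` with `class`, `mean_plddt`,
#'   `p_confident`, `max_confident_run`, `length`.
#' @export
classify_foldability <- function(plddt, mean_cutoff = 80,
                                 p_confident_cutoff = 0.90,
                                 confident_cutoff = 70,
                                 partial_fraction = 0.30,
                                 partial_run = 50) {
  if (length(plddt) < 1) stop("empty pLDDT profile")
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    stop("pLDDT scores must be finite and within [0, 100]")
  }
  conf <- plddt > confident_cutoff
  p_conf <- mean(conf)
  runs <- rle(conf)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  m <- mean(plddt)
  cls <- if (m > mean_cutoff && p_conf > p_confident_cutoff) {
    "well_folded"
  } else if (p_conf > partial_fraction || max_run > partial_run) {
    "partially_folded"
  } else {
    "not_folded"
  }
  structure(list(class = cls, mean_plddt = m, p_confident = p_conf,
                 max_confident_run = max_run, length = length(plddt)),
            class = "foldability")
}

#' @export
print.foldability <- function(x, ...) {
  cat(sprintf("%s (mean pLDDT %.1f, P(confident) %.2f, longest run %d / %d)\n",
              x$class, x$mean_plddt, x$p_confident, x$max_confident_run,
              x$length))
  invisible(x)
}

#' Least-RMSD rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; reflections corrected through
#' the smallest singular vector) and translation minimizing the RMSD of `B`
#' onto `A`, with residues paired by row index.
#'
#' @param A,B L x 3 coordinate matrices (Angstrom), L >= 3.
#' @return list with `rotation` (3x3, applied as `B %*% t(rotation)`),
#'   `translation` (length 3), `rmsd`, and `transformed` (B after the
#'   motion).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3) stop("A and B must be equal-size L x 3 matrices")
  if (nrow(A) < 3) stop("need at least 3 paired points")
  if (any(!is.finite(A)) || any(!is.finite(B))) stop("coordinates must be finite")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) {
    warning("ill-conditioned (degenerate) point set; best-effort superposition")
    d <- 1
  }
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)            # rotation applied to centered B rows
  Bt <- B0 %*% t(R)
  Bt <- sweep(Bt, 2, ca, FUN = "+")
  rmsd <- sqrt(mean(rowSums((Bt - A)^2)))
  list(rotation = R, translation = ca - as.vector(R %*% cb),
       rmsd = rmsd, transformed = Bt)
}

#' TM-score normalization distance d0
#' @param l_norm normalization length.
#' @return d0 in Angstrom, floored at 0.5.
#' @export
tm_d0 <- function(l_norm) {
  pmax(0.5, 1.24 * (pmax(l_norm, 15.001) - 15)^(1 / 3) - 1.8)
}

#' TM-score of two index-paired structures
#'
#' Superposes `B` on `A` (Kabsch on all residues), then iteratively
#' re-superposes on the residue subset with deviation `< d0` until the
#' subset stabilizes (at most `max_iter` rounds), and returns the maximum
#' over iterations of `(1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` evaluated
#' over all residues.  `d0 = max(0.5, 1.24*(L_norm-15)^(1/3) - 1.8)`.
#'
#' @param A,B L x 3 coordinate matrices, residues paired by index.
#' @param l_norm normalization length (default `nrow(A)`).
#' @param max_iter maximum refinement iterations (default 20).
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(A, B, l_norm = nrow(A), max_iter = 20L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("structure length mismatch")
  if (l_norm < 1) stop("l_norm must be >= 1")
  d0 <- tm_d0(l_norm)
  score_of <- function(Bt) {
    d2 <- rowSums((Bt - A)^2)
    sum(1 / (1 + d2 / d0^2)) / l_norm
  }
  sup <- kabsch_superpose(A, B)
  best <- score_of(sup$transformed)
  subset_prev <- NULL
  Bt <- sup$transformed
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((Bt - A)^2))
    subset <- which(d < d0)
    if (length(subset) < 3 || identical(subset, subset_prev)) break
    subset_prev <- subset
    sup_s <- kabsch_superpose(A[subset, , drop = FALSE],
                              B[subset, , drop = FALSE])
    # apply the subset-derived motion to the full structure
    Bt <- sweep(B %*% t(sup_s$rotation), 2, sup_s$translation, FUN = "+")
    best <- max(best, score_of(Bt))
  }
  best
}

#' Select the k lowest-energy models of an ensemble
#'
#' @param models a `structure_ensemble` (see [as_structure_ensemble()]) with
#'   an `energies` component.
#' @param k number of models to keep (default 20); ties at the cut are
#'   broken by model id.
#' @return the sub-ensemble.
#' @export
select_low_energy <- function(models, k = 20L) {
  models <- as_structure_ensemble(models)
  if (is.null(models$energies)) stop("ensemble has no energies")
  if (k > length(models$coords)) stop("k exceeds ensemble size")
  ord <- order(models$energies, models$ids)
  keep <- sort(ord[seq_len(k)])
  as_structure_ensemble(list(coords = models$coords[keep],
                             ids = models$ids[keep],
                             energies = models$energies[keep]))
}

#' Ensemble convergence: average pairwise TM-score x 100
#'
#' The mean over all unordered model pairs of [tm_score()] (normalized by
#' the common model length), multiplied by 100 to put the statistic on the
#' pLDDT scale.
#'
#' @param models a `structure_ensemble` of >= 2 equal-length models.
#' @return value in `(0, 100]`.
#' @export
ensemble_convergence <- function(models) {
  models <- as_structure_ensemble(models)
  n <- length(models$coords)
  if (n < 2) stop("ensemble convergence needs at least 2 models")
  s <- 0; np <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + tm_score(models$coords[[i]], models$coords[[j]])
      np <- np + 1L
    }
  }
  100 * s / np
}

#' Density-peaks clustering of a distance matrix
#'
#' Local density `rho_i = #\{j != i : d_ij < d_c\}`; separation `delta_i` =
#' distance to the nearest point of strictly higher density (ties in rho
#' broken by index; the global peak takes the maximum distance).  The `k`
#' points maximizing `gamma = rho * delta` become cluster centers, and the
#' remaining points are assigned, in decreasing-density order, to the
#' cluster of their nearest already-assigned neighbor of higher density.
#'
#' @param distances symmetric nonnegative matrix with zero diagonal.
#' @param k number of clusters.
#' @param d_c density cutoff; default is the 2nd percentile of off-diagonal
#'   distances.
#' @return list of class `density_peaks` with `labels`, `centers` (indices),
#'   `rho`, `delta`.
#' @export
density_peaks_cluster <- function(distances, k, d_c = NULL) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(D < 0) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("distances must be a symmetric nonnegative matrix with zero diagonal")
  }
  if (k < 1 || k > n) stop("k must be in 1..n")
  if (is.null(d_c)) {
    off <- D[upper.tri(D)]
    d_c <- as.numeric(quantile(off, 0.02))
    if (d_c <= 0) d_c <- min(off[off > 0], na.rm = TRUE)
  }
  rho <- vapply(seq_len(n), function(i) sum(D[i, -i] < d_c), numeric(1))
  # order by decreasing density, ties by index (stable)
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(D[ord[1], ])
  nn_higher[ord[1]] <- NA_integer_
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    nn_higher[i] <- j
  }
  gamma <- rho * delta
  centers <- order(-gamma, seq_len(n))[seq_len(k)]
  labels <- integer(n)
  labels[centers] <- seq_len(k)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] == 0L) {
      labels[i] <- if (is.na(nn_higher[i])) {
        # densest point not selected as a center: nearest center claims it
        labels[centers[which.min(D[i, centers])]]
      } else {
        labels[nn_higher[i]]
      }
    }
  }
  structure(list(labels = labels, centers = centers, rho = rho,
                 delta = delta, d_c = d_c),
            class = "density_peaks")
}

#' @export
print.density_peaks <- function(x, ...) {
  cat(sprintf("Density-peaks clustering: %d points, %d clusters (d_c = %.3g)\n",
              length(x$labels), length(x$centers), x$d_c))
  print(table(x$labels))
  invisible(x)
}

#' Representative models of a conformation clustering
#'
#' Cluster centers ordered by decreasing cluster size (ties by center
#' index); the refined model is the center of the largest cluster.
#'
#' @param clustering a `density_peaks` result.
#' @param models optional `structure_ensemble`; when given, coordinates of
#'   the representatives are attached.
#' @return list with `representatives` (center indices, largest cluster
#'   first), `refined` (single index), and optionally `coords`.
#' @export
representative_models <- function(clustering, models = NULL) {
  stopifnot(inherits(clustering, "density_peaks"))
  sizes <- tabulate(clustering$labels, nbins = length(clustering$centers))
  cl_order <- order(-sizes, clustering$centers)
  reps <- clustering$centers[cl_order]
  out <- list(representatives = reps, refined = reps[1])
  if (!is.null(models)) {
    models <- as_structure_ensemble(models)
    out$coords <- models$coords[reps]
  }
  out
}

#' Flag a potentially novel fold
#'
#' @param max_tm_to_reference_set maximum TM-score of the model against a
#'   reference structure set.
#' @return `TRUE` when the maximum TM-score is strictly below 0.5.
#' @export
novel_fold_flag <- function(max_tm_to_reference_set) {
  stopifnot(all(max_tm_to_reference_set > 0),
            all(max_tm_to_reference_set <= 1))
  max_tm_to_reference_set < 0.5
}

#' Pairwise backbone RMSD matrix of an ensemble (after Kabsch superposition)
#' @param models a `structure_ensemble`.
#' @return symmetric matrix of RMSDs in Angstrom.
#' @export
ensemble_rmsd_matrix <- function(models) {
  models <- as_structure_ensemble(models)
  n <- length(models$coords)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <-
          kabsch_superpose(models$coords[[i]], models$coords[[j]])$rmsd
      }
    }
  }
  D
}

# --- ensemble container and plain-text PDB I/O -----------------------------

#' Coerce to a structure ensemble
#'
#' A `structure_ensemble` is a list with `coords` (list of L x 3 matrices of
#' equal L), `ids` (model identifiers) and optional `energies`.
#'
#' @param x a `structure_ensemble`, a list with a `coords` element, or a
#'   bare list of L x 3 matrices.
#' @export
as_structure_ensemble <- function(x) {
  if (inherits(x, "structure_ensemble")) return(x)
  if (is.list(x) && !is.null(x$coords)) {
    coords <- x$coords; ids <- x$ids; energies <- x$energies
  } else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    coords <- x; ids <- NULL; energies <- NULL
  } else {
    stop("cannot interpret input as a structure ensemble")
  }
  if (is.null(ids)) ids <- seq_along(coords)
  L <- vapply(coords, nrow, integer(1))
  if (length(unique(L)) != 1) stop("models differ in length")
  if (any(!vapply(coords, function(m) all(is.finite(m)), logical(1)))) {
    stop("non-finite coordinates in ensemble")
  }
  structure(list(coords = coords, ids = ids, energies = energies),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d models x %d residues%s\n",
              length(x$coords), nrow(x$coords[[1]]),
              if (is.null(x$energies)) "" else " (with energies)"))
  invisible(x)
}

#' Write a CA-trace structure ensemble as a multi-model PDB file
#' @param models a `structure_ensemble`.
#' @param path output path.
#' @export
write_pdb_ensemble <- function(models, path) {
  models <- as_structure_ensemble(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models$coords)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- models$coords[[m]]
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), seq_len(nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model CA-trace PDB file written by [write_pdb_ensemble()]
#' @param path PDB file path.
#' @return a `structure_ensemble`.
#' @export
read_pdb_ensemble <- function(path) {
  lines <- readLines(path)
  coords <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur <- numeric(0)
    } else if (startsWith(ln, "ATOM")) {
      if (is.null(cur)) cur <- numeric(0)  # single-model file without MODEL
      cur <- c(cur, as.numeric(substr(ln, 31, 38)),
               as.numeric(substr(ln, 39, 46)),
               as.numeric(substr(ln, 47, 54)))
    } else if (tag == "ENDMDL") {
      coords[[length(coords) + 1L]] <- matrix(cur, ncol = 3, byrow = TRUE)
      cur <- NULL
    }
  }
  if (!is.null(cur) && length(cur)) {
    coords[[length(coords) + 1L]] <- matrix(cur, ncol = 3, byrow = TRUE)
  }
  as_structure_ensemble(coords)
}
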