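# Independent oracles used across the suite.  Each re-derives the quantity
# it checks by direct enumeration or a textbook alternative algorithm,
# sharing no code path with the package implementation it verifies.

# ---- exhaustive spliced-alignment enumeration -----------------------------
# Enumerates all locally chained move sequences over (protein consumed i,
# DNA consumed j) with an explicit loop over intron lengths; affine gaps are
# tracked through per-move-type values.  Feasible for N <= 8, DNA <= 60 nt.
oracle_spliced_score <- function(protein, dna, params = align_params()) {
  smat <- denovoscan:::residue_codon_scores(protein, params)
  cod <- denovoscan:::encode_codons(dna)
  N <- nrow(smat); M <- length(cod)
  NEG <- -Inf
  Em <- matrix(NEG, N + 1, M + 1)  # last move: codon match
  Ei <- matrix(NEG, N + 1, M + 1)  # last move: intron
  Ep <- matrix(NEG, N + 1, M + 1)  # last move: protein gap
  Ed <- matrix(NEG, N + 1, M + 1)  # last move: DNA codon gap
  bestprev <- function(i, j) {
    max(0, Em[i + 1, j + 1], Ei[i + 1, j + 1], Ep[i + 1, j + 1], Ed[i + 1, j + 1])
  }
  for (i in 0:N) {
    for (j in 0:M) {
      if (i >= 1 && j >= 3 && cod[j - 2] >= 0) {
        Em[i + 1, j + 1] <- bestprev(i - 1, j - 3) +
          smat[i, cod[j - 2] + 1]
      }
      if (j >= params$min_intron) {
        v <- NEG
        for (jp in 0:(j - params$min_intron)) {
          v <- max(v, bestprev(i, jp) + params$intron_penalty)
        }
        Ei[i + 1, j + 1] <- v
      }
      if (i >= 1) {
        Ep[i + 1, j + 1] <- max(bestprev(i - 1, j) + params$gap_open,
                                Ep[i, j + 1] + params$gap_ext)
      }
      if (j >= 3) {
        Ed[i + 1, j + 1] <- max(bestprev(i, j - 3) + params$gap_open,
                                Ed[i + 1, j - 2] + params$gap_ext)
      }
    }
  }
  best <- 0
  for (i in 0:N) for (j in 0:M) best <- max(best, bestprev(i, j))
  best
}

# ---- direct rule evaluator for branch inference / candidate status --------
# Applies the identification rules verbatim to one per-branch class profile
# (no evidence tables): returns the furthest ortholog branch, outgroup
# support, and the resulting status.
oracle_branch_decision <- function(profile) {
  n <- length(profile)
  ortho <- profile %in% c("annotated_ortholog", "unannotated_ortholog")
  aligned <- any(profile != "no_alignment")
  if (!aligned) {
    return(list(branch = NA_integer_, support = NA, status = "not_aligned"))
  }
  br <- if (any(ortho)) max(which(ortho)) else 0L
  support <- br < n && any(profile[seq(br + 1, n)] == "nongenic")
  status <- if (support) "candidate" else "rejected_no_nongenic_support"
  list(branch = br, support = support, status = status)
}

# ---- quadratic all-pairs peak proximity -----------------------------------
oracle_peak_proximity <- function(genes, peaks, window = 500) {
  out <- data.frame(gene_id = genes$gene_id, n_peaks = 0L,
                    mean_intensity = NA_real_, nearest_distance = Inf)
  for (g in seq_len(nrow(genes))) {
    ws <- max(genes$start[g] - window, 0); we <- genes$end[g] + window
    ints <- c(); best <- Inf
    for (p in seq_len(nrow(peaks))) {
      if (peaks$contig[p] != genes$contig[g]) next
      # half-open overlap with the window
      if (peaks$start[p] < we && peaks$end[p] > ws) {
        out$n_peaks[g] <- out$n_peaks[g] + 1L
        if ("score" %in% names(peaks)) ints <- c(ints, peaks$score[p])
      }
      # edge gap to the gene span itself
      if (peaks$start[p] < genes$end[g] && peaks$end[p] > genes$start[g]) {
        best <- 0
      } else {
        gap <- max(peaks$start[p] - genes$end[g], genes$start[g] - peaks$end[p])
        best <- min(best, gap)
      }
    }
    if (length(ints)) out$mean_intensity[g] <- mean(ints)
    out$nearest_distance[g] <- best
  }
  out
}

# ---- position-by-position ORF scan ----------------------------------------
oracle_orf_scan <- function(seq, min_len = 75) {
  n <- nchar(seq)
  rc <- denovoscan:::revcomp(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (pos in 1:(n - 2)) {
      if (substr(s, pos, pos + 2) != "ATG") next
      q <- pos
      repeat {
        if (q + 2 > n) break
        cod <- substr(s, q, q + 2)
        if (q > pos && cod %in% c("TAA", "TAG", "TGA")) {
          len <- q + 3 - pos
          if (len >= min_len) {
            st <- pos - 1; en <- q + 2
            if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
            rows[[length(rows) + 1L]] <- data.frame(
              start = st, end = en, strand = strand, length = len)
          }
          break
        }
        q <- q + 3
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# ---- quaternion (Horn) absolute-orientation RMSD --------------------------
oracle_quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  S <- crossprod(B0, A0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# ---- O(n^2) Kendall tau-b and rank-Pearson Spearman -----------------------
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0; tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# ---- random rigid motions --------------------------------------------------
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_motion <- function(xyz, R, t) {
  sweep(xyz %*% R, 2, t, FUN = "+")
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
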