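# Surrogate spliced-alignment scorer used by the calibration null model.
# The DP itself lives in src/spliced_align.cpp; this file prepares the
# residue-vs-codon scoring matrix and exposes the user-facing functions.

BASES <- c("A", "C", "G", "T")

# cache for the 64-codon translation table and BLOSUM62
.align_cache <- new.env(parent = emptyenv())

codon_strings <- function() {
  if (is.null(.align_cache$codons)) {
    # index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3 -> build in that order
    idx <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
    .align_cache$codons <- paste0(BASES[idx$b1 + 1L],
                                  BASES[idx$b2 + 1L],
                                  BASES[idx$b3 + 1L])
    .align_cache$codon_aa <- unname(Biostrings::GENETIC_CODE[.align_cache$codons])
  }
  .align_cache$codons
}

codon_aa_table <- function() {
  codon_strings()
  .align_cache$codon_aa
}

blosum62 <- function() {
  if (is.null(.align_cache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$blosum <- e$BLOSUM62
  }
  .align_cache$blosum
}

#' Alignment scoring parameters
#'
#' Parameters of the surrogate spliced-alignment dynamic program: BLOSUM62
#' residue-vs-translated-codon match scores, a flat score for aligning a
#' residue to a stop codon, affine gap costs applied both to protein-only and
#' DNA-codon-only gaps, and a flat intron penalty for skipping at least
#' `min_intron` nucleotides of the target (the "penalty for introducing
#' splicing sites" retained by the reported score).
#'
#' @param gap_open gap opening cost (negative), default -11.
#' @param gap_ext gap extension cost (negative), default -1.
#' @param intron_penalty flat cost of introducing one intron, default -8.
#' @param min_intron minimum intron length in nucleotides, default 40.
#' @param stop_score score of aligning any residue to a stop codon, default -6.
#' @return an object of class `align_params`.
#' @export
align_params <- function(gap_open = -11, gap_ext = -1, intron_penalty = -8,
                         min_intron = 40L, stop_score = -6) {
  stopifnot(gap_open <= 0, gap_ext <= 0, intron_penalty <= 0, min_intron >= 1)
  structure(list(gap_open = gap_open, gap_ext = gap_ext,
                 intron_penalty = intron_penalty,
                 min_intron = as.integer(min_intron),
                 stop_score = stop_score),
            class = "align_params")
}

# N x 64 matrix: score of residue i against each codon
residue_codon_scores <- function(protein, params) {
  aa <- codon_aa_table()
  b <- blosum62()
  res <- strsplit(protein, "")[[1]]
  if (!all(res %in% AA20)) {
    stop("protein sequence contains letters outside the 20-residue alphabet")
  }
  m <- b[res, aa[aa != "*"], drop = FALSE]
  out <- matrix(params$stop_score, nrow = length(res), ncol = 64)
  out[, aa != "*"] <- m
  out
}

encode_codons <- function(dna) {
  base_num <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(dna, "")[[1]]
  if (!all(chars %in% BASES)) stop("DNA sequence contains letters outside ACGT")
  v <- unname(base_num[chars])
  M <- length(v)
  if (M < 3) return(integer(0))
  cod <- 16L * v[1:(M - 2)] + 4L * v[2:(M - 1)] + v[3:M]
  c(cod, -1L, -1L)  # positions whose codon would run off the end
}

#' Score a protein query against a DNA target by spliced local alignment
#'
#' Computes the best locally chained alignment of the protein against the
#' DNA under codon matches (BLOSUM62 against the translated codon), affine
#' protein/DNA gaps, and flat-penalty introns of length at least
#' `params$min_intron`. The empty alignment scores 0, so the score is never
#' negative.
#'
#' @param protein character scalar, protein sequence over the 20-letter
#'   alphabet.
#' @param dna character scalar, DNA sequence over ACGT, at least 3 nt.
#' @param params an [align_params()] object.
#' @return a list of class `score_result` with elements `score`,
#'   `protein_length`, `n_introns`, `aligned_fraction`.
#' @examples
#' p <- "MKWV"
#' dna <- paste0("ATGAAGTGGGTA")
#' spliced_align_score(p, dna)$score
#' @export
spliced_align_score <- function(protein, dna, params = align_params()) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) >= 1L,
            is.character(dna), length(dna) == 1L)
  if (nchar(dna) < 3) stop("DNA target shorter than 3 nt")
  smat <- residue_codon_scores(protein, params)
  cod <- encode_codons(dna)
  r <- spliced_align_core(smat, cod, params$gap_open, params$gap_ext,
                          params$intron_penalty, params$min_intron)
  structure(list(score = r$score,
                 protein_length = nrow(smat),
                 n_introns = r$n_introns,
                 aligned_fraction = r$n_matched / nrow(smat)),
            class = "score_result")
}

#' Generate a random protein sequence
#'
#' Residues are drawn i.i.d. from the supplied amino-acid frequencies
#' (defaults approximate the D. melanogaster proteome composition).
#'
#' @param n protein length in residues (>= 1).
#' @param aa_freqs named or unnamed 20-entry frequency vector summing to 1,
#'   ordered as `A R N D C Q E G H I L K M F P S T W Y V` when unnamed.
#' @return character scalar of length-`n` residues.
#' @export
random_protein <- function(n, aa_freqs = DMEL_AA_FREQS) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  aa_freqs <- check_aa_freqs(aa_freqs)
  paste(sample(AA20, n, replace = TRUE, prob = aa_freqs), collapse = "")
}

#' Generate a random DNA target for a protein of length `n`
#'
#' The target length is `3 * (n + 300)` nucleotides; G and C are each drawn
#' with probability `gc/2`, A and T with `(1 - gc)/2`.
#'
#' @param n protein length the target is sized for (>= 1).
#' @param gc GC content in `[0, 1]`.
#' @return character scalar of DNA.
#' @export
random_dna <- function(n, gc = DMEL_CODING_GC) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  len <- 3L * (as.integer(n) + 300L)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p[BASES]), collapse = "")
}

check_aa_freqs <- function(aa_freqs) {
  if (length(aa_freqs) != 20L) stop("aa_freqs must have 20 entries")
  if (!is.null(names(aa_freqs))) {
    if (!setequal(names(aa_freqs), AA20)) stop("aa_freqs names must be the 20 residues")
    aa_freqs <- aa_freqs[AA20]
  }
  if (any(aa_freqs < 0) || abs(sum(aa_freqs) - 1) > 1e-9) {
    stop("aa_freqs must be nonnegative and sum to 1")
  }
  unname(aa_freqs)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("spliced alignment: score %.1f, N = %d, introns = %d, aligned %.2f\n",
              x$score, x$protein_length, x$n_introns, x$aligned_fraction))
  invisible(x)
}
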