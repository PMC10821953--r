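# Synthetic-data generator with planted ground truth.
#
# Emulates the study design the identification pipeline expects: a ladder
# of outgroup branches, genes planted at known origination branches with
# ortholog / non-genic syntenic evidence, homology-search E-value tables,
# pLDDT foldability archetypes, helix/coil structure ensembles, and tissue
# and stage expression with planted male-biased and tissue-specific genes.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a 9-branch outgroup ladder, 30% planted de novo genes (uniform over
#' branches 1..8; the deepest branch has no outgroup in the ladder and
#' cannot carry the required non-coding evidence), a 20% unannotated
#' fraction among ortholog hits, log-uniform E-values (1e-30..1e-6 for true
#' homologs, 1e-2..1e2 for spurious ones, at a 5% spurious-row rate),
#' foldability archetype weights close to the observed well/partial/none
#' proportions, four stage archetypes peaking from early to late
#' spermatogenesis, and a 50% male-bias rate among planted de novo genes.
#'
#' @param n_genes number of simulated genes.
#' @param n_branches outgroup branches in the ladder (>= 2, default 9).
#' @param frac_de_novo fraction of genes planted as de novo candidates.
#' @param branch_weights per-branch origination probabilities (length
#'   `n_branches`, summing to 1).
#' @param frac_unannotated fraction of ortholog hits left unannotated.
#' @param p_no_alignment chance an outgroup species has no lifted region
#'   instead of a non-genic hit.
#' @param p_spurious_homolog per-gene chance of a spurious homology row.
#' @param frac_intragenic fraction of de novo genes born inside an existing
#'   gene's span.
#' @param fold_weights probabilities of the well/partial/none pLDDT
#'   archetypes.
#' @param stage_weights probabilities of the four stage archetypes.
#' @param frac_male_biased fraction of de novo genes planted male-biased.
#' @param evalue_true_homolog,evalue_unrelated log10 E-value ranges.
#' @param aa_freqs,gc_content random-sequence composition.
#' @param length_range protein length range (residues).
#' @param stage_noise_sd Gaussian noise added to scaled stage templates.
#' @param seed master seed; every simulate_* function derives its stream
#'   from it.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 500L,
                              n_branches = 9L,
                              frac_de_novo = 0.3,
                              branch_weights = NULL,
                              frac_unannotated = 0.2,
                              p_no_alignment = 0.1,
                              p_spurious_homolog = 0.05,
                              frac_intragenic = 0.3,
                              fold_weights = c(well = 0.06, partial = 0.54,
                                               none = 0.40),
                              stage_weights = c(0.10, 0.32, 0.48, 0.10),
                              frac_male_biased = 0.5,
                              evalue_true_homolog = c(-30, -6),
                              evalue_unrelated = c(-2, 2),
                              aa_freqs = DMEL_AA_FREQS,
                              gc_content = DMEL_CODING_GC,
                              length_range = c(90L, 250L),
                              stage_noise_sd = 0.15,
                              seed = 1L) {
  if (n_branches < 2) stop("invalid config: n_branches must be >= 2")
  if (is.null(branch_weights)) {
    branch_weights <- c(rep(1 / (n_branches - 1), n_branches - 1), 0)
  }
  stopifnot(length(branch_weights) == n_branches,
            abs(sum(branch_weights) - 1) < 1e-9,
            all(branch_weights >= 0))
  fracs <- c(frac_de_novo, frac_unannotated, p_no_alignment,
             p_spurious_homolog, frac_intragenic, frac_male_biased,
             gc_content)
  if (any(fracs < 0 | fracs > 1)) stop("invalid config: fractions must be in [0, 1]")
  aa_freqs <- check_aa_freqs(aa_freqs)
  stopifnot(abs(sum(fold_weights) - 1) < 1e-9,
            abs(sum(stage_weights) - 1) < 1e-9)
  structure(list(
    n_genes = as.integer(n_genes), n_branches = as.integer(n_branches),
    frac_de_novo = frac_de_novo, branch_weights = branch_weights,
    frac_unannotated = frac_unannotated, p_no_alignment = p_no_alignment,
    p_spurious_homolog = p_spurious_homolog,
    frac_intragenic = frac_intragenic,
    fold_weights = fold_weights, stage_weights = stage_weights,
    frac_male_biased = frac_male_biased,
    evalue_true_homolog = evalue_true_homolog,
    evalue_unrelated = evalue_unrelated,
    aa_freqs = aa_freqs, gc_content = gc_content,
    length_range = as.integer(length_range),
    stage_noise_sd = stage_noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# derive a reproducible substream seed from the master seed
substream_seed <- function(config, offset) {
  (config$seed * 7919L + offset * 104729L) %% .Machine$integer.max
}

#' Generate a ladder species tree
#'
#' Branch `i` separates the focal taxon (`sp0`) from outgroup `i`; leaves
#' are `sp0, sp1, ..., spN` with `sp1` the closest outgroup.
#'
#' @param n_branches number of outgroup branches (>= 2).
#' @return an `ape` `phylo` object.
#' @export
generate_species_tree <- function(n_branches) {
  if (length(n_branches) != 1L || n_branches < 2) {
    stop("invalid config: n_branches must be >= 2")
  }
  txt <- "sp0:1"
  for (i in seq_len(n_branches)) {
    txt <- sprintf("(%s,sp%d:%d):1", txt, i, i)
  }
  ape::read.tree(text = paste0(txt, ";"))
}

draw_archetypes <- function(n, weights, labels) {
  labels[sample.int(length(weights), n, replace = TRUE, prob = weights)]
}

#' Simulate gene histories: planted truth, syntenic hits, annotation
#'
#' Genes are either "ancient" (orthologs in every branch, plus true distant
#' homologs) or planted de novo at branch `b` (orthologs in branches
#' `<= b`, non-genic hits or no alignment beyond `b`, with at least one
#' non-genic outgroup hit).  A fraction of ortholog hits is left
#' unannotated and carries a significant genic p-value instead of a blastp
#' E-value.  Gene spans are laid out on one contig; intragenic de novo
#' genes are nested inside a host gene's span.
#'
#' @param config a [simulation_config()].
#' @return list of class `gene_histories` with `truth` (gene_id, origin,
#'   true_branch, context, fold_archetype, stage_archetype, male_biased,
#'   length), `hits` (gene_id, species, branch, class, annotated_evalue,
#'   genic_pvalue), `annotation` (gene spans incl. intragenic hosts), and
#'   `sequences` (named CDS and protein character vectors).
#' @export
simulate_gene_histories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config, 1L))
  n <- config$n_genes
  nb <- config$n_branches
  ids <- sprintf("g%04d", seq_len(n))

  de_novo <- runif(n) < config$frac_de_novo
  branch <- rep(NA_integer_, n)
  if (any(de_novo)) {
    branch[de_novo] <- sample.int(nb, sum(de_novo), replace = TRUE,
                                  prob = config$branch_weights)
  }
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  truth <- data.frame(
    gene_id = ids,
    origin = ifelse(de_novo, "de_novo", "ancient"),
    true_branch = branch,
    context = ifelse(de_novo & runif(n) < config$frac_intragenic,
                     "intragenic", "intergenic"),
    fold_archetype = draw_archetypes(n, config$fold_weights,
                                     c("well", "partial", "none")),
    stage_archetype = sample.int(4L, n, replace = TRUE,
                                 prob = config$stage_weights),
    male_biased = de_novo & (runif(n) < config$frac_male_biased),
    length = lens,
    stringsAsFactors = FALSE)

  # per-gene hit rows across branches
  lo <- config$evalue_true_homolog[1]; hi <- config$evalue_true_homolog[2]
  rows <- vector("list", n)
  gene_seeds <- sample.int(.Machine$integer.max, n)
  for (g in seq_len(n)) {
    set.seed(gene_seeds[g])
    b_max <- if (de_novo[g]) branch[g] else nb
    cls <- character(nb)
    ann_e <- rep(NA_real_, nb); gen_p <- rep(NA_real_, nb)
    for (b in seq_len(nb)) {
      if (b <= b_max) {
        if (runif(1) < config$frac_unannotated) {
          cls[b] <- "unannotated_ortholog"
          gen_p[b] <- 10^runif(1, -30, -8)
        } else {
          cls[b] <- "annotated_ortholog"
          ann_e[b] <- 10^runif(1, lo, hi)
        }
      } else {
        if (runif(1) < config$p_no_alignment) {
          cls[b] <- "no_alignment"
        } else {
          cls[b] <- "nongenic"
          gen_p[b] <- runif(1, 0.01, 1)
        }
      }
    }
    # a plantable candidate needs at least one non-genic outgroup hit
    if (de_novo[g] && b_max < nb && !any(cls[(b_max + 1):nb] == "nongenic")) {
      cls[nb] <- "nongenic"
      gen_p[nb] <- runif(1, 0.01, 1)
    }
    rows[[g]] <- data.frame(gene_id = ids[g], species = paste0("sp", seq_len(nb)),
                            branch = seq_len(nb), class = cls,
                            annotated_evalue = ann_e, genic_pvalue = gen_p,
                            stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)

  # genome layout: genes 10 kb apart; intragenic genes nested in a host span
  set.seed(substream_seed(config, 2L))
  start <- cumsum(rep(10000L, n)) - 5000L
  end <- start + 3L * (lens + 1L)
  annotation <- data.frame(gene_id = ids, contig = "chr2L",
                           start = start, end = end, strand = "+",
                           stringsAsFactors = FALSE)
  intra <- which(truth$context == "intragenic")
  if (length(intra)) {
    hosts <- data.frame(gene_id = paste0("host_", ids[intra]),
                        contig = "chr2L",
                        start = pmax(start[intra] - 2000L, 0L),
                        end = end[intra] + 2000L, strand = "-",
                        stringsAsFactors = FALSE)
    annotation <- rbind(annotation, hosts)
  }

  sequences <- simulate_cds_set(lens, config$gc_content)
  names(sequences$cds) <- ids
  names(sequences$protein) <- ids

  structure(list(truth = truth, hits = hits, annotation = annotation,
                 sequences = sequences, config = config),
            class = "gene_histories")
}

# random CDS (ATG + non-stop codons + stop) and their proteins
simulate_cds_set <- function(lens, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cods <- codon_strings()
  aa <- codon_aa_table()
  ok <- aa != "*" & cods != "ATG"
  # codon sampling weights from base composition
  w <- vapply(strsplit(cods, ""), function(b) prod(p[b]), numeric(1))
  cds <- character(length(lens)); prot <- character(length(lens))
  for (i in seq_along(lens)) {
    body <- sample(cods[ok], lens[i] - 1L, replace = TRUE, prob = w[ok])
    stopc <- sample(STOP_CODONS, 1L, prob = w[match(STOP_CODONS, cods)])
    cds[i] <- paste(c("ATG", body, stopc), collapse = "")
    prot[i] <- paste(c("M", aa[match(body, cods)]), collapse = "")
  }
  list(cds = cds, protein = prot)
}

#' Simulate homology-search evidence tables
#'
#' Ancient genes receive true distant-homolog rows (at least two searches,
#' log10 E-values in the true-homolog range) in both the UniProt-style and
#' arthropod tables; de novo genes receive only rare spurious rows in the
#' unrelated E-value range.
#'
#' @param histories a [simulate_gene_histories()] result (or its `truth`).
#' @param config the [simulation_config()]; taken from `histories` when
#'   omitted.
#' @return list with `evidence` (gene_id, subject_species, subject_branch,
#'   search, evalue, best_domain_evalue) and `arthropod` (gene_id,
#'   subject_species, evalue).
#' @export
simulate_homolog_evidence <- function(histories, config = NULL) {
  if (inherits(histories, "gene_histories")) {
    truth <- histories$truth
    if (is.null(config)) config <- histories$config
  } else {
    truth <- histories
  }
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config, 3L))
  lo_t <- config$evalue_true_homolog[1]; hi_t <- config$evalue_true_homolog[2]
  lo_u <- config$evalue_unrelated[1]; hi_u <- config$evalue_unrelated[2]

  ev <- list(); ar <- list()
  for (g in seq_len(nrow(truth))) {
    id <- truth$gene_id[g]
    if (truth$origin[g] == "ancient") {
      searches <- sample(SEARCH_NAMES[1:3], 2L + rbinom(1, 1, 0.5))
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = id, subject_species = "uniprot_distant",
        subject_branch = Inf, search = searches,
        evalue = 10^runif(length(searches), lo_t, hi_t),
        best_domain_evalue = 10^runif(length(searches), lo_t, hi_t),
        stringsAsFactors = FALSE)
      ar[[length(ar) + 1L]] <- data.frame(
        gene_id = id, subject_species = "arthropod_1",
        evalue = 10^runif(1, lo_t, hi_t), stringsAsFactors = FALSE)
    } else {
      if (runif(1) < config$p_spurious_homolog) {
        ev[[length(ev) + 1L]] <- data.frame(
          gene_id = id, subject_species = "uniprot_distant",
          subject_branch = Inf, search = sample(SEARCH_NAMES[1:3], 1L),
          evalue = 10^runif(1, lo_u, hi_u),
          best_domain_evalue = 10^runif(1, lo_u, hi_u),
          stringsAsFactors = FALSE)
      }
      if (runif(1) < config$p_spurious_homolog) {
        ar[[length(ar) + 1L]] <- data.frame(
          gene_id = id, subject_species = "arthropod_1",
          evalue = 10^runif(1, lo_u, hi_u), stringsAsFactors = FALSE)
      }
    }
  }
  empty_ev <- data.frame(gene_id = character(0), subject_species = character(0),
                         subject_branch = numeric(0), search = character(0),
                         evalue = numeric(0), best_domain_evalue = numeric(0))
  empty_ar <- data.frame(gene_id = character(0), subject_species = character(0),
                         evalue = numeric(0))
  list(evidence = if (length(ev)) do.call(rbind, ev) else empty_ev,
       arthropod = if (length(ar)) do.call(rbind, ar) else empty_ar)
}

#' Simulate per-residue confidence (pLDDT) profiles
#'
#' Archetypes: `well` draws every residue from N(88, 4); `partial` draws
#' one contiguous segment of at least 60 residues from N(80, 4) and the
#' remainder from N(45, 8); `none` draws everything from N(40, 8).  Scores
#' are clipped to `[0, 100]`.
#'
#' @param histories a [simulate_gene_histories()] result (or a `truth`
#'   data.frame with `gene_id`, `fold_archetype`, `length`).
#' @param config optional [simulation_config()] for the seed.
#' @return named list of numeric profiles, one per gene.
#' @export
simulate_plddt_profiles <- function(histories, config = NULL) {
  if (inherits(histories, "gene_histories")) {
    truth <- histories$truth
    if (is.null(config)) config <- histories$config
  } else {
    truth <- histories
  }
  if (!is.null(config)) set.seed(substream_seed(config, 4L))
  out <- vector("list", nrow(truth))
  names(out) <- truth$gene_id
  for (g in seq_len(nrow(truth))) {
    out[[g]] <- plddt_archetype_profile(truth$fold_archetype[g],
                                        truth$length[g])
  }
  out
}

#' One pLDDT profile from a foldability archetype
#' @param archetype `"well"`, `"partial"`, or `"none"`.
#' @param length protein length in residues (>= 90 recommended for the
#'   partial archetype, whose confident segment spans 60..0.75*L residues).
#' @return numeric vector in `[0, 100]`.
#' @export
plddt_archetype_profile <- function(archetype, length) {
  L <- as.integer(length)
  stopifnot(L >= 1)
  x <- switch(archetype,
    well = rnorm(L, 88, 4),
    none = rnorm(L, 40, 8),
    partial = {
      seg_max <- max(60L, floor(0.75 * L))
      seg <- if (seg_max > 60L) sample(60:seg_max, 1L) else 60L
      seg <- min(seg, L)
      at <- if (L > seg) sample.int(L - seg + 1L, 1L) else 1L
      v <- rnorm(L, 45, 8)
      v[at:(at + seg - 1L)] <- rnorm(seg, 80, 4)
      v
    },
    stop("unknown archetype: ", archetype))
  pmin(pmax(x, 0), 100)
}

#' Simulate a structure ensemble from an archetype
#'
#' `well`: an ideal alpha-helix CA trace (rise 1.5 A per residue, 100 deg
#' turn, radius 2.3 A), perturbed per model by Gaussian coordinate noise
#' and placed in a random orientation.  `none`: an independent
#' self-avoiding random walk per model (3.8 A steps, 3.5 A exclusion).
#'
#' @param archetype `"well"` or `"none"`.
#' @param n_models ensemble size (>= 2).
#' @param length residues per model.
#' @param noise_sd per-coordinate Gaussian noise for the helix archetype
#'   (Angstrom, default 0.5).
#' @return a `structure_ensemble` with uniform pseudo-energies.
#' @export
simulate_structure_ensemble <- function(archetype, n_models, length = 100L,
                                        noise_sd = 0.5) {
  if (n_models < 2) stop("invalid config: n_models must be >= 2")
  L <- as.integer(length)
  coords <- vector("list", n_models)
  if (archetype == "well") {
    base <- ideal_helix(L)
    for (m in seq_len(n_models)) {
      pert <- base + matrix(rnorm(3 * L, 0, noise_sd), ncol = 3)
      coords[[m]] <- random_rigid_motion(pert)
    }
  } else if (archetype == "none") {
    for (m in seq_len(n_models)) {
      coords[[m]] <- self_avoiding_walk(L)
    }
  } else {
    stop("unknown archetype: ", archetype)
  }
  as_structure_ensemble(list(coords = coords, ids = seq_len(n_models),
                             energies = runif(n_models, -100, 0)))
}

ideal_helix <- function(L, rise = 1.5, turn_deg = 100, radius = 2.3) {
  t <- seq_len(L) - 1L
  ang <- t * turn_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * t)
}

random_rigid_motion <- function(xyz) {
  # uniform-ish random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(xyz %*% q, 2, runif(3, -20, 20), FUN = "+")
}

self_avoiding_walk <- function(L, step = 3.8, exclusion = 3.5,
                               max_tries = 50L) {
  repeat {
    xyz <- matrix(0, L, 3)
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        d <- rnorm(3)
        d <- d / sqrt(sum(d^2)) * step
        cand <- xyz[i - 1, ] + d
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        if (i == 2 || all(rowSums(sweep(prev, 2, cand)^2) > exclusion^2)) {
          xyz[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
}

FLY_TISSUES <- c(
  "head", "eye", "brain", "thoracic_ganglion", "salivary_gland", "crop",
  "midgut", "hindgut", "malpighian_tubule", "fat_body", "heart", "trachea",
  "carcass", "rectal_pad", "testis", "accessory_gland", "ovary",
  "spermatheca", "wing", "leg", "proboscis", "antenna", "haltere",
  "male_gut", "female_gut", "larval_cns", "larval_fat_body")

# scaled stage archetype templates over the six spermatogenesis stages,
# peaking from early spermatogonia (1) to late spermatids (4)
stage_archetype_templates <- function() {
  stages <- 1:6
  centers <- c(1, 2.8, 4.6, 6)
  t(vapply(centers, function(cc) {
    v <- exp(-((stages - cc) / 1.1)^2)
    (v - mean(v)) / sd(v)
  }, numeric(6)))
}

#' Simulate tissue and stage expression with planted specificity
#'
#' Produces a 27-tissue FPKM matrix (male-biased genes concentrate their
#' expression in the testis; other genes draw a broad profile), male and
#' female whole-body means with replicate SDs (male mean at least 4x the
#' female mean for planted male-biased genes), and a 6-stage scaled testis
#' profile per gene drawn from the gene's stage archetype plus Gaussian
#' noise.
#'
#' @param histories a [simulate_gene_histories()] result (or `truth`).
#' @param config optional [simulation_config()].
#' @return list with `tissue_fpkm` (genes x 27), `whole_body` (data.frame
#'   gene_id, male_mean, female_mean, male_sd, female_sd), `stages`
#'   (genes x 6 matrix), `templates` (4 x 6 archetype matrix).
#' @export
simulate_expression <- function(histories, config = NULL) {
  if (inherits(histories, "gene_histories")) {
    truth <- histories$truth
    if (is.null(config)) config <- histories$config
  } else {
    truth <- histories
  }
  if (!is.null(config)) set.seed(substream_seed(config, 5L))
  noise_sd <- if (!is.null(config)) config$stage_noise_sd else 0.15
  n <- nrow(truth)
  nt <- length(FLY_TISSUES)
  testis_col <- which(FLY_TISSUES == "testis")

  fpkm <- matrix(0, n, nt, dimnames = list(truth$gene_id, FLY_TISSUES))
  male_mean <- female_mean <- male_sd <- female_sd <- numeric(n)
  for (g in seq_len(n)) {
    base <- exp(rnorm(1, 2, 1))              # overall expression level
    if (truth$male_biased[g]) {
      w <- rgamma(nt, shape = 0.05)          # highly concentrated
      w[testis_col] <- w[testis_col] + 3
    } else if (truth$origin[g] == "de_novo") {
      w <- rgamma(nt, shape = 0.3)           # narrow but not sex-biased
    } else {
      w <- rgamma(nt, shape = 5)             # broad ancient expression
    }
    fpkm[g, ] <- base * w / mean(w)
    bias <- if (truth$male_biased[g]) runif(1, 4, 10) else 1
    true_f <- base
    true_m <- base * bias
    male_sd[g] <- 0.1 * true_m + 0.01
    female_sd[g] <- 0.1 * true_f + 0.01
    male_mean[g] <- max(0, true_m + rnorm(1, 0, male_sd[g]))
    female_mean[g] <- max(0, true_f + rnorm(1, 0, female_sd[g]))
  }
  templates <- stage_archetype_templates()
  stages <- templates[truth$stage_archetype, , drop = FALSE] +
    matrix(rnorm(6 * n, 0, noise_sd), n, 6)
  dimnames(stages) <- list(truth$gene_id,
                           c("early_spermatogonia", "late_spermatogonia",
                             "early_spermatocytes", "late_spermatocytes",
                             "early_spermatids", "late_spermatids"))
  attr(fpkm, "unit") <- "FPKM"
  list(tissue_fpkm = fpkm,
       whole_body = data.frame(gene_id = truth$gene_id,
                               male_mean = male_mean,
                               female_mean = female_mean,
                               male_sd = male_sd, female_sd = female_sd,
                               stringsAsFactors = FALSE),
       stages = stages, templates = templates)
}

#' Simulate ATAC-like peaks near gene spans
#'
#' Each annotated gene receives, with probability `p_peak`, one peak within
#' its +/- 500 bp flank; background peaks are scattered across the contig.
#'
#' @param annotation gene-span table (`gene_id`, `contig`, `start`, `end`).
#' @param p_peak per-gene peak probability (default 0.7).
#' @param n_background background peak count (default 50).
#' @param config optional [simulation_config()] for the seed.
#' @return BED-style data.frame (`contig`, `start`, `end`, `name`,
#'   `score`), 0-based half-open.
#' @export
simulate_peaks <- function(annotation, p_peak = 0.7, n_background = 50L,
                           config = NULL) {
  if (!is.null(config)) set.seed(substream_seed(config, 6L))
  rows <- list()
  for (g in seq_len(nrow(annotation))) {
    if (runif(1) < p_peak) {
      off <- sample(-500:500, 1L)
      s <- max(annotation$start[g] + off, 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = annotation$contig[g], start = s, end = s + 200L,
        name = paste0("peak_", annotation$gene_id[g]),
        score = round(exp(rnorm(1, 4, 1)), 2), stringsAsFactors = FALSE)
    }
  }
  span_max <- max(annotation$end) + 10000L
  bg_start <- sort(sample.int(span_max, n_background))
  rows[[length(rows) + 1L]] <- data.frame(
    contig = annotation$contig[1], start = bg_start, end = bg_start + 200L,
    name = sprintf("bg_%03d", seq_len(n_background)),
    score = round(exp(rnorm(n_background, 3, 1)), 2),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete dataset
#'
#' Runs every generator with streams derived from the config seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `denovo_simulation` bundling histories, homology
#'   evidence, pLDDT profiles, expression, and peaks.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  hist <- simulate_gene_histories(config)
  hom <- simulate_homolog_evidence(hist)
  plddt <- simulate_plddt_profiles(hist)
  expr <- simulate_expression(hist)
  peaks <- simulate_peaks(hist$annotation, config = config)
  structure(list(config = config, truth = hist$truth, hits = hist$hits,
                 annotation = hist$annotation, sequences = hist$sequences,
                 evidence = hom$evidence, arthropod = hom$arthropod,
                 plddt = plddt, expression = expr, peaks = peaks),
            class = "denovo_simulation")
}

#' @export
print.denovo_simulation <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes (%d planted de novo), %d branches, seed %d\n",
              x$config$n_genes, sum(x$truth$origin == "de_novo"),
              x$config$n_branches, x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits protein/CDS FASTA, a GFF3 of gene models (1-based inclusive), the
#' newick species tree, TSV hit/evidence/expression/pLDDT tables, a BED
#' peak file (0-based half-open) and a JSON planted-truth file.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "denovo_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(outdir, "proteins.fasta"),
    cds = file.path(outdir, "cds.fasta"),
    gff = file.path(outdir, "genes.gff3"),
    tree = file.path(outdir, "tree.nwk"),
    hits = file.path(outdir, "hits.tsv"),
    evidence = file.path(outdir, "evidence.tsv"),
    arthropod = file.path(outdir, "arthropod.tsv"),
    plddt = file.path(outdir, "plddt.tsv"),
    fpkm = file.path(outdir, "tissue_fpkm.tsv"),
    whole_body = file.path(outdir, "whole_body.tsv"),
    stages = file.path(outdir, "stages.tsv"),
    peaks = file.path(outdir, "peaks.bed"),
    truth = file.path(outdir, "truth.json"))

  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sim$sequences$protein), paths["proteins"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences$cds), paths["cds"])

  ann <- sim$annotation
  gff <- sprintf("%s\tdenovoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 ann$contig, ann$start + 1L, ann$end, ann$strand, ann$gene_id)
  writeLines(c("##gff-version 3", gff), paths["gff"])

  ape::write.tree(generate_species_tree(sim$config$n_branches), paths["tree"])

  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(sim$hits, paths["hits"])
  tsv(sim$evidence, paths["evidence"])
  tsv(sim$arthropod, paths["arthropod"])
  plddt_df <- do.call(rbind, lapply(names(sim$plddt), function(id) {
    data.frame(gene = id, residue_index = seq_along(sim$plddt[[id]]),
               plddt = round(sim$plddt[[id]], 2), stringsAsFactors = FALSE)
  }))
  tsv(plddt_df, paths["plddt"])
  tsv(data.frame(gene_id = rownames(sim$expression$tissue_fpkm),
                 sim$expression$tissue_fpkm, check.names = FALSE),
      paths["fpkm"])
  tsv(sim$expression$whole_body, paths["whole_body"])
  tsv(data.frame(gene_id = rownames(sim$expression$stages),
                 sim$expression$stages, check.names = FALSE),
      paths["stages"])
  write.table(sim$peaks, paths["peaks"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA)
  invisible(paths)
}
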