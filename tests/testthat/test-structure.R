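# Foldability classification, Kabsch/TM-score, ensemble convergence,
# density peaks, and the PDB ensemble round-trip.

test_that("foldability classes follow the threshold rules, strictly", {
  expect_equal(classify_foldability(rep(90, 100))$class, "well_folded")
  prof <- c(rep(80, 60), rep(40, 140))
  expect_equal(classify_foldability(prof)$class, "partially_folded")
  expect_equal(classify_foldability(rep(40, 100))$class, "not_folded")
  # boundaries fall to the lower class: mean exactly 80, run exactly 50
  at_mean <- rep(80, 100)                      # mean 80, p_confident 1
  expect_equal(classify_foldability(at_mean)$class, "partially_folded")
  run50 <- c(rep(71, 50), rep(10, 450))        # run exactly 50, p = 0.1
  expect_equal(classify_foldability(run50)$class, "not_folded")
  run51 <- c(rep(71, 51), rep(10, 450))
  expect_equal(classify_foldability(run51)$class, "partially_folded")
  expect_error(classify_foldability(numeric(0)), "empty")
  expect_error(classify_foldability(c(50, 120)), "within")
})

test_that("raising any residue's confidence never demotes the class", {
  rank_of <- c(not_folded = 1, partially_folded = 2, well_folded = 3)
  set.seed(12)
  for (i in 1:50) {
    p <- runif(80, 0, 100)
    base <- rank_of[classify_foldability(p)$class]
    j <- sample(80, 1)
    p2 <- p
    p2[j] <- min(100, p[j] + runif(1, 0, 40))
    expect_gte(rank_of[classify_foldability(p2)$class], base)
  }
})

test_that("kabsch recovers rigid motions exactly", {
  set.seed(13)
  A <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  R <- random_rotation(); t <- c(3, -2, 7)
  B <- apply_motion(A, R, t)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-8)
  ident <- kabsch_superpose(A, A)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ident$translation, rep(0, 3), tolerance = 1e-10)
})

test_that("kabsch RMSD equals the quaternion-method oracle", {
  set.seed(14)
  for (i in 1:25) {
    L <- sample(4:40, 1)
    A <- matrix(rnorm(L * 3, sd = 4), ncol = 3)
    B <- A + matrix(rnorm(L * 3, sd = 1), ncol = 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-6)
  }
  # 4-point toy square vs a perturbed copy
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  pert <- sq + matrix(rnorm(12), ncol = 3)
  expect_equal(kabsch_superpose(sq, pert)$rmsd,
               oracle_quaternion_rmsd(sq, pert), tolerance = 1e-6)
})

test_that("kabsch cross-checks against bio3d's superposition", {
  set.seed(15)
  A <- matrix(rnorm(20 * 3, sd = 4), ncol = 3)
  B <- A + matrix(rnorm(20 * 3, sd = 0.8), ncol = 3)
  ours <- kabsch_superpose(A, B)$rmsd
  xyzA <- as.vector(t(A)); xyzB <- as.vector(t(B))
  theirs <- bio3d::rmsd(xyzA, xyzB, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("tm_score is exact on constructed geometries", {
  set.seed(16)
  helix <- denovoscan:::ideal_helix(100)
  expect_equal(tm_score(helix, helix), 1.0)
  # every deviation exactly d0 after superposition: alternating +/- d0
  # displacements along z on a planar square grid (zero mean, zero moment)
  L <- 36
  g <- as.matrix(expand.grid(x = seq_len(6), y = seq_len(6)))
  A <- cbind(10 * g, 0)
  d0 <- tm_d0(L)
  zsign <- (-1)^(g[, 1] + g[, 2])
  B <- A + cbind(0, 0, d0 * zsign)
  expect_equal(tm_score(A, B), 0.5, tolerance = 1e-9)
})

test_that("tm_score equals the direct formula on the final superposition", {
  set.seed(17)
  helix <- denovoscan:::ideal_helix(100)
  noisy <- helix + matrix(rnorm(300, 0, 0.5), ncol = 3)
  got <- tm_score(helix, noisy)
  # formula oracle: evaluate on the full-set Kabsch superposition and on
  # iteratively refined subsets; the reported score is their maximum
  d0 <- tm_d0(100)
  score_of <- function(Bt) sum(1 / (1 + rowSums((Bt - helix)^2) / d0^2)) / 100
  sup <- kabsch_superpose(helix, noisy)
  best <- score_of(sup$transformed)
  Bt <- sup$transformed
  prev <- NULL
  for (i in 1:20) {
    ss <- which(sqrt(rowSums((Bt - helix)^2)) < d0)
    if (length(ss) < 3 || identical(ss, prev)) break
    prev <- ss
    sp <- kabsch_superpose(helix[ss, ], noisy[ss, ])
    Bt <- sweep(noisy %*% t(sp$rotation), 2, sp$translation, FUN = "+")
    best <- max(best, score_of(Bt))
  }
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("tm_score is symmetric and rigid-motion invariant", {
  set.seed(18)
  A <- denovoscan:::ideal_helix(60)
  B <- A + matrix(rnorm(180, 0, 1), ncol = 3)
  s0 <- tm_score(A, B, l_norm = 60)
  expect_equal(tm_score(B, A, l_norm = 60), s0, tolerance = 1e-9)
  for (i in 1:20) {
    R <- random_rotation(); t <- rnorm(3, 0, 10)
    expect_equal(tm_score(A, apply_motion(B, R, t), l_norm = 60), s0,
                 tolerance = 1e-9)
    expect_equal(tm_score(apply_motion(A, R, t), B, l_norm = 60), s0,
                 tolerance = 1e-9)
  }
})

test_that("low-energy selection is an order statistic with id tie-breaks", {
  set.seed(19)
  coords <- replicate(10, matrix(rnorm(15), ncol = 3), simplify = FALSE)
  ens <- as_structure_ensemble(list(coords = coords, ids = 1:10,
                                    energies = c(5, 1, 3, 3, 2, 9, 8, 7, 6, 4)))
  sel <- select_low_energy(ens, 4)
  expect_equal(sel$ids, c(2, 3, 4, 5))
  expect_equal(select_low_energy(ens, 10)$ids, 1:10)
  expect_error(select_low_energy(ens, 11), "exceeds")
  expect_error(select_low_energy(as_structure_ensemble(coords), 2),
               "no energies")
})

test_that("ensemble convergence behaves on identical, paired, duplicated models", {
  set.seed(20)
  m <- denovoscan:::ideal_helix(50)
  same <- as_structure_ensemble(list(coords = list(m, m, m)))
  expect_equal(ensemble_convergence(same), 100)
  noisy <- m + matrix(rnorm(150, 0, 1), ncol = 3)
  pair <- as_structure_ensemble(list(coords = list(m, noisy)))
  expect_equal(ensemble_convergence(pair), 100 * tm_score(m, noisy))
  # duplicating an existing model never lowers convergence
  third <- m + matrix(rnorm(150, 0, 2), ncol = 3)
  ens <- as_structure_ensemble(list(coords = list(m, noisy, third)))
  dup <- as_structure_ensemble(list(coords = list(m, noisy, third, third)))
  expect_gte(ensemble_convergence(dup), ensemble_convergence(ens) - 1e-9)
})

test_that("helix ensembles converge more than random-coil ensembles", {
  set.seed(22)
  for (i in 1:5) {
    well <- simulate_structure_ensemble("well", 6, length = 80)
    coil <- simulate_structure_ensemble("none", 6, length = 80)
    expect_gt(ensemble_convergence(well), ensemble_convergence(coil))
  }
})

test_that("density peaks separates two planted blobs exactly", {
  set.seed(24)
  blob1 <- matrix(rnorm(40 * 2, 0, 0.3), ncol = 2)
  blob2 <- matrix(rnorm(30 * 2, 8, 0.3), ncol = 2)
  pts <- rbind(blob1, blob2)
  D <- as.matrix(dist(pts))
  cl <- density_peaks_cluster(D, k = 2)
  truth <- rep(1:2, c(40, 30))
  expect_equal(adjusted_rand(cl$labels, truth), 1)
  # k = 1 and k = n degenerate cases
  one <- density_peaks_cluster(D, k = 1)
  expect_true(all(one$labels == 1))
  expect_equal(one$centers, which.max(cl$rho * cl$delta))
  all_k <- density_peaks_cluster(D, k = nrow(D))
  expect_equal(sort(unique(all_k$labels)), seq_len(nrow(D)))
  expect_error(density_peaks_cluster(D[, -1], 2), "symmetric")
})

test_that("density peaks labels are permutation-equivariant", {
  set.seed(25)
  pts <- rbind(matrix(rnorm(30, 0, 0.4), ncol = 2),
               matrix(rnorm(30, 6, 0.4), ncol = 2))
  D <- as.matrix(dist(pts))
  cl <- density_peaks_cluster(D, k = 2)
  perm <- sample(nrow(D))
  clp <- density_peaks_cluster(D[perm, perm], k = 2)
  # cluster memberships agree up to label names
  expect_equal(adjusted_rand(cl$labels[perm], clp$labels), 1)
})

test_that("representative models are cluster centers, largest first", {
  labels <- rep(c(1, 2, 3), c(50, 30, 20))
  n <- length(labels)
  # distance matrix with three tight groups so centers land inside groups
  set.seed(26)
  pts <- c(rnorm(50, 0, 0.1), rnorm(30, 10, 0.1), rnorm(20, 20, 0.1))
  D <- as.matrix(dist(pts))
  cl <- density_peaks_cluster(D, k = 3)
  reps <- representative_models(cl)
  sizes <- tabulate(cl$labels)
  expect_equal(cl$labels[reps$refined],
               which.max(sizes))
  expect_equal(length(reps$representatives), 3)
  expect_equal(reps$refined, reps$representatives[1])
})

test_that("novel fold flag uses a strict 0.5 boundary", {
  expect_true(novel_fold_flag(0.42))
  expect_false(novel_fold_flag(0.70))
  expect_false(novel_fold_flag(0.5))
})

test_that("PDB ensemble writing round-trips coordinates", {
  set.seed(27)
  ens <- simulate_structure_ensemble("well", 3, length = 40)
  path <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, path)
  back <- read_pdb_ensemble(path)
  expect_equal(length(back$coords), 3)
  for (m in 1:3) {
    expect_equal(back$coords[[m]], unname(ens$coords[[m]]), tolerance = 1e-3)
  }
})
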