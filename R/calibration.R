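# Random-expectation calibration of spliced-alignment scores.
#
# Random protein/DNA pairs are scored on a grid of protein lengths N; the
# per-length Mean and SD of the null score are then modelled as two-phase
# exponential decays in N:
#
#   S(N) = S0 + SpanFast * exp(-KFast * N) + SpanSlow * exp(-KSlow * N)
#   SpanFast = (S0 - Smin) * PercentFast * 0.01
#   SpanSlow = (S0 - Smin) * (1 - PercentFast * 0.01)
#
# with KFast >= KSlow >= 0 and PercentFast in [0, 100].  A real score is then
# assigned an upper-tail Gaussian p-value under the predicted Mean(N)/SD(N),
# and regions are called "genic" at p <= 1e-6.

DEFAULT_LENGTH_GRID <- c(15, 20, 25, 50, 75, 100, 200, 500, 1000)

decay_value <- function(S0, Smin, PercentFast, KFast, KSlow, N) {
  span_fast <- (S0 - Smin) * PercentFast * 0.01
  span_slow <- (S0 - Smin) * (1 - PercentFast * 0.01)
  S0 + span_fast * exp(-KFast * N) + span_slow * exp(-KSlow * N)
}

#' Fit a two-phase exponential decay to values on a length grid
#'
#' Least-squares fit of
#' `S(N) = S0 + SpanFast*exp(-KFast*N) + SpanSlow*exp(-KSlow*N)` with
#' `SpanFast = (S0-Smin)*PercentFast/100`, `SpanSlow = (S0-Smin)*(1-PercentFast/100)`,
#' under the constraints `KFast >= KSlow >= 0` and `0 <= PercentFast <= 100`.
#' The constraint is enforced by parameterizing `KSlow = KFast * r` with
#' `r in [0, 1]`; because the objective is multimodal the Levenberg-Marquardt
#' solver is restarted from a grid of log-spaced `(KFast, r)` values and the
#' best residual sum of squares is kept.
#'
#' @param x strictly increasing numeric vector of protein lengths (>= 5 points).
#' @param y numeric vector of values (e.g. null-score means) at `x`.
#' @param n_starts number of multi-start initializations (default 8).
#' @return an object of class `decay_fit` with components `S0`, `Smin`,
#'   `PercentFast`, `KFast`, `KSlow`, `rss`, `fitted`, `converged`, `data`.
#' @export
fit_two_phase_decay <- function(x, y, n_starts = 8L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 points to fit a two-phase decay")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")

  mk_fit <- function(S0, Smin, PercentFast, KFast, KSlow, rss, converged) {
    fitted <- decay_value(S0, Smin, PercentFast, KFast, KSlow, x)
    structure(list(S0 = S0, Smin = Smin, PercentFast = PercentFast,
                   KFast = KFast, KSlow = KSlow,
                   SpanFast = (S0 - Smin) * PercentFast * 0.01,
                   SpanSlow = (S0 - Smin) * (1 - PercentFast * 0.01),
                   rss = rss, fitted = fitted, converged = converged,
                   data = list(x = x, y = y)),
              class = "decay_fit")
  }

  if (max(y) - min(y) < 1e-12 * max(1, abs(y[1]))) {
    # flat data: the exact degenerate solution, no spans
    return(mk_fit(y[1], y[1], 50, 0, 0, 0, TRUE))
  }

  # residuals in the (S0, Smin, pf, kf, r) parameterization
  resid_fn <- function(p) {
    ks <- p[4] * p[5]
    decay_value(p[1], p[2], p[3], p[4], ks, x) - y
  }

  y_end <- y[length(y)]
  y_start <- y[1]
  kf_grid <- 10^seq(-3, -0.7, length.out = max(2L, ceiling(n_starts / 2)))
  r_grid <- c(0.05, 0.5)
  starts <- expand.grid(kf = kf_grid, r = r_grid)
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- c(S0 = y_end, Smin = 2 * y_end - y_start, pf = 70,
            kf = starts$kf[s], r = starts$r[s])
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = c(-Inf, -Inf, 0, 0, 0),
                         upper = c(Inf, Inf, 100, Inf, 1),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = ans$par, rss = rss, info = ans$info)
    }
  }
  if (is.null(best)) stop("two-phase decay fit failed from every start")
  p <- best$par
  mk_fit(p[[1]], p[[2]], p[[3]], p[[4]], p[[4]] * p[[5]],
         best$rss, best$info %in% 1:4)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Two-phase decay fit\n")
  cat(sprintf("  S0 = %.4g, Smin = %.4g, PercentFast = %.3g%%\n",
              x$S0, x$Smin, x$PercentFast))
  cat(sprintf("  KFast = %.4g, KSlow = %.4g (per residue), RSS = %.4g\n",
              x$KFast, x$KSlow, x$rss))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(S0 = object$S0, Smin = object$Smin, PercentFast = object$PercentFast,
    KFast = object$KFast, KSlow = object$KSlow)
}

#' Predict a fitted two-phase decay at new lengths
#' @param object a `decay_fit`.
#' @param newdata numeric vector of lengths; defaults to the fitted grid.
#' @param ... unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  N <- if (is.null(newdata)) object$data$x else newdata
  decay_value(object$S0, object$Smin, object$PercentFast,
              object$KFast, object$KSlow, N)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$y - object$fitted
}

#' Build a null-score calibration table across protein lengths
#'
#' For every length in `length_grid`, draws `n_reps` independent random
#' protein/DNA pairs (protein length N, DNA length `3*(N+300)`), scores each
#' with [spliced_align_score()], and records the per-length mean and SD of
#' the null score.  Both summaries are then fitted as two-phase decays in N.
#' Randomness is taken from the session RNG; call `set.seed()` beforehand
#' for reproducibility.
#'
#' @param length_grid strictly increasing protein lengths (default
#'   `c(15, 20, 25, 50, 75, 100, 200, 500, 1000)`).
#' @param n_reps simulations per length (>= 2).
#' @param aa_freqs,gc random-sequence composition, see [random_protein()]
#'   and [random_dna()].
#' @param params alignment scoring parameters, see [align_params()].
#' @return an object of class `score_calibration`: a list with `table`
#'   (data.frame `N`, `mean`, `sd`, `n_reps`), `mean_fit` and `sd_fit`
#'   (`decay_fit` objects), and the generation settings.
#' @export
build_calibration <- function(length_grid = DEFAULT_LENGTH_GRID,
                              n_reps = 1000L,
                              aa_freqs = DMEL_AA_FREQS,
                              gc = DMEL_CODING_GC,
                              params = align_params()) {
  stopifnot(n_reps >= 2)
  if (any(diff(length_grid) <= 0)) stop("length_grid must be strictly increasing")
  aa_freqs <- check_aa_freqs(aa_freqs)
  means <- numeric(length(length_grid))
  sds <- numeric(length(length_grid))
  for (i in seq_along(length_grid)) {
    N <- length_grid[i]
    sc <- vapply(seq_len(n_reps), function(k) {
      spliced_align_score(random_protein(N, aa_freqs),
                          random_dna(N, gc), params)$score
    }, numeric(1))
    means[i] <- mean(sc)
    sds[i] <- sd(sc)
  }
  structure(list(
    table = data.frame(N = length_grid, mean = means, sd = sds,
                       n_reps = n_reps),
    mean_fit = fit_two_phase_decay(length_grid, means),
    sd_fit = fit_two_phase_decay(length_grid, sds),
    aa_freqs = stats::setNames(aa_freqs, AA20), gc = gc,
    params = unclass(params)),
    class = "score_calibration")
}

#' @export
print.score_calibration <- function(x, ...) {
  cat(sprintf("Null-score calibration: %d lengths (%g..%g), %d reps each\n",
              nrow(x$table), min(x$table$N), max(x$table$N), x$table$n_reps[1]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Predict the null-score mean and SD at a protein length
#'
#' Evaluates the fitted mean and SD decay curves at `N`; the SD is floored
#' at a small positive epsilon so downstream p-values are always defined.
#'
#' @param calibration a `score_calibration`.
#' @param N protein length(s), >= 1.
#' @param sd_floor lower bound applied to the predicted SD (default 1e-6).
#' @return list with numeric vectors `mean` and `sd`.
#' @export
predict_mean_sd <- function(calibration, N, sd_floor = 1e-6) {
  stopifnot(inherits(calibration, "score_calibration"), all(N >= 1))
  list(mean = predict(calibration$mean_fit, N),
       sd = pmax(predict(calibration$sd_fit, N), sd_floor))
}

#' Upper-tail Gaussian p-value of a spliced-alignment score
#'
#' The probability of a random (non-homologous) protein/DNA pair of protein
#' length `N` reaching at least `score`, under a one-tailed Gaussian with the
#' calibrated Mean(N) and SD(N).
#'
#' @param score observed spliced-alignment score(s).
#' @param N protein length(s).
#' @param calibration a `score_calibration`.
#' @return p-value(s) in `[0, 1]`.
#' @export
genic_pvalue <- function(score, N, calibration) {
  ms <- predict_mean_sd(calibration, N)
  pnorm(score, mean = ms$mean, sd = ms$sd, lower.tail = FALSE)
}

#' Call a region genic from its null p-value
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param threshold significance cutoff; the comparison is inclusive
#'   (`p <= threshold`), default 1e-6.
#' @return logical vector.
#' @export
is_genic <- function(p, threshold = 1e-6) {
  stopifnot(all(p >= 0 & p <= 1))
  p <= threshold
}

#' Serialize a calibration table (with fit provenance) to JSON
#' @param calibration a `score_calibration`.
#' @param path output file path.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "score_calibration"))
  fit_as_list <- function(f) {
    list(S0 = f$S0, Smin = f$Smin, PercentFast = f$PercentFast,
         KFast = f$KFast, KSlow = f$KSlow, rss = f$rss,
         converged = f$converged, x = f$data$x, y = f$data$y)
  }
  obj <- list(table = calibration$table,
              mean_fit = fit_as_list(calibration$mean_fit),
              sd_fit = fit_as_list(calibration$sd_fit),
              aa_freqs = as.list(calibration$aa_freqs),
              gc = calibration$gc,
              params = calibration$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration table written by [write_calibration()]
#' @param path JSON file path.
#' @return a `score_calibration`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_from_list <- function(f) {
    fitted <- decay_value(f$S0, f$Smin, f$PercentFast, f$KFast, f$KSlow, f$x)
    structure(list(S0 = f$S0, Smin = f$Smin, PercentFast = f$PercentFast,
                   KFast = f$KFast, KSlow = f$KSlow,
                   SpanFast = (f$S0 - f$Smin) * f$PercentFast * 0.01,
                   SpanSlow = (f$S0 - f$Smin) * (1 - f$PercentFast * 0.01),
                   rss = f$rss, fitted = fitted, converged = f$converged,
                   data = list(x = f$x, y = f$y)),
              class = "decay_fit")
  }
  structure(list(table = obj$table,
                 mean_fit = fit_from_list(obj$mean_fit),
                 sd_fit = fit_from_list(obj$sd_fit),
                 aa_freqs = unlist(obj$aa_freqs), gc = obj$gc,
                 params = obj$params),
            class = "score_calibration")
}
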