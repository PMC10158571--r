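# Phase-randomized surrogates of `x`, one column per surrogate. The DFT
# amplitude spectrum (and hence mean and autocorrelation) is preserved
# bin-wise; phases of non-DC (and non-Nyquist, for even length) bins are
# drawn uniformly with Hermitian symmetry so the output is real.
phase_randomize_many <- function(x, n_sim, seed = NULL) {
  n <- length(x)
  if (n < 4) stop("Series must have length >= 4.")
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) seq(2, n / 2) else seq(2, (n + 1) / 2)
  S <- matrix(0 + 0i, n, n_sim)
  S[1, ] <- X[1]
  if (n %% 2 == 0) S[n / 2 + 1, ] <- X[n / 2 + 1]
  ph <- with_seed(seed, matrix(stats::runif(length(half) * n_sim, 0, 2 * pi),
                               length(half), n_sim))
  S[half, ] <- Mod(X[half]) * exp(1i * ph)
  S[n - half + 2, ] <- Conj(S[half, ])
  Re(stats::mvfft(S, inverse = TRUE)) / n
}

#' Phase-randomization surrogate of a time series
#'
#' Constructs a surrogate with the original amplitude spectrum but uniformly
#' random Fourier phases, preserving the autocorrelation structure while
#' destroying any stimulus alignment. The mean (DC bin) is preserved
#' exactly; a constant series is returned unchanged.
#'
#' @param series Numeric series of length >= 4.
#' @param seed Integer seed for reproducibility.
#' @return Surrogate series of the same length.
#' @export
phase_randomize <- function(series, seed = NULL) {
  as.vector(phase_randomize_many(series, 1L, seed = seed))
}

#' Per-subject surrogate null of the leave-one-out ISC
#'
#' Correlates `n_sim` phase-randomized surrogates of one subject's time
#' course with the veridical average of the remaining subjects, Fisher
#' transforms, and fits a Gaussian by moment matching (sample mean and SD).
#' Randomizing only the left-out series nulls that subject's stimulus
#' locking while preserving the reference.
#'
#' @param series The subject's (z-scored) time course.
#' @param others_avg Average time course of the remaining subjects, same
#'   length.
#' @param n_sim Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @return Object of class `surrogate_null`: `mu`, `sigma` (Fisher-z scale),
#'   `n_sim`.
#' @export
subject_null <- function(series, others_avg, n_sim = 1000, seed = NULL) {
  if (length(series) != length(others_avg)) stop("Series lengths differ.")
  if (stats::sd(series) == 0 || stats::sd(others_avg) == 0) {
    stop("Zero-variance input; the null is undefined.")
  }
  surr <- phase_randomize_many(series, n_sim, seed = seed)
  z <- fisher_z(drop(stats::cor(surr, others_avg)))
  structure(list(mu = mean(z), sigma = stats::sd(z), n_sim = n_sim),
            class = "surrogate_null")
}

#' Combine per-subject surrogate nulls into a group null
#'
#' Analytic combination under independence: the null of the group-averaged
#' Fisher-z ISC has mean `mean(mu_i)` and SD `sqrt(sum(sigma_i^2)) / N`.
#' Leave-one-out ISCs of different subjects are in fact positively
#' correlated (they share data), so this combination is anti-conservative;
#' the package's calibration tests measure by how much.
#'
#' @param nulls Non-empty list of `surrogate_null` objects.
#' @return Object of class `group_null`: `mu`, `sigma`, `n_subjects`.
#' @export
combine_null <- function(nulls) {
  if (length(nulls) == 0) stop("Need at least one subject null.")
  mu <- vapply(nulls, `[[`, 0, "mu")
  sg <- vapply(nulls, `[[`, 0, "sigma")
  structure(list(mu = mean(mu), sigma = sqrt(sum(sg^2)) / length(nulls),
                 n_subjects = length(nulls)),
            class = "group_null")
}

#' One-tailed p value of a group-averaged ISC
#'
#' Upper-tail normal p value of the observed group mean Fisher-z ISC under
#' the combined surrogate null: `p = 1 - pnorm((zbar - mu) / sigma)`.
#'
#' @param group_mean_z Observed group-averaged Fisher-z ISC.
#' @param null A `group_null` with `sigma > 0`.
#' @return One-tailed p value.
#' @export
isc_pvalue <- function(group_mean_z, null) {
  if (null$sigma <= 0) stop("Group null sigma must be > 0.")
  1 - stats::pnorm((group_mean_z - null$mu) / null$sigma)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: rejects all hypotheses with adjusted p value at or
#' below `q`. Adjusted p values are monotone non-decreasing in the raw p
#' values.
#'
#' @param pvals P values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical) and `adjusted` p values.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("P values must lie in [0, 1].")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(reject = !is.na(adjusted) & adjusted <= q, adjusted = adjusted)
}

#' Group ISC significance test for one fROI and condition
#'
#' Computes leave-one-out ISCs from a subject x frame matrix, averages the
#' Fisher-z values, builds each subject's phase-randomization null against
#' the veridical leave-one-out average, combines the Gaussian parameters
#' across subjects, and converts the observed group mean to a one-tailed p
#' value. Per-subject surrogate seeds are derived deterministically from
#' `seed`.
#'
#' @param series Subject x frame matrix of z-scored time courses.
#' @param n_sim Surrogates per subject (default 1000).
#' @param seed Master integer seed.
#' @return List: `r` (per-subject ISC), `group_mean_z`, `null`
#'   (`group_null`), `z_score`, `p`.
#' @export
group_isc_test <- function(series, n_sim = 1000, seed = 1) {
  series <- as.matrix(series)
  N <- nrow(series)
  r <- loo_isc(series)
  zbar <- mean(fisher_z(r), na.rm = TRUE)
  tot <- colSums(series)
  nulls <- lapply(seq_len(N), function(i) {
    subject_null(series[i, ], (tot - series[i, ]) / (N - 1), n_sim = n_sim,
                 seed = derive_seed(seed, "subject_null", i))
  })
  gn <- combine_null(nulls)
  list(r = r, group_mean_z = zbar, null = gn,
       z_score = (zbar - gn$mu) / gn$sigma, p = isc_pvalue(zbar, gn))
}
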