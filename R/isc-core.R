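#' Extract a condition time course from a cleaned run
#'
#' Averages the fROI's voxels frame-by-frame over the stimulus window,
#' dropping the first `trim` seconds after stimulus onset (to exclude the
#' initial hemodynamic rise relative to fixation, which would inflate ISC),
#' then z-scores the result.
#'
#' @param run Voxel x time matrix or a `clean_run`.
#' @param voxels Row indices of the fROI (non-empty).
#' @param tr Repetition time, seconds (taken from a `clean_run` if given).
#' @param window Frame pair `(onset, offset)` of the stimulus within the run;
#'   default is the whole run. Trailing fixation should be excluded via
#'   `offset`.
#' @param trim Seconds discarded after stimulus onset (default 6, i.e., 3
#'   frames at TR = 2 s).
#' @param condition Optional label used in error messages.
#' @return Z-scored numeric series (sample mean 0, sample SD 1), with
#'   attribute `n_frames`.
#' @export
extract_condition_timecourse <- function(run, voxels, tr = NULL,
                                         window = NULL, trim = 6,
                                         condition = NULL) {
  if (inherits(run, "clean_run")) {
    if (is.null(tr)) tr <- run$tr
    run <- run$data
  }
  if (is.null(tr)) stop("`tr` is required.")
  if (length(voxels) == 0) stop("Empty fROI.")
  n <- ncol(run)
  if (is.null(window)) window <- c(1L, n)
  start <- window[1] + ceiling(trim / tr)
  if (window[2] > n) stop("Stimulus window exceeds the run.")
  frames <- seq(start, window[2])
  if (length(frames) < 10) {
    stop("Trimmed window has ", length(frames), " frames (< 10)",
         if (!is.null(condition)) paste0(" for condition ", condition), ".")
  }
  m <- colMeans(run[voxels, frames, drop = FALSE])
  z <- (m - mean(m)) / stats::sd(m)
  attr(z, "n_frames") <- length(frames)
  z
}

#' Leave-one-out inter-subject correlations
#'
#' For each subject, the Pearson correlation between that subject's z-scored
#' time course and the average of all *other* subjects' z-scored time
#' courses (not the grand average). The averaged reference is not
#' re-standardized; Pearson correlation is unaffected by that choice.
#'
#' @param series Subject x frame matrix of (z-scored) time courses, >= 2
#'   rows of equal length.
#' @return Numeric vector of per-subject correlations. A zero-variance row
#'   or leave-one-out average yields `NA` for that subject, with a warning.
#' @export
loo_isc <- function(series) {
  series <- as.matrix(series)
  N <- nrow(series)
  if (N < 2) stop("Need at least 2 subjects.")
  tot <- colSums(series)
  r <- vapply(seq_len(N), function(i) {
    ref <- (tot - series[i, ]) / (N - 1)
    s1 <- stats::sd(series[i, ])
    s2 <- stats::sd(ref)
    if (is.na(s1) || is.na(s2) || s1 == 0 || s2 == 0) return(NA_real_)
    stats::cor(series[i, ], ref)
  }, 0)
  if (anyNA(r)) {
    warning("ISC undefined (zero variance) for subject(s): ",
            paste(which(is.na(r)), collapse = ", "))
  }
  names(r) <- rownames(series)
  r
}

#' Fisher z transform of a correlation
#'
#' `atanh` after clipping `|r|` at `1 - 1e-7`, so boundary correlations map
#' to a large finite value (~8.4) instead of infinity. Strictly increasing.
#'
#' @param r Correlation(s) in `[-1, 1]` (a small float tolerance beyond 1 is
#'   clipped; anything further is an error).
#' @return Fisher-transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("Correlations must lie in [-1, 1].")
  }
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}
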