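#' Temporal principal components of a noise compartment
#'
#' Extracts the top-k temporal principal components of a compartment's
#' voxel x time matrix after per-voxel mean removal (no variance
#' normalization), together with the across-voxel average series. Components
#' are orthonormal over frames. If `k` exceeds the matrix rank, the available
#' components are returned with a warning.
#'
#' @param run Voxel x time matrix.
#' @param mask Voxel indices of the compartment (non-empty).
#' @param k Number of components (default 5).
#' @return List with `pcs` (frame x k matrix), `mean` (length-T average
#'   series) and `values` (component variances).
#' @export
extract_noise_pcs <- function(run, mask, k = 5) {
  if (length(mask) == 0) stop("Compartment mask is empty.")
  X <- run[mask, , drop = FALSE]
  n_frames <- ncol(X)
  if (k > min(length(mask), n_frames)) {
    stop("k must be <= min(#voxels, #frames).")
  }
  Xc <- X - rowMeans(X)
  S <- crossprod(Xc) / nrow(Xc)          # frame x frame covariance
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  rank <- sum(e$values > tol)
  k_eff <- min(k, rank)
  if (k_eff < k) {
    warning("Compartment has rank ", rank, " < k = ", k,
            "; returning ", k_eff, " components.")
  }
  list(pcs = e$vectors[, seq_len(k_eff), drop = FALSE],
       mean = colMeans(X),
       values = e$values[seq_len(k_eff)])
}

#' Framewise displacement from motion parameters
#'
#' Scan-to-scan head displacement: the sum of absolute first differences of
#' the three translations (mm) plus the three rotations (radians) converted
#' to arc length on a sphere of radius `radius` mm. The first frame has
#' displacement 0.
#'
#' @param motion Frame x 6 matrix (trans_x..z in mm, rot_x..z in radians).
#' @param radius Head radius in mm used to convert rotations (default 50).
#' @return Numeric vector of per-frame displacements.
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  d <- abs(rbind(0, diff(motion)))
  rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Flag outlier frames from global signal and motion
#'
#' A frame is flagged iff the z-scored scan-to-scan difference of the global
#' BOLD signal exceeds `z_thresh` in absolute value, or the framewise
#' displacement exceeds `motion_thresh`. Defaults follow the standard
#' artifact-detection thresholds of 5 SD and 0.9 mm. The first frame is never
#' flagged by either delta criterion.
#'
#' @param global_signal Length-T global (gray-matter mean) BOLD series.
#' @param motion Frame x 6 motion parameter matrix.
#' @param z_thresh Threshold on the z-scored global-signal difference (SD).
#' @param motion_thresh Threshold on framewise displacement (mm).
#' @return Logical vector, TRUE for flagged frames.
#' @export
detect_outlier_frames <- function(global_signal, motion,
                                  z_thresh = 5, motion_thresh = 0.9) {
  if (length(global_signal) != nrow(as.matrix(motion))) {
    stop("Global signal and motion table must share the frame count.")
  }
  d <- diff(global_signal)
  s <- stats::sd(d)
  zflag <- if (is.na(s) || s == 0) rep(FALSE, length(d)) else abs((d - mean(d)) / s) > z_thresh
  fd <- framewise_displacement(motion)
  c(FALSE, zflag) | fd > motion_thresh
}

#' Assemble a nuisance regressor set for one run
#'
#' Builds the standard temporal-denoising regressors: six motion parameters
#' and their first temporal derivatives (first frame 0), `k` temporal
#' principal components plus the mean series of each noise compartment
#' (white matter and CSF), and a 0/1 spike regressor per detected outlier
#' frame.
#'
#' @param run Voxel x time matrix.
#' @param geometry Geometry as from [make_geometry()] (supplies tissue masks).
#' @param motion Frame x 6 motion parameter matrix.
#' @param k Temporal PCs per compartment (default 5).
#' @param z_thresh,motion_thresh Outlier thresholds, see
#'   [detect_outlier_frames()].
#' @return Object of class `nuisance_set`: `motion` (frame x 12),
#'   `compartments` (named list with `pcs` and `mean` per compartment),
#'   `outliers` (logical per frame).
#' @export
build_nuisance <- function(run, geometry, motion, k = 5,
                           z_thresh = 5, motion_thresh = 0.9) {
  gm <- which(geometry$tissue == "gm")
  comps <- list()
  for (cp in c("wm", "csf")) {
    idx <- which(geometry$tissue == cp)
    if (length(idx)) comps[[cp]] <- run[idx, , drop = FALSE]
  }
  nuisance_from_parts(motion, comps, colMeans(run[gm, , drop = FALSE]),
                      k = k, z_thresh = z_thresh, motion_thresh = motion_thresh)
}

# Assemble a nuisance_set from precomputed parts: a motion table, a named
# list of compartment voxel x time matrices, and the global (GM mean) series.
nuisance_from_parts <- function(motion, compartments, global_signal, k = 5,
                                z_thresh = 5, motion_thresh = 0.9) {
  motion <- as.matrix(motion)
  dmot <- rbind(0, diff(motion))
  colnames(dmot) <- paste0(colnames(motion), "_deriv")
  comps <- lapply(compartments, function(m) {
    extract_noise_pcs(m, seq_len(nrow(m)), k = min(k, nrow(m)))
  })
  structure(
    list(motion = cbind(motion, dmot), compartments = comps,
         outliers = detect_outlier_frames(global_signal, motion,
                                          z_thresh, motion_thresh)),
    class = "nuisance_set"
  )
}

#' Expand a nuisance set into a design matrix
#'
#' Intercept, 12 motion columns, per-compartment PCs and mean series, and one
#' spike column per flagged frame.
#'
#' @param nuisance A `nuisance_set` (or a plain numeric matrix of regressors,
#'   returned with an intercept prepended).
#' @param n_frames Number of frames (required when `nuisance` is a matrix
#'   without rows to check against).
#' @return Frame x p design matrix with named columns.
#' @export
nuisance_design <- function(nuisance, n_frames = NULL) {
  if (is.matrix(nuisance) || is.numeric(nuisance)) {
    X <- cbind(intercept = 1, as.matrix(nuisance))
    return(X)
  }
  stopifnot(inherits(nuisance, "nuisance_set"))
  Tn <- nrow(nuisance$motion)
  X <- cbind(intercept = rep(1, Tn), nuisance$motion)
  for (cp in names(nuisance$compartments)) {
    comp <- nuisance$compartments[[cp]]
    pcs <- comp$pcs
    colnames(pcs) <- paste0(cp, "_pc", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
    X <- cbind(X, stats::setNames(data.frame(comp$mean), paste0(cp, "_mean"))[[1]])
    colnames(X)[ncol(X)] <- paste0(cp, "_mean")
  }
  for (fr in which(nuisance$outliers)) {
    spike <- numeric(Tn)
    spike[fr] <- 1
    X <- cbind(X, spike)
    colnames(X)[ncol(X)] <- paste0("spike_", fr)
  }
  X
}

#' Regress nuisance signals out of a run
#'
#' Least-squares projection of every voxel's time course onto the orthogonal
#' complement of the nuisance design (intercept + nuisance columns + spike
#' columns). Rank-deficient designs are handled by dropping dependent
#' columns, with a warning naming them. Residuals are exactly orthogonal to
#' every retained regressor, and the operation is idempotent.
#'
#' @param run Voxel x time matrix (or a single series).
#' @param nuisance A `nuisance_set` or a frame x p regressor matrix
#'   (an intercept is added in either case).
#' @return Residual matrix (or vector) with the input's shape.
#' @export
regress_nuisance <- function(run, nuisance) {
  vec <- is.null(dim(run))
  Y <- if (vec) matrix(run, nrow = 1) else run
  X <- nuisance_design(nuisance, ncol(Y))
  if (nrow(X) != ncol(Y)) stop("Design and run frame counts differ.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("Dropping collinear nuisance columns: ",
            paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qrX, t(Y)))
  if (vec) as.vector(res) else res
}

# Zero-phase forward-backward IIR pass with odd (antisymmetric) reflection
# padding to suppress edge transients at very low cutoff frequencies.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 3 * max(length(a), length(b)) * 8)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Band-pass filter a run
#'
#' Zero-phase band-pass filtering of each voxel's (or region's) time course;
#' the default band 0.008--0.09 Hz preserves only low-frequency fluctuations.
#' Two realizations meeting the same pass/stop contract are available: a
#' forward-backward 2nd-order Butterworth (default) and an exact DFT mask.
#' Input series are demeaned first, so a constant series maps to zero.
#'
#' @param run Voxel x time matrix or a single series.
#' @param tr Sampling interval, seconds.
#' @param band Hz pair inside (0, Nyquist); default `c(0.008, 0.09)`.
#' @param method `"butterworth"` or `"fft"`.
#' @return Filtered matrix/series with the input's shape.
#' @export
bandpass <- function(run, tr, band = c(0.008, 0.09),
                     method = c("butterworth", "fft")) {
  method <- match.arg(method)
  check_passband(band, tr)
  vec <- is.null(dim(run))
  Y <- if (vec) matrix(run, nrow = 1) else run
  Y <- Y - rowMeans(Y)
  n <- ncol(Y)
  if (method == "fft") {
    f <- dft_frequencies(n, tr)
    keep <- f >= band[1] & f <= band[2]
    G <- t(stats::mvfft(t(Y)))
    G[, !keep] <- 0 + 0i
    out <- Re(t(stats::mvfft(t(G), inverse = TRUE))) / n
  } else {
    nyq <- 1 / (2 * tr)
    bf <- signal::butter(2, band / nyq, type = "pass")
    out <- t(apply(Y, 1, function(x) zero_phase_filter(bf$b, bf$a, x)))
  }
  if (vec) as.vector(out) else out
}

#' Temporal preprocessing of one run
#'
#' Full temporal-denoising chain for a naturalistic run: nuisance regression
#' (motion + derivatives, compartment PCs and means, outlier spike
#' regressors) followed by band-pass filtering. Flagged frames are regressed
#' out via spike regressors rather than deleted, preserving the time-axis
#' alignment across subjects that ISC requires.
#'
#' @param run Voxel x time matrix.
#' @param geometry Geometry with tissue masks.
#' @param motion Frame x 6 motion table.
#' @param tr Repetition time, seconds.
#' @param k Temporal PCs per noise compartment.
#' @param filter Apply the band-pass step? (`TRUE` by default; conclusions
#'   should not depend on it.)
#' @param band,method Passed to [bandpass()].
#' @return Object of class `clean_run`: `data` (voxel x time residuals),
#'   `tr`, and `provenance` (filter settings, regressor count, outliers).
#' @export
clean_run <- function(run, geometry, motion, tr, k = 5, filter = TRUE,
                      band = c(0.008, 0.09),
                      method = c("butterworth", "fft")) {
  method <- match.arg(method)
  ns <- build_nuisance(run, geometry, motion, k = k)
  X <- nuisance_design(ns)
  res <- regress_nuisance(run, ns)
  if (filter) res <- bandpass(res, tr, band, method)
  structure(
    list(data = res, tr = tr,
         provenance = list(band = if (filter) band else NULL, method = method,
                           n_regressors = ncol(X),
                           outlier_frames = which(ns$outliers))),
    class = "clean_run"
  )
}
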