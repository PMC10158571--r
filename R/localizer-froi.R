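#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking ~5--6 s after
#' stimulus onset minus a later gamma density (undershoot ~15--16 s) scaled
#' by `1/ratio`. Values are returned unnormalized; [build_design_matrix()]
#' normalizes the sampled kernel to unit sum.
#'
#' @param t Time in seconds (vector).
#' @param peak Shape of the response gamma (default 6; mode at `peak - 1` s).
#' @param undershoot Shape of the undershoot gamma (default 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
}

#' Build a localizer GLM design matrix
#'
#' One HRF-convolved boxcar column per condition (blocks modeled as entire
#' blocks), plus its first-order temporal derivative, an intercept, and
#' discrete-cosine drift columns equivalent to high-pass filtering at
#' `hp_cutoff` seconds. Boxcars are built on an oversampled grid, convolved
#' with the unit-sum canonical HRF, and sampled at frame acquisition times.
#'
#' @param design Data frame with columns `onset`, `duration` (seconds),
#'   `condition`. Blocks must be non-overlapping and fit within the run.
#' @param n_frames Run length in frames.
#' @param tr Repetition time, seconds.
#' @param conditions Conditions to model (default: those present in
#'   `design`); a requested condition with no blocks is an error.
#' @param hp_cutoff High-pass cutoff in seconds for the drift basis
#'   (default 200).
#' @param oversample Oversampling factor for boxcar construction.
#' @return Frame x regressor matrix; attribute `condition_cols` names the
#'   condition effect columns.
#' @export
build_design_matrix <- function(design, n_frames, tr,
                                conditions = unique(design$condition),
                                hp_cutoff = 200, oversample = 16) {
  stopifnot(all(c("onset", "duration", "condition") %in% names(design)))
  run_len <- n_frames * tr
  if (any(design$onset < 0) || any(design$onset + design$duration > run_len)) {
    stop("Blocks must fit within the run (", run_len, " s).")
  }
  missing <- setdiff(conditions, design$condition)
  if (length(missing)) {
    stop("Condition(s) with no blocks: ", paste(missing, collapse = ", "))
  }
  dt <- tr / oversample
  n_fine <- n_frames * oversample
  occupancy <- numeric(n_fine)
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  hrf <- hrf / sum(hrf)
  frame_at <- (seq_len(n_frames) - 1) * oversample + 1

  cols <- list()
  for (cn in conditions) {
    box <- numeric(n_fine)
    blocks <- design[design$condition == cn, , drop = FALSE]
    for (b in seq_len(nrow(blocks))) {
      i0 <- floor(blocks$onset[b] / dt) + 1
      i1 <- min(n_fine, ceiling((blocks$onset[b] + blocks$duration[b]) / dt))
      box[i0:i1] <- box[i0:i1] + 1
    }
    occupancy <- occupancy + box
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)]
    reg <- conv[frame_at]
    cols[[cn]] <- reg
    cols[[paste0(cn, "_deriv")]] <- c(0, diff(reg)) / tr
  }
  if (any(occupancy > 1)) stop("Overlapping blocks in the design.")

  X <- do.call(cbind, cols)
  X <- cbind(X, intercept = rep(1, n_frames))
  n_drift <- floor(2 * n_frames * tr / hp_cutoff)
  if (n_drift > 0) {
    tgrid <- seq_len(n_frames) - 0.5
    drift <- sapply(seq_len(n_drift), function(k) {
      cos(pi * k * tgrid / n_frames)
    })
    colnames(drift) <- paste0("drift", seq_len(n_drift))
    X <- cbind(X, drift)
  }
  attr(X, "condition_cols") <- conditions
  X
}

#' Fit a voxelwise GLM and form a contrast map
#'
#' Ordinary least squares per voxel; the contrast effect is the weighted sum
#' of condition betas and `t = effect / se(effect)` with the design's
#' residual degrees of freedom.
#'
#' @param run Voxel x time matrix.
#' @param X Design matrix from [build_design_matrix()] (full rank).
#' @param contrast Named weights over condition columns, e.g.
#'   `c(A = 1, B = -1)`; difference contrasts should sum to zero.
#' @param subject Optional subject identifier carried in the result.
#' @return Object of class `contrast_map`: `effect` and `t` (per voxel),
#'   `df`, `contrast`, `subject`.
#' @export
fit_glm_contrast <- function(run, X, contrast, subject = NULL) {
  if (ncol(run) < ncol(X)) stop("Fewer frames than regressors.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("Design matrix is rank deficient.")
  B <- qr.coef(qrX, t(run))            # p x V
  res <- t(run) - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  if (!all(names(contrast) %in% colnames(X))) {
    stop("Contrast names must match design columns.")
  }
  cvec[names(contrast)] <- contrast
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  effect <- drop(crossprod(B, cvec))
  se <- sqrt(cvar * sigma2)
  structure(
    list(effect = effect, t = effect / se, df = df,
         contrast = contrast, subject = subject),
    class = "contrast_map"
  )
}

#' Average contrast maps across runs
#'
#' Fixed-effects combination for multi-run localizers: effects are averaged,
#' and t statistics combined by the Stouffer rule with summed degrees of
#' freedom.
#'
#' @param maps List of `contrast_map` objects on the same voxel grid.
#' @return A single `contrast_map`.
#' @export
average_contrast_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (length(maps) == 1) return(maps[[1]])
  eff <- Reduce(`+`, lapply(maps, `[[`, "effect")) / length(maps)
  tt <- Reduce(`+`, lapply(maps, `[[`, "t")) / sqrt(length(maps))
  structure(
    list(effect = eff, t = tt, df = sum(vapply(maps, `[[`, 0, "df")),
         contrast = maps[[1]]$contrast, subject = maps[[1]]$subject),
    class = "contrast_map"
  )
}

#' Define a subject-specific functional ROI inside a parcel
#'
#' Selects the top fraction of gray-matter parcel voxels by contrast effect
#' (default top 10%), so that fROIs exist in every participant and have the
#' same size across participants for a given parcel. The voxel count is
#' `ceiling(fraction * |parcel GM voxels|)`, at least 1; ties at the
#' selection boundary break by ascending voxel index for determinism.
#'
#' @param cmap A `contrast_map`.
#' @param parcel Voxel indices of the parcel.
#' @param fraction Proportion of voxels to keep (default 0.10).
#' @param gm Optional gray-matter voxel indices; the parcel is intersected
#'   with it.
#' @param parcel_name,network Labels carried in the result.
#' @return Object of class `froi`: `subject`, `parcel`, `network`, `voxels`
#'   (ascending indices).
#' @export
define_froi <- function(cmap, parcel, fraction = 0.10, gm = NULL,
                        parcel_name = NA_character_, network = NA_character_) {
  vox <- if (is.null(gm)) parcel else intersect(parcel, gm)
  if (length(vox) == 0) stop("Empty parcel (after GM restriction).")
  n <- max(1L, ceiling(fraction * length(vox)))
  ord <- vox[order(-cmap$effect[vox], vox)]
  structure(
    list(subject = cmap$subject, parcel = parcel_name, network = network,
         voxels = sort(ord[seq_len(n)])),
    class = "froi"
  )
}

#' Localizer quality control for one subject
#'
#' Counts voxels exceeding the uncorrected one-sided significance threshold
#' (positive contrast tail) within the union of a network's masks; the
#' subject fails if the count is below `min_voxels`. Defaults implement the
#' "fewer than 100 suprathreshold voxels at p < 0.001" exclusion rule, so a
#' count of 99 fails and 100 passes.
#'
#' @param cmap A `contrast_map` with t values and residual df.
#' @param masks List of voxel-index vectors (the network's parcels).
#' @param p_thresh Uncorrected one-sided p threshold (default 0.001),
#'   converted to a t threshold via the map's residual df.
#' @param min_voxels Minimum suprathreshold count to pass (default 100).
#' @return List with `pass`, `count` and the `t_threshold` used.
#' @export
qc_subject <- function(cmap, masks, p_thresh = 0.001, min_voxels = 100) {
  vox <- sort(unique(unlist(masks)))
  thr <- stats::qt(1 - p_thresh, df = cmap$df)
  count <- sum(cmap$t[vox] > thr)
  list(pass = count >= min_voxels, count = count, t_threshold = thr)
}

#' Remove cross-network fROI overlap
#'
#' Within each subject, any voxel assigned to fROIs of two or more networks
#' is removed from all of them. Returns the cleaned fROIs plus a per-pair
#' overlap report (counts and percentages relative to each fROI's size).
#'
#' @param frois List of `froi` objects (any mix of subjects/networks).
#' @return List with `frois` (same order, shrunk) and `report` (data frame:
#'   subject, froi_a, froi_b, n_overlap, pct_a, pct_b).
#' @export
exclude_overlap <- function(frois) {
  subj <- vapply(frois, function(f) as.character(f$subject %||% NA), "")
  report <- list()
  out <- frois
  for (s in unique(subj)) {
    idx <- which(subj == s)
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      if (identical(frois[[a]]$network, frois[[b]]$network)) next
      ov <- intersect(frois[[a]]$voxels, frois[[b]]$voxels)
      if (length(ov)) {
        report[[length(report) + 1]] <- data.frame(
          subject = s,
          froi_a = frois[[a]]$parcel, froi_b = frois[[b]]$parcel,
          n_overlap = length(ov),
          pct_a = 100 * length(ov) / length(frois[[a]]$voxels),
          pct_b = 100 * length(ov) / length(frois[[b]]$voxels),
          stringsAsFactors = FALSE
        )
      }
    }
    # voxels claimed by >= 2 networks within this subject
    nets <- lapply(idx, function(i) {
      data.frame(vox = frois[[i]]$voxels, net = frois[[i]]$network,
                 stringsAsFactors = FALSE)
    })
    nets <- unique(do.call(rbind, nets))
    shared <- as.integer(names(which(tapply(nets$net, nets$vox,
                                            function(x) length(unique(x))) >= 2)))
    if (length(shared)) {
      for (i in idx) out[[i]]$voxels <- setdiff(out[[i]]$voxels, shared)
    }
  }
  list(
    frois = out,
    report = if (length(report)) do.call(rbind, report) else
      data.frame(subject = character(), froi_a = character(),
                 froi_b = character(), n_overlap = integer(),
                 pct_a = numeric(), pct_b = numeric())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
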