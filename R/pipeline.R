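#' Run the full ISC pipeline on a simulated study
#'
#' Generates (streaming, subject by subject) the configured naturalistic
#' runs, applies temporal preprocessing (nuisance regression and band-pass
#' filtering), extracts trimmed z-scored region time courses, and computes
#' leave-one-out ISCs per region and condition.
#'
#' Regions default to the anatomical parcels (the generator plants network
#' coupling uniformly within a parcel, so parcels act as fROIs; the
#' localizer-based [define_froi()] path is exercised separately). Because
#' nuisance regression and filtering are linear operations sharing one
#' within-subject design across voxels, they commute exactly with voxel
#' averaging; the pipeline therefore preprocesses region-mean series
#' (`level = "roi"`) by default, with a voxelwise path available.
#'
#' @param config An `isc_sim_config`.
#' @param conditions Condition names to analyze (default all configured).
#' @param preprocess Apply nuisance regression (and filtering)?
#' @param filter Apply the band-pass step (ignored if `preprocess = FALSE`)?
#' @param filter_method `"butterworth"` or `"fft"`.
#' @param trim Seconds trimmed after stimulus onset (default 6).
#' @param k_pcs Temporal PCs per noise compartment (default 5).
#' @param level `"roi"` (preprocess region means) or `"voxel"`.
#' @param marginalize_voxels Use the region-resolution generator, which
#'   draws each parcel's voxel-noise *mean* (SD `sigma_voxel / sqrt(V)`)
#'   instead of `V` voxel series -- distributionally identical for the
#'   region-level pipeline and much faster for replicate studies. Requires
#'   `level = "roi"`.
#' @return Object of class `isc_result`: `table` (long format: participant,
#'   network, froi, condition, condition_type, n_frames, r, z),
#'   `timecourses` (per condition, per region: subject x frame matrix),
#'   `config`, `geometry`.
#' @export
run_isc_pipeline <- function(config, conditions = NULL, preprocess = TRUE,
                             filter = TRUE,
                             filter_method = c("butterworth", "fft"),
                             trim = 6, k_pcs = 5,
                             level = c("roi", "voxel"),
                             marginalize_voxels = FALSE) {
  filter_method <- match.arg(filter_method)
  level <- match.arg(level)
  if (marginalize_voxels && level != "roi") {
    stop("`marginalize_voxels` requires level = \"roi\".")
  }
  if (is.null(conditions)) conditions <- config$conditions$name
  geometry <- make_geometry(config)
  parcels <- geometry$parcels
  pvox <- geometry$parcel_voxels
  N <- config$n_subjects
  Tn <- config$n_timepoints
  n_keep <- Tn - ceiling(trim / config$tr)

  tcs <- list()
  rows <- list()
  for (cond in conditions) {
    if (!cond %in% config$conditions$name) stop("Unknown condition: ", cond)
    ctype <- config$conditions$type[match(cond, config$conditions$name)]
    shared <- make_shared_signal(Tn, config$tr, config$passband,
                                 seed = derive_seed(config$seed, "shared", cond))
    Z <- lapply(pvox, function(v) matrix(NA_real_, N, n_keep))
    for (i in seq_len(N)) {
      sub <- if (marginalize_voxels) {
        simulate_subject_run_roi(config, geometry, shared, cond, i)
      } else {
        simulate_subject_run(config, geometry, shared, cond, i)
      }
      if (level == "roi") {
        roi_mat <- if (marginalize_voxels) {
          sub$roi
        } else {
          t(vapply(pvox, function(v) colMeans(sub$bold[v, , drop = FALSE]),
                   numeric(Tn)))
        }
        if (preprocess) {
          ns <- if (marginalize_voxels) {
            nuisance_from_parts(sub$motion, sub$compartments, sub$global,
                                k = k_pcs)
          } else {
            build_nuisance(sub$bold, geometry, sub$motion, k = k_pcs)
          }
          roi_mat <- regress_nuisance(roi_mat, ns)
          if (filter) roi_mat <- bandpass(roi_mat, config$tr,
                                          config$passband, filter_method)
        }
        for (p in seq_along(pvox)) {
          Z[[p]][i, ] <- extract_condition_timecourse(
            roi_mat, p, tr = config$tr, trim = trim, condition = cond)
        }
      } else {
        dat <- if (preprocess) {
          clean_run(sub$bold, geometry, sub$motion, config$tr, k = k_pcs,
                    filter = filter, band = config$passband,
                    method = filter_method)$data
        } else {
          sub$bold
        }
        for (p in seq_along(pvox)) {
          Z[[p]][i, ] <- extract_condition_timecourse(
            dat, pvox[[p]], tr = config$tr, trim = trim, condition = cond)
        }
      }
    }
    tcs[[cond]] <- Z
    for (p in seq_along(pvox)) {
      r <- loo_isc(Z[[p]])
      rows[[length(rows) + 1]] <- data.frame(
        participant = paste0("sub", seq_len(N)),
        network = parcels$network[p],
        froi = parcels$parcel[p],
        condition = cond,
        condition_type = ctype,
        n_frames = n_keep,
        r = r,
        z = fisher_z(r),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         timecourses = tcs, config = config, geometry = geometry),
    class = "isc_result"
  )
}

#' Add condition-type flag columns to an ISC table
#'
#' Derives two-level factors from the `+Lang`/`+ToM` condition-type labels:
#' `linguistic` (linguistic vs non-linguistic) and `mental` (mental vs
#' non-mental state content). Rest rows get `NA`.
#'
#' @param table Long ISC table with a `condition_type` column.
#' @return The table with `linguistic` and `mental` columns added.
#' @export
add_condition_flags <- function(table) {
  ty <- table$condition_type
  table$linguistic <- ifelse(ty == "rest", NA,
                             ifelse(grepl("+Lang", ty, fixed = TRUE),
                                    "linguistic", "non-linguistic"))
  table$mental <- ifelse(ty == "rest", NA,
                         ifelse(grepl("+ToM", ty, fixed = TRUE),
                                "mental", "non-mental"))
  table
}

#' Group-level surrogate-null inference over an ISC result
#'
#' Runs [group_isc_test()] for every (region, condition) -- or, with
#' `by = "network"`, for every (network, condition) after averaging each
#' subject's z-scored region series within network and re-standardizing --
#' and applies Benjamini-Hochberg FDR across the whole family.
#'
#' @param result An `isc_result` from [run_isc_pipeline()].
#' @param by `"froi"` or `"network"`.
#' @param n_sim Surrogates per subject (default 1000).
#' @param seed Master integer seed for surrogate generation.
#' @param q FDR level (default 0.05).
#' @return Data frame: unit, condition, group_mean_z, null_mu, null_sigma,
#'   z_score, p, p_fdr, reject.
#' @export
isc_group_inference <- function(result, by = c("froi", "network"),
                                n_sim = 1000, seed = 1, q = 0.05) {
  by <- match.arg(by)
  parcels <- result$geometry$parcels
  rows <- list()
  for (cond in names(result$timecourses)) {
    Zs <- result$timecourses[[cond]]
    units <- if (by == "froi") {
      stats::setNames(as.list(seq_along(Zs)), parcels$parcel)
    } else {
      lapply(split(seq_along(Zs), parcels$network), identity)
    }
    for (un in names(units)) {
      idx <- units[[un]]
      Z <- if (length(idx) == 1) {
        Zs[[idx[1]]]
      } else {
        avg <- Reduce(`+`, Zs[idx]) / length(idx)
        t(apply(avg, 1, function(x) (x - mean(x)) / stats::sd(x)))
      }
      gt <- group_isc_test(Z, n_sim = n_sim,
                           seed = derive_seed(seed, "null", cond, un))
      rows[[length(rows) + 1]] <- data.frame(
        unit = un, condition = cond, group_mean_z = gt$group_mean_z,
        null_mu = gt$null$mu, null_sigma = gt$null$sigma,
        z_score = gt$z_score, p = gt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$p_fdr <- fdr$adjusted
  out$reject <- fdr$reject
  rownames(out) <- NULL
  out
}
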