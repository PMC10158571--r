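#' Default naturalistic condition set
#'
#' Seven naturalistic conditions spanning three condition types (three
#' linguistic narratives with mental state content, three non-linguistic
#' films/animations with mental state content, one expository text without
#' mental state content) plus a resting-state control. Types are labelled by
#' the presence of linguistic (`+Lang`/`-Lang`) and mental state
#' (`+ToM`/`-ToM`) content.
#'
#' @return A data frame with columns `name` and `type`.
#' @export
default_conditions <- function() {
  data.frame(
    name = c("story", "audio_play", "dialogue",
             "animated_film", "live_action_film", "shapes_animation",
             "expository_text", "rest"),
    type = c("+Lang+ToM", "+Lang+ToM", "+Lang+ToM",
             "-Lang+ToM", "-Lang+ToM", "-Lang+ToM",
             "+Lang-ToM", "rest"),
    stringsAsFactors = FALSE
  )
}

#' Default network definition
#'
#' Two functional networks at the scale used throughout the package: a
#' left-hemisphere language network with five parcels and a bilateral
#' theory-of-mind (ToM) network with six parcels.
#'
#' @param voxels_per_parcel Number of gray-matter voxels per parcel.
#' @return Named list of networks, each a list with `n_parcels` and
#'   `voxels_per_parcel`.
#' @export
default_networks <- function(voxels_per_parcel = 50) {
  list(
    language = list(n_parcels = 5, voxels_per_parcel = voxels_per_parcel),
    tom      = list(n_parcels = 6, voxels_per_parcel = voxels_per_parcel)
  )
}

#' Default network-by-condition coupling weights
#'
#' Couplings encode how strongly each network's voxels follow the shared
#' stimulus-locked signal in each condition. The defaults plant the
#' dissociation under study: the language network couples strongly (0.35) to
#' linguistic conditions and weakly (0.10) to non-linguistic ones; the ToM
#' network couples strongly (0.30) to conditions with mental state content
#' and weakly (0.10) to the condition without it. Rest has zero coupling
#' everywhere. Networks other than `language`/`tom` default to 0.10 for all
#' non-rest conditions and should usually be given explicit weights.
#'
#' @param conditions Condition data frame as from [default_conditions()].
#' @param networks Network list as from [default_networks()].
#' @return Matrix of couplings, networks in rows, conditions in columns.
#' @export
default_coupling <- function(conditions = default_conditions(),
                             networks = default_networks()) {
  a <- matrix(0, nrow = length(networks), ncol = nrow(conditions),
              dimnames = list(names(networks), conditions$name))
  for (nm in names(networks)) {
    for (j in seq_len(nrow(conditions))) {
      ty <- conditions$type[j]
      a[nm, j] <- if (identical(ty, "rest")) {
        0
      } else if (nm == "language") {
        if (grepl("+Lang", ty, fixed = TRUE)) 0.35 else 0.10
      } else if (nm == "tom") {
        if (grepl("+ToM", ty, fixed = TRUE)) 0.30 else 0.10
      } else {
        0.10
      }
    }
  }
  a
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic multi-subject BOLD
#' generator. The defaults mirror the study design the package targets:
#' 30 subjects per condition, ~5-minute runs (160 frames at TR = 2 s), a
#' band-limited shared signal confined to 0.008--0.09 Hz, unit-variance
#' subject-global and voxel noise, and nuisance contamination (drift,
#' motion-locked artifacts, WM/CSF compartment signals) at half the shared
#' signal's standard deviation.
#'
#' @param n_subjects Subjects per condition.
#' @param n_timepoints Frames per run.
#' @param tr Repetition time in seconds.
#' @param conditions Data frame with columns `name`, `type`.
#' @param networks Named list; see [default_networks()].
#' @param coupling Network x condition matrix of coupling weights `a >= 0`;
#'   defaults to [default_coupling()].
#' @param sigma_shared SD of the shared stimulus-locked signal (BOLD a.u.).
#' @param sigma_subject SD of the subject-global noise, shared across all of
#'   a subject's gray-matter voxels but independent across subjects.
#' @param sigma_voxel SD of iid voxel noise.
#' @param nuisance List with `drift`, `motion`, `compartment` amplitudes
#'   (multiples of `sigma_shared`) and `n_noise_rois` (noise compartments;
#'   2 = WM and CSF).
#' @param passband Hz pair for the band-limited shared signal.
#' @param grid 3D lattice dimensions of the voxel grid.
#' @param n_wm,n_csf Number of white-matter / CSF voxels on the grid; the
#'   remainder is gray matter.
#' @param seed Master integer seed; the full dataset is a pure function of
#'   `(config, seed)`.
#' @return An object of class `isc_sim_config`.
#' @export
sim_config <- function(n_subjects = 30,
                       n_timepoints = 160,
                       tr = 2,
                       conditions = default_conditions(),
                       networks = default_networks(),
                       coupling = NULL,
                       sigma_shared = 1,
                       sigma_subject = 1,
                       sigma_voxel = 1,
                       nuisance = list(drift = 0.5, motion = 0.5,
                                       compartment = 0.5, n_noise_rois = 2),
                       passband = c(0.008, 0.09),
                       grid = c(14, 14, 8),
                       n_wm = 260,
                       n_csf = 130,
                       seed = 1) {
  stopifnot(n_subjects >= 1, n_timepoints >= 8, tr > 0)
  if (any(c(sigma_shared, sigma_subject, sigma_voxel) < 0)) {
    stop("All standard deviations must be >= 0.")
  }
  check_passband(passband, tr)
  if (!all(c("name", "type") %in% names(conditions))) {
    stop("`conditions` needs columns `name` and `type`.")
  }
  if (is.null(coupling)) coupling <- default_coupling(conditions, networks)
  if (!all(names(networks) %in% rownames(coupling)) ||
      !all(conditions$name %in% colnames(coupling))) {
    stop("`coupling` must be defined for every (network, condition) pair.")
  }
  if (any(coupling < 0)) stop("Coupling weights must be >= 0.")
  n_parcel_vox <- sum(vapply(networks, function(n) n$n_parcels * n$voxels_per_parcel, 0))
  n_gm <- prod(grid) - n_wm - n_csf
  if (n_gm <= n_parcel_vox) {
    stop("Grid too small: ", n_gm, " GM voxels for ", n_parcel_vox, " parcel voxels.")
  }
  structure(
    list(n_subjects = n_subjects, n_timepoints = n_timepoints, tr = tr,
         conditions = conditions, networks = networks, coupling = coupling,
         sigma_shared = sigma_shared, sigma_subject = sigma_subject,
         sigma_voxel = sigma_voxel, nuisance = nuisance,
         passband = passband, grid = grid, n_wm = n_wm, n_csf = n_csf,
         seed = as.integer(seed)),
    class = "isc_sim_config"
  )
}

#' Voxel grid geometry for a simulation
#'
#' Lays out tissue compartments and network parcels on the configured 3D
#' lattice. Assignment is deterministic: the first `n_wm` linear voxel
#' indices are white matter, the next `n_csf` are CSF, the rest gray matter;
#' parcels occupy consecutive gray-matter indices. Every parcel voxel is a
#' gray-matter voxel by construction.
#'
#' @param config An `isc_sim_config`.
#' @return A list with `dim`, `tissue` (factor gm/wm/csf per voxel),
#'   `parcel_id` (integer per voxel, 0 = unassigned), `parcels` (data frame:
#'   parcel, network, n_voxels) and `parcel_voxels` (named list of voxel
#'   index vectors).
#' @export
make_geometry <- function(config) {
  n_vox <- prod(config$grid)
  tissue <- rep("gm", n_vox)
  tissue[seq_len(config$n_wm)] <- "wm"
  tissue[config$n_wm + seq_len(config$n_csf)] <- "csf"
  tissue <- factor(tissue, levels = c("gm", "wm", "csf"))
  gm_idx <- which(tissue == "gm")

  parcel_id <- integer(n_vox)
  parcels <- list()
  voxels <- list()
  pos <- 1L
  pid <- 0L
  for (nm in names(config$networks)) {
    net <- config$networks[[nm]]
    for (p in seq_len(net$n_parcels)) {
      pid <- pid + 1L
      vox <- gm_idx[pos:(pos + net$voxels_per_parcel - 1L)]
      pos <- pos + net$voxels_per_parcel
      pname <- sprintf("%s_p%d", nm, p)
      parcel_id[vox] <- pid
      parcels[[pid]] <- data.frame(parcel = pname, network = nm,
                                   n_voxels = length(vox),
                                   stringsAsFactors = FALSE)
      voxels[[pname]] <- vox
    }
  }
  list(dim = config$grid, tissue = tissue, parcel_id = parcel_id,
       parcels = do.call(rbind, parcels), parcel_voxels = voxels)
}

#' Band-limited shared stimulus signal
#'
#' Draws a Gaussian white series, zeroes every DFT bin outside the passband
#' (including DC), inverts the transform and standardizes. The result has
#' sample mean 0, sample SD 1, and all of its spectral power inside the
#' passband, so it is invariant (up to edge effects of the chosen filter)
#' under the pipeline's band-pass step.
#'
#' @param n_timepoints Series length in frames.
#' @param tr Sampling interval, seconds.
#' @param passband Hz pair strictly inside (0, Nyquist).
#' @param seed Integer seed; identical calls are bit-identical.
#' @return Numeric vector of length `n_timepoints`.
#' @export
make_shared_signal <- function(n_timepoints, tr, passband = c(0.008, 0.09),
                               seed = NULL) {
  check_passband(passband, tr)
  f <- dft_frequencies(n_timepoints, tr)
  keep <- f >= passband[1] & f <= passband[2]
  if (!any(keep)) {
    stop("Passband contains no DFT bins at this length/TR; increase n or widen band.")
  }
  x <- with_seed(seed, stats::rnorm(n_timepoints))
  X <- stats::fft(x)
  X[!keep] <- 0 + 0i
  s <- Re(stats::fft(X, inverse = TRUE)) / n_timepoints
  s <- s - mean(s)
  s / stats::sd(s)
}

#' Expected leave-one-out inter-subject correlation
#'
#' Closed-form large-T expectation of the correlation between one subject's
#' regional time course `a * s(t) + noise` and the average of the remaining
#' `N - 1` subjects' time courses:
#' `a^2 s_s^2 / sqrt((a^2 s_s^2 + s_n^2) * (a^2 s_s^2 + s_n^2 / (N - 1)))`.
#' Strictly increasing in the coupling `a` (for `sigma_n > 0`) and in `N`.
#'
#' @param a Coupling weight (>= 0); vectorized.
#' @param sigma_s SD of the shared signal.
#' @param sigma_n Effective SD of the per-subject noise on the regional mean
#'   time course (for `V` voxels with voxel noise `sigma_v` and
#'   subject-global noise `sigma_g`: `sqrt(sigma_g^2 + sigma_v^2 / V)`).
#' @param n_subjects Number of subjects (>= 2).
#' @return Expected Pearson correlation(s).
#' @export
expected_isc <- function(a, sigma_s, sigma_n, n_subjects) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2.")
  if (any(a < 0) || sigma_s < 0 || sigma_n < 0) stop("`a` and SDs must be >= 0.")
  if (sigma_s == 0 && sigma_n == 0) stop("sigma_s and sigma_n cannot both be 0.")
  sig2 <- a^2 * sigma_s^2
  sig2 / sqrt((sig2 + sigma_n^2) * (sig2 + sigma_n^2 / (n_subjects - 1)))
}

# Smooth 6-parameter motion trace (random walk; translations in mm,
# rotations in radians), with rare abrupt jumps so outlier detection and
# spike regression see realistic work. Typical framewise displacement is a
# few hundredths of a mm; a jump frame exceeds the 0.9 mm threshold.
simulate_motion <- function(n_timepoints, trans_scale = 0.02,
                            rot_scale = 2e-4, jump_prob = 0.005) {
  step <- cbind(matrix(stats::rnorm(n_timepoints * 3, sd = trans_scale),
                       n_timepoints, 3),
                matrix(stats::rnorm(n_timepoints * 3, sd = rot_scale),
                       n_timepoints, 3))
  jump <- stats::runif(n_timepoints) < jump_prob
  step[jump, ] <- step[jump, , drop = FALSE] * 40
  m <- apply(step, 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

# One subject's voxel x time matrix for one condition, plus nuisance truth.
# The RNG stream is fully determined by (config$seed, condition, i).
simulate_subject_run <- function(config, geometry, shared, condition, i) {
  Tn <- config$n_timepoints
  n_vox <- prod(config$grid)
  ctype <- config$conditions$type[match(condition, config$conditions$name)]
  with_seed(derive_seed(config$seed, "run", condition, i), {
    gm <- geometry$tissue == "gm"
    wm <- geometry$tissue == "wm"
    csf <- geometry$tissue == "csf"

    motion <- simulate_motion(Tn)
    dmot <- rbind(0, diff(motion))
    w <- stats::rnorm(6)
    art <- as.vector(dmot %*% w)
    art_sd <- stats::sd(art)
    if (art_sd > 0) art <- (art - mean(art)) / art_sd

    drift_basis <- as.vector(scale(seq_len(Tn)))
    drift_coef <- stats::rnorm(1)

    n_noise <- config$nuisance$n_noise_rois
    comp_wm <- if (n_noise >= 1) stats::rnorm(Tn) else numeric(Tn)
    comp_csf <- if (n_noise >= 2) stats::rnorm(Tn) else numeric(Tn)

    g <- stats::rnorm(Tn, sd = config$sigma_subject)

    Y <- matrix(stats::rnorm(n_vox * Tn, sd = config$sigma_voxel), n_vox, Tn)

    # stimulus-locked shared component, network-specific coupling
    a_vox <- numeric(n_vox)
    if (!identical(ctype, "rest")) {
      for (pname in names(geometry$parcel_voxels)) {
        net <- geometry$parcels$network[geometry$parcels$parcel == pname]
        a_vox[geometry$parcel_voxels[[pname]]] <- config$coupling[net, condition]
      }
    }
    nz <- a_vox != 0
    if (any(nz)) Y[nz, ] <- Y[nz, ] + a_vox[nz] %o% (config$sigma_shared * shared)

    # subject-global noise and nuisance contamination of gray matter
    amp <- config$sigma_shared
    nuis_gm <- config$nuisance$drift * amp * drift_coef * drift_basis +
      config$nuisance$motion * amp * art +
      config$nuisance$compartment * amp * (comp_wm + comp_csf)
    Y[gm, ] <- Y[gm, ] + rep(1, sum(gm)) %o% (g + nuis_gm)

    # noise compartments carry their own shared signals
    if (n_noise >= 1) Y[wm, ] <- Y[wm, ] + rep(1, sum(wm)) %o% comp_wm
    if (n_noise >= 2) Y[csf, ] <- Y[csf, ] + rep(1, sum(csf)) %o% comp_csf

    list(bold = Y, motion = motion,
         truth = list(g = g, drift_coef = drift_coef, drift = drift_basis,
                      art = art, comp_wm = comp_wm, comp_csf = comp_csf))
  })
}

# Region-resolution variant of simulate_subject_run: independent voxel noise
# enters region means only as Gaussian noise with SD sigma_voxel / sqrt(V),
# so it is marginalized analytically instead of simulated per voxel. The
# result is distributionally identical to averaging the voxel-level
# generator over each parcel (and over gray matter, for the global signal);
# WM/CSF compartments keep voxel resolution because the principal-component
# step consumes voxel data.
simulate_subject_run_roi <- function(config, geometry, shared, condition, i) {
  Tn <- config$n_timepoints
  ctype <- config$conditions$type[match(condition, config$conditions$name)]
  with_seed(derive_seed(config$seed, "run", condition, i), {
    motion <- simulate_motion(Tn)
    dmot <- rbind(0, diff(motion))
    w <- stats::rnorm(6)
    art <- as.vector(dmot %*% w)
    art_sd <- stats::sd(art)
    if (art_sd > 0) art <- (art - mean(art)) / art_sd
    drift_basis <- as.vector(scale(seq_len(Tn)))
    drift_coef <- stats::rnorm(1)
    n_noise <- config$nuisance$n_noise_rois
    comp_wm <- if (n_noise >= 1) stats::rnorm(Tn) else numeric(Tn)
    comp_csf <- if (n_noise >= 2) stats::rnorm(Tn) else numeric(Tn)
    g <- stats::rnorm(Tn, sd = config$sigma_subject)

    amp <- config$sigma_shared
    nuis_gm <- config$nuisance$drift * amp * drift_coef * drift_basis +
      config$nuisance$motion * amp * art +
      config$nuisance$compartment * amp * (comp_wm + comp_csf)

    pv <- geometry$parcel_voxels
    roi <- matrix(0, length(pv), Tn, dimnames = list(names(pv), NULL))
    for (p in seq_along(pv)) {
      net <- geometry$parcels$network[p]
      a <- if (identical(ctype, "rest")) 0 else config$coupling[net, condition]
      roi[p, ] <- a * amp * shared + g + nuis_gm +
        stats::rnorm(Tn, sd = config$sigma_voxel / sqrt(length(pv[[p]])))
    }
    n_gm <- sum(geometry$tissue == "gm")
    n_rest <- n_gm - sum(lengths(pv))
    rest_mean <- g + nuis_gm +
      stats::rnorm(Tn, sd = config$sigma_voxel / sqrt(n_rest))
    w_p <- lengths(pv) / n_gm
    global <- drop(w_p %*% roi) + (n_rest / n_gm) * rest_mean

    n_wm <- config$n_wm
    n_csf <- config$n_csf
    comps <- list()
    if (n_wm > 0) {
      comps$wm <- rep(1, n_wm) %o% comp_wm +
        matrix(stats::rnorm(n_wm * Tn, sd = config$sigma_voxel), n_wm, Tn)
    }
    if (n_csf > 0) {
      comps$csf <- rep(1, n_csf) %o% comp_csf +
        matrix(stats::rnorm(n_csf * Tn, sd = config$sigma_voxel), n_csf, Tn)
    }
    list(roi = roi, compartments = comps, global = global, motion = motion,
         truth = list(g = g, drift_coef = drift_coef, drift = drift_basis,
                      art = art, comp_wm = comp_wm, comp_csf = comp_csf))
  })
}

#' Simulate one naturalistic condition for all subjects
#'
#' Every gray-matter voxel of subject `i` follows
#' `a(network, condition) * sigma_shared * s(t) + g_i(t) + voxel noise +
#' nuisance`, where `s(t)` is a band-limited shared signal common to all
#' subjects, `g_i(t)` is subject-global noise (shared across a subject's
#' voxels, independent across subjects -- it must *not* inflate ISC), and the
#' nuisance terms (drift, motion-locked artifact, WM/CSF compartment
#' signals) are stored as ground truth so their removal can be verified.
#' For `condition = "rest"` all couplings are zero.
#'
#' @param config An `isc_sim_config`.
#' @param condition Condition name present in `config$conditions`.
#' @param subjects Integer subject indices (default all).
#' @param geometry Optional precomputed [make_geometry()] result.
#' @return A list of class `isc_run_set` with elements `condition`, `type`,
#'   `tr`, `geometry`, `subjects` (each with `bold`, `motion`, `truth`) and
#'   `truth` (shared signal and coupling column).
#' @export
simulate_naturalistic_run <- function(config, condition,
                                      subjects = seq_len(config$n_subjects),
                                      geometry = NULL) {
  if (!condition %in% config$conditions$name) {
    stop("Unknown condition: ", condition)
  }
  if (is.null(geometry)) geometry <- make_geometry(config)
  shared <- make_shared_signal(config$n_timepoints, config$tr, config$passband,
                               seed = derive_seed(config$seed, "shared", condition))
  ctype <- config$conditions$type[match(condition, config$conditions$name)]
  a <- config$coupling[, condition]
  if (identical(ctype, "rest")) a[] <- 0
  subs <- lapply(subjects, function(i) {
    simulate_subject_run(config, geometry, shared, condition, i)
  })
  names(subs) <- paste0("sub", subjects)
  structure(
    list(condition = condition, type = ctype, tr = config$tr,
         geometry = geometry, subjects = subs,
         truth = list(shared = shared, coupling = a)),
    class = "isc_run_set"
  )
}

#' Simulate a localizer run with planted voxel effects
#'
#' Each voxel's time course is `effect[v] * x(t) + noise`, where `x(t)` is
#' the HRF-convolved difference between the two condition boxcars of the
#' block design (or the single condition's convolved boxcar when the design
#' has one condition). The planted effect map is returned as ground truth.
#'
#' @param n_frames Run length in frames.
#' @param tr Repetition time, seconds.
#' @param design Data frame with columns `onset`, `duration` (seconds) and
#'   `condition`; blocks must not overlap and must fit in the run.
#' @param effect Numeric vector, one effect size per voxel.
#' @param sigma_noise SD of iid voxel noise.
#' @param seed Integer seed.
#' @return List with `bold` (voxel x time), `design`, `tr` and `truth`
#'   (effect map and contrast regressor).
#' @export
simulate_localizer_run <- function(n_frames, tr, design, effect,
                                   sigma_noise = 1, seed = NULL) {
  X <- build_design_matrix(design, n_frames, tr)
  conds <- attr(X, "condition_cols")
  xc <- if (length(conds) >= 2) X[, conds[1]] - X[, conds[2]] else X[, conds[1]]
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(effect) * n_frames, sd = sigma_noise),
                    length(effect), n_frames)
    list(bold = effect %o% xc + noise, design = design, tr = tr,
         truth = list(effect = effect, regressor = xc))
  })
}

#' Simulate a full multi-condition dataset
#'
#' Convenience wrapper generating every configured condition (or a subset)
#' with a shared geometry. Identical `(config, seed)` give a bit-identical
#' dataset.
#'
#' @param config An `isc_sim_config`.
#' @param conditions Character vector of condition names (default all).
#' @return A list of class `isc_dataset`: `config`, `geometry`, `runs`
#'   (named list of `isc_run_set`).
#' @export
simulate_dataset <- function(config, conditions = config$conditions$name) {
  geometry <- make_geometry(config)
  runs <- lapply(conditions, function(cn) {
    simulate_naturalistic_run(config, cn, geometry = geometry)
  })
  names(runs) <- conditions
  structure(list(config = config, geometry = geometry, runs = runs),
            class = "isc_dataset")
}
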