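test_that("design matrices have the expected structure and HRF timing", {
  d1 <- data.frame(onset = 20, duration = 20, condition = "A")
  X1 <- build_design_matrix(d1, 100, 2)
  # condition + derivative + intercept + discrete-cosine drifts (period
  # >= 200 s: k <= 2 * 200 s / 200 s = 2 of them for this run)
  expect_identical(colnames(X1),
                   c("A", "A_deriv", "intercept", "drift1", "drift2"))

  # convolved boxcar of a short block peaks ~5-6 s after onset
  d2 <- data.frame(onset = 40, duration = 2, condition = "A")
  X2 <- build_design_matrix(d2, 150, 1)
  peak_t <- which.max(X2[, "A"]) - 1
  expect_gte(peak_t - 40, 4)
  expect_lte(peak_t - 40, 7)

  # two alternating conditions: 2 * 2 condition columns + nuisance
  d3 <- data.frame(onset = c(10, 50, 90, 130), duration = 20,
                   condition = c("A", "B", "A", "B"))
  X3 <- build_design_matrix(d3, 160, 2)
  expect_identical(sum(colnames(X3) %in% c("A", "A_deriv", "B", "B_deriv")), 4L)

  expect_error(build_design_matrix(d1, 100, 2, conditions = c("A", "C")),
               "no blocks")
  dov <- data.frame(onset = c(10, 20), duration = 20, condition = c("A", "B"))
  expect_error(build_design_matrix(dov, 100, 2), "Overlapping")
  dout <- data.frame(onset = 190, duration = 20, condition = "A")
  expect_error(build_design_matrix(dout, 100, 2), "fit within")
})

test_that("GLM contrasts recover noiseless effects exactly and null t follows Student t", {
  d <- data.frame(onset = c(10, 50, 90, 130), duration = 20,
                  condition = c("A", "B", "A", "B"))
  X <- build_design_matrix(d, 160, 2)
  y <- 3 * X[, "A"] - 3 * X[, "B"]
  cm <- fit_glm_contrast(matrix(y, 1), X, c(A = 1, B = -1))
  expect_equal(cm$effect, 6, tolerance = 1e-8)

  set.seed(15)
  noise <- matrix(rnorm(10000 * 160), 10000, 160)
  cm0 <- fit_glm_contrast(noise, X, c(A = 1, B = -1))
  expect_equal(cm0$df, 160 - ncol(X))
  ks <- suppressWarnings(ks.test(cm0$t, function(q) pt(q, cm0$df)))
  expect_gt(ks$p.value, 0.01)

  expect_error(fit_glm_contrast(noise[, 1:5], X, c(A = 1, B = -1)), "Fewer frames")
})

test_that("fROI definition implements the deterministic top-fraction rule", {
  cmap <- structure(list(effect = c(rep(0, 10), 5, 1:8, 10), t = NULL,
                         df = 100, subject = "s1"), class = "contrast_map")
  fr <- define_froi(cmap, parcel = 1:20, fraction = 0.10)
  expect_identical(fr$voxels, c(19L, 20L))   # the two largest effects (8, 10)
  expect_identical(eval(formals(define_froi)$fraction), 0.10)

  # full-sort oracle on random values, several parcel sizes
  set.seed(10)
  for (psize in c(7, 20, 53)) {
    eff <- rnorm(200)
    cm <- structure(list(effect = eff, df = 50, subject = "s"),
                    class = "contrast_map")
    parcel <- sort(sample(200, psize))
    fr <- define_froi(cm, parcel, fraction = 0.1)
    k <- max(1, ceiling(0.1 * psize))
    oracle <- sort(parcel[order(-eff[parcel], parcel)][1:k])
    expect_identical(fr$voxels, oracle)
    # invariance under a strictly increasing transform
    cm2 <- structure(list(effect = exp(eff / 2), df = 50, subject = "s"),
                     class = "contrast_map")
    expect_identical(define_froi(cm2, parcel, fraction = 0.1)$voxels, oracle)
  }

  # ties at the boundary break by ascending voxel index
  cmt <- structure(list(effect = rep(1, 30), df = 50, subject = "s"),
                   class = "contrast_map")
  expect_identical(define_froi(cmt, 5:34, fraction = 0.1)$voxels, c(5L, 6L, 7L))
  expect_error(define_froi(cmap, integer(0)), "Empty parcel")
})

test_that("QC counts suprathreshold voxels with the exact 99/100 boundary", {
  df <- 120
  thr <- qt(1 - 0.001, df)
  make_map <- function(n_above) {
    t_vals <- rep(0, 500)
    if (n_above > 0) t_vals[seq_len(n_above)] <- thr + 1
    structure(list(effect = t_vals, t = t_vals, df = df), class = "contrast_map")
  }
  masks <- list(1:250, 251:500)
  expect_false(qc_subject(make_map(99), masks)$pass)
  expect_true(qc_subject(make_map(100), masks)$pass)
  q0 <- qc_subject(make_map(0), masks)
  expect_false(q0$pass)
  expect_identical(q0$count, 0L)
  # planted strong effect in 150 mask voxels, low noise
  d <- data.frame(onset = c(10, 50, 90, 130), duration = 20,
                  condition = c("A", "B", "A", "B"))
  X <- build_design_matrix(d, 160, 2)
  eff <- c(rep(5, 150), rep(0, 350))
  sim <- simulate_localizer_run(160, 2, d, eff, sigma_noise = 0.5, seed = 3)
  cm <- fit_glm_contrast(sim$bold, X, c(A = 1, B = -1))
  qq <- qc_subject(cm, masks)
  expect_true(qq$pass)
  expect_gt(qq$count, 140)
})

test_that("cross-network overlap removal equals the set-difference oracle", {
  mk <- function(vox, parcel, network, subject = "s1") {
    structure(list(subject = subject, parcel = parcel, network = network,
                   voxels = sort(vox)), class = "froi")
  }
  # disjoint fROIs are untouched
  fr <- list(mk(1:10, "p1", "language"), mk(21:30, "q1", "tom"))
  out <- exclude_overlap(fr)
  expect_identical(out$frois[[1]]$voxels, 1:10)
  expect_identical(nrow(out$report), 0L)

  # exactly 7 shared voxels shrink both fROIs
  fr2 <- list(mk(1:20, "p1", "language"), mk(14:33, "q1", "tom"))
  out2 <- exclude_overlap(fr2)
  expect_identical(out2$frois[[1]]$voxels, 1:13)
  expect_identical(out2$frois[[2]]$voxels, 21:33)
  expect_identical(out2$report$n_overlap, 7L)

  # random fROIs across three networks vs brute force
  set.seed(12)
  fr3 <- list(mk(sample(60, 25), "p1", "language"),
              mk(sample(60, 25), "q1", "tom"),
              mk(sample(60, 25), "r1", "md"))
  out3 <- exclude_overlap(fr3)
  vox <- lapply(fr3, `[[`, "voxels")
  shared <- sort(unique(c(intersect(vox[[1]], vox[[2]]),
                          intersect(vox[[1]], vox[[3]]),
                          intersect(vox[[2]], vox[[3]]))))
  for (i in 1:3) {
    expect_identical(out3$frois[[i]]$voxels, setdiff(vox[[i]], shared))
  }

  # same-network fROIs within a subject are not deoverlapped
  fr4 <- list(mk(1:10, "p1", "language"), mk(5:14, "p2", "language"))
  out4 <- exclude_overlap(fr4)
  expect_identical(out4$frois[[1]]$voxels, 1:10)
})
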