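test_that("shared signal is standardized, band-limited, and deterministic", {
  s <- make_shared_signal(300, 2, c(0.008, 0.09), seed = 1)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_identical(s, make_shared_signal(300, 2, c(0.008, 0.09), seed = 1))
  expect_false(identical(s, make_shared_signal(300, 2, c(0.008, 0.09), seed = 2)))

  # out-of-band mass fraction < 0.05 by the brute-force DFT periodogram
  pg <- brute_periodogram(s)
  f <- natisc:::dft_frequencies(300, 2)
  out_band <- f < 0.008 | f > 0.09
  expect_lt(sum(pg[out_band]) / sum(pg), 0.05)

  expect_error(make_shared_signal(300, 2, c(0.09, 0.008)), "Degenerate")
  expect_error(make_shared_signal(300, 2, c(0.01, 0.3)), "Nyquist")
})

test_that("expected_isc matches its closed form, limits, and monotonicity", {
  expect_equal(expected_isc(0, 1, 1, 10), 0)
  expect_equal(expected_isc(0.7, 1, 0, 10), 1)
  expect_equal(expected_isc(1, 1, 1, 30), 0.6952, tolerance = 1e-4)
  expect_error(expected_isc(1, 1, 1, 1), ">= 2")
  expect_error(expected_isc(1, 0, 0, 10), "both")

  a <- seq(0, 2, by = 0.1)
  expect_true(all(diff(expected_isc(a, 1, 1, 10)) > 0))
  byN <- vapply(2:40, function(N) expected_isc(0.5, 1, 1, N), 0)
  expect_true(all(diff(byN) > 0))
})

test_that("expected_isc agrees with a direct Monte-Carlo estimate", {
  set.seed(42)
  Tn <- 20000
  N <- 6
  s <- rnorm(Tn)
  X <- vapply(seq_len(N), function(i) s + rnorm(Tn), numeric(Tn))
  Z <- scale(X)
  r <- loo_isc(t(Z))
  expect_equal(mean(r), expected_isc(1, 1, 1, N), tolerance = 0.02)
})

test_that("simulated datasets are a pure function of (config, seed)", {
  cfg <- tiny_config(seed = 7)
  r1 <- simulate_naturalistic_run(cfg, "story", subjects = 1:2)
  r2 <- simulate_naturalistic_run(cfg, "story", subjects = 1:2)
  expect_identical(r1$subjects$sub1$bold, r2$subjects$sub1$bold)
  expect_identical(r1$subjects$sub2$motion, r2$subjects$sub2$motion)
  cfg2 <- tiny_config(seed = 8)
  r3 <- simulate_naturalistic_run(cfg2, "story", subjects = 1:2)
  expect_false(identical(r1$subjects$sub1$bold, r3$subjects$sub1$bold))
  expect_error(simulate_naturalistic_run(cfg, "no_such_condition"), "Unknown")
})

test_that("noiseless unit-coupling runs reproduce the shared signal exactly", {
  cfg <- noiseless_config(seed = 2)
  rs <- simulate_naturalistic_run(cfg, "story")
  g <- rs$geometry
  pv <- g$parcel_voxels[[1]]
  for (nm in names(rs$subjects)) {
    m <- colMeans(rs$subjects[[nm]]$bold[pv, ])
    expect_equal(m, rs$truth$shared, tolerance = 1e-10)
  }
  Z <- t(vapply(rs$subjects, function(s) {
    x <- colMeans(s$bold[pv, ])
    (x - mean(x)) / sd(x)
  }, numeric(cfg$n_timepoints)))
  expect_equal(unname(loo_isc(Z)), rep(1, 3), tolerance = 1e-10)
})

test_that("rest runs and zero-coupling runs carry no inter-subject signal", {
  cfg <- tiny_config(n_subjects = 8, n_timepoints = 200, seed = 11)
  rs <- simulate_naturalistic_run(cfg, "rest")
  expect_true(all(rs$truth$coupling == 0))
  pv <- rs$geometry$parcel_voxels[[3]]
  Z <- t(vapply(rs$subjects, function(s) {
    x <- colMeans(s$bold[pv, ])
    (x - mean(x)) / sd(x)
  }, numeric(cfg$n_timepoints)))
  r <- loo_isc(Z)
  # subject-global noise is shared within but not across subjects
  expect_lt(abs(mean(r)), 0.08)
})

test_that("empirical leave-one-out ISC inherits coupling monotonicity", {
  conds <- data.frame(name = c("c1", "c2", "c3"),
                      type = rep("+Lang+ToM", 3))
  nets <- list(net = list(n_parcels = 1, voxels_per_parcel = 10))
  a <- matrix(c(0, 0.4, 1), 1, 3, dimnames = list("net", conds$name))
  cfg <- sim_config(n_subjects = 10, n_timepoints = 400, conditions = conds,
                    networks = nets, coupling = a, grid = c(6, 6, 4),
                    n_wm = 30, n_csf = 20,
                    nuisance = list(drift = 0, motion = 0, compartment = 0,
                                    n_noise_rois = 2), seed = 5)
  res <- run_isc_pipeline(cfg, preprocess = FALSE, marginalize_voxels = TRUE)
  mz <- tapply(res$table$z, res$table$condition, mean)[conds$name]
  expect_true(all(diff(mz) > 0))
})

test_that("localizer simulation plants recoverable voxel effects", {
  design <- data.frame(onset = c(10, 50, 90, 130), duration = 20,
                       condition = c("A", "B", "A", "B"))
  # null effects give near-null contrast estimates
  sim0 <- simulate_localizer_run(160, 2, design, effect = rep(0, 100),
                                 sigma_noise = 1, seed = 1)
  X <- build_design_matrix(design, 160, 2)
  cm0 <- fit_glm_contrast(sim0$bold, X, c(A = 1, B = -1))
  expect_lt(abs(mean(cm0$effect)), 0.2)

  # graded planted effects are recovered in rank order
  eff <- seq(0, 3, length.out = 200)
  sim <- simulate_localizer_run(160, 2, design, effect = eff,
                                sigma_noise = 1, seed = 2)
  cm <- fit_glm_contrast(sim$bold, X, c(A = 1, B = -1))
  expect_gt(cor(eff, cm$effect, method = "spearman"), 0.8)

  bad <- data.frame(onset = c(10, 20), duration = 20, condition = c("A", "B"))
  expect_error(simulate_localizer_run(160, 2, bad, effect = rep(0, 10)),
               "Overlapping")
})
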