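# Build a long ISC-style table directly (no simulation) for solver tests.
# Conditions are nested in condition types (as in the real design), so the
# crossed condition intercept is not confounded with the type contrast.
make_table <- function(n_sub = 12, frois = c("f1", "f2"),
                       conds = c("c1", "c2", "c3", "c4"),
                       types = c("tA", "tA", "tB", "tB"),
                       effect = 0, sd_noise = 0.1, sd_sub = 0.05, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant = paste0("s", seq_len(n_sub)),
                   froi = frois, condition = conds,
                   stringsAsFactors = FALSE)
  g$network <- "net"
  g$condition_type <- types[match(g$condition, conds)]
  b_sub <- rnorm(n_sub, 0, sd_sub)
  x <- ifelse(g$condition_type == "tA", 0.5, -0.5)
  g$z <- 0.2 + effect * x + b_sub[match(g$participant, unique(g$participant))] +
    rnorm(nrow(g), 0, sd_noise)
  g
}

test_that("a two-level contrast reduces to the paired mean difference", {
  tab <- make_table(n_sub = 10, frois = "f1",
                    sd_sub = 0, sd_noise = 0.2, effect = 0.3, seed = 2)
  res <- fit_condition_contrast(tab, "condition_type", c("tA", "tB"))
  cellmeans <- tapply(tab$z, tab$condition_type, mean)
  expect_equal(res$beta, unname(cellmeans["tA"] - cellmeans["tB"]),
               tolerance = 1e-6)

  # label permutation flips the sign, |t| unchanged
  res_sw <- fit_condition_contrast(tab, "condition_type", c("tB", "tA"))
  expect_equal(res_sw$beta, -res$beta, tolerance = 1e-6)
  expect_equal(abs(res_sw$t), abs(res$t), tolerance = 1e-4)
})

test_that("planted condition differences are recovered with coverage", {
  tab <- make_table(n_sub = 30, effect = 0.2, sd_noise = 0.1, sd_sub = 0.08,
                    seed = 3)
  res <- fit_condition_contrast(tab, "condition_type", c("tA", "tB"))
  expect_true(res$converged)
  expect_lt(abs(res$beta - 0.2), 3 * res$se)
  expect_lt(res$p, 0.01)
  expect_gt(res$df, 1)

  # row order invariance
  tab2 <- tab[sample(nrow(tab)), ]
  res2 <- fit_condition_contrast(tab2, "condition_type", c("tA", "tB"))
  expect_equal(res2$beta, res$beta, tolerance = 1e-6)
})

test_that("degenerate inputs are flagged, not crashed; bad subsets error", {
  tab <- make_table(n_sub = 6, seed = 4)
  tab$z <- 0.5
  res <- fit_condition_contrast(tab, "condition_type", c("tA", "tB"))
  expect_equal(res$beta, 0, tolerance = 1e-10)
  expect_false(res$converged)
  expect_true(is.na(res$p))

  one <- make_table(n_sub = 6, seed = 5)
  expect_error(fit_condition_contrast(one[one$condition_type == "tA", ],
                                      "condition_type"),
               "two levels|Both levels")
  single <- make_table(n_sub = 1, seed = 6)
  expect_error(fit_condition_contrast(single, "condition_type", c("tA", "tB")),
               "2 participants")
})

test_that("the interaction model recovers a planted crossover", {
  set.seed(7)
  n_sub <- 20
  g <- expand.grid(participant = paste0("s", seq_len(n_sub)),
                   network = c("language", "tom"),
                   froi = paste0("f", 1:3),
                   condition = c("c1", "c2"), stringsAsFactors = FALSE)
  g$condition_type <- ifelse(g$condition == "c1", "tA", "tB")
  net <- ifelse(g$network == "language", 0.5, -0.5)
  ct <- ifelse(g$condition_type == "tA", 0.5, -0.5)
  g$z <- 0.2 + 0.4 * net * ct + rnorm(n_sub)[match(g$participant,
                                                   unique(g$participant))] * 0.05 +
    rnorm(nrow(g), 0, 0.1)
  res <- fit_interaction(g, c("language", "tom"), c("tA", "tB"))
  expect_true(res$converged)
  expect_gt(res$beta, 0)
  expect_lt(abs(res$beta - 0.4), 3 * res$se)
  expect_lt(res$p, 0.05)
  expect_match(res$re_structure, "participant")

  # constant response: interaction is exactly 0 and flagged
  g0 <- g
  g0$z <- 1
  res0 <- fit_interaction(g0, c("language", "tom"), c("tA", "tB"))
  expect_equal(res0$beta, 0, tolerance = 1e-10)
  expect_false(res0$converged)

  expect_error(fit_interaction(g[g$network == "language", ],
                               c("language", "tom"), c("tA", "tB")),
               "present")
})

test_that("baseline tests are one-tailed per cell with family FDR", {
  tab <- make_table(n_sub = 15, effect = 0, sd_noise = 0.05, sd_sub = 0.05,
                    seed = 8)
  tab$z <- tab$z - 0.2 + 0.3 * (tab$froi == "f1")  # f1 cells positive, f2 null
  res <- test_against_baseline(tab, by = c("froi", "condition"))
  expect_identical(nrow(res), 8L)   # 2 fROIs x 4 conditions
  expect_true(all(res$reject[res$froi == "f1"]))
  expect_false(any(res$reject[res$froi == "f2"]))
  # one-tailed: a negative mean gives p > 0.5
  tabneg <- tab
  tabneg$z <- -abs(tab$z)
  rneg <- test_against_baseline(tabneg, by = "froi")
  expect_true(all(rneg$p > 0.5))

  expect_error(test_against_baseline(tab[tab$participant == "s1", ],
                                     by = "froi"),
               "2 participants")
})
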