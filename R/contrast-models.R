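# Mixed-effects contrasts over the long ISC table.
#
# Factors of interest are coded numerically as +1/2 vs -1/2 (sum-to-zero,
# symmetric in factor ordering), so a main-effect beta is the mean difference
# between the two levels and the interaction beta is the difference of
# differences. The first element of each supplied pair is coded +1/2, fixing
# the sign convention: beta > 0 means the first level (or the first network's
# preference for the first condition type) is larger.

contrast_cols <- c("term", "beta", "se", "t", "df", "p", "converged",
                   "re_structure")

new_contrast_result <- function(term, beta, se, t, df, p, converged,
                                re_structure) {
  data.frame(term = term, beta = beta, se = se, t = t, df = df, p = p,
             converged = converged, re_structure = re_structure,
             stringsAsFactors = FALSE)
}

# Random-effects simplification ladder: random slopes are dropped first
# (highest-order term first), then the crossed condition intercept, then the
# crossed fROI intercept; the last resort is a fixed-effects fit.
build_ladder <- function(data, slope_specs) {
  has_froi <- "froi" %in% names(data) && length(unique(data$froi)) > 1
  has_cond <- "condition" %in% names(data) && length(unique(data$condition)) > 1
  crossed_full <- c(if (has_froi) "(1 | froi)", if (has_cond) "(1 | condition)")
  rungs <- character()
  for (sl in slope_specs) {
    part <- if (identical(sl, "1")) "(1 | participant)" else
      sprintf("(1 + %s | participant)", sl)
    rungs <- c(rungs, paste(c(part, crossed_full), collapse = " + "))
  }
  if (has_cond) {
    rungs <- c(rungs, paste(c("(1 | participant)",
                              if (has_froi) "(1 | froi)"), collapse = " + "))
  }
  if (has_froi) rungs <- c(rungs, "(1 | participant)")
  unique(rungs)
}

lmer_converged <- function(fit) {
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) return(FALSE)
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || all(grepl("boundary|singular", msgs, ignore.case = TRUE))
}

# Fit down the ladder until a converged model yields a usable Satterthwaite
# row for `term`; fall back to OLS (exact t, residual df) when no mixed model
# is estimable.
fit_ladder <- function(data, fixed_rhs, slope_specs, term,
                       one_tailed = FALSE) {
  if (length(unique(data$participant)) < 2) {
    stop("Need at least 2 participants.")
  }
  degenerate <- stats::var(data$z) == 0
  if (!degenerate) {
    for (rung in build_ladder(data, slope_specs)) {
      f <- stats::as.formula(paste("z ~", fixed_rhs, "+", rung))
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(f, data = data, REML = TRUE,
                     control = lme4::lmerControl(
                       calc.derivs = FALSE,
                       check.conv.singular = lme4::.makeCC(
                         action = "ignore", tol = 1e-4)))
        )),
        error = function(e) NULL)
      if (is.null(fit) || !lmer_converged(fit)) next
      co <- tryCatch(
        suppressWarnings(suppressMessages(
          stats::coef(summary(lmerTest::as_lmerModLmerTest(fit))))),
        error = function(e) NULL)
      if (is.null(co) || !term %in% rownames(co)) next
      row <- co[term, ]
      if (!is.finite(row[["Std. Error"]]) || row[["Std. Error"]] <= 0 ||
          !is.finite(row[["df"]]) || row[["df"]] <= 0) next
      p <- if (one_tailed) {
        stats::pt(row[["t value"]], row[["df"]], lower.tail = FALSE)
      } else {
        row[["Pr(>|t|)"]]
      }
      return(new_contrast_result(term, row[["Estimate"]], row[["Std. Error"]],
                                 row[["t value"]], row[["df"]], p,
                                 TRUE, rung))
    }
  }
  # fixed-effects fallback (also the degenerate constant-response path)
  fit <- stats::lm(stats::as.formula(paste("z ~", fixed_rhs)), data = data)
  co <- suppressWarnings(stats::coef(summary(fit)))
  if (!term %in% rownames(co)) stop("Term ", term, " not estimable.")
  beta <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  tval <- co[term, "t value"]
  df <- fit$df.residual
  p <- if (degenerate || !is.finite(se) || se == 0) {
    NA_real_
  } else if (one_tailed) {
    stats::pt(tval, df, lower.tail = FALSE)
  } else {
    co[term, "Pr(>|t|)"]
  }
  new_contrast_result(term, beta, if (degenerate) NA_real_ else se,
                      if (degenerate) NA_real_ else tval, df, p,
                      !degenerate, "none")
}

check_isc_table <- function(table, type_col = NULL) {
  need <- c("participant", "network", "froi", "condition", "z")
  if (!is.null(type_col)) need <- c(need, type_col)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("ISC table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Network-by-condition-type interaction on the ISC table
#'
#' Fits a linear mixed-effects regression of Fisher-z ISC on network,
#' condition type, and their interaction, with the maximal feasible random
#' effects: random intercepts and slopes for the effects of interest by
#' participant, and crossed random intercepts for fROI and condition. On
#' non-convergence the random-effects structure is simplified (slopes first,
#' highest order first; then the condition intercept; then the fROI
#' intercept) and the structure actually fitted is reported. Degrees of
#' freedom use the Satterthwaite approximation; the test is two-tailed.
#'
#' The interaction beta is the difference of differences
#' `(networks[1]: types[1] - types[2]) - (networks[2]: types[1] - types[2])`;
#' a positive beta means the first network prefers the first condition type
#' more than the second network does.
#'
#' @param table Long ISC table with columns `participant`, `network`,
#'   `froi`, `condition`, `z`, and the condition-type column.
#' @param networks Character pair of network labels.
#' @param types Character pair of condition-type labels (values of
#'   `type_col`).
#' @param type_col Name of the condition-type column (default
#'   `"condition_type"`).
#' @return A one-row data frame (`term`, `beta`, `se`, `t`, `df`, `p`,
#'   `converged`, `re_structure`). A constant response yields `beta = 0`
#'   with `converged = FALSE` rather than an error.
#' @export
fit_interaction <- function(table, networks, types,
                            type_col = "condition_type") {
  check_isc_table(table, type_col)
  stopifnot(length(networks) == 2, length(types) == 2)
  d <- table[table$network %in% networks & table[[type_col]] %in% types, ,
             drop = FALSE]
  if (!all(networks %in% d$network) || !all(types %in% d[[type_col]])) {
    stop("Both networks and both condition types must be present.")
  }
  d$net <- ifelse(d$network == networks[1], 0.5, -0.5)
  d$ct <- ifelse(d[[type_col]] == types[1], 0.5, -0.5)
  out <- fit_ladder(d, "net * ct", c("net * ct", "net + ct", "net", "1"),
                    "net:ct")
  out$term <- sprintf("%s vs %s x %s vs %s", networks[1], networks[2],
                      types[1], types[2])
  out
}

#' Two-level condition (or network) contrast on an ISC table subset
#'
#' Mixed-effects estimate of the mean Fisher-z difference between two levels
#' of a factor, with the same maximal-then-simplified random-effects ladder
#' as [fit_interaction()]. The first level is coded +1/2, so `beta` is the
#' `levels[1] - levels[2]` mean difference; permuting the labels flips the
#' sign and leaves `|t|` unchanged.
#'
#' @param table Long ISC table (see [fit_interaction()]).
#' @param factor_col Column holding the two-level factor.
#' @param levels Character pair; defaults to the two levels present.
#' @return One-row contrast data frame; see [fit_interaction()].
#' @export
fit_condition_contrast <- function(table, factor_col, levels = NULL) {
  check_isc_table(table)
  if (!factor_col %in% names(table)) stop("No column ", factor_col, ".")
  if (is.null(levels)) levels <- unique(as.character(table[[factor_col]]))
  if (length(levels) != 2) stop("Exactly two levels are required; got ",
                                length(levels), ".")
  d <- table[table[[factor_col]] %in% levels, , drop = FALSE]
  if (!all(levels %in% d[[factor_col]])) stop("Both levels must be present.")
  d$x <- ifelse(d[[factor_col]] == levels[1], 0.5, -0.5)
  out <- fit_ladder(d, "x", c("x", "1"), "x")
  out$term <- sprintf("%s: %s vs %s", factor_col, levels[1], levels[2])
  out
}

#' Intercept (baseline) tests of ISC within cells
#'
#' For each cell of the ISC table (by default each fROI x condition), tests
#' whether the mean Fisher-z ISC exceeds zero with participant random
#' effects (one-tailed, matching the directional surrogate test), then
#' applies Benjamini-Hochberg FDR across the family of cells. Cells with a
#' single participant are an error, not a silent fit.
#'
#' @param table Long ISC table.
#' @param by Character vector of columns defining the cells
#'   (default `c("froi", "condition")`).
#' @param q FDR level (default 0.05).
#' @return Data frame with the cell labels, the contrast columns, and
#'   `p_fdr` / `reject`.
#' @export
test_against_baseline <- function(table, by = c("froi", "condition"),
                                  q = 0.05) {
  check_isc_table(table)
  cells <- split(seq_len(nrow(table)),
                 interaction(table[by], drop = TRUE, sep = " / "))
  rows <- lapply(names(cells), function(cn) {
    d <- table[cells[[cn]], , drop = FALSE]
    res <- fit_ladder(d, "1", "1", "(Intercept)", one_tailed = TRUE)
    cbind(stats::setNames(as.data.frame(d[1, by, drop = FALSE],
                                        row.names = NULL), by),
          res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$p_fdr <- fdr$adjusted
  out$reject <- fdr$reject
  rownames(out) <- NULL
  out
}
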