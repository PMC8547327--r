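# Repeated-measures group comparisons. Every donor contributes every
# condition exactly once (complete blocks, no imputation); the run order is
# balanced experimentally and only recorded, never modelled.

.checkCompleteBlocks <- function(tab, donor, condCols) {
  if (!all(c(donor, condCols) %in% names(tab)))
    stop(sprintf("table needs columns: %s",
                 paste(c(donor, condCols), collapse = ", ")))
  key <- interaction(tab[condCols], drop = FALSE)
  tt <- table(tab[[donor]], key)
  if (any(tt != 1L))
    stop("validation error: every donor must have every condition exactly once")
  if (any(!is.finite(tab$value)))
    stop("validation error: values must be finite")
  invisible(tab)
}

.degenerateF <- function(ssNum) abs(ssNum) < 1e-12

#' Two-way repeated-measures ANOVA on a 2x2 within-subject design
#'
#' Compares an endpoint (typically the 30-minute integrated density) across
#' a fully within-subject 2x2 design, e.g. quench status crossed with drug
#' treatment, every donor measured in all four cells. Main effects and the
#' interaction are tested against their respective effect-by-donor error
#' strata (for 2-level factors no sphericity correction is needed: each
#' effect has 1 df). Tukey-adjusted pairwise comparisons among the four
#' cells are computed on the estimated marginal means.
#'
#' An effect whose sum of squares is exactly zero (e.g. all values
#' identical, or perfectly additive data for the interaction) is reported
#' as F = 0, p = 1 rather than the indeterminate 0/0.
#'
#' @param tab data.frame with columns `donor_id`, the two factor columns,
#'   and `value`. An optional `run_order` column is carried but not
#'   modelled (the assay balances run order across days).
#' @param factors names of the two factor columns (each with 2 levels).
#' @param value name of the value column.
#' @param donor name of the donor column.
#' @return A [TestResult-class] with one statistics row per effect and
#'   Tukey-adjusted pairwise comparisons of the four cells.
#' @examples
#' tab <- expand.grid(donor_id = paste0("d", 1:6),
#'                    quench = c("unquenched", "quenched"),
#'                    treatment = c("control", "drug"))
#' tab$value <- rnorm(nrow(tab), 10)
#' rmAnova2x2(tab)
#' @export
rmAnova2x2 <- function(tab, factors = c("quench", "treatment"),
                       value = "value", donor = "donor_id") {
  tab <- as.data.frame(tab)
  names(tab)[names(tab) == value] <- "value"
  .checkCompleteBlocks(tab, donor, factors)
  A <- factor(tab[[factors[1]]])
  B <- factor(tab[[factors[2]]])
  if (nlevels(A) != 2L || nlevels(B) != 2L)
    stop("both factors must have exactly 2 levels")
  d <- data.frame(value = tab$value, A = A, B = B,
                  donor = factor(tab[[donor]]))
  n <- nlevels(d$donor)
  # sum-to-zero contrasts up front so emmeans needs no re-fit
  fit <- stats::aov(value ~ A * B + Error(donor / (A * B)), data = d,
                    contrasts = list(A = "contr.sum", B = "contr.sum"))
  sm <- summary(fit)
  effects <- c("A", "B", "A:B")
  labels <- c(factors[1], factors[2], paste(factors, collapse = ":"))
  stat <- data.frame(effect = labels, statistic = NA_real_, df1 = NA_real_,
                     df2 = NA_real_, p_value = NA_real_)
  for (i in seq_along(effects)) {
    stratum <- sm[[sprintf("Error: donor:%s", effects[i])]][[1]]
    row <- stratum[trimws(rownames(stratum)) == effects[i], , drop = FALSE]
    ssNum <- row[["Sum Sq"]]
    if (.degenerateF(ssNum)) {
      stat$statistic[i] <- 0; stat$p_value[i] <- 1
      stat$df1[i] <- 1; stat$df2[i] <- n - 1
    } else {
      stat$statistic[i] <- row[["F value"]]
      stat$df1[i] <- row[["Df"]]
      stat$df2[i] <- n - 1
      stat$p_value[i] <- row[["Pr(>F)"]]
    }
  }
  pw <- tryCatch({
    em <- suppressMessages(emmeans::emmeans(fit, specs = ~ A * B, data = d))
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    data.frame(comparison = as.character(pr$contrast),
               estimate = pr$estimate, p_raw = NA_real_,
               p_adj = pr$p.value, adjust = "tukey")
  }, error = function(e)
    data.frame(comparison = character(), estimate = numeric(),
               p_raw = numeric(), p_adj = numeric(), adjust = character()))
  new("TestResult",
      method = "Two-way repeated-measures ANOVA (Tukey post hoc)",
      statistics = stat, pairwise = pw)
}

#' Friedman test with Dunn's post hoc on complete blocks
#'
#' Nonparametric one-way repeated-measures comparison: values are ranked
#' within each donor (average ranks for ties -- the 40-minute censor
#' guarantees ties) and Friedman's chi-squared tests for any difference
#' among conditions. Dunn's post hoc compares mean ranks pairwise,
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{k(k+1)/(6n)},}
#' with a multiplicity adjustment (Holm by default; the classical
#' Bonferroni variant is selectable).
#'
#' @param tab data.frame with columns `donor_id`, `condition`, `value`.
#' @param value,donor,condition column names.
#' @param p_adjust multiplicity adjustment for Dunn's comparisons, any
#'   method of [stats::p.adjust()] (default "holm").
#' @return A [TestResult-class]: Friedman chi-squared, df and p, plus
#'   Dunn's z and adjusted p per condition pair.
#' @examples
#' tab <- expand.grid(donor_id = paste0("d", 1:6),
#'                    condition = c("control", "drug"))
#' tab$value <- c(rnorm(6, 12), rep(40, 6))
#' friedmanDunn(tab)
#' @export
friedmanDunn <- function(tab, value = "value", donor = "donor_id",
                         condition = "condition", p_adjust = "holm") {
  tab <- as.data.frame(tab)
  names(tab)[names(tab) == value] <- "value"
  .checkCompleteBlocks(tab, donor, condition)
  conds <- unique(as.character(tab[[condition]]))
  k <- length(conds)
  if (k < 2L) stop("need at least 2 conditions")
  donors <- unique(as.character(tab[[donor]]))
  n <- length(donors)
  m <- matrix(NA_real_, n, k, dimnames = list(donors, conds))
  for (r in seq_len(nrow(tab)))
    m[as.character(tab[[donor]][r]), as.character(tab[[condition]][r])] <-
      tab$value[r]
  ft <- stats::friedman.test(m)
  chi <- unname(ft$statistic); pv <- unname(ft$p.value)
  if (!is.finite(chi)) { chi <- 0; pv <- 1 }  # fully tied data: no evidence
  stat <- data.frame(effect = "condition",
                     statistic = chi,
                     df1 = unname(ft$parameter), df2 = NA_real_,
                     p_value = pv)
  ranks <- t(apply(m, 1L, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(conds, 2L)
  z <- apply(pairs, 2L, function(p) (rbar[p[1]] - rbar[p[2]]) / se)
  praw <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(
    comparison = apply(pairs, 2L, paste, collapse = " - "),
    estimate = z, p_raw = praw,
    p_adj = stats::p.adjust(praw, method = p_adjust),
    adjust = p_adjust)
  new("TestResult", method = "Friedman test (Dunn post hoc)",
      statistics = stat, pairwise = pw)
}

#' Assemble a censored occlusion-time table
#'
#' Applies [censoredTime()] to a set of labelled occlusion calls and
#' assembles the complete-blocks table expected by [friedmanDunn()].
#'
#' @param calls list of [OcclusionCall-class] objects.
#' @param donor_id character vector of donor labels, one per call.
#' @param condition character vector of condition labels, one per call.
#' @param run_order optional integer vector of run-order positions, recorded
#'   as a covariate column only.
#' @param censor_min optional censoring value overriding the calls' own.
#' @return data.frame with columns `donor_id`, `condition`, `value` (the
#'   censored time in minutes) and, if given, `run_order`.
#' @export
censoredEndpointTable <- function(calls, donor_id, condition,
                                  run_order = NULL, censor_min = NULL) {
  if (length(calls) != length(donor_id) || length(calls) != length(condition))
    stop("'calls', 'donor_id' and 'condition' must have equal length")
  if (anyDuplicated(paste(donor_id, condition, sep = "\r")))
    stop("validation error: duplicate (donor, condition) pair")
  tab <- data.frame(
    donor_id = as.character(donor_id),
    condition = as.character(condition),
    value = vapply(calls, censoredTime, 0, censor_min = censor_min))
  if (!is.null(run_order)) tab$run_order <- as.integer(run_order)
  .checkCompleteBlocks(tab, "donor_id", "condition")
  tab
}
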