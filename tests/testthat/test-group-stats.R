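# Repeated-measures group comparisons

.makeTab2x2 <- function(n, fun) {
  tab <- expand.grid(donor_id = sprintf("d%d", seq_len(n)),
                     quench = c("unquenched", "quenched"),
                     treatment = c("control", "drug"),
                     stringsAsFactors = FALSE)
  tab$value <- fun(tab)
  tab
}

test_that("RM-ANOVA agrees with the explicit sums-of-squares oracle", {
  set.seed(41)
  tab <- .makeTab2x2(6, function(d) rnorm(nrow(d), 10, 2) +
                       2 * (d$treatment == "drug") +
                       1 * (d$quench == "quenched"))
  res <- rmAnova2x2(tab)
  st <- statistics(res)
  orc <- oracleRmAnova2x2(tab$value, tab$quench, tab$treatment, tab$donor_id)
  expect_equal(st$statistic, unname(orc$F[c("A", "B", "AB")]),
               tolerance = 1e-6)
  expect_equal(st$p_value, unname(orc$p[c("A", "B", "AB")]), tolerance = 1e-6)
  expect_equal(st$df1, rep(1, 3))
  expect_equal(st$df2, rep(5, 3))
  # Tukey pairwise: all 6 cell comparisons present with p in [0,1]
  pw <- pairwise(res)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
})

test_that("degenerate RM-ANOVA inputs give F = 0, p = 1", {
  tab <- .makeTab2x2(5, function(d) rep(7, nrow(d)))
  # aov warns about the perfect fit; the degenerate rule is what we check
  st <- statistics(suppressWarnings(rmAnova2x2(tab)))
  expect_equal(st$statistic, rep(0, 3))
  expect_equal(st$p_value, rep(1, 3))
  # perfectly additive data: the interaction has exactly zero sum of squares
  tab2 <- .makeTab2x2(5, function(d)
    10 + 2 * (d$treatment == "drug") + 3 * (d$quench == "quenched") +
      as.integer(factor(d$donor_id)) / 10)
  st2 <- statistics(suppressWarnings(rmAnova2x2(tab2)))
  expect_equal(st2$statistic[st2$effect == "quench:treatment"], 0)
  expect_equal(st2$p_value[st2$effect == "quench:treatment"], 1)
})

test_that("RM-ANOVA rejects incomplete blocks", {
  tab <- .makeTab2x2(4, function(d) rnorm(nrow(d)))
  expect_error(rmAnova2x2(tab[-1, ]), "validation")
  dup <- rbind(tab, tab[1, ])
  expect_error(rmAnova2x2(dup), "validation")
})

test_that("Friedman chi-squared matches hand-computed ranks", {
  # hand-rankable: within each donor the ordering is c < a < b, untied
  m <- rbind(c(2, 3, 1), c(5, 9, 4), c(6, 8, 2), c(3, 7, 1))
  tab <- data.frame(donor_id = rep(sprintf("d%d", 1:4), 3),
                    condition = rep(c("a", "b", "c"), each = 4),
                    value = as.vector(m))
  res <- friedmanDunn(tab)
  expect_equal(statistics(res)$statistic, oracleFriedman(m))
  expect_equal(statistics(res)$statistic, 8)  # perfect ordering, k=3, n=4
  expect_equal(statistics(res)$df1, 2)
  # identical columns: no evidence at all
  tabc <- data.frame(donor_id = rep(sprintf("d%d", 1:4), 3),
                     condition = rep(c("a", "b", "c"), each = 4),
                     value = rep(5, 12))
  expect_equal(statistics(friedmanDunn(tabc))$statistic, 0)
  expect_equal(statistics(friedmanDunn(tabc))$p_value, 1)
})

test_that("Friedman is invariant under strictly monotone transforms", {
  set.seed(42)
  tab <- data.frame(donor_id = rep(sprintf("d%d", 1:6), 4),
                    condition = rep(c("a", "b", "c", "d"), each = 6),
                    value = rnorm(24, 20, 5))
  a <- statistics(friedmanDunn(tab))$statistic
  tab$value <- exp(tab$value / 10)
  expect_equal(statistics(friedmanDunn(tab))$statistic, a)
})

test_that("Dunn comparisons rank a censored-vs-fast contrast smallest", {
  set.seed(43)
  tab <- data.frame(
    donor_id = rep(sprintf("d%d", 1:6), 3),
    condition = rep(c("fast", "mid", "censored"), each = 6),
    value = c(rnorm(6, 10, 0.5), rnorm(6, 22, 2), rep(40, 6)))
  pw <- pairwise(friedmanDunn(tab))
  best <- pw$comparison[which.min(pw$p_adj)]
  expect_match(best, "fast")
  expect_match(best, "censored")
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-12))
})

test_that("Friedman type-I error is calibrated under within-donor permutation", {
  set.seed(44)
  n <- 10; k <- 4
  base <- matrix(rnorm(n * k, 15, 3), n, k)
  donors <- sprintf("d%d", seq_len(n))
  reject <- logical(500)
  for (b in 1:500) {
    perm <- t(apply(base, 1, sample))  # permute labels within every donor
    tab <- data.frame(donor_id = rep(donors, k),
                      condition = rep(letters[1:k], each = n),
                      value = as.vector(perm))
    reject[b] <- statistics(friedmanDunn(tab))$p_value < 0.05
  }
  # binomial band around 0.05 at B = 500 (about +/- 3 sd)
  expect_gt(mean(reject), 0.05 - 0.03)
  expect_lt(mean(reject), 0.05 + 0.03)
})

test_that("a strong simulated drug effect is detected at alpha = 0.05", {
  set.seed(45)
  tab <- data.frame(
    donor_id = rep(sprintf("d%d", 1:6), 2),
    condition = rep(c("control", "drug"), each = 6),
    value = c(runif(6, 8, 15), rep(40, 6)))  # all treated censored
  expect_lt(statistics(friedmanDunn(tab))$p_value, 0.05)
})

test_that("censored endpoint tables assemble complete blocks", {
  t <- seq(0, 1800, by = 5)
  occ <- detectOcclusion(flowSeries(t, ifelse(t < 600, 0.02, 0)))
  non <- detectOcclusion(flowSeries(t, rep(0.02, length(t))))
  tab <- censoredEndpointTable(list(occ, non, occ, occ),
                               donor_id = c("d1", "d1", "d2", "d2"),
                               condition = c("ctl", "drug", "ctl", "drug"),
                               run_order = c(1, 2, 2, 1))
  expect_equal(tab$value, c(10, 40, 10, 10))
  expect_equal(tab$run_order, c(1L, 2L, 2L, 1L))
  expect_error(censoredEndpointTable(list(occ, occ), c("d1", "d1"),
                                     c("ctl", "ctl")), "duplicate")
  expect_error(censoredEndpointTable(list(occ, non, occ),
                                     c("d1", "d1", "d2"),
                                     c("ctl", "drug", "ctl")), "validation")
})
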