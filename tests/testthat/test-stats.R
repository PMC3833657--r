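test_that("value distributions reproduce the published marginals", {
  cp <- cge_ccs_corpus()
  d <- value_distribution(cp, "CGE")
  expect_equal(d$count, c(567, 254))
  expect_equal(d$percent, c(69, 31))
  expect_equal(unique(d$denominator), 821)

  ccs <- value_distribution(cp, "CCS")
  expect_equal(ccs$count[ccs$value == "normal->cancer"], 397)
  expect_equal(ccs$percent[ccs$value == "unidentifiable"], 37)

  # IGE denominator excludes skipped values: 2 up / 212 unchanged /
  # 304 unidentifiable over 518 identifiable-CCS units -> 0% / 41% / 59%
  spec <- data.frame(
    ccs = c(rep("normal->cancer", 214), rep("cancer->normal", 304),
            rep("unidentifiable", 303)),
    ige = c(rep("up-regulated", 2), rep("unchanged", 212),
            rep("unidentifiable", 304), rep(NA, 303)),
    cge = "increased",
    pt = c(rep("observation", 518), rep(NA, 303)))
  d <- value_distribution(values_corpus(spec), "IGE")
  expect_equal(unique(d$denominator), 518)
  expect_equal(d$count, c(2, 0, 212, 304))
  expect_equal(d$percent, c(0, 0, 41, 59))

  # degenerate corpus: single value takes 100%
  one <- value_distribution(values_corpus(data.frame(
    cge = rep("increased", 4), ccs = "unidentifiable")), "CGE")
  expect_equal(one$percent, c(100, 0))
  expect_error(value_distribution(cp, "XYZ"), "unknown concept")

  # percentages sum to 100 within integer-rounding slack
  syn <- generate_corpus(default_generator_config(n_units = 500, seed = 2))
  for (concept in c("CGE", "CCS", "IGE", "PT")) {
    d <- value_distribution(syn, concept)
    expect_lte(abs(sum(d$percent) - 100), 1)
  }
})

test_that("corpus cross-tabulation matches an independent tally", {
  cp <- cge_ccs_corpus()
  ct <- contingency(cp, "CGE", "CCS")
  expect_equal(unname(ct$observed), unname(cge_ccs_counts()))
  # never-observed CCS values are dropped
  expect_identical(colnames(ct$observed),
                   c("normal->cancer", "cancer->normal", "unidentifiable"))

  # minimal 2x2
  four <- values_corpus(data.frame(
    cge = c("increased", "increased", "decreased", "decreased"),
    ccs = rep(c("normal->cancer", "cancer->normal"), 2),
    ige = "unidentifiable",
    pt = rep(c("observation", "causality"), each = 2)))
  ct4 <- contingency(four, "CGE", "CCS")
  expect_equal(unname(ct4$observed), matrix(1L, 2, 2))

  # independent group-by tally on a synthetic corpus
  syn <- generate_corpus(default_generator_config(n_units = 2000, seed = 11))
  ct <- contingency(syn, "CGE", "CCS")
  df <- as.data.frame(syn)
  for (r in rownames(ct$observed))
    for (cc in colnames(ct$observed))
      expect_equal(ct$observed[r, cc], sum(df$cge == r & df$ccs == cc),
                   label = paste(r, cc))

  # IGE tables only use identifiable-CCS units
  cti <- contingency(syn, "IGE", "CCS")
  expect_false("unidentifiable" %in% colnames(cti$observed))
  expect_equal(sum(cti$observed), sum(df$ccs != "unidentifiable"))
  expect_error(contingency(syn, "IGE", "CCS",
                           ccs_filter = c("unidentifiable")),
               "must exclude")
  expect_error(contingency(syn, "CGE", "CGE"), "must differ")
})

test_that("Pearson residuals reproduce the published cells", {
  ct <- contingency_table(cge_ccs_counts(), "CGE", "CCS")
  R <- pearson_residuals(ct)
  expect_equal(round(R["increased", "normal->cancer"], 2), 2.65)
  expect_equal(round(R["decreased", "cancer->normal"], 2), 6.30)
  # row sums of observed - expected vanish
  expect_equal(max(abs(rowSums(ct$observed - ct$expected))), 0,
               tolerance = 1e-9)
  expect_equal(sum(ct$expected), ct$n, tolerance = 1e-9)

  # a table with O = E everywhere has all-zero residuals
  flat <- contingency_table(matrix(10, 2, 2))
  expect_equal(unname(pearson_residuals(flat)), matrix(0, 2, 2))

  zero <- contingency_table(matrix(c(3, 5, 0, 0), 2, byrow = TRUE,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(pearson_residuals(zero), "zero row margin.*b")
  zcol <- contingency_table(matrix(c(3, 0, 5, 0), 2, byrow = TRUE,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(pearson_residuals(zcol), "zero column margin.*y")
})

test_that("chi-square equals the sum of squared residuals", {
  ct <- contingency_table(cge_ccs_counts(), "CGE", "CCS")
  t <- chi_square_test(ct)
  expect_lt(t$p.value, 2.2e-16)
  expect_equal(t$df, 2)
  expect_equal(t$statistic, sum(pearson_residuals(ct)^2))
  expect_identical(format_p_value(t$p.value), "<2.2e-16")

  flat <- contingency_table(matrix(10, 2, 2))
  tf <- chi_square_test(flat)
  expect_equal(tf$statistic, 0)
  expect_equal(tf$p.value, 1)

  # random small tables: agreement cell-by-cell and with the stock test
  set.seed(5)
  for (i in 1:10) {
    O <- matrix(rpois(6, 8) + 1, 2, 3)
    ct <- contingency_table(O)
    t <- chi_square_test(ct)
    direct <- sum((O - ct$expected)^2 / ct$expected)
    expect_equal(t$statistic, direct)
    ref <- suppressWarnings(chisq.test(O, correct = FALSE))
    expect_equal(t$statistic, unname(ref$statistic))
    expect_equal(t$p.value, ref$p.value)
  }
})

test_that("odds ratios match the published one-decimal truncations", {
  pt_ccs <- contingency_table(
    matrix(c(311, 86, 43, 78), 2,
           dimnames = list(c("observation", "causality"),
                           c("normal->cancer", "cancer->normal"))),
    "PT", "CCS")
  or <- odds_ratio(pt_ccs)
  expect_equal(or, (311 * 78) / (43 * 86))
  expect_equal(truncate_decimal(or), 6.5)

  pt_ige <- contingency_table(
    matrix(c(191, 21, 163, 141), 2,
           dimnames = list(c("observation", "causality"),
                           c("unchanged", "unidentifiable"))),
    "PT", "IGE")
  expect_equal(truncate_decimal(odds_ratio(pt_ige)), 7.8)

  # proportional rows give OR = 1; swapping rows inverts the ratio
  prop <- contingency_table(matrix(c(10, 20, 30, 60), 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(odds_ratio(prop), 1)
  expect_equal(odds_ratio(pt_ccs, rows = c("causality", "observation")),
               1 / odds_ratio(pt_ccs))

  withzero <- contingency_table(matrix(c(5, 3, 0, 7), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("x", "y"))))
  expect_error(odds_ratio(withzero), "zero denominator")
  expect_equal(odds_ratio(withzero, correction = TRUE),
               (5.5 * 7.5) / (0.5 * 3.5))
})

test_that("the stratified test accepts independence and detects dependence", {
  # two identical independent strata -> p near 1
  blk <- expand.grid(cge = c("increased", "decreased"),
                     pt = c("observation", "causality"),
                     ccs = c("normal->cancer", "cancer->normal"),
                     stringsAsFactors = FALSE)
  blk$n <- 20
  blk$ige <- "unidentifiable"
  flat <- values_corpus(expand_counts(blk))
  res <- stratified_independence_test(flat, "CGE", "PT")
  expect_gt(res$p.value, 0.9)
  expect_equal(res$n_strata_used, 2)

  # strong within-stratum dependence -> tiny p
  dep <- expand_counts(data.frame(
    cge = rep(c("increased", "decreased"), 2),
    pt = rep(c("observation", "causality"), 2),
    ccs = rep(c("normal->cancer", "cancer->normal"), each = 2),
    ige = "unidentifiable",
    n = c(58, 58, 58, 58)))
  # add a sprinkle of off-diagonal so margins are positive
  off <- expand_counts(data.frame(
    cge = rep(c("increased", "decreased"), 2),
    pt = rep(c("causality", "observation"), 2),
    ccs = rep(c("normal->cancer", "cancer->normal"), each = 2),
    ige = "unidentifiable",
    n = 2))
  both <- rbind(dep, off)
  res <- stratified_independence_test(values_corpus(both), "CGE", "PT")
  expect_lt(res$p.value, 0.01)

  # type-I error calibration: concepts sampled independently given CCS
  set.seed(31)
  rejections <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    syn <- generate_corpus(default_generator_config(n_units = 600,
                                                    seed = 1000 + i))
    p <- stratified_independence_test(syn, "CGE", "PT")$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  # binomial(60, .05): 3 +/- 3 sd keeps the rate below ~0.14
  expect_lte(rejections / n_rep, 0.14)
})

test_that("rule distribution reproduces the published shares", {
  cp <- rule_totals_corpus()
  rd <- rule_distribution(cp)
  expect_equal(unname(rd$counts["7", "Total"]), 311)
  expect_equal(unname(rd$counts["none", "Total"]), 303)
  expect_equal(unname(rd$column_totals["Total"]), 821)
  expect_equal(unname(rd$percent["7", "Total"]), 38)
  expect_equal(unname(rd$class_percent["biomarker", "Total"]), 43)
  expect_equal(unname(rd$class_percent["oncogene", "Total"]), 14)
  expect_equal(unname(rd$class_percent["tumor_suppressor_gene", "Total"]), 6)
  expect_equal(unname(rd$class_percent["not_related", "Total"]), 37)
  # class shares sum to 100 within rounding slack
  expect_lte(abs(sum(rd$class_percent[, "Total"]) - 100), 1)

  empty <- rule_distribution(corpus(list()))
  expect_true(all(empty$counts == 0))

  # per-rule counts equal an independent unit-wise tally
  syn <- generate_corpus(default_generator_config(n_units = 2000, seed = 5))
  rd <- rule_distribution(syn)
  df <- as.data.frame(syn)
  ids <- mapply(match_rule, df$cge, df$ccs, df$ige, df$pt)
  for (r in as.character(1:10))
    expect_equal(unname(rd$counts[r, "Total"]),
                 sum(!is.na(ids) & ids == as.integer(r)), label = r)
  expect_equal(unname(rd$counts["none", "Total"]), sum(is.na(ids)))
})
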