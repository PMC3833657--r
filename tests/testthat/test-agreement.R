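test_that("simple agreement is the proportion of agreed pairs", {
  p <- agreement_pairs("CGE", c("increased", "increased"),
                       c("increased", "decreased"))
  expect_equal(simple_agreement(p), 0.5)
  expect_equal(simple_agreement(agreement_pairs("PT", "causality",
                                                "causality")), 1)
  expect_error(simple_agreement(agreement_pairs("CGE", character(0),
                                                character(0))), "empty")
  expect_error(agreement_pairs("CGE", "increased", "huge"), "inadmissible")

  # Monte-Carlo recovery of a known flip rate
  set.seed(101)
  vals <- concept_values("CCS")
  a <- sample(vals, 10000, replace = TRUE)
  b <- ifelse(runif(10000) < 0.2,
              vapply(a, function(v) sample(setdiff(vals, v), 1),
                     character(1)), a)
  expect_equal(simple_agreement(agreement_pairs("CCS", a, b)), 0.8,
               tolerance = 0.015)
})

test_that("Cohen's kappa corrects for chance and degenerates to N/A", {
  # perfect agreement over >= 2 used categories
  p <- agreement_pairs("CGE", c("increased", "decreased"),
                       c("increased", "decreased"))
  expect_equal(cohen_kappa(p), 1)

  # po = pe = 0.5 -> kappa 0
  p0 <- agreement_pairs("CGE",
                        c("increased", "increased", "decreased", "decreased"),
                        c("increased", "decreased", "increased", "decreased"))
  expect_equal(cohen_kappa(p0), 0)

  # one single category used by both annotators: pe = 1, kappa undefined
  pu <- agreement_pairs("IGE", rep("unidentifiable", 10),
                        rep("unidentifiable", 10))
  expect_true(is.na(cohen_kappa(pu)))

  # asymmetric case against a direct po/pe computation
  p2 <- agreement_pairs("PT",
                        c(rep("observation", 7), rep("causality", 3)),
                        c(rep("observation", 5), rep("causality", 2),
                          "observation", rep("causality", 2)))
  po <- mean(p2$a == p2$b)
  pe <- mean(p2$a == "observation") * mean(p2$b == "observation") +
    mean(p2$a == "causality") * mean(p2$b == "causality")
  expect_equal(po, 0.7)
  expect_equal(pe, 0.54)
  expect_equal(cohen_kappa(p2), (po - pe) / (1 - pe))
})

test_that("G-index uses the pre-specified category count", {
  # po = 1 for any k
  expect_equal(g_index(agreement_pairs("CCS", rep("unidentifiable", 3),
                                       rep("unidentifiable", 3))), 1)

  # published overall IGE cell: po = 0.98 with k = 4 -> 0.97 (2 dp)
  a <- rep("unidentifiable", 100)
  b <- c(rep("unidentifiable", 98), "unchanged", "unchanged")
  p <- agreement_pairs("IGE", a, b)
  expect_equal(simple_agreement(p), 0.98)
  expect_equal(round(g_index(p), 2), 0.97)
  expect_equal(g_index(p), (0.98 - 0.25) / 0.75)

  # direct formula check at po = 0.5, k = 4
  p5 <- agreement_pairs("IGE", c("unchanged", "unchanged"),
                        c("unchanged", "unidentifiable"))
  expect_equal(g_index(p5), (0.5 - 0.25) / 0.75, tolerance = 1e-12)
})

test_that("chance correction never raises agreement; G is relabel-invariant", {
  set.seed(202)
  for (i in 1:25) {
    concept <- sample(c("CGE", "CCS", "IGE", "PT"), 1)
    vals <- concept_values(concept)
    n <- sample(5:60, 1)
    a <- sample(vals, n, replace = TRUE)
    b <- ifelse(runif(n) < 0.3,
                vapply(a, function(v) sample(setdiff(vals, v), 1),
                       character(1)), a)
    p <- agreement_pairs(concept, a, b)
    po <- simple_agreement(p)
    k <- cohen_kappa(p)
    if (!is.na(k)) expect_lte(k, po + 1e-12)
    expect_lte(g_index(p), po + 1e-12)

    # relabeling categories by a permutation leaves G (and kappa) unchanged
    perm <- setNames(sample(vals), vals)
    pp <- agreement_pairs(concept, unname(perm[a]), unname(perm[b]))
    expect_equal(g_index(pp), g_index(p))
    if (!is.na(k)) expect_equal(cohen_kappa(pp), k)
  }
})

test_that("validation records get the right match level", {
  rec <- data.frame(
    rule_id = c(7L, 1L, 1L),
    inferred_class = c("biomarker", "oncogene", "oncogene"),
    annot1_class = c("biomarker", "biomarker", "biomarker"),
    annot2_class = c("biomarker", "oncogene", "biomarker"))
  scored <- score_validation(rec)
  expect_identical(scored$match_level, c("full", "one", "none"))
  expect_error(score_validation(transform(rec, annot1_class = "gene")),
               "inadmissible")
})

test_that("validation summary reproduces the published micro and macro rates", {
  vs <- validation_summary(validation_records())
  t <- vs$table
  expect_equal(t$total[t$rule == "7"], 30)
  expect_equal(t$rate[t$rule == "7"], 29 / 30)
  expect_equal(t$rate[t$rule == "none"], 40 / 42, tolerance = 1e-12)
  expect_true(all(is.na(t$rate[t$rule %in% c("5", "6", "9", "10")])))
  expect_equal(sum(t$total), 92)
  expect_equal(vs$micro, 87 / 92)
  expect_equal(round_half_up(100 * vs$micro), 95)
  expect_equal(round_half_up(100 * vs$macro), 89)

  # micro is the total-weighted mean of the per-row rates
  pop <- t[t$total > 0, ]
  expect_equal(vs$micro, sum(pop$rate * pop$total) / sum(pop$total))
  expect_equal(vs$macro, mean(pop$rate))

  # all-full records give micro = macro = 1
  allfull <- data.frame(rule_id = c(1L, 7L, NA), inferred_class = "biomarker",
                        annot1_class = "biomarker",
                        annot2_class = "biomarker")
  allfull$inferred_class <- c("oncogene", "biomarker", "not_related")
  allfull$annot1_class <- allfull$inferred_class
  allfull$annot2_class <- allfull$inferred_class
  vs1 <- validation_summary(allfull)
  expect_equal(vs1$micro, 1)
  expect_equal(vs1$macro, 1)

  # micro equals a flat recount of match levels on random records
  set.seed(303)
  classes <- c("oncogene", "tumor_suppressor_gene", "biomarker",
               "not_related")
  rec <- data.frame(rule_id = sample(c(1:10, NA), 200, replace = TRUE),
                    inferred_class = sample(classes, 200, replace = TRUE),
                    annot1_class = sample(classes, 200, replace = TRUE),
                    annot2_class = sample(classes, 200, replace = TRUE))
  scored <- score_validation(rec)
  vs2 <- validation_summary(scored)
  expect_equal(vs2$micro, mean(scored$match_level %in% c("full", "one")))
})

test_that("pair and validation files round-trip through their readers", {
  d <- tempfile(); dir.create(d)
  pf <- file.path(d, "pairs.tsv")
  writeLines(c("unit_id\tconcept\tannotator_a\tannotator_b",
               "u1\tCGE\tincreased\tincreased",
               "u2\tCGE\tincreased\tdecreased",
               "u1\tPT\tobservation\tobservation"), pf)
  ps <- read_pair_file(pf)
  expect_named(ps, c("CGE", "PT"))
  expect_equal(simple_agreement(ps$CGE), 0.5)

  vf <- file.path(d, "val.tsv")
  writeLines(c("unit_id\trule_id\tinferred_class\tannot1_class\tannot2_class",
               "u1\t7\tbiomarker\tbiomarker\tbiomarker",
               "u2\t-\tnot_related\tnot_related\tbiomarker"), vf)
  rec <- read_validation_file(vf)
  expect_identical(rec$match_level, c("full", "one"))
  expect_true(is.na(rec$rule_id[2]))
  unlink(d, recursive = TRUE)
})
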