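# fixture builders shared across test files; everything is constructed in
# code so no binary fixtures are needed

# one unit with a mechanically realized sentence and exact spans
fixture_unit <- function(id, cge, ccs, ige = NA_character_, pt = NA_character_,
                         gene = "TP53", cancer_type = "prostate",
                         term = "prostate cancer", kw = NULL) {
  if (is.null(kw)) kw <- if (identical(cge, "increased")) "overexpressed"
                         else "reduced"
  s <- paste0(gene, " is ", kw, " in ", term)
  annotation_unit(
    id, s,
    gene = span(gene, 0, nchar(gene)),
    expression_keywords = list(span(kw, nchar(gene) + 4L,
                                    nchar(gene) + 4L + nchar(kw))),
    cancer_terms = list(span(term, nchar(s) - nchar(term), nchar(s))),
    cge = cge, ccs = ccs, ige = ige, pt = pt, cancer_type = cancer_type)
}

# corpus from a data frame of concept values (one row per unit)
values_corpus <- function(df) {
  units <- lapply(seq_len(nrow(df)), function(i)
    fixture_unit(sprintf("f%05d", i), df$cge[i], df$ccs[i],
                 if ("ige" %in% names(df)) df$ige[i] else NA_character_,
                 if ("pt" %in% names(df)) df$pt[i] else NA_character_,
                 cancer_type = if ("cancer_type" %in% names(df))
                   df$cancer_type[i] else "prostate"))
  corpus(units)
}

# repeat rows of concept values n times each
expand_counts <- function(spec) {
  spec[rep(seq_len(nrow(spec)), spec$n), setdiff(names(spec), "n"),
       drop = FALSE]
}

# the three published worked examples, with their real sentences
worked_example_units <- function() {
  s1 <- "Cdc25B is frequently overexpressed in human prostate cancer tissues"
  u1 <- annotation_unit(
    "ex1", s1, gene = span("Cdc25B", 0, 6),
    expression_keywords = list(span("overexpressed", 21, 34)),
    cancer_terms = list(span("prostate cancer", 44, 59)),
    cge = "increased", ccs = "normal->cancer", ige = "unchanged",
    pt = "observation", pmid = "12569365", cancer_type = "prostate")
  s2 <- "Downregulation of protein kinase C suppresses induction of apoptosis in human prostatic carcinoma cells"
  u2 <- annotation_unit(
    "ex2", s2, gene = span("protein kinase C", 18, 34),
    expression_keywords = list(span("Downregulation", 0, 14)),
    cancer_terms = list(span("prostatic carcinoma", 78, 97)),
    cge = "decreased", ccs = "normal->cancer", ige = "unidentifiable",
    pt = "causality", pmid = "8612685", cancer_type = "prostate")
  s3 <- "Suppression of CLU expression sensitizes prostate cancer cells to chemotherapeutic drugs"
  u3 <- annotation_unit(
    "ex3", s3, gene = span("CLU", 15, 18),
    expression_keywords = list(span("Suppression", 0, 11),
                               span("expression", 19, 29)),
    cancer_terms = list(span("prostate cancer", 41, 56)),
    cge = "decreased", ccs = "cancer->normal", ige = "up-regulated",
    pt = "causality", pmid = "19879420", cancer_type = "prostate")
  list(u1, u2, u3)
}

# published pairwise CGE x CCS counts (all 821 units)
cge_ccs_counts <- function() {
  matrix(c(318, 79, 45, 76, 204, 99), nrow = 2,
         dimnames = list(c("increased", "decreased"),
                         c("normal->cancer", "cancer->normal",
                           "unidentifiable")))
}

# a corpus inducing the published CGE x CCS counts; IGE/PT filled with any
# admissible value for identifiable CCS
cge_ccs_corpus <- function() {
  O <- cge_ccs_counts()
  spec <- expand.grid(cge = rownames(O), ccs = colnames(O),
                      stringsAsFactors = FALSE)
  spec$n <- as.vector(O)
  df <- expand_counts(spec)
  df$ige <- ifelse(df$ccs == "unidentifiable", NA, "unidentifiable")
  df$pt <- ifelse(df$ccs == "unidentifiable", NA, "observation")
  values_corpus(df)
}

# published per-rule application totals; one concrete matching tuple per rule
rule_total_counts <- function() {
  data.frame(
    rule = c(1:10, NA),
    n = c(69, 43, 2, 17, 33, 0, 311, 43, 0, 0, 303))
}

rule_tuple_for <- function(rule) {
  switch(as.character(rule),
    "1" = c("increased", "normal->cancer", "unidentifiable", "causality"),
    "2" = c("decreased", "cancer->normal", "unidentifiable", "causality"),
    "3" = c("decreased", "cancer->normal", "up-regulated", "causality"),
    "4" = c("decreased", "normal->cancer", "unidentifiable", "causality"),
    "5" = c("increased", "cancer->normal", "unidentifiable", "causality"),
    "6" = c("increased", "cancer->normal", "down-regulated", "observation"),
    "7" = c("increased", "normal->cancer", "unchanged", "observation"),
    "8" = c("increased", "cancer->normal", "unidentifiable", "observation"),
    "9" = c("decreased", "cancer->cancer", "up-regulated", "observation"),
    "10" = c("increased", "cancer->cancer", "down-regulated", "observation"),
    c("increased", "unidentifiable", NA, NA))
}

# corpus whose per-rule classification counts equal the published totals
rule_totals_corpus <- function() {
  rc <- rule_total_counts()
  rows <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i) {
    if (rc$n[i] == 0) return(NULL)
    t <- rule_tuple_for(rc$rule[i])
    data.frame(cge = t[1], ccs = t[2], ige = t[3], pt = t[4],
               n = rc$n[i], stringsAsFactors = FALSE)
  }))
  values_corpus(expand_counts(rows))
}

# published rule-validation per-row (full, one, none) counts
validation_counts <- function() {
  data.frame(
    rule_id = c(1, 2, 3, 4, 7, 8, NA),
    full = c(4, 3, 1, 2, 28, 6, 40),
    one = c(0, 0, 0, 0, 1, 2, 0),
    none = c(1, 0, 1, 0, 1, 0, 2))
}

# expand the counts into per-unit validation records
validation_records <- function() {
  vc <- validation_counts()
  rules <- builtin_rules()
  other <- function(cls) setdiff(c("oncogene", "tumor_suppressor_gene",
                                   "biomarker", "not_related"), cls)[1]
  rows <- do.call(rbind, lapply(seq_len(nrow(vc)), function(i) {
    cls <- if (is.na(vc$rule_id[i])) "not_related"
           else rules$gene_class[rules$rule_id == vc$rule_id[i]]
    mk <- function(n, a1, a2) {
      if (n == 0) return(NULL)
      data.frame(rule_id = rep(vc$rule_id[i], n), inferred_class = cls,
                 annot1_class = a1, annot2_class = a2,
                 stringsAsFactors = FALSE)
    }
    rbind(mk(vc$full[i], cls, cls),
          mk(vc$one[i], cls, other(cls)),
          mk(vc$none[i], other(cls), other(cls)))
  }))
  rows$unit_id <- sprintf("v%03d", seq_len(nrow(rows)))
  rows
}

# brute-force oracle for the longest-match tagger: enumerate every
# (position, term) candidate with token-boundary checks, then apply
# leftmost-longest selection with resume-after-match
oracle_longest_match <- function(text, dictionary) {
  n <- nchar(text)
  chars <- if (n) strsplit(text, "")[[1]] else character(0)
  w <- grepl("[[:alnum:]]", chars)
  cands <- list()
  for (term in unique(tolower(dictionary))) {
    L <- nchar(term)
    if (L > n) next
    for (i in 0:(n - L)) {
      j <- i + L
      if (tolower(substr(text, i + 1, j)) != term) next
      if (!(w[i + 1] && (i == 0 || !w[i]))) next          # start boundary
      if (!(w[j] && (j == n || !w[j + 1]))) next          # end boundary
      cands[[length(cands) + 1]] <- c(start = i, end = j)
    }
  }
  if (!length(cands)) return(list())
  cdf <- do.call(rbind, cands)
  cdf <- cdf[order(cdf[, "start"], -cdf[, "end"]), , drop = FALSE]
  out <- list()
  pos <- 0
  for (r in seq_len(nrow(cdf))) {
    if (cdf[r, "start"] < pos) next
    # sort order guarantees the first candidate at or after `pos` has the
    # smallest start, longest term first
    out[[length(out) + 1]] <- span(substr(text, cdf[r, "start"] + 1,
                                          cdf[r, "end"]),
                                   cdf[r, "start"], cdf[r, "end"])
    pos <- cdf[r, "end"]
  }
  out
}
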