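#' Round half up
#'
#' Integer rounding with ties away from zero for non-negative input
#' (`0.5 -> 1`), the convention used for all printed percentages.
#'
#' @param x Numeric vector (non-negative in the intended use).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Truncate to a fixed number of decimals
#'
#' Paper-parity formatter for odds ratios: values are truncated, not
#' rounded (6.56 prints as 6.5).
#'
#' @param x Numeric vector.
#' @param digits Number of decimals kept.
#' @return Truncated numeric vector.
#' @export
truncate_decimal <- function(x, digits = 1L) {
  f <- 10^digits
  trunc(x * f) / f
}

#' Display formatter for p-values
#'
#' Values below the double-precision reporting floor are shown as
#' `"<2.2e-16"`; the raw value is never altered.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 2.2e-16, "<2.2e-16", format(signif(p, 3L)))
}

#' Distribution of a concept's values
#'
#' Counts and integer percentages of one concept's values, over the whole
#' corpus and optionally per cancer type. Units whose concept is skipped
#' (`NA`, possible for IGE/PT when CCS is unidentifiable) are excluded
#' from the denominator, so IGE/PT denominators are the units with
#' identifiable CCS. Percentages are rounded half up.
#'
#' @param corpus An `annotation_corpus`.
#' @param concept `"CGE"`, `"CCS"`, `"IGE"` or `"PT"`.
#' @param by_cancer_type Also report one block per cancer type.
#' @return A data frame of class `distribution_table` with columns
#'   `group`, `value`, `count`, `percent`, `denominator`.
#' @export
value_distribution <- function(corpus, concept, by_cancer_type = FALSE) {
  vals <- concept_values(concept)  # errors on unknown concept
  df <- as.data.frame(corpus)
  col <- tolower(concept)
  groups <- if (by_cancer_type) c(unique(df$cancer_type), "Total") else "Total"
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- if (g == "Total") df[[col]] else df[[col]][df$cancer_type == g]
    x <- x[!is.na(x)]
    denom <- length(x)
    count <- vapply(vals, function(v) sum(x == v), integer(1))
    data.frame(group = g, value = vals, count = count,
               percent = if (denom > 0) round_half_up(100 * count / denom)
                         else rep(0, length(vals)),
               denominator = denom, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("distribution_table", "data.frame")
  out
}

#' Contingency table with expected counts and Pearson residuals
#'
#' @param observed Integer matrix of observed counts with dimnames.
#' @param row_concept,col_concept Names of the row/column concepts (for
#'   labeling only).
#' @return Object of class `contingency_table`: a list with `observed`,
#'   `expected`, `residuals`, `n`, `row_concept`, `col_concept`.
#' @export
contingency_table <- function(observed, row_concept = "", col_concept = "") {
  observed <- as.matrix(observed)
  stopifnot(is.numeric(observed), all(observed >= 0))
  n <- sum(observed)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  rt <- rowSums(observed)
  ct <- colSums(observed)
  expected <- outer(rt, ct) / n
  residuals <- (observed - expected) / sqrt(expected)
  structure(list(observed = observed, expected = expected,
                 residuals = residuals, n = n,
                 row_concept = row_concept, col_concept = col_concept),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, digits = 2L, ...) {
  cat(sprintf("<contingency_table %s x %s, n = %d>\n",
              x$row_concept, x$col_concept, as.integer(x$n)))
  m <- matrix(sprintf("%d (%.*f)", as.integer(x$observed), digits,
                      x$residuals),
              nrow = nrow(x$observed), dimnames = dimnames(x$observed))
  print(m, quote = FALSE)
  invisible(x)
}

#' Cross-tabulate two concepts over a corpus
#'
#' Builds the observed-count contingency table of two concepts. When
#' either concept is IGE or PT, only units with identifiable CCS qualify
#' (IGE/PT are skipped when CCS is unidentifiable), so `ccs_filter`
#' defaults to the identifiable CCS values. Rows or columns whose counts
#' are all zero (concept values never observed) are dropped before any
#' testing.
#'
#' @param corpus An `annotation_corpus`.
#' @param row_concept,col_concept Distinct concept names.
#' @param ccs_filter Optional subset of CCS values a unit must have to be
#'   counted. Must exclude `"unidentifiable"` when IGE or PT is involved.
#' @return A [contingency_table()].
#' @export
contingency <- function(corpus, row_concept, col_concept, ccs_filter = NULL) {
  if (identical(row_concept, col_concept))
    stop("row and column concepts must differ", call. = FALSE)
  rv <- concept_values(row_concept)
  cv <- concept_values(col_concept)
  needs_id_ccs <- any(c(row_concept, col_concept) %in% c("IGE", "PT"))
  if (is.null(ccs_filter) && needs_id_ccs)
    ccs_filter <- setdiff(concept_values("CCS"), "unidentifiable")
  if (needs_id_ccs && "unidentifiable" %in% ccs_filter)
    stop("ccs_filter must exclude 'unidentifiable' when IGE or PT is tabulated",
         call. = FALSE)
  df <- as.data.frame(corpus)
  if (!is.null(ccs_filter)) df <- df[df$ccs %in% ccs_filter, , drop = FALSE]
  r <- df[[tolower(row_concept)]]
  cc <- df[[tolower(col_concept)]]
  keep <- !is.na(r) & !is.na(cc)
  r <- r[keep]; cc <- cc[keep]
  O <- table(factor(r, levels = rv), factor(cc, levels = cv))
  O <- matrix(as.integer(O), nrow = length(rv),
              dimnames = list(rv, cv))
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  if (length(O) == 0L || sum(O) == 0L)
    stop("no qualifying units after filtering", call. = FALSE)
  contingency_table(O, row_concept, col_concept)
}

#' Pearson residuals of a contingency table
#'
#' `(O - E) / sqrt(E)` with `E = row_total * col_total / n`. The squared
#' residuals sum to the chi-square statistic.
#'
#' @param table A [contingency_table()].
#' @return Numeric matrix of residuals.
#' @export
pearson_residuals <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  check_margins(table)
  table$residuals
}

check_margins <- function(table) {
  rt <- rowSums(table$observed)
  ct <- colSums(table$observed)
  if (any(rt == 0))
    stop("zero row margin for ", dQuote(names(rt)[rt == 0][1]), call. = FALSE)
  if (any(ct == 0))
    stop("zero column margin for ", dQuote(names(ct)[ct == 0][1]),
         call. = FALSE)
  invisible(TRUE)
}

#' Chi-square test of independence
#'
#' Pearson chi-square without continuity correction; the statistic is the
#' sum of squared Pearson residuals, `df = (r-1)(c-1)`, and the p-value is
#' the upper tail of the corresponding chi-square distribution.
#'
#' @param table A [contingency_table()].
#' @return A list of class `concept_test` with `statistic`, `df`,
#'   `p.value`, `method`.
#' @export
chi_square_test <- function(table) {
  R <- pearson_residuals(table)
  stat <- sum(R^2)
  df <- (nrow(R) - 1L) * (ncol(R) - 1L)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Pearson chi-square test of independence"),
            class = "concept_test")
}

#' @export
print.concept_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p %s\n", x$statistic, x$df,
              ifelse(x$p.value < 2.2e-16, "<2.2e-16",
                     paste("=", format(signif(x$p.value, 3))))))
  if (!is.null(x$n_strata_dropped) && x$n_strata_dropped > 0)
    cat(sprintf("  (%d stratum/strata dropped for zero margins)\n",
                x$n_strata_dropped))
  invisible(x)
}

#' Odds ratio of a 2x2 sub-table
#'
#' `OR = (O[r1,c1] * O[r2,c2]) / (O[r1,c2] * O[r2,c1])` over the selected
#' row and column labels; full precision is returned. Use
#' [truncate_decimal()] for the printed one-decimal form.
#'
#' @param table A [contingency_table()].
#' @param rows,cols Pairs of row/column labels; default the first two of
#'   each.
#' @param correction Apply the Haldane-Anscombe +0.5 correction to all
#'   four cells (required to obtain a finite ratio with a zero cell).
#' @return The odds ratio as a single number.
#' @export
odds_ratio <- function(table, rows = NULL, cols = NULL, correction = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  O <- table$observed
  if (is.null(rows)) rows <- rownames(O)[1:2]
  if (is.null(cols)) cols <- colnames(O)[1:2]
  if (!all(rows %in% rownames(O)) || !all(cols %in% colnames(O)))
    stop("selected labels not present in the table", call. = FALSE)
  m <- O[rows, cols]
  if (correction) m <- m + 0.5
  if (m[1, 2] == 0 || m[2, 1] == 0)
    stop("zero denominator cell; use correction = TRUE for a finite ratio",
         call. = FALSE)
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Stratified test of conditional independence
#'
#' Cochran-Mantel-Haenszel pooled test of independence between two
#' concepts within strata defined by CCS values, without continuity
#' correction. Strata with a zero row or column margin are dropped with a
#' warning and counted in the result.
#'
#' @param corpus An `annotation_corpus`.
#' @param concept_a,concept_b Distinct concepts to test.
#' @param strata CCS values defining the strata (default: the identifiable
#'   directions `normal->cancer` and `cancer->normal`).
#' @return A `concept_test` list with `statistic`, `df`, `p.value`,
#'   `method`, `n_strata_used`, `n_strata_dropped`.
#' @export
stratified_independence_test <- function(corpus, concept_a, concept_b,
                                         strata = c("normal->cancer",
                                                    "cancer->normal")) {
  if (length(strata) == 0L) stop("strata must be non-empty", call. = FALSE)
  df <- as.data.frame(corpus)
  df <- df[df$ccs %in% strata, , drop = FALSE]
  a <- df[[tolower(concept_a)]]
  b <- df[[tolower(concept_b)]]
  keep <- !is.na(a) & !is.na(b)
  df <- df[keep, , drop = FALSE]; a <- a[keep]; b <- b[keep]
  # common levels: values observed anywhere in the pooled data
  la <- intersect(concept_values(concept_a), unique(a))
  lb <- intersect(concept_values(concept_b), unique(b))
  if (length(la) < 2L || length(lb) < 2L)
    stop("fewer than two observed values for a concept; cannot test",
         call. = FALSE)
  slabs <- intersect(strata, unique(df$ccs))
  tabs <- lapply(slabs, function(s) {
    sel <- df$ccs == s
    table(factor(a[sel], levels = la), factor(b[sel], levels = lb))
  })
  ok <- vapply(tabs, function(t) all(rowSums(t) > 0) && all(colSums(t) > 0),
               logical(1))
  dropped <- sum(!ok)
  if (dropped > 0)
    warning(sprintf("%d stratum/strata dropped for zero margins", dropped),
            call. = FALSE)
  tabs <- tabs[ok]
  if (length(tabs) == 0L) stop("no usable strata", call. = FALSE)
  arr <- array(unlist(tabs), dim = c(length(la), length(lb), length(tabs)),
               dimnames = list(la, lb, slabs[ok]))
  ht <- stats::mantelhaen.test(arr, correct = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value,
                 method = "Cochran-Mantel-Haenszel test (no correction)",
                 n_strata_used = length(tabs), n_strata_dropped = dropped),
            class = "concept_test")
}

#' Distribution of applied inference rules
#'
#' Tabulates which rule classified each unit (ids 1-10 plus "No rule
#' applied"), per cancer type and in total, with column percentages
#' (rounded half up). Gene-class shares aggregate the per-rule counts
#' through the rule table's own rule-to-class mapping.
#'
#' @param corpus An `annotation_corpus`.
#' @param rules A `rule_table`.
#' @return A list of class `rule_distribution`: `counts` and `percent`
#'   matrices (rows = rules and `"none"`, columns = cancer types and
#'   `"Total"`), and `class_counts` / `class_percent` for the gene-class
#'   aggregation.
#' @export
rule_distribution <- function(corpus, rules = builtin_rules()) {
  cl <- classify_corpus(corpus, rules)
  types <- unique(cl$cancer_type)
  cols <- c(types, "Total")
  rows <- c(as.character(rules$rule_id), "none")
  counts <- matrix(0L, nrow = length(rows), ncol = length(cols),
                   dimnames = list(rows, cols))
  for (g in cols) {
    sub <- if (g == "Total") cl else cl[cl$cancer_type == g, , drop = FALSE]
    rid <- ifelse(is.na(sub$rule_id), "none", as.character(sub$rule_id))
    t <- table(factor(rid, levels = rows))
    counts[, g] <- as.integer(t)
  }
  totals <- colSums(counts)
  percent <- counts
  for (g in cols)
    percent[, g] <- if (totals[g] > 0)
      round_half_up(100 * counts[, g] / totals[g]) else 0

  class_of <- c(stats::setNames(rules$gene_class, as.character(rules$rule_id)),
                none = "not_related")
  classes <- gene_class_values()
  class_counts <- matrix(0L, nrow = length(classes), ncol = length(cols),
                         dimnames = list(classes, cols))
  for (k in classes)
    class_counts[k, ] <- colSums(counts[class_of[rows] == k, , drop = FALSE])
  class_percent <- class_counts
  for (g in cols)
    class_percent[, g] <- if (totals[g] > 0)
      round_half_up(100 * class_counts[, g] / totals[g]) else 0

  structure(list(counts = counts, percent = percent,
                 class_counts = class_counts, class_percent = class_percent,
                 column_totals = totals),
            class = "rule_distribution")
}

#' @export
print.rule_distribution <- function(x, ...) {
  cat("<rule_distribution>\n")
  m <- matrix(sprintf("%d(%d%%)", x$counts, x$percent), nrow = nrow(x$counts),
              dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

# ---- paper-layout TSV exporters -------------------------------------------

#' Export tables in a "count (percent)" / "count (residual)" TSV layout
#'
#' Formats a [value_distribution()], [contingency_table()] or
#' [rule_distribution()] result for visual inspection, mirroring the
#' published table layouts.
#'
#' @param x The table object.
#' @param path Optional output path.
#' @return TSV lines, invisibly when `path` is given.
#' @export
table_to_tsv <- function(x, path = NULL) {
  lines <- if (inherits(x, "contingency_table")) {
    cells <- matrix(sprintf("%d (%.2f)", as.integer(x$observed), x$residuals),
                    nrow = nrow(x$observed))
    c(paste(c(x$row_concept, colnames(x$observed)), collapse = "\t"),
      vapply(seq_len(nrow(cells)), function(i)
        paste(c(rownames(x$observed)[i], cells[i, ]), collapse = "\t"),
        character(1)))
  } else if (inherits(x, "distribution_table")) {
    c("group\tvalue\tcount_percent",
      sprintf("%s\t%s\t%d(%d%%)", x$group, x$value, x$count, x$percent))
  } else if (inherits(x, "rule_distribution")) {
    cells <- matrix(sprintf("%d(%d%%)", x$counts, x$percent),
                    nrow = nrow(x$counts))
    c(paste(c("rule", colnames(x$counts)), collapse = "\t"),
      vapply(seq_len(nrow(cells)), function(i)
        paste(c(rownames(x$counts)[i], cells[i, ]), collapse = "\t"),
        character(1)))
  } else stop("unsupported table object", call. = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
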