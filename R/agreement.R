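#' Paired annotator labels for one concept
#'
#' @param concept Concept name; fixes the pre-specified category count `k`
#'   used by the G-index.
#' @param a,b Equal-length character vectors of the two annotators' labels
#'   over the same units; every label must be admissible for the concept.
#' @return An object of class `agreement_pairs` with fields `concept`,
#'   `a`, `b`, `k`.
#' @export
agreement_pairs <- function(concept, a, b) {
  vals <- concept_values(concept)
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b))
    stop("annotator label vectors must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(a, b)), vals)
  if (length(bad))
    stop("inadmissible ", concept, " label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(concept = concept, a = a, b = b, k = concept_k(concept)),
            class = "agreement_pairs")
}

check_pairs <- function(pairs) {
  stopifnot(inherits(pairs, "agreement_pairs"))
  if (length(pairs$a) == 0L)
    stop("empty pair set", call. = FALSE)
  invisible(TRUE)
}

#' Simple inter-annotator agreement
#'
#' The proportion of units on which the two annotators agree.
#'
#' @param pairs An [agreement_pairs()] object.
#' @return Proportion in `[0, 1]`.
#' @export
simple_agreement <- function(pairs) {
  check_pairs(pairs)
  mean(pairs$a == pairs$b)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` where `pe` is the
#' product-of-marginals chance agreement. When both annotators use one
#' single category throughout, `pe = 1` and kappa is undefined; `NA` is
#' returned (rendered `"N/A"` in summaries). Kappa is known to devaluate
#' agreement under heavily skewed label distributions; see [g_index()] for
#' the skew-robust alternative.
#'
#' @param pairs An [agreement_pairs()] object.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(pairs) {
  check_pairs(pairs)
  n <- length(pairs$a)
  po <- mean(pairs$a == pairs$b)
  cats <- unique(c(pairs$a, pairs$b))
  pa <- vapply(cats, function(v) sum(pairs$a == v), numeric(1)) / n
  pb <- vapply(cats, function(v) sum(pairs$b == v), numeric(1)) / n
  pe <- sum(pa * pb)
  if (isTRUE(all.equal(pe, 1))) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' G-index of agreement
#'
#' Like Cohen's kappa but with chance agreement fixed at `1/k`, the
#' multiplicative inverse of the number of *pre-specified* categories of
#' the concept (not the number observed in the sample): `G = (po - 1/k) /
#' (1 - 1/k)`. Robust to skewed category distributions.
#'
#' @param pairs An [agreement_pairs()] object.
#' @return G-index value.
#' @export
g_index <- function(pairs) {
  check_pairs(pairs)
  po <- mean(pairs$a == pairs$b)
  k <- pairs$k
  (po - 1 / k) / (1 - 1 / k)
}

#' Score rule-validation records
#'
#' For each unit, compares the rule-inferred gene class with the classes
#' assigned independently by two annotators: `full` match when both agree
#' with the inference, `one` when exactly one does, `none` otherwise.
#'
#' @param records Data frame with columns `rule_id` (integer, `NA` for no
#'   rule applied), `inferred_class`, `annot1_class`, `annot2_class`
#'   (admissible gene classes), and optionally `unit_id`.
#' @return The records with a `match_level` column added.
#' @export
score_validation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("rule_id", "inferred_class", "annot1_class",
                  "annot2_class") %in% names(records)))
  for (col in c("inferred_class", "annot1_class", "annot2_class")) {
    bad <- setdiff(unique(records[[col]]), gene_class_values())
    if (length(bad))
      stop("inadmissible gene class in ", col, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  n_agree <- (records$annot1_class == records$inferred_class) +
    (records$annot2_class == records$inferred_class)
  records$match_level <- c("none", "one", "full")[n_agree + 1L]
  records
}

#' Summarize rule-validation results
#'
#' Per-rule agreement table plus pooled rates. The per-rule agreement rate
#' is `(full + one) / total`; rules with no records are reported `NA`
#' (printed `"n/a"`). The micro-average rate pools counts over all rows;
#' the macro-average is the unweighted mean of the defined per-row rates,
#' including the "no rule applied" row.
#'
#' @param records Output of [score_validation()] (or a data frame with the
#'   same columns; `match_level` is recomputed if absent).
#' @return A list of class `validation_summary` with `table` (per-rule
#'   data frame: `rule`, `full`, `one`, `none`, `total`, `rate`), `micro`
#'   and `macro`.
#' @export
validation_summary <- function(records) {
  if (!nrow(records)) stop("no validation records", call. = FALSE)
  if (!"match_level" %in% names(records)) records <- score_validation(records)
  rows <- c(as.character(1:10), "none")
  rid <- ifelse(is.na(records$rule_id), "none", as.character(records$rule_id))
  tab <- do.call(rbind, lapply(rows, function(r) {
    sub <- records$match_level[rid == r]
    data.frame(rule = r,
               full = sum(sub == "full"), one = sum(sub == "one"),
               none = sum(sub == "none"), total = length(sub),
               stringsAsFactors = FALSE)
  }))
  tab$rate <- ifelse(tab$total > 0, (tab$full + tab$one) / tab$total, NA_real_)
  pop <- tab[tab$total > 0, , drop = FALSE]
  structure(list(table = tab,
                 micro = sum(pop$full + pop$one) / sum(pop$total),
                 macro = mean(pop$rate)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>\n")
  t <- x$table
  t$rate <- ifelse(is.na(t$rate), "n/a", sprintf("%.2f", t$rate))
  print.data.frame(t, row.names = FALSE)
  cat(sprintf("micro %.0f%%, macro %.0f%%\n",
              round_half_up(100 * x$micro), round_half_up(100 * x$macro)))
  invisible(x)
}

#' Read annotator pair files
#'
#' TSV with columns `unit_id`, `concept`, `annotator_a`, `annotator_b`;
#' one [agreement_pairs()] object is built per concept present.
#'
#' @param path Path to the TSV file.
#' @return Named list of `agreement_pairs`, one per concept.
#' @export
read_pair_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("unit_id", "concept", "annotator_a", "annotator_b")
  if (!all(need %in% names(df)))
    stop("pair file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$concept), function(d)
    agreement_pairs(d$concept[1], d$annotator_a, d$annotator_b))
  out[intersect(names(concept_catalog()), names(out))]
}

#' Read a rule-validation file
#'
#' TSV with columns `unit_id`, `rule_id` (`-` or empty for no rule),
#' `inferred_class`, `annot1_class`, `annot2_class`.
#'
#' @param path Path to the TSV file.
#' @return Scored records (see [score_validation()]).
#' @export
read_validation_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("unit_id", "rule_id", "inferred_class", "annot1_class",
            "annot2_class")
  if (!all(need %in% names(df)))
    stop("validation file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$rule_id <- suppressWarnings(as.integer(ifelse(df$rule_id %in% c("-", ""),
                                                   NA, df$rule_id)))
  score_validation(df)
}
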