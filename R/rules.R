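#' The ten built-in gene-classification rules
#'
#' Each rule is a pattern over the four concept values (with `"*"` as a
#' wildcard) plus an output gene class. A gene mention whose annotation
#' matches a rule is classified as an oncogene, a tumor suppressor gene or
#' a biomarker; when no rule matches, the gene is regarded as not related
#' to cancer. The cell-state concept (CCS) is always fixed in a rule and is
#' never `unidentifiable`, so units with unidentifiable CCS never match.
#'
#' @return A data frame of class `rule_table` with columns `rule_id`,
#'   `cge`, `ccs`, `ige`, `pt`, `gene_class`.
#' @seealso [match_rule()], [derive_rule_table()] for the first-principles
#'   derivation of the same table.
#' @export
builtin_rules <- function() {
  rules <- data.frame(
    rule_id = 1:10,
    cge = c("increased", "decreased", "decreased", "decreased", "increased",
            "increased", "*", "*", "decreased", "increased"),
    ccs = c("normal->cancer", "cancer->normal", "cancer->normal",
            "normal->cancer", "cancer->normal", "cancer->normal",
            "normal->cancer", "cancer->normal", "cancer->cancer",
            "cancer->cancer"),
    ige = c("*", "unidentifiable", "up-regulated", "*", "unidentifiable",
            "down-regulated", "*", "unidentifiable", "up-regulated",
            "down-regulated"),
    pt = c("causality", "causality", "*", "causality", "causality", "*",
           "observation", "observation", "observation", "observation"),
    gene_class = c("oncogene", "oncogene", "oncogene",
                   "tumor_suppressor_gene", "tumor_suppressor_gene",
                   "tumor_suppressor_gene", "biomarker", "biomarker",
                   "biomarker", "biomarker"),
    stringsAsFactors = FALSE)
  class(rules) <- c("rule_table", "data.frame")
  rules
}

pattern_matches <- function(pattern, value) pattern == "*" | pattern == value

#' Match an annotation tuple against the rule table
#'
#' @param cge,ccs,ige,pt Concept values. `ige`/`pt` may be `NA` (skipped)
#'   only when `ccs` is `"unidentifiable"`; such tuples match no rule.
#' @param rules A `rule_table`, by default [builtin_rules()].
#' @return The matching `rule_id` as an integer, or `NA_integer_` when no
#'   rule matches. More than one matching rule is an internal-consistency
#'   error: the table is mutually exclusive by construction.
#' @examples
#' match_rule("increased", "normal->cancer", "unchanged", "observation") # 7
#' @export
match_rule <- function(cge, ccs, ige, pt, rules = builtin_rules()) {
  check_tuple(cge, ccs, ige, pt)
  if (identical(ccs, "unidentifiable") || is.na(ige) || is.na(pt))
    return(NA_integer_)
  hit <- pattern_matches(rules$cge, cge) &
    pattern_matches(rules$ccs, ccs) &
    pattern_matches(rules$ige, ige) &
    pattern_matches(rules$pt, pt)
  ids <- rules$rule_id[hit]
  if (length(ids) > 1L)
    stop("internal error: rules ", paste(ids, collapse = ", "),
         " all match (", cge, ", ", ccs, ", ", ige, ", ", pt, ")",
         call. = FALSE)
  if (length(ids) == 0L) NA_integer_ else as.integer(ids)
}

check_tuple <- function(cge, ccs, ige, pt) {
  if (!is_admissible("CGE", cge))
    stop("inadmissible CGE value: ", deparse(cge), call. = FALSE)
  if (!is_admissible("CCS", ccs))
    stop("inadmissible CCS value: ", deparse(ccs), call. = FALSE)
  na_ok <- identical(ccs, "unidentifiable")
  if (!is_admissible("IGE", ige, allow_na = na_ok))
    stop("inadmissible IGE value: ", deparse(ige),
         if (!na_ok && length(ige) == 1L && is.na(ige))
           " (IGE may be skipped only with unidentifiable CCS)",
         call. = FALSE)
  if (!is_admissible("PT", pt, allow_na = na_ok))
    stop("inadmissible PT value: ", deparse(pt),
         if (!na_ok && length(pt) == 1L && is.na(pt))
           " (PT may be skipped only with unidentifiable CCS)",
         call. = FALSE)
  invisible(TRUE)
}

#' Classify one annotation unit
#'
#' @param unit A valid [annotation_unit()].
#' @param rules A `rule_table`.
#' @return A one-row data frame with `unit_id`, `gene_class` and `rule_id`
#'   (`NA` when no rule applied, in which case the class is `not_related`).
#' @export
classify_unit <- function(unit, rules = builtin_rules()) {
  v <- validate_unit(unit)
  if (length(v))
    stop("invalid unit ", dQuote(unit$unit_id), ": ",
         paste(v, collapse = "; "), call. = FALSE)
  id <- match_rule(unit$cge, unit$ccs, unit$ige, unit$pt, rules)
  cls <- if (is.na(id)) "not_related" else rules$gene_class[rules$rule_id == id]
  data.frame(unit_id = unit$unit_id, gene_class = cls, rule_id = id,
             stringsAsFactors = FALSE)
}

#' Classify every unit of a corpus
#'
#' @param corpus An `annotation_corpus`.
#' @param rules A `rule_table`.
#' @return Data frame with one row per unit: `unit_id`, `gene`,
#'   `cancer_type`, `rule_id`, `gene_class`.
#' @export
classify_corpus <- function(corpus, rules = builtin_rules()) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  df <- as.data.frame(corpus)
  ids <- mapply(match_rule, df$cge, df$ccs, df$ige, df$pt,
                MoreArgs = list(rules = rules), USE.NAMES = FALSE)
  cls <- ifelse(is.na(ids), "not_related",
                rules$gene_class[match(ids, rules$rule_id)])
  data.frame(unit_id = df$unit_id, gene = df$gene,
             cancer_type = df$cancer_type, rule_id = as.integer(ids),
             gene_class = cls, stringsAsFactors = FALSE)
}

#' First-principles gene class for an annotation tuple
#'
#' Assigns a gene class directly from the meaning of the four concepts,
#' without consulting the rule table:
#'
#' 1. Unidentifiable or `normal->normal` CCS carries no evidence of a
#'    gene-cancer relation: `not_related`.
#' 2. For `normal->cancer`, claimed causality makes an increased gene an
#'    oncogene and a decreased gene a tumor suppressor; mere observation
#'    makes it a biomarker.
#' 3. For `cancer->normal`, claimed causality reverses the mapping
#'    (decreased -> oncogene, increased -> tumor suppressor). Under
#'    observation, causality can still be *deduced* when the initial level
#'    and the change point the same way (`up-regulated` + `decreased` ->
#'    oncogene; `down-regulated` + `increased` -> tumor suppressor);
#'    otherwise the gene is a biomarker.
#' 4. For `cancer->cancer`, only the two deduced-initial-level
#'    observations (`up-regulated`+`decreased`, `down-regulated`+
#'    `increased`) mark a biomarker; everything else is `not_related`.
#' 5. When IGE is `unidentifiable`, the class is the *weakest* among the
#'    classes obtained under each concrete IGE value
#'    (`not_related` < `biomarker` < oncogene/tumor suppressor).
#'
#' Combinations that assert a class but are essentially unreported in the
#' literature are tagged implausible: a concrete (non-`unidentifiable`)
#' IGE together with `cancer->normal` CCS, unless the (IGE, CGE) pair is
#' one of the two causality-deducing pairs. These tuples are dropped when
#' the rule table is compressed by [derive_rule_table()].
#'
#' @param cge,ccs,ige,pt Concept values (`ige`/`pt` `NA` only with
#'   unidentifiable CCS).
#' @return A list with `gene_class` and `plausible` (logical; `FALSE`
#'   tags an implausible-or-rare combination).
#' @export
first_principles_class <- function(cge, ccs, ige, pt) {
  check_tuple(cge, ccs, ige, pt)
  cls <- fp_class(cge, ccs, ige, pt)
  list(gene_class = cls, plausible = cls == "not_related" || fp_plausible(cge, ccs, ige))
}

fp_class <- function(cge, ccs, ige, pt) {
  if (ccs %in% c("unidentifiable", "normal->normal")) return("not_related")
  if (identical(ige, "unidentifiable")) {
    concrete <- setdiff(concept_values("IGE"), "unidentifiable")
    return(weakest_class(vapply(concrete, function(g) fp_class(cge, ccs, g, pt),
                                character(1))))
  }
  deduced_onco <- identical(ige, "up-regulated") && identical(cge, "decreased")
  deduced_tsg <- identical(ige, "down-regulated") && identical(cge, "increased")
  if (ccs == "normal->cancer") {
    if (pt == "causality")
      return(if (cge == "increased") "oncogene" else "tumor_suppressor_gene")
    return("biomarker")
  }
  if (ccs == "cancer->normal") {
    if (pt == "causality")
      return(if (cge == "decreased") "oncogene" else "tumor_suppressor_gene")
    if (deduced_onco) return("oncogene")
    if (deduced_tsg) return("tumor_suppressor_gene")
    return("biomarker")
  }
  # cancer->cancer: no cell change; only a deduced abnormal initial level
  # under observation marks the gene at all
  if (pt == "observation" && (deduced_onco || deduced_tsg)) return("biomarker")
  "not_related"
}

# rarely-reported filter: concrete IGE with cancer->normal CCS is essentially
# unreported unless (IGE, CGE) is a causality-deducing pair
fp_plausible <- function(cge, ccs, ige) {
  if (!identical(ccs, "cancer->normal")) return(TRUE)
  if (is.na(ige) || ige == "unidentifiable") return(TRUE)
  (identical(ige, "up-regulated") && identical(cge, "decreased")) ||
    (identical(ige, "down-regulated") && identical(cge, "increased"))
}

# all 2 x 5 x 4 x 2 = 80 complete concept-value tuples
complete_tuples <- function() {
  expand.grid(cge = concept_values("CGE"), ccs = concept_values("CCS"),
              ige = concept_values("IGE"), pt = concept_values("PT"),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Derive the rule table from first principles
#'
#' Enumerates all 80 complete concept-value tuples, assigns each a class
#' with [first_principles_class()], drops `not_related` and
#' implausible-or-rare tuples, and compresses the survivors into
#' maximally wildcarded, mutually exclusive rules. The result is
#' pattern-equivalent to [builtin_rules()]: both induce the same
#' tuple-to-class map.
#'
#' @return A `rule_table` data frame (rule ids renumbered in the builtin
#'   table's order when equivalent, otherwise in derivation order).
#' @export
derive_rule_table <- function() {
  tup <- complete_tuples()
  fp <- lapply(seq_len(nrow(tup)), function(i)
    first_principles_class(tup$cge[i], tup$ccs[i], tup$ige[i], tup$pt[i]))
  tup$gene_class <- vapply(fp, `[[`, character(1), "gene_class")
  tup$plausible <- vapply(fp, `[[`, logical(1), "plausible")
  surv <- tup[tup$plausible & tup$gene_class != "not_related", , drop = FALSE]

  key <- function(d) paste(d$cge, d$ccs, d$ige, d$pt)
  surv_class <- setNames(surv$gene_class, key(surv))

  # candidate patterns: CCS always fixed; CGE/IGE/PT each a value or "*"
  cand <- expand.grid(
    cge = c("*", concept_values("CGE")),
    ccs = unique(surv$ccs),
    ige = c("*", setdiff(concept_values("IGE"), NULL)),
    pt = c("*", concept_values("PT")),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  matched_keys <- function(p) {
    m <- pattern_matches(p$cge, tup$cge) & pattern_matches(p$ccs, tup$ccs) &
      pattern_matches(p$ige, tup$ige) & pattern_matches(p$pt, tup$pt)
    key(tup[m, , drop = FALSE])
  }
  # a pattern is valid iff every complete tuple it matches is a surviving
  # tuple, and all of those share one class
  valid <- list()
  for (i in seq_len(nrow(cand))) {
    ks <- matched_keys(cand[i, ])
    cls <- surv_class[ks]
    if (length(ks) && !anyNA(cls) && length(unique(cls)) == 1L)
      valid[[length(valid) + 1L]] <-
        cbind(cand[i, ], gene_class = unname(cls[1L]),
              n_wild = sum(cand[i, c("cge", "ige", "pt")] == "*"),
              stringsAsFactors = FALSE)
  }
  valid <- do.call(rbind, valid)
  valid <- valid[order(-valid$n_wild), , drop = FALSE]

  # greedy cover, most general first; keep a pattern only if it covers a
  # still-uncovered surviving tuple
  covered <- character(0)
  chosen <- list()
  for (i in seq_len(nrow(valid))) {
    ks <- matched_keys(valid[i, ])
    if (length(setdiff(ks, covered)) == 0L) next
    if (length(intersect(ks, covered)))
      stop("internal error: derived rules are not mutually exclusive",
           call. = FALSE)
    covered <- c(covered, ks)
    chosen[[length(chosen) + 1L]] <- valid[i, ]
  }
  stopifnot(setequal(covered, key(surv)))
  out <- do.call(rbind, chosen)[, c("cge", "ccs", "ige", "pt", "gene_class")]

  # align ids with the builtin table when row-identical up to order
  bi <- builtin_rules()
  sig <- function(d) paste(d$cge, d$ccs, d$ige, d$pt, d$gene_class)
  idx <- match(sig(out), sig(bi))
  out$rule_id <- if (!anyNA(idx)) bi$rule_id[idx] else seq_len(nrow(out))
  out <- out[order(out$rule_id), c("rule_id", "cge", "ccs", "ige", "pt",
                                   "gene_class")]
  rownames(out) <- NULL
  class(out) <- c("rule_table", "data.frame")
  out
}

#' @export
print.rule_table <- function(x, ...) {
  cat("<rule_table:", nrow(x), "rules>\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Export a rule table as TSV lines
#'
#' Column order: rule id, CGE, CCS, IGE, PT, gene class; `"*"` marks a
#' wildcard.
#'
#' @param rules A `rule_table`.
#' @param path Optional output path.
#' @return The TSV lines, invisibly when `path` is given.
#' @export
rules_to_tsv <- function(rules, path = NULL) {
  lines <- c(paste(c("rule_id", "cge", "ccs", "ige", "pt", "gene_class"),
                   collapse = "\t"),
             apply(rules[, c("rule_id", "cge", "ccs", "ige", "pt",
                             "gene_class")], 1L, paste, collapse = "\t"))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Aggregate classification evidence per gene
#'
#' Groups unit-level classifications by (case-insensitively normalized gene
#' string, cancer type) and counts supporting units per gene class. One
#' annotation unit is one piece of textual evidence; conclusions about a
#' gene's role should rest on the collected evidence, not single mentions.
#'
#' @param corpus An `annotation_corpus`.
#' @param rules A `rule_table`.
#' @return Data frame with columns `gene` (normalized, upper case),
#'   `cancer_type`, one count column per gene class (`oncogene`,
#'   `tumor_suppressor_gene`, `biomarker`, `not_related`), `n_units`, and a
#'   list column `units` of per-class supporting unit ids.
#' @export
aggregate_evidence <- function(corpus, rules = builtin_rules()) {
  cl <- classify_corpus(corpus, rules)
  if (nrow(cl) == 0L) {
    out <- data.frame(gene = character(0), cancer_type = character(0),
                      oncogene = integer(0), tumor_suppressor_gene = integer(0),
                      biomarker = integer(0), not_related = integer(0),
                      n_units = integer(0), stringsAsFactors = FALSE)
    out$units <- list()
    return(out)
  }
  cl$gene_key <- toupper(cl$gene)
  keys <- unique(cl[, c("gene_key", "cancer_type")])
  classes <- gene_class_values()
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- cl$gene_key == keys$gene_key[i] & cl$cancer_type == keys$cancer_type[i]
    sub <- cl[sel, , drop = FALSE]
    counts <- vapply(classes, function(k) sum(sub$gene_class == k), integer(1))
    row <- data.frame(gene = keys$gene_key[i], cancer_type = keys$cancer_type[i],
                      stringsAsFactors = FALSE)
    for (k in classes) row[[k]] <- counts[[k]]
    row$n_units <- nrow(sub)
    row$units <- list(split(sub$unit_id, sub$gene_class))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
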