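#' Character span within a sentence
#'
#' Offsets are 0-based, half-open, counted in Unicode code points of the
#' containing sentence, so `substr(sentence, start + 1, end)` equals `text`.
#'
#' @param text Covered text.
#' @param start,end Integer offsets, `0 <= start < end`.
#' @return An object of class `span`.
#' @export
span <- function(text, start, end) {
  stopifnot(is.character(text), length(text) == 1L,
            is.numeric(start), is.numeric(end),
            length(start) == 1L, length(end) == 1L)
  structure(list(text = text, start = as.integer(start), end = as.integer(end)),
            class = "span")
}

#' @export
print.span <- function(x, ...) {
  cat(sprintf("<span [%d,%d) %s>\n", x$start, x$end, dQuote(x$text)))
  invisible(x)
}

# violations of the span invariants against `sentence`, tagged with `field`
check_span <- function(sp, sentence, field) {
  v <- character(0)
  if (!inherits(sp, "span")) return(sprintf("%s: not a span", field))
  n <- nchar(sentence)
  if (is.na(sp$start) || is.na(sp$end) || sp$start < 0L || sp$start >= sp$end ||
      sp$end > n) {
    v <- c(v, sprintf("%s: span offsets [%s,%s) invalid for sentence of length %d",
                      field, sp$start, sp$end, n))
  } else if (substr(sentence, sp$start + 1L, sp$end) != sp$text) {
    v <- c(v, sprintf("%s: span text %s does not match sentence substring %s",
                      field, dQuote(sp$text),
                      dQuote(substr(sentence, sp$start + 1L, sp$end))))
  }
  v
}

#' Construct an annotation unit
#'
#' An annotation unit is one mention of a gene expression change that
#' co-occurs with at least one cancer-related term in a sentence, annotated
#' with the four concept values. `ige` and `pt` must be `NA` (skipped)
#' exactly when `ccs` is `"unidentifiable"`; `cge` is always annotated.
#'
#' @param unit_id Unique identifier within a corpus.
#' @param sentence The full sentence (window of context).
#' @param gene [span] of the gene name.
#' @param expression_keywords List of [span]s of the expression-change
#'   keywords (at least one).
#' @param cancer_terms List of [span]s of cancer-related terms (at least one).
#' @param cge,ccs,ige,pt Concept values; see [concept_catalog()]. `ige`/`pt`
#'   may be `NA` only when `ccs == "unidentifiable"`.
#' @param pmid PubMed identifier of the source abstract, or `""`.
#' @param cancer_type `"prostate"`, `"breast"`, `"ovarian"` or
#'   `"other:<name>"`.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `annotation_unit`.
#' @examples
#' s <- "Cdc25B is frequently overexpressed in human prostate cancer tissues"
#' u <- annotation_unit("u1", s,
#'   gene = span("Cdc25B", 0, 6),
#'   expression_keywords = list(span("overexpressed", 21, 34)),
#'   cancer_terms = list(span("prostate cancer", 44, 59)),
#'   cge = "increased", ccs = "normal->cancer",
#'   ige = "unchanged", pt = "observation")
#' @export
annotation_unit <- function(unit_id, sentence, gene, expression_keywords,
                            cancer_terms, cge, ccs, ige = NA_character_,
                            pt = NA_character_, pmid = "",
                            cancer_type = "other:unspecified",
                            validate = TRUE) {
  u <- structure(
    list(unit_id = as.character(unit_id), pmid = as.character(pmid),
         cancer_type = as.character(cancer_type),
         sentence = as.character(sentence), gene = gene,
         expression_keywords = expression_keywords,
         cancer_terms = cancer_terms,
         cge = as.character(cge), ccs = as.character(ccs),
         ige = as.character(ige), pt = as.character(pt)),
    class = "annotation_unit")
  if (validate) {
    v <- validate_unit(u)
    if (length(v))
      stop("invalid annotation unit ", dQuote(u$unit_id), ":\n  ",
           paste(v, collapse = "\n  "), call. = FALSE)
  }
  u
}

#' Validate an annotation unit
#'
#' Checks every structural invariant of the annotation scheme. Violations
#' are returned as data, not raised, so corpus-level validation can report
#' all of them.
#'
#' @param unit An [annotation_unit()].
#' @return Character vector of violation messages; empty when the unit is
#'   valid. Each message names the field and the invariant broken.
#' @export
validate_unit <- function(unit) {
  v <- character(0)
  if (!inherits(unit, "annotation_unit"))
    return("unit: not an annotation_unit")
  if (!nzchar(unit$unit_id)) v <- c(v, "unit_id: must be non-empty")
  if (!nzchar(unit$sentence)) v <- c(v, "sentence: must be non-empty")
  ct <- unit$cancer_type
  if (!(ct %in% c("prostate", "breast", "ovarian") || startsWith(ct, "other:")))
    v <- c(v, sprintf(
      "cancer_type: %s is not prostate/breast/ovarian or 'other:<name>'",
      dQuote(ct)))

  if (!is_admissible("CGE", unit$cge))
    v <- c(v, sprintf("cge: inadmissible value %s (CGE is always annotated)",
                      dQuote(unit$cge)))
  if (!is_admissible("CCS", unit$ccs))
    v <- c(v, sprintf("ccs: inadmissible value %s", dQuote(unit$ccs)))
  if (!is_admissible("IGE", unit$ige, allow_na = TRUE))
    v <- c(v, sprintf("ige: inadmissible value %s", dQuote(unit$ige)))
  if (!is_admissible("PT", unit$pt, allow_na = TRUE))
    v <- c(v, sprintf("pt: inadmissible value %s", dQuote(unit$pt)))

  # IGE/PT skipped iff CCS unidentifiable
  if (identical(unit$ccs, "unidentifiable")) {
    if (!is.na(unit$ige))
      v <- c(v, "ige: IGE annotated with unidentifiable CCS")
    if (!is.na(unit$pt))
      v <- c(v, "pt: PT annotated with unidentifiable CCS")
  } else if (is_admissible("CCS", unit$ccs)) {
    if (is.na(unit$ige))
      v <- c(v, "ige: IGE missing although CCS is identifiable")
    if (is.na(unit$pt))
      v <- c(v, "pt: PT missing although CCS is identifiable")
  }

  v <- c(v, check_span(unit$gene, unit$sentence, "gene"))
  if (!is.list(unit$expression_keywords) || length(unit$expression_keywords) == 0L) {
    v <- c(v, "expression_keywords: at least one span required")
  } else {
    for (i in seq_along(unit$expression_keywords))
      v <- c(v, check_span(unit$expression_keywords[[i]], unit$sentence,
                           sprintf("expression_keywords[%d]", i)))
  }
  if (!is.list(unit$cancer_terms) || length(unit$cancer_terms) == 0L) {
    v <- c(v, "cancer_terms: at least one cancer-term span required")
  } else {
    for (i in seq_along(unit$cancer_terms))
      v <- c(v, check_span(unit$cancer_terms[[i]], unit$sentence,
                           sprintf("cancer_terms[%d]", i)))
  }
  v
}

#' @export
print.annotation_unit <- function(x, ...) {
  cat(sprintf("<annotation_unit %s [%s]>\n", x$unit_id, x$cancer_type))
  cat(" ", render_marked_sentence(x), "\n")
  cat(sprintf("  CGE=%s CCS=%s IGE=%s PT=%s\n", x$cge, x$ccs,
              ifelse(is.na(x$ige), "-", x$ige),
              ifelse(is.na(x$pt), "-", x$pt)))
  invisible(x)
}

#' Construct a corpus of annotation units
#'
#' @param units List of [annotation_unit()]s with unique `unit_id`s.
#' @param provenance Named list of free-text metadata (source file,
#'   generator seed, version, ...).
#' @return An object of class `annotation_corpus`.
#' @export
corpus <- function(units = list(), provenance = list()) {
  ids <- vapply(units, function(u) u$unit_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate unit_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  structure(list(units = units, provenance = provenance),
            class = "annotation_corpus")
}

#' @export
length.annotation_corpus <- function(x) length(x$units)

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus: %d units>\n", length(x$units)))
  if (length(x$units)) {
    df <- as.data.frame(x)
    tab <- table(df$cancer_type)
    cat("  cancer types:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(x$provenance))
    cat("  provenance:",
        paste(names(x$provenance),
              vapply(x$provenance, function(p) paste(format(p), collapse = " "),
                     character(1)),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Concept-value view of a corpus
#'
#' Flattens a corpus to one row per unit with the four concept values
#' (skipped IGE/PT as `NA`), the gene surface string and the cancer type —
#' the view the statistics functions operate on.
#'
#' @param x An `annotation_corpus`.
#' @param ... Unused.
#' @return A data frame with columns `unit_id`, `pmid`, `cancer_type`,
#'   `gene`, `cge`, `ccs`, `ige`, `pt`.
#' @export
as.data.frame.annotation_corpus <- function(x, ...) {
  f <- function(get) vapply(x$units, get, character(1))
  data.frame(
    unit_id = f(function(u) u$unit_id),
    pmid = f(function(u) u$pmid),
    cancer_type = f(function(u) u$cancer_type),
    gene = f(function(u) u$gene$text),
    cge = f(function(u) u$cge),
    ccs = f(function(u) u$ccs),
    ige = f(function(u) u$ige),
    pt = f(function(u) u$pt),
    stringsAsFactors = FALSE
  )
}

#' Validate every unit of a corpus
#'
#' @param corpus An `annotation_corpus`.
#' @return A data frame with columns `unit_id` and `violation`, one row per
#'   violation; zero rows when the corpus is clean.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  out <- lapply(corpus$units, function(u) {
    v <- validate_unit(u)
    if (length(v)) data.frame(unit_id = u$unit_id, violation = v,
                              stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), violation = character(0),
                      stringsAsFactors = FALSE)
  out
}
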