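#' Annotation concept catalog
#'
#' The four annotation concepts and their pre-specified value sets. Each
#' annotation unit carries one value per concept:
#'
#' * `CGE` (change in gene expression): direction of the expression-level
#'   change — `increased` or `decreased`.
#' * `CCS` (change in cell state): how the cell or tissue's cancerous
#'   properties change along with the expression change.
#' * `IGE` (initial gene expression level): the gene's expression level
#'   before the change, relative to a normal cell.
#' * `PT` (proposition type): whether causality between the expression
#'   change and the cell-state change is claimed or merely co-reported.
#'
#' `IGE` and `PT` are skipped (encoded `NA`) exactly when `CCS` is
#' `unidentifiable`; the skip marker is distinct from the annotator's
#' judgment `unidentifiable`.
#'
#' @return A named list with one entry per concept (`CGE`, `CCS`, `IGE`,
#'   `PT`), each a character vector of admissible values in canonical order.
#' @examples
#' concept_catalog()$CGE
#' concept_k("IGE")
#' @export
concept_catalog <- function() {
  list(
    CGE = c("increased", "decreased"),
    CCS = c("normal->normal", "normal->cancer", "cancer->cancer",
            "cancer->normal", "unidentifiable"),
    IGE = c("up-regulated", "down-regulated", "unchanged", "unidentifiable"),
    PT  = c("observation", "causality")
  )
}

#' Human-readable definitions of the concept values
#'
#' @return A data frame with columns `concept`, `value`, `definition`.
#' @export
concept_definitions <- function() {
  data.frame(
    concept = rep(names(concept_catalog()), times = c(2L, 5L, 4L, 2L)),
    value = unlist(concept_catalog(), use.names = FALSE),
    definition = c(
      "Expression level of the gene is increased.",
      "Expression level of the gene is decreased.",
      "The cell or tissue remains normal after the expression change.",
      "The cell or tissue acquires or strengthens cancerous properties as the expression level changes.",
      "No change in the cancerous properties of the cell or tissue despite the expression change.",
      "The cell or tissue loses or weakens cancerous properties as the expression level changes.",
      "Whether the expression change accompanies a cell-state change is not stated.",
      "Initial expression level is higher than in the normal state.",
      "Initial expression level is lower than in the normal state.",
      "Initial expression level is comparable to the normal state.",
      "Information about the initial expression level is not provided.",
      "The cell-state change is reported as observed; causality is not claimed.",
      "Causality between the expression change and the cell-state change is claimed."
    ),
    stringsAsFactors = FALSE
  )
}

#' Number of pre-specified categories for a concept
#'
#' Used as the chance denominator of the G-index: chance agreement is
#' `1/k` with `k` the full pre-specified category count, not the number of
#' categories actually observed in a sample.
#'
#' @param concept One of `"CGE"`, `"CCS"`, `"IGE"`, `"PT"`.
#' @return Integer category count (CGE 2, CCS 5, IGE 4, PT 2).
#' @export
concept_k <- function(concept) {
  length(concept_values(concept))
}

#' Admissible values of a concept
#'
#' @param concept One of `"CGE"`, `"CCS"`, `"IGE"`, `"PT"`.
#' @return Character vector of admissible values.
#' @export
concept_values <- function(concept) {
  cat <- concept_catalog()
  if (!is.character(concept) || length(concept) != 1L || !concept %in% names(cat))
    stop("unknown concept: ", deparse(concept), call. = FALSE)
  cat[[concept]]
}

# TRUE iff `value` is admissible for `concept`; NA (= skipped concept) is
# admitted only when allow_na.
is_admissible <- function(concept, value, allow_na = FALSE) {
  if (length(value) != 1L) return(FALSE)
  if (is.na(value)) return(allow_na)
  value %in% concept_values(concept)
}

#' Gene classes and their relation strength
#'
#' The engine assigns one of four classes to a gene mention. Classes are
#' ordered by the strength of the gene-cancer relation they assert:
#' `not_related` (0) < `biomarker` (1) < `oncogene` = `tumor_suppressor_gene`
#' (2). The weakest-relation resolution used when IGE is `unidentifiable`
#' picks the minimum under this order.
#'
#' @return Named integer vector mapping class name to strength rank.
#' @export
gene_class_strength <- function() {
  c(not_related = 0L, biomarker = 1L,
    oncogene = 2L, tumor_suppressor_gene = 2L)
}

gene_class_values <- function() names(gene_class_strength())

# weakest class among those given (by strength rank; oncogene/TSG tie is
# irrelevant because the minimum is taken)
weakest_class <- function(classes) {
  s <- gene_class_strength()[classes]
  unname(classes[which.min(s)])
}
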