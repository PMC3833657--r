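#' Default generator configuration
#'
#' A [generator_config()] whose distributions are the published corpus
#' frequencies: the cancer-type proportions (310/255/256 of 821), the
#' CGE x CCS joint counts (the pairwise table's three observed CCS
#' columns, including the unidentifiable-CCS column), and the IGE-given-CCS
#' and PT-given-CCS conditionals from the pairwise tables. IGE and PT are
#' sampled conditionally independent given CCS, which the corpus's own
#' conditional-independence analysis supports. Default annotator flip
#' rates are one minus the overall simple agreement per concept.
#'
#' @param n_units Number of units to generate.
#' @param seed Integer seed.
#' @return A `generator_config`.
#' @export
default_generator_config <- function(n_units = 821L, seed = 1L) {
  joint <- matrix(c(318, 79, 45, 76, 204, 99) / 821, nrow = 2,
                  dimnames = list(c("increased", "decreased"),
                                  c("normal->cancer", "cancer->normal",
                                    "unidentifiable")))
  generator_config(
    n_units = n_units, seed = seed,
    cancer_type_probs = c(prostate = 310, breast = 255, ovarian = 256) / 821,
    cge_ccs_joint = joint,
    ige_given_ccs = list(
      "normal->cancer" = c("up-regulated" = 0, "down-regulated" = 0,
                           "unchanged" = 212, "unidentifiable" = 185) / 397,
      "cancer->normal" = c("up-regulated" = 2, "down-regulated" = 0,
                           "unchanged" = 0, "unidentifiable" = 119) / 121),
    pt_given_ccs = list(
      "normal->cancer" = c(observation = 311, causality = 86) / 397,
      "cancer->normal" = c(observation = 43, causality = 78) / 121),
    flip_rates = c(CGE = 0.01, CCS = 0.21, IGE = 0.02, PT = 0.14))
}

#' Synthetic corpus generator configuration
#'
#' Bundles every knob of [generate_corpus()]: sizes, seed, the sampling
#' distributions over concept values, the sentence-realization pools and
#' the annotator-disagreement flip rates used by [perturb_annotations()].
#' All probability vectors must sum to 1.
#'
#' @param n_units Number of units.
#' @param seed Integer seed (one source of randomness per run, split into
#'   a value substream and a sentence-realization substream so extending
#'   one does not shift the other).
#' @param cancer_type_probs Named probabilities over cancer types.
#' @param cge_ccs_joint Matrix of joint probabilities, CGE rows x CCS
#'   columns (columns limited to CCS values with positive mass).
#' @param ige_given_ccs,pt_given_ccs Named lists of conditional probability
#'   vectors per identifiable CCS value; for CCS values absent from the
#'   list (and for `unidentifiable`) the concept is skipped (`NA`).
#' @param gene_pool Character vector of gene symbols.
#' @param templates Sentence templates containing the placeholders
#'   `{GENE}`, `{KW}` and `{CANCER}` exactly once each.
#' @param keywords Named list with elements `increased` and `decreased`:
#'   expression-change keyword pools per CGE direction.
#' @param cancer_terms Named list of cancer-term pools per cancer type.
#' @param flip_rates Named per-concept probabilities that a simulated
#'   second annotator replaces the value by a random different one.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_units, seed,
                             cancer_type_probs,
                             cge_ccs_joint,
                             ige_given_ccs,
                             pt_given_ccs,
                             gene_pool = default_gene_pool(),
                             templates = default_templates(),
                             keywords = default_keywords(),
                             cancer_terms = default_cancer_terms(),
                             flip_rates = c(CGE = 0, CCS = 0, IGE = 0,
                                            PT = 0)) {
  cfg <- structure(list(
    n_units = as.integer(n_units), seed = as.integer(seed),
    cancer_type_probs = cancer_type_probs, cge_ccs_joint = cge_ccs_joint,
    ige_given_ccs = ige_given_ccs, pt_given_ccs = pt_given_ccs,
    gene_pool = gene_pool, templates = templates, keywords = keywords,
    cancer_terms = cancer_terms, flip_rates = flip_rates),
    class = "generator_config")
  v <- validate_generator_config(cfg)
  if (length(v))
    stop("invalid generator config:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  cfg
}

validate_generator_config <- function(cfg) {
  v <- character(0)
  sums_to_one <- function(p) isTRUE(all.equal(sum(p), 1, tolerance = 1e-9))
  if (is.na(cfg$n_units) || cfg$n_units < 0L) v <- c(v, "n_units must be >= 0")
  if (is.na(cfg$seed)) v <- c(v, "seed must be an integer")
  if (!sums_to_one(cfg$cancer_type_probs))
    v <- c(v, "cancer_type_probs must sum to 1")
  if (!sums_to_one(cfg$cge_ccs_joint))
    v <- c(v, "cge_ccs_joint must sum to 1")
  if (!all(rownames(cfg$cge_ccs_joint) %in% concept_values("CGE")))
    v <- c(v, "cge_ccs_joint rows must be CGE values")
  if (!all(colnames(cfg$cge_ccs_joint) %in% concept_values("CCS")))
    v <- c(v, "cge_ccs_joint columns must be CCS values")
  for (nm in names(cfg$ige_given_ccs))
    if (!sums_to_one(cfg$ige_given_ccs[[nm]]))
      v <- c(v, paste0("ige_given_ccs[", nm, "] must sum to 1"))
  for (nm in names(cfg$pt_given_ccs))
    if (!sums_to_one(cfg$pt_given_ccs[[nm]]))
      v <- c(v, paste0("pt_given_ccs[", nm, "] must sum to 1"))
  if (any(cfg$flip_rates < 0 | cfg$flip_rates > 1))
    v <- c(v, "flip_rates must lie in [0, 1]")
  tmpl_ok <- vapply(cfg$templates, function(t)
    all(vapply(c("{GENE}", "{KW}", "{CANCER}"), function(p) {
      m <- gregexpr(p, t, fixed = TRUE)[[1L]]
      m[1L] != -1L && length(m) == 1L
    }, logical(1))), logical(1))
  if (!all(tmpl_ok))
    v <- c(v, "every template must contain {GENE}, {KW}, {CANCER} exactly once")
  v
}

default_gene_pool <- function() {
  c("TP53", "PTEN", "BRCA1", "MYC", "EGFR", "AR", "CDC25B", "CLU", "TGFB1",
    "ERBB2", "CCND1", "CDKN1A", "BCL2", "VEGFA", "KLK3", "ESR1", "MKI67",
    "CDH1", "MMP9", "RASSF1A")
}

default_templates <- function() {
  c("{GENE} is frequently {KW} in human {CANCER} tissues",
    "Expression of {GENE} was {KW} in {CANCER} cells",
    "We found that {GENE} is {KW} in patients with {CANCER}",
    "{GENE} mRNA levels were {KW} in {CANCER} specimens",
    "Immunostaining showed that {GENE} is {KW} in primary {CANCER}")
}

default_keywords <- function() {
  list(increased = c("overexpressed", "up-regulated", "elevated", "induced"),
       decreased = c("down-regulated", "reduced", "suppressed", "silenced"))
}

default_cancer_terms <- function() {
  list(prostate = c("prostate cancer", "prostatic carcinoma"),
       breast = c("breast cancer", "breast carcinoma"),
       ovarian = c("ovarian cancer", "ovarian carcinoma"))
}

# fill a template; returns the sentence plus one span per placeholder
fill_template <- function(template, values) {
  m <- gregexpr("\\{(GENE|KW|CANCER)\\}", template)[[1L]]
  lens <- attr(m, "match.length")
  sentence <- ""
  spans <- list()
  cursor <- 1L
  for (i in seq_along(m)) {
    sentence <- paste0(sentence, substr(template, cursor, m[i] - 1L))
    slot <- substr(template, m[i] + 1L, m[i] + lens[i] - 2L)
    text <- values[[slot]]
    start <- nchar(sentence)
    sentence <- paste0(sentence, text)
    spans[[slot]] <- span(text, start, start + nchar(text))
    cursor <- m[i] + lens[i]
  }
  sentence <- paste0(sentence, substr(template, cursor, nchar(template)))
  list(sentence = sentence, spans = spans)
}

#' Generate a synthetic annotated corpus
#'
#' Samples `n_units` annotation units under the configured distributions:
#' cancer type first, then the CGE x CCS joint, then IGE and PT
#' conditionally independent given CCS (skipped when CCS is
#' unidentifiable). Sentences are realized from a small template pool with
#' gene, keyword and cancer-term spans whose offsets are exact. The same
#' `(config, seed)` always yields a byte-identical corpus.
#'
#' @param config A [generator_config()].
#' @return An `annotation_corpus` whose every unit passes
#'   [validate_unit()].
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_units
  if (n == 0L)
    return(corpus(list(), list(generator = "synthetic", seed = config$seed)))

  # value substream
  set.seed(config$seed)
  types <- sample(names(config$cancer_type_probs), n, replace = TRUE,
                  prob = config$cancer_type_probs)
  joint <- config$cge_ccs_joint
  cells <- sample.int(length(joint), n, replace = TRUE, prob = as.vector(joint))
  cge <- rownames(joint)[(cells - 1L) %% nrow(joint) + 1L]
  ccs <- colnames(joint)[(cells - 1L) %/% nrow(joint) + 1L]
  ige <- rep(NA_character_, n)
  pt <- rep(NA_character_, n)
  for (s in unique(ccs)) {
    idx <- which(ccs == s)
    pi <- config$ige_given_ccs[[s]]
    pp <- config$pt_given_ccs[[s]]
    if (!is.null(pi))
      ige[idx] <- sample(names(pi), length(idx), replace = TRUE, prob = pi)
    if (!is.null(pp))
      pt[idx] <- sample(names(pp), length(idx), replace = TRUE, prob = pp)
  }

  # sentence-realization substream (independent of the value draws)
  set.seed(config$seed + 1000003L)
  genes <- sample(config$gene_pool, n, replace = TRUE)
  tmpl <- sample(config$templates, n, replace = TRUE)
  kw <- vapply(cge, function(d) sample(config$keywords[[d]], 1L),
               character(1), USE.NAMES = FALSE)
  cterm <- vapply(types, function(t) {
    pool <- config$cancer_terms[[t]]
    if (is.null(pool)) sub("^other:", "", t) else sample(pool, 1L)
  }, character(1), USE.NAMES = FALSE)

  units <- vector("list", n)
  for (i in seq_len(n)) {
    filled <- fill_template(tmpl[i], list(GENE = genes[i], KW = kw[i],
                                          CANCER = cterm[i]))
    units[[i]] <- annotation_unit(
      unit_id = sprintf("syn%05d", i), sentence = filled$sentence,
      gene = filled$spans$GENE,
      expression_keywords = list(filled$spans$KW),
      cancer_terms = list(filled$spans$CANCER),
      cge = cge[i], ccs = ccs[i], ige = ige[i], pt = pt[i],
      cancer_type = types[i], validate = FALSE)
  }
  corpus(units, list(generator = "synthetic", seed = config$seed,
                     n_units = n))
}

#' Simulate a second annotator by random flips
#'
#' For each unit and concept, with the configured per-concept probability
#' the value is replaced by a uniformly random *different* admissible
#' value; otherwise it is copied. Skipped IGE/PT values (unidentifiable
#' CCS) stay skipped and contribute no pair. The result feeds the
#' agreement metrics.
#'
#' @param corpus An `annotation_corpus` (the first annotator's labels).
#' @param flip_rates Named per-concept flip probabilities (`CGE`, `CCS`,
#'   `IGE`, `PT`).
#' @param seed Integer seed for the perturbation substream.
#' @return Named list of [agreement_pairs()], one per concept.
#' @export
perturb_annotations <- function(corpus, flip_rates, seed) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (any(flip_rates < 0 | flip_rates > 1))
    stop("flip_rates must lie in [0, 1]", call. = FALSE)
  df <- as.data.frame(corpus)
  set.seed(seed)
  out <- list()
  for (concept in names(concept_catalog())) {
    a <- df[[tolower(concept)]]
    a <- a[!is.na(a)]
    if (length(a) == 0L) next
    f <- flip_rates[[concept]]
    if (is.null(f) || is.na(f)) f <- 0
    vals <- concept_values(concept)
    flip <- stats::runif(length(a)) < f
    b <- a
    if (any(flip))
      b[flip] <- vapply(a[flip], function(v)
        sample(setdiff(vals, v), 1L), character(1))
    out[[concept]] <- agreement_pairs(concept, a, b)
  }
  out
}
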