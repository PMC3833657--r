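#' Read a corpus from its canonical JSONL or TSV dialect
#'
#' Two canonical on-disk dialects are defined:
#'
#' * **jsonl** — one JSON object per line with keys `unit_id`, `pmid`,
#'   `cancer_type`, `sentence`, `gene` (`{text,start,end}`),
#'   `expression_keywords`, `cancer_terms` (arrays of span objects),
#'   `cge`, `ccs`, `ige`, `pt`; skipped IGE/PT are JSON `null`. Offsets are
#'   0-based half-open code-point offsets on `sentence`.
#' * **tsv** — header row `unit_id`, `pmid`, `cancer_type`,
#'   `marked_sentence`, `cge`, `ccs`, `ige`, `pt`; spans are carried by the
#'   bracket markup of `marked_sentence` (see [render_marked_sentence()]);
#'   an empty cell means the concept was skipped.
#'
#' Every record must pass [validate_unit()]; otherwise parsing stops with
#' an error naming the offending line and field.
#'
#' @param source File path, connection, or a character vector of lines.
#' @param format `"jsonl"` or `"tsv"`.
#' @return An `annotation_corpus`.
#' @seealso [write_corpus()] for the inverse; round-tripping through either
#'   dialect is the identity on valid corpora.
#' @export
parse_corpus <- function(source, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  lines <- read_source_lines(source)
  if (format == "jsonl") parse_corpus_jsonl(lines, provenance_of(source))
  else parse_corpus_tsv(lines, provenance_of(source))
}

read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1L && file.exists(source))
    return(readLines(source, warn = FALSE, encoding = "UTF-8"))
  as.character(source)
}

provenance_of <- function(source) {
  if (is.character(source) && length(source) == 1L && file.exists(source))
    list(source = source)
  else list(source = "<in-memory>")
}

json_field <- function(obj, key, line) {
  if (is.null(obj[[key]]))
    stop(sprintf("line %d: missing field %s", line, dQuote(key)), call. = FALSE)
  obj[[key]]
}

json_span <- function(x, line, field) {
  if (!is.list(x) || is.null(x$text) || is.null(x$start) || is.null(x$end))
    stop(sprintf("line %d: field %s is not a span object", line, dQuote(field)),
         call. = FALSE)
  span(x$text, x$start, x$end)
}

# NULL (JSON null) -> NA; check the token against the concept catalog here so
# a typo is reported with its line number
json_value <- function(x, concept, line, allow_na) {
  if (is.null(x)) {
    if (allow_na) return(NA_character_)
    stop(sprintf("line %d: %s must not be null", line, concept), call. = FALSE)
  }
  if (!is_admissible(concept, x))
    stop(sprintf("line %d: %s value %s not in the concept catalog",
                 line, concept, dQuote(as.character(x))), call. = FALSE)
  as.character(x)
}

parse_corpus_jsonl <- function(lines, provenance) {
  keep <- nzchar(trimws(lines))
  units <- vector("list", sum(keep))
  k <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE))
    u <- annotation_unit(
      unit_id = json_field(obj, "unit_id", i),
      pmid = if (is.null(obj$pmid)) "" else as.character(obj$pmid),
      cancer_type = json_field(obj, "cancer_type", i),
      sentence = json_field(obj, "sentence", i),
      gene = json_span(json_field(obj, "gene", i), i, "gene"),
      expression_keywords = lapply(json_field(obj, "expression_keywords", i),
                                   json_span, line = i,
                                   field = "expression_keywords"),
      cancer_terms = lapply(json_field(obj, "cancer_terms", i), json_span,
                            line = i, field = "cancer_terms"),
      cge = json_value(obj$cge, "CGE", i, allow_na = FALSE),
      ccs = json_value(obj$ccs, "CCS", i, allow_na = FALSE),
      ige = json_value(obj$ige, "IGE", i, allow_na = TRUE),
      pt = json_value(obj$pt, "PT", i, allow_na = TRUE),
      validate = FALSE)
    v <- validate_unit(u)
    if (length(v))
      stop(sprintf("line %d: invalid unit %s: %s", i, dQuote(u$unit_id),
                   paste(v, collapse = "; ")), call. = FALSE)
    k <- k + 1L
    units[[k]] <- u
  }
  corpus(units[seq_len(k)], provenance)
}

tsv_columns <- c("unit_id", "pmid", "cancer_type", "marked_sentence",
                 "cge", "ccs", "ige", "pt")

parse_corpus_tsv <- function(lines, provenance) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(corpus(list(), provenance))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, tsv_columns))
    stop("line 1: TSV header must be: ", paste(tsv_columns, collapse = ", "),
         call. = FALSE)
  units <- vector("list", length(lines) - 1L)
  for (i in seq_along(units)) {
    lineno <- i + 1L
    f <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(tsv_columns)  # pad trailing empty cells
    f[is.na(f)] <- ""
    names(f) <- tsv_columns
    parsed <- parse_marked_sentence(f[["marked_sentence"]])
    roles <- vapply(parsed$spans, function(s) s$role, character(1))
    if (sum(roles == "g") != 1L)
      stop(sprintf("line %d: marked_sentence must contain exactly one gene marker",
                   lineno), call. = FALSE)
    get_role <- function(r) lapply(parsed$spans[roles == r],
                                   function(s) s$span)
    blank_na <- function(x, concept) {
      if (!nzchar(x)) return(NA_character_)
      if (!is_admissible(concept, x))
        stop(sprintf("line %d: %s value %s not in the concept catalog",
                     lineno, concept, dQuote(x)), call. = FALSE)
      x
    }
    u <- annotation_unit(
      unit_id = f[["unit_id"]], pmid = f[["pmid"]],
      cancer_type = f[["cancer_type"]], sentence = parsed$sentence,
      gene = get_role("g")[[1L]],
      expression_keywords = get_role("e"),
      cancer_terms = get_role("c"),
      cge = blank_na(f[["cge"]], "CGE"),
      ccs = blank_na(f[["ccs"]], "CCS"),
      ige = blank_na(f[["ige"]], "IGE"),
      pt = blank_na(f[["pt"]], "PT"),
      validate = FALSE)
    v <- validate_unit(u)
    if (length(v))
      stop(sprintf("line %d: invalid unit %s: %s", lineno, dQuote(u$unit_id),
                   paste(v, collapse = "; ")), call. = FALSE)
    units[[i]] <- u
  }
  corpus(units, provenance)
}

#' Write a corpus in a canonical dialect
#'
#' Serializes to the JSONL or TSV dialect documented in [parse_corpus()].
#' Units violating the scheme invariants are refused.
#'
#' @param corpus An `annotation_corpus`.
#' @param path Output file path, or `NULL` to return the lines.
#' @param format `"jsonl"` or `"tsv"`.
#' @return The serialized lines, invisibly when `path` is given.
#' @export
write_corpus <- function(corpus, path = NULL, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "annotation_corpus"))
  for (u in corpus$units) {
    v <- validate_unit(u)
    if (length(v))
      stop("refusing to serialize invalid unit ", dQuote(u$unit_id), ": ",
           paste(v, collapse = "; "), call. = FALSE)
  }
  lines <- if (format == "jsonl") {
    vapply(corpus$units, unit_to_json, character(1))
  } else {
    c(paste(tsv_columns, collapse = "\t"),
      vapply(corpus$units, unit_to_tsv, character(1)))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = FALSE)
    return(invisible(lines))
  }
  lines
}

unit_to_json <- function(u) {
  span_obj <- function(s) list(text = s$text, start = s$start, end = s$end)
  obj <- list(
    unit_id = u$unit_id, pmid = u$pmid, cancer_type = u$cancer_type,
    sentence = u$sentence, gene = span_obj(u$gene),
    expression_keywords = lapply(u$expression_keywords, span_obj),
    cancer_terms = lapply(u$cancer_terms, span_obj),
    cge = u$cge, ccs = u$ccs, ige = u$ige, pt = u$pt)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                                digits = NA))
}

unit_to_tsv <- function(u) {
  cell <- function(x) if (is.na(x)) "" else x
  paste(c(u$unit_id, u$pmid, u$cancer_type, render_marked_sentence(u),
          u$cge, u$ccs, cell(u$ige), cell(u$pt)), collapse = "\t")
}

#' Read a term dictionary
#'
#' One term per line, UTF-8; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the dictionary file.
#' @return Character vector of terms.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
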