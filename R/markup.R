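#' Render a unit with inline bracket markup
#'
#' Wraps the gene span as `[*...*]_g_`, expression keywords as `[*...*]_e_`
#' and cancer terms as `[*...*]_c_`, the display convention used for
#' annotated example sentences. Markers are inserted right-to-left so that
#' earlier offsets stay valid; [strip_markers()] recovers the original
#' sentence exactly.
#'
#' @param unit A valid [annotation_unit()].
#' @return The marked sentence as a single string.
#' @export
render_marked_sentence <- function(unit) {
  spans <- collect_role_spans(unit)
  # reject overlaps between different roles: the flat bracket notation
  # cannot represent them unambiguously
  if (nrow(spans) > 1L) {
    o <- order(spans$start, spans$end)
    s <- spans[o, ]
    for (i in seq_len(nrow(s) - 1L)) {
      if (s$end[i] > s$start[i + 1L])
        stop(sprintf(
          "overlapping spans: %s [%d,%d) and %s [%d,%d)",
          s$role[i], s$start[i], s$end[i],
          s$role[i + 1L], s$start[i + 1L], s$end[i + 1L]), call. = FALSE)
    }
  }
  out <- unit$sentence
  spans <- spans[order(spans$start, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    out <- paste0(
      substr(out, 1L, spans$start[i]),
      "[*", substr(out, spans$start[i] + 1L, spans$end[i]), "*]_",
      spans$role[i], "_",
      substr(out, spans$end[i] + 1L, nchar(out)))
  }
  out
}

collect_role_spans <- function(unit) {
  one <- function(sp, role)
    data.frame(start = sp$start, end = sp$end, role = role,
               stringsAsFactors = FALSE)
  rows <- c(list(one(unit$gene, "g")),
            lapply(unit$expression_keywords, one, role = "e"),
            lapply(unit$cancer_terms, one, role = "c"))
  do.call(rbind, rows)
}

#' Strip inline bracket markup
#'
#' Inverse of [render_marked_sentence()]: removes all `[*...*]_g_` /
#' `_e_` / `_c_` markers, returning the plain sentence.
#'
#' @param marked Marked sentence string(s).
#' @return Plain sentence string(s).
#' @export
strip_markers <- function(marked) {
  gsub("\\[\\*(.*?)\\*\\]_[gec]_", "\\1", marked, perl = TRUE)
}

# Parse a bracket-marked sentence into the plain sentence plus role spans
# (offsets on the plain sentence). Used by the TSV corpus reader.
parse_marked_sentence <- function(marked) {
  m <- gregexpr("\\[\\*(.*?)\\*\\]_([gec])_", marked, perl = TRUE)[[1]]
  plain <- ""
  spans <- list()
  cursor <- 1L  # 1-based position in `marked`
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      pre <- substr(marked, cursor, m[i] - 1L)
      plain <- paste0(plain, pre)
      whole <- substr(marked, m[i], m[i] + lens[i] - 1L)
      text <- sub("\\[\\*(.*?)\\*\\]_([gec])_", "\\1", whole, perl = TRUE)
      role <- sub("\\[\\*(.*?)\\*\\]_([gec])_", "\\2", whole, perl = TRUE)
      start <- nchar(plain)
      plain <- paste0(plain, text)
      spans[[length(spans) + 1L]] <-
        list(span = span(text, start, start + nchar(text)), role = role)
      cursor <- m[i] + lens[i]
    }
  }
  plain <- paste0(plain, substr(marked, cursor, nchar(marked)))
  list(sentence = plain, spans = spans)
}
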