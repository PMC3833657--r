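#' Dictionary-based longest-match tagging
#'
#' Tags occurrences of dictionary terms in a text by leftmost-longest,
#' non-overlapping, case-insensitive matching at token boundaries — the
#' standard way cancer-related terms are located in candidate sentences.
#' Tokens are maximal runs of letters and digits; a match must start and
#' end on token boundaries, and scanning resumes immediately after each
#' accepted match.
#'
#' @param text A single string to scan.
#' @param dictionary Non-empty character vector of terms.
#' @return List of [span()]s, sorted by start offset, never overlapping.
#' @examples
#' longest_match_tag("human prostate cancer tissues",
#'                   c("prostate cancer", "cancer"))
#' @export
longest_match_tag <- function(text, dictionary) {
  stopifnot(is.character(text), length(text) == 1L)
  dictionary <- unique(as.character(dictionary))
  dictionary <- dictionary[nzchar(dictionary)]
  if (length(dictionary) == 0L)
    stop("dictionary must contain at least one non-empty term", call. = FALSE)

  n <- nchar(text)
  chars <- if (n) strsplit(text, "", fixed = TRUE)[[1L]] else character(0)
  is_word <- grepl("[[:alnum:]]", chars)
  # token boundary positions: i (0-based offset) is a start boundary if
  # char i+1 is a word char and char i is not; end boundary symmetric
  start_ok <- function(i) i < n && is_word[i + 1L] && (i == 0L || !is_word[i])
  end_ok <- function(i) i > 0L && is_word[i] && (i == n || !is_word[i + 1L])

  dict_lower <- tolower(dictionary)
  ord <- order(nchar(dict_lower), decreasing = TRUE)  # longest first
  dict_lower <- dict_lower[ord]
  text_lower <- tolower(text)

  out <- list()
  i <- 0L
  while (i < n) {
    if (!start_ok(i)) { i <- i + 1L; next }
    hit <- NULL
    for (term in dict_lower) {
      j <- i + nchar(term)
      if (j > n || !end_ok(j)) next
      if (substr(text_lower, i + 1L, j) == term) { hit <- j; break }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    out[[length(out) + 1L]] <- span(substr(text, i + 1L, hit), i, hit)
    i <- hit
  }
  out
}
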