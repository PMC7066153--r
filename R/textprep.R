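#' Default filled-pause lexicon
#'
#' Hesitation markers that transcribers commonly write out ("uh", "um", ...)
#' and that are removed during preprocessing, since they carry no recall
#' content. Override by passing your own character vector to [preprocess()],
#' or via the `hesitation_markers` entry of a pipeline config file.
#'
#' @return Character vector of lowercase markers.
#' @export
default_hesitation_markers <- function() {
  c("uh", "um", "er", "ah", "eh", "hm", "hmm", "mhm", "uh-huh", "um-hum")
}

#' Normalize raw text into a token sequence
#'
#' Lowercases (full Unicode case folding), removes punctuation and filled
#' pauses, and splits on whitespace. Apostrophes are kept only between
#' letters or digits ("dad's"); every other non-alphanumeric character,
#' including hyphens and dashes, acts as a separator. A whitespace chunk that
#' equals a hesitation marker once surrounding punctuation is stripped (e.g.
#' "uh-huh,") is dropped whole, so multi-part markers are matched before
#' hyphen splitting.
#'
#' No stemming, stop-word removal or spelling correction is applied: surface
#' and semantic features downstream expect the verbatim surviving words.
#'
#' @param text A single character string (may be empty or `NA`, both of which
#'   yield an empty token sequence).
#' @param hesitation_markers Character vector of markers to remove;
#'   compared after lowercasing.
#' @return Character vector of tokens in surface order.
#' @examples
#' preprocess("The boy, uh, RAN.")
#' preprocess("Dad's red—balloon!!")
#' @export
preprocess <- function(text, hesitation_markers = default_hesitation_markers()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- stringi::stri_trans_tolower(text)
  chunks <- stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)[[1L]]
  if (!length(chunks)) return(character(0))
  toks <- lapply(chunks, function(ch) {
    bare <- gsub("^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$", "", ch, perl = TRUE)
    if (bare %in% hesitation_markers || !nzchar(bare)) return(character(0))
    # non-alphanumeric, non-apostrophe characters separate tokens
    s <- gsub("[^\\p{L}\\p{N}']+", " ", bare, perl = TRUE)
    # apostrophes survive only between alphanumerics
    s <- gsub("(?<![\\p{L}\\p{N}])'|'(?![\\p{L}\\p{N}])", "", s, perl = TRUE)
    out <- stringi::stri_split_regex(s, "\\s+", omit_empty = TRUE)[[1L]]
    out[!out %in% hesitation_markers]
  })
  unlist(toks, use.names = FALSE)
}

#' Preprocess a vector of texts
#'
#' @param texts Character vector.
#' @inheritParams preprocess
#' @return List of token vectors, one per input element.
#' @export
preprocess_all <- function(texts, hesitation_markers = default_hesitation_markers()) {
  lapply(as.character(texts), preprocess, hesitation_markers = hesitation_markers)
}

#' Distinct word types of a token sequence
#'
#' A word type is a distinct word form; repeated tokens count once.
#'
#' @param tokens Character vector of tokens (as from [preprocess()]).
#' @return Character vector of distinct tokens, in order of first occurrence.
#' @export
word_types <- function(tokens) {
  stopifnot(is.character(tokens))
  unique(tokens)
}
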