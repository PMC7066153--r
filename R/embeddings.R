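#' Read word embeddings in word2vec text format
#'
#' The file must start with a header line `<vocab_size> <dim>`, followed by
#' one line per word: the word, then `dim` whitespace-separated numbers.
#' Binary word2vec files are not supported.
#'
#' @param path Path to a UTF-8 text file.
#' @return A numeric matrix with one row per word (rownames are the
#'   vocabulary) and `dim` columns, of class `embedding_space`.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("embedding file is empty: ", path)
  hdr <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  hdr_n <- suppressWarnings(as.integer(hdr))
  if (length(hdr) != 2L || anyNA(hdr_n) || any(hdr_n < 1L))
    stop("line 1: malformed word2vec header, expected '<vocab_size> <dim>', got '",
         lines[[1L]], "'")
  nv <- hdr_n[[1L]]
  d <- hdr_n[[2L]]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nv)
    stop("header declares ", nv, " words but file has ", length(body), " entry lines")
  parts <- strsplit(trimws(body), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- matrix(NA_real_, nrow = nv, ncol = d)
  for (i in seq_len(nv)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (length(v) != d || anyNA(v))
      stop("line ", i + 1L, ": expected ", d, " numeric values for word '",
           words[[i]], "', got ", length(parts[[i]]) - 1L)
    mat[i, ] <- v
  }
  dup <- anyDuplicated(words)
  if (dup) stop("line ", dup + 1L, ": duplicate word '", words[[dup]], "'")
  rownames(mat) <- words
  class(mat) <- c("embedding_space", class(mat))
  mat
}

#' Write word embeddings in word2vec text format
#'
#' @param space Numeric matrix with vocabulary rownames.
#' @param path Output file path.
#' @param digits Significant digits used when printing vector components.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(space, path, digits = 8L) {
  stopifnot(is.matrix(space), !is.null(rownames(space)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(space), ncol(space)), con)
  rows <- apply(space, 1L, function(v)
    paste(format(v, digits = digits, trim = TRUE, scientific = TRUE), collapse = " "))
  writeLines(paste(rownames(space), rows), con)
  invisible(path)
}

#' Construct an embedding space from a matrix
#'
#' @param mat Numeric matrix; rownames are the vocabulary.
#' @return The validated matrix, of class `embedding_space`.
#' @export
embedding_space <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), ncol(mat) >= 1L)
  if (is.null(rownames(mat)) || any(!nzchar(rownames(mat))))
    stop("embedding matrix needs non-empty vocabulary rownames")
  if (anyDuplicated(rownames(mat))) stop("duplicate words in embedding vocabulary")
  if (!inherits(mat, "embedding_space")) class(mat) <- c("embedding_space", class(mat))
  mat
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", nrow(x), " words, ", ncol(x), " dimensions\n", sep = "")
  invisible(x)
}

#' Partition tokens by embedding vocabulary membership
#'
#' Matching is exact string match on preprocessed tokens; no subword or case
#' fallback. Multiplicity is preserved: the two parts together are a
#' permutation-free split of the input.
#'
#' @param space An `embedding_space` (or any matrix with vocabulary rownames).
#' @param tokens Character vector of tokens.
#' @return List with elements `in_vocab` and `out_of_vocab`.
#' @export
lookup_tokens <- function(space, tokens) {
  stopifnot(is.character(tokens))
  known <- tokens %in% rownames(space)
  list(in_vocab = tokens[known], out_of_vocab = tokens[!known])
}
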