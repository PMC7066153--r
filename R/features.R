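#' Count word types shared between prompt and response
#'
#' The surface similarity feature: the number of distinct word forms that
#' occur in both the story prompt and the recall, each counted once however
#' often it is repeated.
#'
#' @param prompt,response Token vectors (as from [preprocess()]).
#' @return Nonnegative integer.
#' @export
common_types <- function(prompt, response) {
  length(intersect(word_types(prompt), word_types(response)))
}

#' Normalized bag-of-words distribution
#'
#' Represents a document as a probability distribution over its distinct
#' in-vocabulary words, weighted by frequency (the nBOW representation used
#' by optimal-transport text distances). Out-of-vocabulary tokens are dropped
#' before normalization; their count is recorded in `n_dropped`.
#'
#' @param tokens Character vector of tokens.
#' @param space Embedding space (matrix with vocabulary rownames).
#' @return An object of class `nbow` with fields `words`, `counts`, `weights`
#'   and `n_dropped`, or `NULL` if no token is in the vocabulary (the
#'   unscorable-response signal, deliberately distinct from an error).
#' @export
nbow <- function(tokens, space) {
  stopifnot(is.character(tokens))
  known <- tokens[tokens %in% rownames(space)]
  n_dropped <- length(tokens) - length(known)
  if (!length(known)) return(NULL)
  tab <- table(known)
  structure(
    list(words = names(tab), counts = as.integer(tab),
         weights = as.numeric(tab) / sum(tab), n_dropped = n_dropped),
    class = "nbow")
}

#' Construct an nBOW distribution from explicit weights
#'
#' @param words Character vector of distinct words.
#' @param weights Positive weights summing to 1 (tolerance 1e-9).
#' @return An `nbow` object.
#' @export
nbow_from_weights <- function(words, weights) {
  stopifnot(is.character(words), is.numeric(weights),
            length(words) == length(weights))
  if (anyDuplicated(words)) stop("nBOW words must be distinct")
  if (any(weights <= 0)) stop("nBOW weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("nBOW weights must sum to 1")
  structure(list(words = words, counts = NULL, weights = as.numeric(weights),
                 n_dropped = 0L), class = "nbow")
}

#' @export
print.nbow <- function(x, ...) {
  cat("<nbow> ", length(x$words), " words (", x$n_dropped,
      " out-of-vocabulary tokens dropped)\n", sep = "")
  invisible(x)
}

# Pairwise cost matrix between two word sets in an embedding space.
embedding_cost_matrix <- function(words_a, words_b, space,
                                  cost = c("euclidean", "cosine")) {
  cost <- match.arg(cost)
  miss <- setdiff(c(words_a, words_b), rownames(space))
  if (length(miss))
    stop("words not in embedding vocabulary: ", paste(miss, collapse = ", "))
  A <- space[words_a, , drop = FALSE]
  B <- space[words_b, , drop = FALSE]
  if (cost == "euclidean") {
    g <- A %*% t(B)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * g
    d2[d2 < 0] <- 0
    d2[outer(words_a, words_b, `==`)] <- 0  # exact zero for identical words
    sqrt(d2)
  } else {
    na <- sqrt(rowSums(A^2))
    nb <- sqrt(rowSums(B^2))
    if (any(na == 0) || any(nb == 0)) stop("zero vector: cosine cost undefined")
    cm <- 1 - (A %*% t(B)) / outer(na, nb)
    cm[cm < 0] <- 0
    cm
  }
}

# Scale probability weights to exactly-summing integers for the exact solver.
integer_weights <- function(w, scale = 1e9) {
  s <- round(w * scale)
  s[which.max(s)] <- s[which.max(s)] + (scale - sum(s))
  if (any(s <= 0)) stop("weight too small to scale; increase `scale`")
  s
}

#' Word Mover's Distance between two nBOW distributions
#'
#' The minimum cumulative embedding-space distance needed to transport the
#' probability mass of one document onto the other: the optimal objective of
#' the transportation problem whose marginals are the two nBOW weight vectors
#' and whose cost between two words is the distance between their vectors
#' (Euclidean by default). Solved exactly by a successive-shortest-path
#' min-cost-flow routine in compiled code; only the objective value is
#' contractual, since optimal plans may be non-unique.
#'
#' @param x,y `nbow` objects (see [nbow()]); all their words must be in
#'   `space`.
#' @param space Embedding space.
#' @param cost `"euclidean"` (default, raw unnormalized vectors) or
#'   `"cosine"`.
#' @return Nonnegative distance; symmetric in `x` and `y`.
#' @seealso [wmd_plan()] for the optimal transport plan,
#'   [word_centroid_distance()] for the cheap lower bound.
#' @export
wmd <- function(x, y, space, cost = c("euclidean", "cosine")) {
  wmd_plan(x, y, space, cost = cost)$distance
}

#' Word Mover's Distance with its optimal transport plan
#'
#' @inheritParams wmd
#' @return List with `distance` (optimal objective) and `plan` (matrix of
#'   transported mass; row sums equal `x$weights`, column sums `y$weights`,
#'   both within 1e-6).
#' @export
wmd_plan <- function(x, y, space, cost = c("euclidean", "cosine")) {
  stopifnot(inherits(x, "nbow"), inherits(y, "nbow"))
  cm <- embedding_cost_matrix(x$words, y$words, space, cost = cost)
  scale <- 1e9
  res <- .transport_ssp(cm, integer_weights(x$weights, scale),
                        integer_weights(y$weights, scale))
  plan <- res$flow / scale
  dimnames(plan) <- list(x$words, y$words)
  list(distance = res$objective / scale, plan = plan)
}

#' Word centroid distance (lower bound on WMD)
#'
#' Distance between the weighted mean word vectors of two documents. For the
#' Euclidean transport cost this never exceeds the Word Mover's Distance of
#' the same pair, which makes it a useful independent check.
#'
#' @inheritParams wmd
#' @return Nonnegative real.
#' @export
word_centroid_distance <- function(x, y, space) {
  stopifnot(inherits(x, "nbow"), inherits(y, "nbow"))
  ca <- colSums(space[x$words, , drop = FALSE] * x$weights)
  cb <- colSums(space[y$words, , drop = FALSE] * y$weights)
  sqrt(sum((ca - cb)^2))
}

#' Extract the two scoring features for one prompt/response pair
#'
#' @param prompt,response Token vectors. The prompt must have at least one
#'   in-vocabulary token; a response with none is unscorable and yields a
#'   missing `wmd` rather than an error.
#' @param space Embedding space.
#' @param cost Transport cost, see [wmd()].
#' @return List with `common_types`, `wmd` (`NA` if unscorable), `n_tokens`
#'   (response length in words) and `n_oov` (response tokens outside the
#'   embedding vocabulary).
#' @export
extract_features <- function(prompt, response, space,
                             cost = c("euclidean", "cosine")) {
  pn <- nbow(prompt, space)
  if (is.null(pn)) stop("prompt has no in-vocabulary tokens")
  rn <- nbow(response, space)
  list(common_types = common_types(prompt, response),
       wmd = if (is.null(rn)) NA_real_ else wmd(pn, rn, space, cost = cost),
       n_tokens = length(response),
       n_oov = if (is.null(rn)) length(response) else rn$n_dropped)
}

#' Feature table for a set of transcribed responses
#'
#' Preprocesses prompts and responses, then computes the common-word-types
#' and Word Mover's Distance features per response. Unscorable responses (no
#' in-vocabulary words) are kept in the table with a missing `wmd`, never
#' silently dropped.
#'
#' @param responses Data frame with columns `response_id`, `prompt_id`,
#'   `text`.
#' @param prompts Data frame with columns `prompt_id`, `text`.
#' @param space Embedding space.
#' @param hesitation_markers Passed to [preprocess()].
#' @param cost Transport cost, see [wmd()].
#' @return Data frame with columns `response_id`, `common_types`, `wmd`,
#'   `n_tokens`, `n_oov`.
#' @export
compute_features <- function(responses, prompts, space,
                             hesitation_markers = default_hesitation_markers(),
                             cost = c("euclidean", "cosine")) {
  need <- c("response_id", "prompt_id", "text")
  stopifnot(all(need %in% names(responses)),
            all(c("prompt_id", "text") %in% names(prompts)))
  unknown <- setdiff(responses$prompt_id, prompts$prompt_id)
  if (length(unknown))
    stop("responses reference unknown prompt_id: ", paste(unique(unknown), collapse = ", "))
  ptoks <- lapply(prompts$text, preprocess, hesitation_markers = hesitation_markers)
  names(ptoks) <- prompts$prompt_id
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    rt <- preprocess(responses$text[[i]], hesitation_markers = hesitation_markers)
    f <- extract_features(ptoks[[as.character(responses$prompt_id[[i]])]], rt,
                          space, cost = cost)
    data.frame(response_id = responses$response_id[[i]],
               common_types = f$common_types, wmd = f$wmd,
               n_tokens = f$n_tokens, n_oov = f$n_oov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
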