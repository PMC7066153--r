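#' Validate a ratings table
#'
#' @param ratings Data frame with columns `response_id`, `rater_id`,
#'   `rating`; ratings must lie on the 0-6 scale and each
#'   (response, rater) pair may appear once.
#' @return The validated data frame (ids coerced to character).
#' @export
validate_ratings <- function(ratings) {
  need <- c("response_id", "rater_id", "rating")
  stopifnot(is.data.frame(ratings), all(need %in% names(ratings)))
  ratings$response_id <- as.character(ratings$response_id)
  ratings$rater_id <- as.character(ratings$rater_id)
  ratings$rating <- as.numeric(ratings$rating)
  if (anyNA(ratings$rating)) stop("missing rating values")
  if (any(ratings$rating < 0 | ratings$rating > 6))
    stop("ratings must lie in [0, 6]")
  if (anyDuplicated(ratings[c("response_id", "rater_id")]))
    stop("duplicate (response_id, rater_id) rating")
  ratings
}

#' Gold-standard rating per response
#'
#' The arithmetic mean of the available human ratings of each response; this
#' average is the target the automated scoring model is trained to predict.
#'
#' @inheritParams validate_ratings
#' @return Named numeric vector: mean rating per `response_id`.
#' @export
gold_standard <- function(ratings) {
  ratings <- validate_ratings(ratings)
  out <- vapply(split(ratings$rating, ratings$response_id), mean, numeric(1))
  out[order(names(out))]
}

#' Correlation of one rater with the rest
#'
#' Pearson correlation between a rater's scores and the mean of the remaining
#' raters' scores over jointly rated responses (leave-one-out gold standard).
#' Set `include_self = TRUE` to correlate against the full gold standard
#' including the rater's own score.
#'
#' @inheritParams validate_ratings
#' @param rater_id Rater to evaluate.
#' @param include_self Include the rater's own rating in the reference mean?
#' @return Pearson correlation.
#' @export
rater_vs_rest <- function(ratings, rater_id, include_self = FALSE) {
  ratings <- validate_ratings(ratings)
  own <- ratings[ratings$rater_id == rater_id, ]
  if (!nrow(own)) stop("unknown rater_id: ", rater_id)
  others <- ratings[ratings$rater_id != rater_id, ]
  ref_pool <- if (include_self) ratings else others
  # responses the rater scored that at least one other rater also scored
  shared <- intersect(own$response_id, unique(others$response_id))
  if (length(shared) < 3L)
    stop("correlation undefined: rater shares fewer than 3 responses with others")
  x <- own$rating[match(shared, own$response_id)]
  y <- vapply(shared, function(id)
    mean(ref_pool$rating[ref_pool$response_id == id]), numeric(1))
  pearson_r(x, y)
}

#' Pairwise inter-rater correlations
#'
#' Pearson correlation for every rater pair over their jointly rated
#' responses, plus the unweighted mean across pairs. Pairs with fewer than
#' `min_overlap` shared responses (or constant scores) are omitted with a
#' message; no imputation is performed.
#'
#' @inheritParams validate_ratings
#' @param min_overlap Minimum number of jointly rated responses per pair.
#' @return List with `pairs` (data frame `rater_i`, `rater_j`, `n`, `r`) and
#'   `mean_r`.
#' @export
pairwise_interrater <- function(ratings, min_overlap = 3L) {
  ratings <- validate_ratings(ratings)
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) < 2L) stop("need at least 2 raters")
  by_rater <- split(ratings, ratings$rater_id)
  rows <- list()
  skipped <- character(0)
  for (a in seq_along(raters)[-length(raters)]) {
    for (b in seq.int(a + 1L, length(raters))) {
      ra <- by_rater[[raters[[a]]]]
      rb <- by_rater[[raters[[b]]]]
      shared <- intersect(ra$response_id, rb$response_id)
      lab <- paste(raters[[a]], raters[[b]], sep = ":")
      x <- ra$rating[match(shared, ra$response_id)]
      y <- rb$rating[match(shared, rb$response_id)]
      if (length(shared) < min_overlap || sd(x) == 0 || sd(y) == 0) {
        skipped <- c(skipped, lab)
        next
      }
      rows[[lab]] <- data.frame(rater_i = raters[[a]], rater_j = raters[[b]],
                                n = length(shared), r = pearson_r(x, y),
                                stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message("omitted ", length(skipped), " rater pair(s) with insufficient overlap: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) stop("no rater pair with sufficient overlap")
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, mean_r = mean(pairs$r))
}

#' Word error rate between two token sequences
#'
#' Aligns a hypothesis transcript against a reference by minimum edit cost
#' (unit costs for substitution, insertion and deletion) and reports the
#' alignment counts and the rate (S + D + I) / reference length. Among
#' tied-cost alignments the backtrace prefers substitution over insertion
#' over deletion; only the S + D + I total is contractual.
#'
#' @param reference,hypothesis Token vectors (use [preprocess()] first so
#'   human and machine transcripts are comparable).
#' @return List with `substitutions`, `deletions`, `insertions`,
#'   `ref_length` and `rate` (`NA` when the reference is empty and the rate
#'   is undefined; counts are still returned).
#' @export
word_error_rate <- function(reference, hypothesis) {
  stopifnot(is.character(reference), is.character(hypothesis))
  n <- length(reference)
  m <- length(hypothesis)
  if (n == 0L) {
    return(list(substitutions = 0L, deletions = 0L, insertions = m,
                ref_length = 0L, rate = NA_real_))
  }
  # DP over (reference prefix i, hypothesis prefix j); rows filled vectorized
  d <- matrix(0L, n + 1L, m + 1L)
  d[1L, ] <- 0L:m
  d[, 1L] <- 0L:n
  if (m > 0L) {
    for (i in seq_len(n)) {
      prev <- d[i, ]
      subc <- prev[1L:m] + (hypothesis != reference[[i]])
      cand <- pmin(prev[2L:(m + 1L)] + 1L, subc)    # deletion vs diagonal
      # insertion chains: row[j] = min_k<=j (cand_or_left-edge[k] + (j - k))
      base <- c(i, cand) - 0L:m
      d[i + 1L, ] <- 0L:m + cummin(base)
    }
  }
  # backtrace, preferring substitution/match, then insertion, then deletion
  S <- 0L; D <- 0L; I <- 0L
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        d[i + 1L, j + 1L] == d[i, j] + (reference[[i]] != hypothesis[[j]])) {
      if (reference[[i]] != hypothesis[[j]]) S <- S + 1L
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && d[i + 1L, j + 1L] == d[i + 1L, j] + 1L) {
      I <- I + 1L; j <- j - 1L
    } else {
      D <- D + 1L; i <- i - 1L
    }
  }
  list(substitutions = S, deletions = D, insertions = I,
       ref_length = n, rate = (S + D + I) / n)
}

#' Corpus-level word error rate
#'
#' Pools alignment counts over reference/hypothesis pairs before dividing:
#' total errors over total reference length, not the mean of per-file rates.
#'
#' @param references,hypotheses Parallel lists of token vectors.
#' @return List with pooled `substitutions`, `deletions`, `insertions`,
#'   `ref_length` and corpus `rate`.
#' @export
corpus_wer <- function(references, hypotheses) {
  stopifnot(is.list(references), is.list(hypotheses),
            length(references) == length(hypotheses))
  if (!length(references)) stop("need at least one reference/hypothesis pair")
  counts <- lapply(seq_along(references), function(i)
    word_error_rate(references[[i]], hypotheses[[i]]))
  S <- sum(vapply(counts, `[[`, integer(1), "substitutions"))
  D <- sum(vapply(counts, `[[`, integer(1), "deletions"))
  I <- sum(vapply(counts, `[[`, integer(1), "insertions"))
  L <- sum(vapply(counts, `[[`, integer(1), "ref_length"))
  if (L == 0L) stop("all references are empty; corpus rate undefined")
  list(substitutions = S, deletions = D, insertions = I,
       ref_length = L, rate = (S + D + I) / L)
}
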