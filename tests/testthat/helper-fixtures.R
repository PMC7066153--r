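# Shared fixture builders; everything is generated in code at test time.

# Random embedding space over the given words.
tiny_space <- function(words, dim = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(length(words) * dim), nrow = length(words))
  rownames(m) <- words
  embedding_space(m)
}

# 1-D embedding space from a named position vector.
line_space <- function(pos) {
  embedding_space(matrix(pos, ncol = 1L, dimnames = list(names(pos))))
}

# Random nBOW over a random subset (<= max_words) of the space's vocabulary.
random_nbow <- function(space, max_words = 5L) {
  k <- sample.int(min(max_words, nrow(space)), 1L)
  words <- sample(rownames(space), k)
  w <- rgamma(k, 1) + 1e-3
  nbow_from_weights(words, w / sum(w))
}

# Independent dense-LP oracle: solves a batch of transportation instances
# with scipy.optimize.linprog through the system python.
lp_oracle_values <- function(instances) {
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, inf, auto_unbox = FALSE, digits = NA)
  script <- testthat::test_path("lp_oracle.py")
  status <- system2("python", c(script, inf, outf))
  if (status != 0L) stop("LP oracle failed with status ", status)
  unlist(jsonlite::read_json(outf, simplifyVector = TRUE))
}

# Independent edit-distance oracle: maps tokens to single characters and
# uses utils::adist, which implements its own Levenshtein DP.
edit_distance_oracle <- function(reference, hypothesis) {
  vocab <- unique(c(reference, hypothesis))
  chars <- intToUtf8(96L + seq_along(vocab), multiple = TRUE)
  enc <- function(x) paste(chars[match(x, vocab)], collapse = "")
  drop(utils::adist(enc(reference), enc(hypothesis)))
}

# A small, fast simulated corpus for pipeline tests.
small_sim_config <- function(seed = 5L) {
  sim_config(seed = seed, vocab_size = 150L, embedding_dim = 16L,
             n_synonym_pairs = 15L, story_length_range = c(20L, 30L),
             n_raters = 3L, n_trials = c(patient = 12L, healthy = 18L))
}

# Default-condition corpus, built once and shared across test files.
default_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_corpus(sim_config(seed = 11L))
    cache
  }
})
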