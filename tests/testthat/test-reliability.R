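ratings_df <- function(mat, raters = sprintf("rater%d", seq_len(ncol(mat)))) {
  # mat: responses x raters
  data.frame(
    response_id = rep(sprintf("r%02d", seq_len(nrow(mat))), times = ncol(mat)),
    rater_id = rep(raters, each = nrow(mat)),
    rating = as.vector(mat), stringsAsFactors = FALSE)
}

test_that("gold standard is the per-response mean rating", {
  r <- ratings_df(rbind(c(4, 5, 6), c(0, 6, 3)))
  g <- gold_standard(r)
  expect_equal(unname(g[c("r01", "r02")]), c(5.0, 3.0))
  # single rater: the rating itself
  one <- data.frame(response_id = "a", rater_id = "x", rating = 4)
  expect_equal(unname(gold_standard(one)), 4)
  # invariance to rater ordering; mean-preserving extra rating changes nothing
  r2 <- r[sample(nrow(r)), ]
  expect_equal(gold_standard(r2), g)
  r3 <- rbind(r, data.frame(response_id = "r01", rater_id = "extra", rating = 5))
  expect_equal(unname(gold_standard(r3)["r01"]), 5.0)
})

test_that("ratings validation rejects malformed tables", {
  expect_error(gold_standard(data.frame(response_id = "a", rater_id = "x",
                                        rating = 7)), "0, 6")
  dup <- data.frame(response_id = c("a", "a"), rater_id = c("x", "x"),
                    rating = c(1, 2))
  expect_error(gold_standard(dup), "duplicate")
})

test_that("rater_vs_rest computes the leave-one-out correlation", {
  # rater1 tracks the mean of the others exactly
  others <- rbind(c(2, 4), c(3, 5), c(1, 3), c(4, 6))
  mat <- cbind(rowMeans(others), others)
  r <- ratings_df(mat)
  expect_equal(rater_vs_rest(r, "rater1"), 1.0)
  # a rater mirrored around the scale midpoint is perfectly anti-correlated
  mat2 <- cbind(6 - rowMeans(others), others)
  expect_equal(rater_vs_rest(ratings_df(mat2), "rater1"), -1.0)
  # handcrafted values against an explicit enumeration oracle
  mat3 <- rbind(c(5, 4, 6), c(2, 3, 1), c(4, 4, 5), c(1, 2, 0))
  r3 <- ratings_df(mat3)
  oracle <- cor(mat3[, 1], rowMeans(mat3[, 2:3]))
  expect_equal(rater_vs_rest(r3, "rater1"), oracle, tolerance = 1e-12)
  # include_self switches to the full gold standard
  oracle_self <- cor(mat3[, 1], rowMeans(mat3))
  expect_equal(rater_vs_rest(r3, "rater1", include_self = TRUE), oracle_self,
               tolerance = 1e-12)
  expect_error(rater_vs_rest(r3, "nobody"), "unknown rater")
})

test_that("pairwise inter-rater correlations match the direct formula", {
  set.seed(8)
  mat <- matrix(sample(0:6, 21, replace = TRUE), nrow = 7)
  mat[, 2] <- pmin(6, mat[, 1] + 1)    # correlated pair
  r <- ratings_df(mat)
  pw <- pairwise_interrater(r)
  expect_equal(nrow(pw$pairs), choose(3, 2))
  for (i in seq_len(nrow(pw$pairs))) {
    a <- as.integer(sub("rater", "", pw$pairs$rater_i[i]))
    b <- as.integer(sub("rater", "", pw$pairs$rater_j[i]))
    expect_equal(pw$pairs$r[i], cor(mat[, a], mat[, b]), tolerance = 1e-12)
  }
  expect_equal(pw$mean_r, mean(pw$pairs$r))
  # identical raters correlate at 1
  two <- ratings_df(cbind(c(1, 3, 5, 2), c(1, 3, 5, 2)))
  expect_equal(pairwise_interrater(two)$pairs$r, 1.0)
  # 7 raters -> 21 pairs when all overlap
  m7 <- matrix(rep(c(0, 2, 4, 5, 1, 3), 7), ncol = 7) +
    matrix(sample(0:1, 42, TRUE), ncol = 7)
  expect_equal(nrow(pairwise_interrater(ratings_df(m7))$pairs), 21L)
})

test_that("pairs without enough overlap are omitted with a message", {
  r <- rbind(
    data.frame(response_id = c("a", "b", "c", "d"), rater_id = "r1",
               rating = c(1, 2, 3, 4)),
    data.frame(response_id = c("a", "b", "c", "d"), rater_id = "r2",
               rating = c(2, 3, 4, 5)),
    data.frame(response_id = "a", rater_id = "r3", rating = 1))
  expect_message(pw <- pairwise_interrater(r), "omitted 2")
  expect_equal(nrow(pw$pairs), 1L)
})

test_that("word error rate counts a minimum-cost alignment", {
  w <- word_error_rate(c("the", "boy", "ran", "home"),
                       c("the", "boy", "walked", "quickly", "home"))
  expect_equal(w$substitutions + w$insertions, 2L)
  expect_equal(w$deletions, 0L)
  expect_equal(w$rate, 0.5)
  same <- word_error_rate(letters[1:5], letters[1:5])
  expect_equal(same$rate, 0)
  expect_equal(same$substitutions + same$deletions + same$insertions, 0L)
  del <- word_error_rate(letters[1:4], character(0))
  expect_equal(del$deletions, 4L)
  expect_equal(del$rate, 1.0)
  ins <- word_error_rate(character(0), letters[1:3])
  expect_equal(ins$insertions, 3L)
  expect_true(is.na(ins$rate))
})

test_that("alignment counts equal an independent edit-distance oracle", {
  set.seed(15)
  vocab <- c("the", "boy", "girl", "ran", "home", "red", "balloon", "a")
  for (rep in 1:200) {
    ref <- sample(vocab, sample(0:12, 1), replace = TRUE)
    hyp <- sample(vocab, sample(0:12, 1), replace = TRUE)
    w <- word_error_rate(ref, hyp)
    expect_equal(w$substitutions + w$deletions + w$insertions,
                 edit_distance_oracle(ref, hyp))
    # zero errors iff identical
    expect_equal(w$substitutions + w$deletions + w$insertions == 0L,
                 identical(ref, hyp))
  }
})

test_that("corpus WER pools counts, not per-file rates", {
  refs <- list(letters[1:4], letters[5:8])
  hyps <- list(c("x", letters[2:4]), letters[5:8])   # rates 0.25 and 0
  expect_equal(corpus_wer(refs, hyps)$rate, 0.125)
  # invariant to pair ordering
  expect_equal(corpus_wer(rev(refs), rev(hyps))$rate, 0.125)
  # all identical -> 0
  expect_equal(corpus_wer(refs, refs)$rate, 0)
  # pooling equals oracle pooling of per-pair counts on random corpora
  set.seed(16)
  for (rep in 1:20) {
    refs <- replicate(4, sample(letters[1:6], sample(1:8, 1), TRUE),
                      simplify = FALSE)
    hyps <- replicate(4, sample(letters[1:6], sample(0:8, 1), TRUE),
                      simplify = FALSE)
    pooled <- sum(mapply(edit_distance_oracle, refs, hyps)) /
      sum(lengths(refs))
    expect_equal(corpus_wer(refs, hyps)$rate, pooled)
  }
})
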