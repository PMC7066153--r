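test_that("synthetic embeddings plant synonym pairs close together", {
  cfg <- small_sim_config()
  sp <- make_embeddings(cfg)
  sp2 <- make_embeddings(cfg)
  expect_identical(sp, sp2)                       # deterministic given seed
  expect_true(all(c("the", "i", "don't", "remember") %in% rownames(sp)))
  # partner distance beats any non-partner distance, for a few pairs
  for (k in c(1L, 7L, 15L)) {
    a <- sprintf("w%04d", 2L * k - 1L)
    b <- sprintf("w%04d", 2L * k)
    d <- sqrt(rowSums(sweep(sp, 2L, sp[a, ])^2))
    d <- d[setdiff(names(d), a)]
    expect_identical(names(which.min(d)), b)
    expect_lt(min(d), 0.2)
  }
  # without synonym pairs, all distances stay bounded away from zero
  cfg0 <- sim_config(seed = 2L, vocab_size = 40L, embedding_dim = 16L,
                     n_synonym_pairs = 0L)
  sp0 <- make_embeddings(cfg0)
  dmat <- as.matrix(dist(sp0))
  expect_gt(min(dmat[upper.tri(dmat)]), 0.2)
})

test_that("stories have configured length and a content-word subset", {
  cfg <- sim_config(seed = 3L, vocab_size = 300L, embedding_dim = 8L,
                    n_synonym_pairs = 10L)
  for (i in 1:5) {
    s <- make_story(cfg, index = i)
    expect_gte(length(s), 62L)
    expect_lte(length(s), 87L)
    expect_true(any(attr(s, "content")))
    # content tokens are distinct content-vocabulary words
    ct <- s[attr(s, "content")]
    expect_false(anyDuplicated(ct) > 0)
  }
  expect_identical(make_story(cfg, 2L), make_story(cfg, 2L))
  cfg5 <- sim_config(seed = 1L, vocab_size = 100L, embedding_dim = 4L,
                     n_synonym_pairs = 0L, story_length_range = c(5L, 5L))
  expect_length(make_story(cfg5), 5L)
})

test_that("the recall channel degrades stories as configured", {
  cfg <- small_sim_config()
  sp <- make_embeddings(cfg)
  story <- make_story(cfg)
  # identity channel
  r1 <- make_recall(story, q = 1, s = 0, f = 0, seed = 4L)
  expect_identical(r1$tokens, as.character(story))
  expect_equal(r1$true_quality, 1)
  # total loss
  r0 <- make_recall(story, q = 0, s = 0, f = 0, seed = 4L)
  expect_length(r0$tokens, 0L)
  expect_equal(r0$true_quality, 0)
  # retention frequency matches the binomial expectation at large n
  long <- rep(sprintf("w%04d", 1:100), 100)        # 10,000 tokens
  r <- make_recall(long, q = 0.5, s = 0, f = 0, seed = 5L)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(r$true_quality - 0.5), 3 * se)
  # synonym substitution replaces retained tokens with embedding neighbors
  rs <- make_recall(story, q = 1, s = 1, f = 0, space = sp, seed = 6L)
  expect_length(rs$tokens, length(story))
  expect_false(identical(rs$tokens, as.character(story)))
  # fillers only insert; the story survives as an ordered subsequence
  rf <- make_recall(story, q = 1, s = 0, f = 0.5, seed = 7L)
  is_subseq <- function(a, b) {
    j <- 1L
    for (t in b) if (j <= length(a) && identical(a[[j]], t)) j <- j + 1L
    j > length(a)
  }
  expect_true(is_subseq(as.character(story), rf$tokens))
  expect_gte(length(rf$tokens), length(story))
})

test_that("simulated raters quantize and clamp the latent quality", {
  expect_identical(simulate_raters(0.5, 4L, 0, seed = 1L), rep(3L, 4))
  expect_identical(simulate_raters(1, 3L, 0, seed = 1L), rep(6L, 3))
  expect_identical(simulate_raters(0, 3L, 0, seed = 1L), rep(0L, 3))
  r <- simulate_raters(0.9, 100L, 5, seed = 2L)
  expect_true(all(r >= 0L & r <= 6L))
  expect_identical(simulate_raters(0.4, 5L, 1, seed = 3L),
                   simulate_raters(0.4, 5L, 1, seed = 3L))
})

test_that("transcript corruption hits its target word error rate", {
  cfg <- small_sim_config()
  sp <- make_embeddings(cfg)
  vocab <- rownames(sp)
  toks <- sample(vocab, 100L, replace = TRUE)
  expect_identical(corrupt_transcript(toks, 0, seed = 1L, vocabulary = vocab),
                   toks)
  for (seed in 1:5) {
    bad <- corrupt_transcript(toks, 0.2, seed = seed, vocabulary = vocab)
    rate <- word_error_rate(toks, bad)$rate
    expect_gte(rate, 0.15)
    expect_lte(rate, 0.25)
  }
  expect_identical(corrupt_transcript(toks, 0.3, seed = 9L, vocabulary = vocab),
                   corrupt_transcript(toks, 0.3, seed = 9L, vocabulary = vocab))
})

test_that("simulated corpora are reproducible and structurally complete", {
  cfg <- small_sim_config()
  corpus <- simulate_corpus(cfg)
  expect_equal(nrow(corpus$trials), 30L)
  expect_equal(nrow(corpus$responses), 30L * 3L)
  expect_setequal(unique(corpus$responses$source),
                  c("human", "custom_asr", "generic_asr"))
  expect_equal(nrow(corpus$ratings), 30L * cfg$n_raters)
  expect_true(all(corpus$ratings$rating >= 0 & corpus$ratings$rating <= 6))
  expect_true(all(corpus$responses$prompt_id %in% corpus$prompts$prompt_id))
  corpus2 <- simulate_corpus(cfg)
  expect_identical(corpus$responses, corpus2$responses)
  expect_identical(corpus$ratings, corpus2$ratings)
  # short-response tail: minimal responses present with the fixed text
  expect_true(any(corpus$trials$minimal_response))
  expect_true(all(corpus$trials$verbatim_text[corpus$trials$minimal_response] ==
                    "i don't remember"))
})

test_that("mean predicted score is nonincreasing as recall quality drops", {
  cfg <- small_sim_config()
  sp <- make_embeddings(cfg)
  story <- make_story(cfg)
  qs <- seq(1, 0, by = -0.2)
  # average features over replicates per quality bin, score with a model of
  # the expected direction (more shared types, less distance -> higher)
  model <- structure(list(intercept = 3, coef_common_types = 0.15,
                          coef_wmd = -2), class = "scoring_model")
  mean_pred <- vapply(seq_along(qs), function(i) {
    preds <- vapply(1:25, function(rep) {
      r <- make_recall(story, q = qs[i], s = 0.1, f = 0.05, space = sp,
                       seed = 1000L * i + rep)
      f <- extract_features(story, r$tokens, sp)
      if (is.na(f$wmd)) model$intercept + model$coef_wmd * 1.5
      else predict(model, data.frame(common_types = f$common_types, wmd = f$wmd))
    }, numeric(1))
    mean(preds)
  }, numeric(1))
  expect_false(is.unsorted(rev(mean_pred)))
})

test_that("cohort contrast reproduces the expected feature directions", {
  corpus <- simulate_corpus(small_sim_config(seed = 21L))
  hum <- corpus$responses[corpus$responses$source == "human", ]
  feats <- compute_features(hum, corpus$prompts, corpus$space)
  feats$group <- corpus$trials$group[match(feats$response_id,
                                           corpus$trials$response_id)]
  ok <- !is.na(feats$wmd)
  d_ct <- cohen_d_samples(feats$common_types[ok & feats$group == "patient"],
                          feats$common_types[ok & feats$group == "healthy"])
  d_wmd <- cohen_d_samples(feats$wmd[ok & feats$group == "patient"],
                           feats$wmd[ok & feats$group == "healthy"])
  expect_gt(d_ct, 0)     # healthy recalls share more word types
  expect_lt(d_wmd, 0)    # and sit closer to the story in embedding space
})

test_that("corpus files round-trip through the plain-text formats", {
  corpus <- simulate_corpus(small_sim_config())
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "embeddings.txt", "prompts.csv", "ratings.csv", "truth.csv",
    "transcripts_human.csv", "transcripts_custom_asr.csv",
    "transcripts_generic_asr.csv")))))
  sp <- read_word2vec(file.path(dir, "embeddings.txt"))
  expect_equal(nrow(sp), nrow(corpus$space))
  tr <- read_transcripts(file.path(dir, "transcripts_human.csv"))
  expect_equal(nrow(tr), nrow(corpus$trials))
  ra <- read_ratings(file.path(dir, "ratings.csv"))
  expect_equal(gold_standard(ra), gold_standard(corpus$ratings))
})
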