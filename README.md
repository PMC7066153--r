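# recallscore

Automated scoring of spoken story recall — the standard probe of verbal
episodic memory in which a participant hears a short passage and retells it,
and experts rate the retelling's accuracy on a 0–6 scale. Human rating is
the bottleneck for frequent, self-administered testing (e.g. monitoring
memory in serious mental illness via smart devices), so `recallscore`
replaces it with a transparent two-feature model, and ships the audit tools
a clinical research team needs alongside: inter-rater reliability,
transcription word error rates, group statistics, and a synthetic-study
generator for end-to-end validation.

## The method

Given a preprocessed prompt *p* and recall *r* (lowercased, punctuation and
filled pauses removed), two features are computed:

* **Common word types** — c(p, r) = |types(p) ∩ types(r)|, each distinct
  word form counted once;
* **Word Mover's Distance** — with each document as an nBOW distribution
  (relative frequencies d, d′ over its distinct in-vocabulary words) in a
  word-embedding space {x_w},

  WMD(p, r) = min over T ≥ 0 of Σᵢⱼ Tᵢⱼ ‖xᵢ − xⱼ‖₂
  subject to Σⱼ Tᵢⱼ = dᵢ and Σᵢ Tᵢⱼ = d′ⱼ,

  the optimal-transport cost of moving one document's word mass onto the
  other's (solved exactly, in compiled code). Synonyms travel cheaply;
  unrelated words do not.

A linear model ŷ = β₀ + β₁·c + β₂·WMD is fitted to the gold standard (the
mean of the human raters' 0–6 scores) by ordinary least squares and
evaluated by 5-fold cross-validation; the headline metric is the Pearson
correlation between concatenated held-out predictions and the gold ratings.

See `vignettes/recall-scoring-methods.Rmd` for assumptions, parameter
defaults, and the design rationale behind every numerical choice.

## Worked example

No clinical recordings are distributable, so the example runs on a
simulated study with the same structure: 300 trials from two cohorts,
story prompts of 62–87 words, 5 raters per response with noise calibrated
to pairwise inter-rater r ≈ 0.73, and three transcript sources corrupted at
word error rates of 7.2% / 10.5% / 23.3%.

```r
library(recallscore)

corpus <- simulate_corpus(sim_config(seed = 42))
corpus
#> <sim_corpus> 300 trials (patient: 100, healthy: 200), 10 prompts,
#>   sources: human, custom_asr, generic_asr

dir <- tempfile(); write_corpus(corpus, dir)

fit <- run_train_cv(
  prompts_file     = file.path(dir, "prompts.csv"),
  transcripts_file = file.path(dir, "transcripts_human.csv"),
  ratings_file     = file.path(dir, "ratings.csv"),
  embeddings_file  = file.path(dir, "embeddings.txt"),
  folds = 5, seed = 42,
  model_out = file.path(dir, "model.json"))
#> pooled R = 0.94 (per-fold 0.925-0.953), R^2 = 0.884 [config 63d79721]

fit$model
#> <scoring_model> rating ~ 4.079 + 0.03579 * common_types + -2.845 * wmd  (n = 300)

pairwise_interrater(corpus$ratings)$mean_r
#> [1] 0.7135802
```

Reading the output: the cross-validated pooled correlation of 0.94 means
the two-feature model predicts the simulated gold-standard rating about as
well as the rating noise allows (the simulated raters themselves agree
pairwise at r ≈ 0.71); the positive common-types coefficient and negative
WMD coefficient are the expected directions — more shared vocabulary and a
shorter semantic distance both indicate a better recall. Comparing
transcript sources:

```r
wer <- run_wer(file.path(dir, "transcripts_human.csv"),
               file.path(dir, "transcripts_custom_asr.csv"))
#> corpus WER = 0.1873 over 14897 reference words
round(unlist(wer$by_group), 3)
#> patient healthy
#>   0.196   0.184
```

Note the 18.7% figure compounds *both* sources' noise against the verbatim
truth (7.2% + 10.5%, independently applied); measured against the `truth.csv`
table each source recovers its own preset.

A thin command-line front end covers the same pipeline
(`simulate`, `train`, `score`, `wer`, `reliability`, `groupstats`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "recallscore.R", package = "recallscore"))')" \
  simulate --out fixtures --seed 3
```

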