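---
title: "Automated story-recall scoring: models, parameters and design notes"
author: "recallscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated story-recall scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallscore)
```

## The measurement problem

Story retelling is a standard probe of verbal episodic memory: a participant
hears a short passage (here, 62–87 words) and retells it, immediately and
again later in the session. Expert raters score each retelling for accuracy
on a 0–6 scale, and the mean across raters is treated as the gold-standard
score. Human rating is expensive and rate-limiting for frequent, ambulatory
testing, so this package implements an automated scorer that emulates the
human gold standard from a transcript alone, plus the audit tools needed to
trust it: inter-rater reliability, transcription word error rates, and group
contrasts.

## The scoring model

Two similarity features are computed between the preprocessed prompt $p$ and
recall $r$:

* **Common word types** $c(p, r) = |\mathrm{types}(p) \cap
  \mathrm{types}(r)|$ — a surface feature; each distinct word form counts
  once however often it is repeated.
* **Word Mover's Distance** $\mathrm{WMD}(p, r)$ — a semantic feature. Each
  document is represented as its nBOW distribution (relative frequencies
  over its distinct in-vocabulary words), and

  $$\mathrm{WMD}(p, r) \;=\; \min_{T \ge 0} \sum_{i,j} T_{ij}\,
  \lVert x_i - x_j \rVert_2 \quad \text{s.t.} \quad
  \textstyle\sum_j T_{ij} = d_i,\; \sum_i T_{ij} = d'_j ,$$

  the optimal-transport cost of moving one document's word mass onto the
  other in a word-embedding space. Synonym use ("father" for "dad") costs
  little because the vectors are close; unrelated words cost a lot.

The two features enter an ordinary least squares model
$\hat{y} = \beta_0 + \beta_1 c + \beta_2\,\mathrm{WMD}$, fitted against the
gold-standard ratings. Performance is always reported as the Pearson
correlation between *held-out* predictions and gold ratings under 5-fold
cross-validation: folds are a uniform random shuffle at the response level
(a fixed seed makes the report reproducible), every response is held out
exactly once, and the headline pooled correlation is computed on the
concatenated held-out predictions only. Per-fold correlations are reported
as a min–max range check, and the reported $R^2$ is the square of the
pooled correlation (a deliberate, documented convention). An optional
`grouping` argument assigns all of a participant's responses to one fold
for users worried about within-person leakage.

### Assumptions and conventions worth knowing

* **Preprocessing** lowercases with full Unicode case folding, removes
  punctuation (apostrophes survive only inside words; hyphens split words),
  and drops filled pauses (`uh`, `um`, …; configurable). No stemming, no
  stop-word removal, no spelling correction. The same policy is applied to
  prompts and responses — the sensible uniform choice given that only
  responses contain transcribed hesitations in practice.
* **Out-of-vocabulary tokens** are dropped before nBOW normalization, with
  a per-response count kept. A response with *no* in-vocabulary word is
  unscorable: it stays in every table with a missing WMD and prediction,
  and is excluded from model fitting — mirroring how responses without
  recognizable speech are excluded in practice. It is never a crash.
* **Transport cost** defaults to the Euclidean distance between raw
  (unnormalized) vectors, the original WMD formulation; a cosine cost sits
  behind a config switch. Stop-word removal before WMD (part of the original
  WMD recipe, but not of the preprocessing description this package
  follows) is deliberately off by default.
* **Predictions are not clipped** to $[0, 6]$ by default; raw model
  behavior (e.g. overshoot on short responses) is diagnostic. `clip = TRUE`
  clamps.
* **Raw features, not standardized**, enter the OLS fit, so coefficient
  magnitudes are scale-dependent; published coefficient values from any
  particular corpus need not transfer.

## Reliability and transcription-fidelity tools

* `gold_standard()` is the per-response mean rating. `rater_vs_rest()`
  correlates one rater with the mean of the *other* raters (leave-one-out)
  by default; `include_self = TRUE` switches to the full-gold convention,
  since published "rater vs gold" figures are ambiguous between the two.
* `pairwise_interrater()` reports Pearson correlations per rater pair on
  jointly rated responses (no imputation; pairs with fewer than 3 shared
  responses are omitted with a message) and their unweighted mean.
* `word_error_rate()` aligns hypothesis to reference tokens by minimum edit
  cost with unit substitution/insertion/deletion costs;
  the rate is $(S + D + I)/\mathrm{ref\ length}$. Only the error total is
  contractual — optimal alignments tie, and the backtrace resolves ties by
  preferring substitution, then insertion, then deletion. `corpus_wer()`
  pools counts over pairs before dividing (corpus-level pooling, not a mean
  of per-file rates). WER is computed on preprocessed tokens so human and
  machine transcripts are comparable; hesitation-marker stripping before
  alignment is off by default because filled-pause output is itself a real
  recognizer error mode.
* `welch_t()`, `cohen_d()` (classic pooled-SD d, second group minus first,
  no small-sample correction) and `holm_correct()` back the
  `group_report()` table; the Holm family is the set of measures in one
  call. `published_group_summaries()` ships per-group printed summary
  statistics (means, SDs, n = 354 patient / 681 healthy trials) from the
  clinical story-recall study this package operationalizes; recomputing
  Cohen's d from those summaries reproduces the printed one-decimal values
  for human rating (1.1), word count (0.8) and predicted score (1.3). The
  printed effect sizes for common types and WMD are *not* recoverable from
  the printed summaries (1.34 vs 1.4 and −0.92 vs −1.0), presumably because
  the printed SDs are rounded to one decimal; the printed t statistics are
  likewise not recoverable under any candidate n, so neither is used as a
  recomputation target.

## The synthetic study generator

No recordings or transcripts from the motivating study are publicly
available, so the package ships a generator that emulates the study's
*statistical structure*, making the full pipeline testable end to end.
`sim_config()` fixes the conditions; the defaults are the study conditions
wherever those are stated, and one-time modeling choices elsewhere:

* **Embeddings**: 1000 content words plus function words as random unit
  vectors in 300 dimensions (the dimensionality of the embedding set used
  with real data). 100 synonym pairs are planted at distance ≈ 0.08 —
  far below the ≈ $\sqrt{2}$ typical distance of unrelated random unit
  vectors — so "paraphrase" substitution is geometrically meaningful.
* **Stories**: length uniform on 62–87 words; ~70% of positions carry
  distinct content words (the recallable material), the rest recurring
  function words.
* **Recall channel**: each story token is retained independently with
  probability $q$ (the latent trial quality); retained tokens are swapped
  for their nearest embedding neighbor with probability 0.10; fillers are
  inserted at rate 0.05. Word order is preserved — harmless here because
  both features are order-insensitive, and noted as a known simplification.
  $q$ is drawn per trial from cohort-specific Beta distributions
  (patient-like Beta(2.4, 1.9), healthy-like Beta(3.3, 1.0), chosen once so
  that 6·E[q] sits near the published cohort mean ratings), and with
  probability 0.197 / 0.054 (patient / healthy, the published short-response
  percentages) the trial collapses to the fixed minimal response
  "i don't remember".
* **Raters**: each of 5 raters reports
  $\mathrm{clamp}(\mathrm{round}(6q + \varepsilon), 0, 6)$ with
  $\varepsilon \sim N(0, \sigma^2)$. $\sigma = 1.10$ was fixed by a
  one-time grid search so that mean pairwise inter-rater correlation over
  1,000 trials from the default quality mixture lands at the published 0.73.
* **Transcription noise**: `corrupt_transcript()` spends a budget of
  $\lceil \mathrm{WER}_{target} \cdot n \rceil$ edits in equal thirds on
  substitutions, deletions and insertions (error-type proportions are not
  published; equal thirds is the neutral choice). Source presets are the
  published corpus rates: 7.2% (human transcription), 10.5% (task-adapted
  recognizer), 23.3% (generic recognizer), each applied to the verbatim
  recall, which stands in for the ground-truth speech. Note that the WER
  *between* two corrupted sources compounds both noise channels (≈ 18%
  between the human and custom-recognizer transcripts), exactly as human-vs-
  machine comparisons do with real data; the presets are recovered when
  measuring against the verbatim truth table.
* **Scale**: the default corpus is 300 trials (100 patient-like, 200
  healthy-like — the published 1:2 trial ratio at roughly a third of the
  published 1035 trials), 10 prompts, 3 transcript sources. This size keeps
  a full simulate–train–validate cycle under a minute on one CPU while
  leaving binomial noise on corpus-level rates near ±1 percentage point.

What passing the end-to-end checks does **not** show: the generator's
recalls are bags of story tokens, not grammatical retellings; real
paraphrase is richer than planted nearest-neighbor synonyms; real recognizer
errors are phonetically structured, not uniform over the vocabulary; and
real rater disagreement is not i.i.d. Gaussian. The synthetic study
validates the *pipeline's mechanics and statistical wiring* — recovery of a
known latent quality, calibrated reliability, robustness to transcription
noise of realistic magnitude — not clinical validity on human speech.

## Numerical choices

* The transportation problem is solved exactly (successive shortest paths
  with node potentials, compiled code). nBOW weights are scaled to integers
  summing to $10^9$ before solving, so flows are exact and termination is
  guaranteed; the induced objective perturbation is below $10^{-8}$ and the
  solver matches an independent dense-LP oracle to $10^{-6}$ on 1,000
  randomized instances in the test suite. Identical words are assigned
  exactly zero cost (the Gram-matrix distance computation would otherwise
  leave $\sim 10^{-8}$ floating-point residue on the diagonal).
* Degenerate inputs fail loudly and specifically: collinear design matrices
  (singular-design error), constant vectors in correlations
  (undefined-correlation error), zero-variance groups in Welch's test,
  empty references in WER (rate is `NA`, counts still returned).
* All randomness flows from one master seed through named substreams
  (stable 32-bit hashes per operation and trial), so any fixture, fold
  assignment or corruption is individually reproducible and adding a new
  consumer of randomness does not reshuffle existing draws.

## Known limitations

* Features ignore word order and syntax entirely; a verbatim recall and a
  shuffled one score identically.
* Exact-match vocabulary lookup: morphological variants ("skater" /
  "skateboarder") are distinct words, handled only insofar as the embedding
  space places them nearby.
* The linear model can assign high scores to short responses that happen to
  contain a few high-value words; clipping mitigates but does not remove
  this.
* `read_word2vec()` reads the text dialect only (header line, then one word
  plus vector per line); binary embedding exports must be converted first.
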