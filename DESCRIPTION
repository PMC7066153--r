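Package: recallscore
Title: Automated Scoring of Spoken Story Recall
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated scoring of verbal episodic memory assessed by story
    retelling. Transcribed recalls are compared with their story prompts
    through two similarity features, the count of shared word types and the
    Word Mover's Distance in a word-embedding space, and a cross-validated
    ordinary least squares model maps the features onto expert 0-6 accuracy
    ratings. Companion tools quantify inter-rater reliability, transcription
    word error rates, and group contrasts (Welch t, Cohen's d, Holm-adjusted
    p-values), and a synthetic-corpus generator emulates prompts, graded
    recalls, multi-rater scores and transcription noise so the whole pipeline
    can be exercised end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
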