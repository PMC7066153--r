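#' Welch's two-sample t-test
#'
#' Two-sided t-test without the equal-variance assumption:
#' t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b) with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2 with nonzero
#'   variance.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("test undefined: both groups have zero variance")
  ht <- t.test(group_a, group_b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Cohen's d from summary statistics
#'
#' Classic pooled-standard-deviation effect size,
#' d = (mean_b - mean_a) / s_pooled with
#' s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)).
#' Sign convention: second group minus first. No small-sample (Hedges)
#' correction is applied.
#'
#' @param mean_a,sd_a,n_a Summary statistics of the first group.
#' @param mean_b,sd_b,n_b Summary statistics of the second group.
#' @return Cohen's d.
#' @export
cohen_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a > 0, sd_b > 0, n_a >= 2, n_b >= 2)
  s_pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  (mean_b - mean_a) / s_pooled
}

#' Cohen's d from raw samples
#'
#' @param group_a,group_b Numeric vectors.
#' @return Cohen's d (second group minus first, pooled SD).
#' @export
cohen_d_samples <- function(group_a, group_b) {
  cohen_d(mean(group_a), sd(group_a), length(group_a),
          mean(group_b), sd(group_b), length(group_b))
}

#' Holm step-down multiple-testing correction
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotonicity by cumulative maxima, caps at 1, and
#' returns the adjusted values in the original input order.
#'
#' @param p_values Numeric vector with all values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_correct <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1L)
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Published group summary statistics
#'
#' Packaged table of per-group summary statistics (mean, SD, n for patient
#' and healthy cohorts) of the measures reported by the clinical
#' story-recall study this package operationalizes: human rating, word
#' count, and the two automated features plus predicted scores per
#' transcript source. `d_printed` is the effect size printed alongside each
#' row, at one decimal. Useful for recomputing effect sizes from summaries
#' via [cohen_d()].
#'
#' @return Data frame.
#' @export
published_group_summaries <- function() {
  read.csv(system.file("extdata", "group_summaries.csv",
                       package = "recallscore"),
           stringsAsFactors = FALSE)
}

#' Group comparison report
#'
#' For each measure column, compares the two groups with means, SDs,
#' Cohen's d (second group minus first), Welch's two-sided t, and
#' Holm-adjusted p-values; the Holm family is the set of measures in this
#' one call.
#'
#' @param data Data frame holding the measures and a group column.
#' @param measures Character vector of numeric column names to compare.
#' @param group Name of the group column (must have exactly the two levels
#'   in `group_levels`).
#' @param group_levels Length-2 character vector: first and second group.
#' @return Data frame with one row per measure: group means/SDs/ns, `d`,
#'   `t`, `df`, `p_raw`, `p_holm`.
#' @export
group_report <- function(data, measures, group,
                         group_levels = sort(unique(as.character(data[[group]])))) {
  stopifnot(is.data.frame(data), all(measures %in% names(data)),
            group %in% names(data), length(group_levels) == 2L)
  g <- as.character(data[[group]])
  rows <- lapply(measures, function(mz) {
    a <- data[[mz]][g == group_levels[[1L]]]
    b <- data[[mz]][g == group_levels[[2L]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    wt <- welch_t(a, b)
    data.frame(measure = mz,
               mean_a = mean(a), sd_a = sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = sd(b), n_b = length(b),
               d = cohen_d_samples(a, b),
               t = -wt$t,  # second group minus first, matching d's sign
               df = wt$df, p_raw = wt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_correct(out$p_raw)
  attr(out, "groups") <- group_levels
  out
}
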