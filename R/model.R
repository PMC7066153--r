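#' Fit the two-feature recall scoring model
#'
#' Ordinary least squares of the gold-standard human rating on the count of
#' common word types and the Word Mover's Distance. Responses with a missing
#' WMD (no recognizable in-vocabulary speech) are excluded from the fit and
#' recorded in the returned object.
#'
#' @param features Data frame with columns `common_types` and `wmd`
#'   (optionally `response_id`).
#' @param gold Numeric vector of gold-standard ratings, aligned with the rows
#'   of `features`.
#' @return An object of class `scoring_model`: intercept, the two
#'   coefficients, the number of responses used and the indices (or ids) of
#'   excluded responses.
#' @export
fit_ols <- function(features, gold) {
  stopifnot(is.data.frame(features),
            all(c("common_types", "wmd") %in% names(features)),
            length(gold) == nrow(features))
  ok <- !is.na(features$wmd) & !is.na(features$common_types) & !is.na(gold)
  if (sum(ok) < 3L)
    stop("need at least 3 responses with non-missing features and ratings")
  d <- data.frame(gold = gold[ok],
                  common_types = as.numeric(features$common_types[ok]),
                  wmd = as.numeric(features$wmd[ok]))
  fit <- lm(gold ~ common_types + wmd, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) stop("singular design: features are collinear")
  dropped <- if ("response_id" %in% names(features))
    features$response_id[!ok] else which(!ok)
  structure(
    list(intercept = unname(cf[["(Intercept)"]]),
         coef_common_types = unname(cf[["common_types"]]),
         coef_wmd = unname(cf[["wmd"]]),
         n_used = sum(ok), dropped = dropped),
    class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model> rating ~ ", format(x$intercept, digits = 4),
      " + ", format(x$coef_common_types, digits = 4), " * common_types + ",
      format(x$coef_wmd, digits = 4), " * wmd  (n = ", x$n_used, ")\n", sep = "")
  invisible(x)
}

#' Predict ratings from features
#'
#' @param object A `scoring_model`.
#' @param features Data frame with columns `common_types` and `wmd`.
#' @param clip If `TRUE`, predictions are clamped to the rating scale
#'   \code{[0, 6]}. Off by default: raw model behavior is informative (e.g.
#'   overshoot on short responses).
#' @param ... Unused.
#' @return Numeric vector of predicted ratings; `NA` where `wmd` is missing.
#' @export
predict.scoring_model <- function(object, features, clip = FALSE, ...) {
  stopifnot(all(c("common_types", "wmd") %in% names(features)))
  p <- object$intercept +
    object$coef_common_types * as.numeric(features$common_types) +
    object$coef_wmd * as.numeric(features$wmd)
  if (clip) p <- pmin(pmax(p, 0), 6)
  p
}

#' Pearson correlation with defined-input checks
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return Sample Pearson correlation in \code{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  cor(x, y)
}

#' K-fold cross-validation of the scoring model
#'
#' Responses are shuffled once (fixed seed) and split into `k` folds at the
#' response level. Each fold is predicted by a model fitted on the remaining
#' folds only, so every held-out prediction comes from a model that never saw
#' that response. The headline metric is the pooled Pearson correlation of
#' the concatenated held-out predictions against the gold ratings; per-fold
#' correlations are reported as a range check, and `r_squared` is the square
#' of the pooled correlation.
#'
#' @param features Data frame with `common_types`, `wmd`, and optionally
#'   `response_id` (used to name fold assignments and predictions).
#' @param gold Numeric gold-standard ratings aligned with `features`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param grouping Optional factor (e.g. participant id): when given, all
#'   responses of a group are assigned to the same fold to prevent
#'   within-person leakage.
#' @return An object of class `cv_report` with `fold_assignments`,
#'   `pooled_r`, `per_fold_r`, `r_squared` and `predictions`.
#' @export
cross_validate <- function(features, gold, k = 5L, seed = 1L, grouping = NULL) {
  n <- nrow(features)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k = ", k, " responses, got ", n)
  ids <- if ("response_id" %in% names(features))
    as.character(features$response_id) else as.character(seq_len(n))
  fold <- integer(n)
  if (is.null(grouping)) {
    perm <- with_seed(seed, sample.int(n))
    fold[perm] <- rep_len(seq_len(k) - 1L, n)
  } else {
    stopifnot(length(grouping) == n)
    g <- unique(as.character(grouping))
    if (length(g) < k) stop("fewer groups than folds")
    gperm <- with_seed(seed, sample(g))
    gfold <- rep_len(seq_len(k) - 1L, length(g))
    fold <- gfold[match(as.character(grouping), gperm)]
  }
  preds <- rep(NA_real_, n)
  per_fold_r <- rep(NA_real_, k)
  for (f in seq_len(k) - 1L) {
    test <- fold == f
    m <- fit_ols(features[!test, , drop = FALSE], gold[!test])
    preds[test] <- predict(m, features[test, , drop = FALSE])
    okt <- test & !is.na(preds) & !is.na(gold)
    if (sum(okt) >= 3L && sd(preds[okt]) > 0 && sd(gold[okt]) > 0)
      per_fold_r[f + 1L] <- pearson_r(preds[okt], gold[okt])
  }
  ok <- !is.na(preds) & !is.na(gold)
  pooled_r <- pearson_r(preds[ok], gold[ok])
  names(fold) <- ids
  names(preds) <- ids
  structure(
    list(fold_assignments = fold, pooled_r = pooled_r,
         per_fold_r = per_fold_r, r_squared = pooled_r^2,
         predictions = preds, k = k, seed = as.integer(seed)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  rng <- range(x$per_fold_r, na.rm = TRUE)
  cat("<cv_report> ", x$k, "-fold, pooled R = ", format(x$pooled_r, digits = 3),
      " (per-fold ", format(rng[1], digits = 3), "-", format(rng[2], digits = 3),
      "), R^2 = ", format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Persist a scoring model as JSON
#'
#' @param model A `scoring_model`.
#' @param path Output path.
#' @param metadata Optional named list stored alongside the coefficients
#'   (e.g. preprocessing fingerprint, embedding fingerprint, seed).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "scoring_model"))
  obj <- c(list(intercept = model$intercept,
                coef_common_types = model$coef_common_types,
                coef_wmd = model$coef_wmd,
                n_used = model$n_used),
           metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scoring model from JSON
#'
#' @param path Path to a model file written by [write_model()].
#' @return A `scoring_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "coef_common_types", "coef_wmd")
  if (!all(need %in% names(obj)))
    stop("model file lacks fields: ", paste(setdiff(need, names(obj)), collapse = ", "))
  structure(list(intercept = as.numeric(obj$intercept),
                 coef_common_types = as.numeric(obj$coef_common_types),
                 coef_wmd = as.numeric(obj$coef_wmd),
                 n_used = if (is.null(obj$n_used)) NA_integer_ else as.integer(obj$n_used),
                 dropped = character(0)),
            class = "scoring_model")
}
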