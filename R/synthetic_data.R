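#' Configuration for the EHR-like synthetic data generator
#'
#' Describes a tabular dataset emulating risk-factor-coded clinical data:
#' integer-coded categorical predictors (ordinal codes such as AGE in
#' 0/1/2), a rare binary outcome, and an optional planted signal expressed
#' as per-feature log-odds per level step.
#'
#' @param n_cases Number of rows (patients).
#' @param n_features Number of predictors.
#' @param positive_rate Target expected outcome prevalence in (0, 1).
#' @param n_levels_per_feature Levels per predictor (>= 2); scalar or
#'   vector recycled across features. Codes run 0..levels-1.
#' @param effect_sizes Log-odds increment per level step for each feature
#'   (0 for pure-noise features); scalar or vector recycled.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @param horizon_label Free-text horizon tag (e.g. `"5-year"`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases, n_features, positive_rate,
                             n_levels_per_feature = 3, effect_sizes = 0,
                             seed = 1L, horizon_label = "synthetic") {
  if (n_cases < 2 || n_features < 1)
    abort("need at least 2 cases and 1 feature", "domain_error")
  if (positive_rate <= 0 || positive_rate >= 1)
    abort("positive_rate must lie in (0, 1)", "domain_error")
  if (any(n_levels_per_feature < 2))
    abort("features need at least 2 levels", "domain_error")
  structure(list(
    n_cases = as.integer(n_cases), n_features = as.integer(n_features),
    positive_rate = positive_rate,
    n_levels = rep_len(n_levels_per_feature, n_features),
    effect_sizes = rep_len(effect_sizes, n_features),
    seed = as.integer(seed), horizon_label = horizon_label
  ), class = "generator_config")
}

new_clinical_dataset <- function(predictors, outcome, feature_names, horizon_label) {
  storage.mode(predictors) <- "integer"
  colnames(predictors) <- feature_names
  if (length(outcome) != nrow(predictors))
    abort("outcome length must equal the number of rows", "domain_error")
  structure(list(predictors = predictors, outcome = as.integer(outcome),
                 feature_names = feature_names, horizon_label = horizon_label),
            class = "clinical_dataset")
}

# calibrate the logistic intercept by bisection so the expected positive
# rate over the sampled predictor matrix hits the target
calibrate_intercept <- function(lp, target, tol = 1e-10) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    abort("positive_rate unreachable given effect sizes", "calibration_error")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic clinical dataset
#'
#' Predictors are drawn independently and uniformly over their level codes;
#' the binary outcome follows a logistic model whose linear predictor is
#' the effect-weighted sum of the codes, with the intercept calibrated by
#' bisection so the expected prevalence matches `positive_rate`. Identical
#' configs produce identical datasets.
#'
#' @param config A [generator_config()].
#' @return A `clinical_dataset`: integer predictor matrix, binary
#'   `outcome`, `feature_names`, `horizon_label`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    X <- vapply(seq_len(config$n_features), function(j) {
      sample.int(config$n_levels[j], config$n_cases, replace = TRUE) - 1L
    }, integer(config$n_cases))
    lp <- as.numeric(X %*% config$effect_sizes)
    b0 <- calibrate_intercept(lp, config$positive_rate)
    y <- stats::rbinom(config$n_cases, 1L, stats::plogis(b0 + lp))
  })
  ds <- new_clinical_dataset(X, y, sprintf("f%02d", seq_len(config$n_features)),
                             config$horizon_label)
  ds$intercept <- b0
  ds
}

#' @export
print.clinical_dataset <- function(x, ...) {
  cat(sprintf("Clinical dataset (%s): %d cases x %d predictors, %d positive / %d negative\n",
              x$horizon_label, nrow(x$predictors), ncol(x$predictors),
              sum(x$outcome == 1L), sum(x$outcome == 0L)))
  invisible(x)
}

#' Write / read a clinical dataset as delimited text
#'
#' Comma-delimited with a header row; the outcome column is named
#' `metastasis` and every predictor column holds small non-negative
#' integer codes. Reading validates the file and reports the first
#' offending row on failure.
#'
#' @param dataset A `clinical_dataset`.
#' @param path File path.
#' @return `read_dataset` returns the `clinical_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  df <- as.data.frame(dataset$predictors)
  df$metastasis <- dataset$outcome
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param horizon_label Horizon tag to attach on read.
#' @export
read_dataset <- function(path, horizon_label = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"metastasis" %in% names(df))
    abort("parse error: no 'metastasis' outcome column", "parse_error")
  pred <- df[, setdiff(names(df), "metastasis"), drop = FALSE]
  for (j in seq_along(pred)) {
    v <- pred[[j]]
    bad <- which(!is.numeric(v) | is.na(v) | v != floor(v) | v < 0)
    if (length(bad))
      abort(sprintf("parse error: non-integer code in column '%s', row %d",
                    names(pred)[j], bad[1]), "parse_error")
  }
  y <- df$metastasis
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    abort(sprintf("parse error: non-binary outcome at row %d", bad[1]), "parse_error")
  new_clinical_dataset(as.matrix(pred), y, names(pred), horizon_label)
}
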