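#' Stratified 80/20 split with a 5-fold partition
#'
#' Splits a dataset into a train-test set (~80% of the cases) and a
#' held-aside validation set (~20% of each class), then divides the
#' train-test set into `n_folds` disjoint portions such that each portion
#' carries an equal share of positives and of negatives (per-class counts
#' differ by at most 1 across folds). Deterministic given the seed.
#'
#' @param dataset A `clinical_dataset`.
#' @param seed Integer seed.
#' @param validation_fraction Held-out fraction (default 0.2).
#' @param n_folds Number of cross-validation portions (default 5).
#' @return A `split_plan`: `train_test_indices`, `validation_indices`,
#'   `folds` (list of index vectors), `seed`.
#' @export
make_split <- function(dataset, seed = 1L, validation_fraction = 0.2, n_folds = 5L) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  y <- dataset$outcome
  if (sum(y == 1L) < 10L || sum(y == 0L) < 10L)
    abort("need at least 10 cases of each class to split", "split_error")
  folds <- vector("list", n_folds)
  val <- integer(0)
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      n_val <- round(validation_fraction * length(idx))
      val <- c(val, idx[seq_len(n_val)])
      rest <- idx[-seq_len(n_val)]
      # deal round-robin so per-class fold counts differ by <= 1
      for (f in seq_len(n_folds)) {
        folds[[f]] <- c(folds[[f]], rest[seq(f, length(rest), by = n_folds)])
      }
    }
  })
  folds <- lapply(folds, sort)
  structure(list(train_test_indices = sort(unlist(folds)),
                 validation_indices = sort(val),
                 folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' Equals the probability that a random positive outscores a random
#' negative, plus half the tie probability; computed from mid-ranks, so it
#' is invariant to strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort("scores and labels must have equal length", "domain_error")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    abort("both classes must be present", "domain_error")
  r <- rank(scores)  # mid-ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_trial_record <- function(setting, fold_aucs, wall_seconds, cycle_label = "",
                             diverged = FALSE, train_seed = NA_integer_) {
  structure(list(setting = setting, fold_aucs = fold_aucs,
                 mean_test_auc = mean(fold_aucs), wall_seconds = wall_seconds,
                 cycle_label = cycle_label, diverged = diverged,
                 train_seed = train_seed),
            class = "trial_record")
}

#' 5-fold cross-validation of one hyperparameter setting
#'
#' Trains one fresh model per fold on the remaining portions of the
#' train-test set, scores the held-out portion by AUC, and records the
#' five fold AUCs, their mean (`mean_test_auc`), and the wall time.
#' Per-fold training seeds are derived from `train_seed` by a fixed
#' counter scheme, so the record is reproducible. A fold whose training
#' diverges (non-finite loss) is recorded with AUC 0.5 and flagged rather
#' than aborting the sweep.
#'
#' @param setting An `hp_setting`.
#' @param dataset A `clinical_dataset`.
#' @param plan A `split_plan` from [make_split()].
#' @param train_seed Master seed for this setting's five trainings.
#' @param cycle_label Free-text label stored in the record.
#' @return A `trial_record`.
#' @export
cross_validate <- function(setting, dataset, plan, train_seed = 1L, cycle_label = "") {
  stopifnot(inherits(plan, "split_plan"))
  t0 <- proc.time()[["elapsed"]]
  k <- length(plan$folds)
  fold_aucs <- numeric(k)
  diverged <- FALSE
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- unlist(plan$folds[-f])
    fseed <- derive_seed(train_seed, paste0("fold", f))
    model <- build_model(setting, ncol(dataset$predictors), seed = fseed)
    model <- train_dfnn(model, dataset$predictors[train_idx, , drop = FALSE],
                        dataset$outcome[train_idx], seed = fseed)
    if (model$diverged) {
      fold_aucs[f] <- 0.5
      diverged <- TRUE
    } else {
      scores <- predict(model, dataset$predictors[test_idx, , drop = FALSE])
      fold_aucs[f] <- auc_score(scores, dataset$outcome[test_idx])
    }
  }
  new_trial_record(setting, fold_aucs, proc.time()[["elapsed"]] - t0,
                   cycle_label, diverged, as.integer(train_seed))
}

#' Refit the top setting on the full train-test set
#'
#' Develops a top model by training a single network on every train-test
#' case; the validation indices are never touched during training.
#'
#' @inheritParams cross_validate
#' @return A trained `dfnn`.
#' @export
refit_top <- function(setting, dataset, plan, train_seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  fseed <- derive_seed(train_seed, "refit")
  model <- build_model(setting, ncol(dataset$predictors), seed = fseed)
  train_dfnn(model, dataset$predictors[plan$train_test_indices, , drop = FALSE],
             dataset$outcome[plan$train_test_indices], seed = fseed)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial [%s]: mean_test_AUC %.5f (folds %s)%s, %.2f s\n",
              x$cycle_label, x$mean_test_auc,
              paste(sprintf("%.3f", x$fold_aucs), collapse = "/"),
              if (x$diverged) " [diverged]" else "", x$wall_seconds))
  invisible(x)
}
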