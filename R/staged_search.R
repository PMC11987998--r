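setting_key <- function(setting) {
  paste(vapply(setting, function(v) paste(format(v, digits = 15), collapse = "|"),
               character(1)), collapse = ";")
}

#' Construct a search log
#'
#' One cycle's worth of trial records (one per hyperparameter setting,
#' unique within the log), with the pool or sweep descriptor that produced
#' them and the master seed that governed the cycle.
#'
#' @param records List of `trial_record`s.
#' @param cycle_label Cycle tag, e.g. `"Stage1"`, `"Stage3-c4"`.
#' @param pool_descriptor The `setting_pool` (or sweep descriptor) used.
#' @param master_seed Integer master seed of the cycle.
#' @return A `search_log`.
#' @export
search_log <- function(records, cycle_label = "custom", pool_descriptor = NULL,
                       master_seed = NA_integer_) {
  keys <- vapply(records, function(r) setting_key(r$setting), character(1))
  if (anyDuplicated(keys))
    abort("settings within one log must be unique", "domain_error")
  structure(list(records = records, cycle_label = cycle_label,
                 pool_descriptor = pool_descriptor,
                 master_seed = master_seed),
            class = "search_log")
}

#' Flatten a search log to a data frame
#'
#' One row per trial record; hyperparameter values become columns
#' (per-layer width vectors are collapsed with `"x"`), followed by
#' `mean_test_auc`, `wall_seconds`, `diverged`, `cycle_label` and the
#' evaluation order.
#'
#' @param log A `search_log`.
#' @return A `data.frame`.
#' @export
log_df <- function(log) {
  stopifnot(inherits(log, "search_log"))
  rows <- lapply(seq_along(log$records), function(i) {
    r <- log$records[[i]]
    vals <- lapply(r$setting, function(v)
      if (length(v) > 1L) paste(v, collapse = "x") else v)
    c(vals, list(mean_test_auc = r$mean_test_auc,
                 wall_seconds = r$wall_seconds, diverged = r$diverged,
                 cycle_label = r$cycle_label, order = i))
  })
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' @export
print.search_log <- function(x, ...) {
  aucs <- vapply(x$records, `[[`, 0, "mean_test_auc")
  cat(sprintf("Search log [%s]: %d settings, best mean_test_AUC %.5f, all-avg %.5f\n",
              x$cycle_label, length(x$records),
              if (length(aucs)) max(aucs) else NA, mean(aucs)))
  invisible(x)
}

#' Write / read search logs as JSON lines
#'
#' The first line holds cycle metadata; every following line is one trial
#' record.
#'
#' @param log A `search_log`.
#' @param path File path.
#' @return `read_search_log` returns the `search_log`; the writer returns
#'   `path` invisibly.
#' @export
write_search_log <- function(log, path) {
  stopifnot(inherits(log, "search_log"))
  meta <- jsonlite::toJSON(list(meta = TRUE, cycle_label = log$cycle_label,
                                master_seed = log$master_seed), auto_unbox = TRUE)
  lines <- vapply(log$records, function(r) {
    as.character(jsonlite::toJSON(list(
      setting = unclass(r$setting), fold_aucs = r$fold_aucs,
      mean_test_auc = r$mean_test_auc, wall_seconds = r$wall_seconds,
      cycle_label = r$cycle_label, diverged = r$diverged,
      train_seed = r$train_seed), auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(meta), lines), path)
  invisible(path)
}

#' @rdname write_search_log
#' @export
read_search_log <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  records <- lapply(lines[-1], function(ln) {
    o <- jsonlite::fromJSON(ln)
    new_trial_record(structure(as.list(o$setting), class = "hp_setting"),
                     o$fold_aucs, o$wall_seconds, o$cycle_label,
                     isTRUE(o$diverged), o$train_seed %||% NA_integer_)
  })
  search_log(records, meta$cycle_label, master_seed = meta$master_seed %||% NA_integer_)
}

# evaluate a list of settings under per-setting derived seeds, honoring an
# optional wall-time budget (partial log kept, truncation flagged)
eval_settings <- function(settings, dataset, plan, master_seed, cycle_label,
                          budget_hours = Inf) {
  records <- vector("list", length(settings))
  spent <- 0
  truncated <- FALSE
  n_done <- 0L
  for (i in seq_along(settings)) {
    if (spent / 3600 > budget_hours) { truncated <- TRUE; break }
    seed_i <- derive_seed(master_seed, paste0(cycle_label, "#", i))
    rec <- cross_validate(settings[[i]], dataset, plan, train_seed = seed_i,
                          cycle_label = cycle_label)
    spent <- spent + rec$wall_seconds
    n_done <- i
    records[[i]] <- rec
  }
  if (truncated)
    warning(sprintf("budget exceeded: cycle %s truncated after %d settings",
                    cycle_label, n_done))
  log <- search_log(records[seq_len(n_done)], cycle_label, master_seed = master_seed)
  log$truncated <- truncated
  log
}

#' Stage 1: single-hyperparameter sweep
#'
#' Varies one hyperparameter over `sweep_values` while holding every other
#' dimension at `base_setting`, producing one trial record per value --
#' the performance trend that proper-value extraction reads.
#'
#' @param space An `hp_space`.
#' @param target_hp Name of the swept hyperparameter.
#' @param sweep_values Values to probe (within the target's domain).
#' @param base_setting `hp_setting` holding the other dimensions fixed.
#' @param dataset,plan Data and split plan.
#' @param master_seed Seed for the sweep.
#' @param cycle_label Log label.
#' @return A `search_log` whose `target_hp` attribute names the swept
#'   dimension.
#' @export
stage1_sweep <- function(space, target_hp, sweep_values, base_setting, dataset,
                         plan, master_seed = 1L, cycle_label = "Stage1") {
  if (length(sweep_values) == 0L)
    abort("sweep_values must be non-empty", "domain_error")
  if (!target_hp %in% names(space$specs))
    abort(sprintf("unknown hyperparameter '%s'", target_hp), "domain_error")
  settings <- lapply(sweep_values, function(v) {
    vals <- unclass(base_setting)
    vals[[target_hp]] <- v
    new_setting(space, vals)
  })
  log <- eval_settings(settings, dataset, plan, master_seed,
                       paste0(cycle_label, ":", target_hp))
  log$target_hp <- target_hp
  log$sweep_values <- sweep_values
  log
}

#' Extract the proper values from a Stage-1 sweep
#'
#' Keeps the sweep values whose mean_test_AUC reaches the cycle mid-point,
#' `(0.5 + best)/2` -- the search's own notion of a "decent" model --
#' thereby removing the extreme values that produce performance outliers.
#' The best-scoring value is always retained, and sweep order is
#' preserved.
#'
#' @param log A `search_log` produced by [stage1_sweep()].
#' @param target_hp The swept hyperparameter (must match the log).
#' @return Vector of retained values (never empty).
#' @export
extract_proper_values <- function(log, target_hp) {
  stopifnot(inherits(log, "search_log"))
  if (is.null(log$target_hp) || log$target_hp != target_hp)
    abort("log is not a Stage-1 sweep for this hyperparameter", "domain_error")
  # all non-target values must be constant across the sweep
  others <- lapply(log$records, function(r) r$setting[setdiff(names(r$setting), target_hp)])
  if (length(unique(vapply(others, function(o) setting_key(structure(o, class = "hp_setting")),
                           character(1)))) != 1L)
    abort("mixed-hyperparameter log: non-target values vary", "domain_error")
  aucs <- vapply(log$records, `[[`, 0, "mean_test_auc")
  threshold <- (0.5 + max(aucs)) / 2
  keep <- aucs >= threshold
  keep[which.max(aucs)] <- TRUE
  vals <- lapply(log$records, function(r) r$setting[[target_hp]])
  unlist(vals[keep])
}

#' Stage 2: full grid with running-time estimation
#'
#' Evaluates settings from [enumerate_pool()] (at most `max_settings`),
#' estimating the mean running time per setting (RTPS) as a running mean
#' over completed settings; returns the log together with the final
#' budget accounting.
#'
#' @param pool A `setting_pool` built from Stage-1 proper values.
#' @param dataset,plan Data and split plan.
#' @param max_settings Cap on evaluated settings.
#' @param master_seed Seed for the cycle.
#' @param budget_hours Optional wall-time cap; exceeding it truncates the
#'   cycle with a warning (partial log kept).
#' @return List with `log` (a `search_log`) and `budget` (a
#'   `budget_estimate` whose `tns` is the number evaluated).
#' @export
stage2_grid <- function(pool, dataset, plan, max_settings, master_seed = 1L,
                        budget_hours = Inf) {
  stopifnot(inherits(pool, "setting_pool"))
  settings <- enumerate_pool(pool, limit = max_settings)
  if (length(settings) == 0L) abort("empty pool", "domain_error")
  log <- eval_settings(settings, dataset, plan, master_seed, "Stage2", budget_hours)
  log$pool_descriptor <- pool
  list(log = log, budget = runtime_accounting(log))
}

sweet_spot_windows <- function(best, candidates, radius) {
  radius <- if (length(radius) == 1L)
    stats::setNames(rep(radius, length(candidates)), names(candidates))
  else radius
  windows <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    pos <- match(best[[nm]], cand)
    if (is.na(pos))
      abort(sprintf("best value for '%s' not among its candidates", nm), "domain_error")
    r <- radius[[nm]]
    if (r < 0) abort("radius must be non-negative", "domain_error")
    windows[[nm]] <- cand[max(1, pos - r):min(length(cand), pos + r)]
  }
  windows
}

#' Build a sweet-spot pool around the best setting
#'
#' For every hyperparameter the new candidate list is the window of
#' `radius` positions either side of the best value within its ordered
#' candidate list (clipped at the ends; categorical lists use their
#' declared order). The resulting pool is the SSGS neighborhood.
#'
#' @param best The center `hp_setting`.
#' @param candidates Named list of ordered candidate vectors containing
#'   the center's values.
#' @param radius Non-negative window half-width in index steps; scalar or
#'   per-hyperparameter named vector.
#' @param space The `hp_space` (defaults to the 13-dimension space sized
#'   by the candidates).
#' @return A `sweet_spot` object holding the `setting_pool` (uniform
#'   structural mode), the center, and the per-dimension windows.
#' @export
build_sweet_spot_pool <- function(best, candidates, radius, space) {
  windows <- sweet_spot_windows(best, candidates, radius)
  pool <- setting_pool(space, windows, structural = "uniform")
  structure(list(center = best, radius = radius, windows = windows, pool = pool),
            class = "sweet_spot")
}

# Settings of a sweet-spot window ordered nearest-first from the center
# (L1 distance in candidate-index space, ties by enumeration order). A
# budget cap on an SSGS cycle then keeps the center and its closest
# perturbations instead of one corner of the window.
neighborhood_settings <- function(spot, limit = NULL) {
  stopifnot(inherits(spot, "sweet_spot"))
  settings <- enumerate_pool(spot$pool)
  dist <- vapply(settings, function(s) {
    sum(vapply(names(spot$windows), function(nm) {
      abs(match(s[[nm]], spot$windows[[nm]]) -
            match(spot$center[[nm]], spot$windows[[nm]]))
    }, 0))
  }, 0)
  settings <- settings[order(dist, seq_along(settings))]
  if (!is.null(limit)) settings <- settings[seq_len(min(limit, length(settings)))]
  settings
}

setting_outside_spot <- function(setting, spot) {
  any(vapply(names(spot$windows), function(nm) {
    !all(setting[[nm]] %in% spot$windows[[nm]])
  }, logical(1)))
}

#' Out-of-the-local-optimum (OLO) reseeding
#'
#' Chooses a new sweet-spot center from everything already evaluated: the
#' best-scoring setting that escapes every excluded neighborhood, i.e.
#' that differs from each excluded center in at least one hyperparameter
#' whose value lies outside that center's window. Ties break by earliest
#' evaluation order (logs concatenated in the order given).
#'
#' @param prior_logs List of `search_log`s (non-empty).
#' @param excluded List of `sweet_spot`s to escape.
#' @return The chosen `hp_setting`.
#' @export
olo_reseed <- function(prior_logs, excluded) {
  if (length(prior_logs) == 0L)
    abort("prior_logs must be non-empty", "domain_error")
  records <- do.call(c, lapply(prior_logs, `[[`, "records"))
  ok <- vapply(records, function(r) {
    all(vapply(excluded, function(sp) setting_outside_spot(r$setting, sp), logical(1)))
  }, logical(1))
  if (!any(ok))
    abort("no evaluated setting escapes the excluded neighborhoods",
          "olo_exhausted")
  cand <- records[ok]
  aucs <- vapply(cand, `[[`, 0, "mean_test_auc")
  cand[[which.max(aucs)]]$setting  # which.max returns the earliest maximum
}

#' Randomized grid search (RGS) sampling
#'
#' Draws `n` unique settings from a pool by sampling every
#' hyperparameter's value uniformly and independently from its candidate
#' list (per-layer widths sampled independently in `"per_layer"` pools);
#' duplicates are redrawn, so every setting in the pool has a chance to be
#' selected. Seeded-deterministic.
#'
#' @param pool A `setting_pool`.
#' @param n Number of unique settings (1 <= n <= pool cardinality).
#' @param seed Integer seed.
#' @return List of `n` unique `hp_setting`s.
#' @export
rgs_sample <- function(pool, n, seed = 1L) {
  stopifnot(inherits(pool, "setting_pool"))
  if (n < 1) abort("n must be at least 1", "domain_error")
  card <- pool_cardinality(pool)
  if (is.numeric(card) && n > card)
    abort("n exceeds the pool cardinality", "domain_error")
  sn <- structural_names(pool$space)
  layers_nm <- sn[1]; nodes_nm <- sn[2]
  draw_one <- function() {
    vals <- lapply(pool$candidates, function(cand) cand[sample.int(length(cand), 1L)])
    if (pool$structural == "per_layer") {
      L <- vals[[layers_nm]]
      cand <- pool$candidates[[nodes_nm]]
      vals[[nodes_nm]] <- cand[sample.int(length(cand), L, replace = TRUE)]
    }
    structure(vals, class = "hp_setting")
  }
  withr::with_seed(seed, {
    out <- list(); seen <- character(0)
    guard <- 0L
    while (length(out) < n) {
      s <- draw_one()
      k <- setting_key(s)
      if (!k %in% seen) {
        out[[length(out) + 1L]] <- s
        seen <- c(seen, k)
        guard <- 0L
      } else {
        guard <- guard + 1L
        if (guard > 10000L)
          abort("rejection sampling stalled; pool nearly exhausted", "domain_error")
      }
    }
  })
  out
}

#' Configure a three-stage run
#'
#' @param space The `hp_space` searched.
#' @param candidates Named list of Stage-1 sweep values per hyperparameter
#'   (single-value lists pin a dimension).
#' @param base_setting Center for Stage-1 sweeps; defaults to the middle
#'   candidate of every dimension.
#' @param sweep_hps Hyperparameters given Stage-1 sweeps; defaults to all
#'   with more than one candidate.
#' @param stage2_max Cap on Stage-2 settings.
#' @param ssgs_radius Sweet-spot window half-width (index steps).
#' @param ssgs_max Cap on settings per SSGS cycle.
#' @param rgs_n Settings drawn by the Stage3-c6 randomized grid search.
#' @param budget_hours Optional wall-time cap per cycle.
#' @return A `three_stage_config` list.
#' @export
three_stage_config <- function(space, candidates, base_setting = NULL,
                               sweep_hps = NULL, stage2_max = 32L,
                               ssgs_radius = 1L, ssgs_max = 32L, rgs_n = 24L,
                               budget_hours = Inf) {
  if (is.null(base_setting)) {
    base_setting <- new_setting(space, lapply(candidates, function(cand)
      cand[[ceiling(length(cand) / 2)]]))
  }
  if (is.null(sweep_hps)) sweep_hps <- names(candidates)[lengths(candidates) > 1L]
  structure(list(space = space, candidates = candidates,
                 base_setting = base_setting, sweep_hps = sweep_hps,
                 stage2_max = stage2_max, ssgs_radius = ssgs_radius,
                 ssgs_max = ssgs_max, rgs_n = rgs_n,
                 budget_hours = budget_hours),
            class = "three_stage_config")
}

#' Run the full three-stage grid-search mechanism
#'
#' Executes the default schedule: Stage-1 single-hyperparameter sweeps
#' with proper-value extraction, a Stage-2 grid over the proper values
#' with RTPS estimation, then six Stage-3 cycles -- c1-c3 sweet-spot grid
#' searches each centered on the previous cycle's best, c4-c5 SSGS after
#' OLO reseeding outside all previous neighborhoods, and c6 a randomized
#' grid search over the full proper pool. Each cycle's pool is chained to
#' the previous cycle's results; the whole run is a deterministic function
#' of the master seed.
#'
#' @param config A [three_stage_config()].
#' @param dataset A `clinical_dataset`.
#' @param plan Optional `split_plan`; derived from `master_seed` when
#'   missing.
#' @param master_seed Master seed of the run.
#' @return A `three_stage_result`: list with `logs` (8 `search_log`s),
#'   `proper_values`, `stage2_budget`, `best` (record + refit model +
#'   validation AUC) and `summary` (per-cycle data frame).
#' @export
run_three_stage <- function(config, dataset, plan = NULL, master_seed = 1L) {
  stopifnot(inherits(config, "three_stage_config"))
  if (is.null(plan)) plan <- make_split(dataset, seed = derive_seed(master_seed, "split"))
  space <- config$space
  bh <- config$budget_hours

  # ---- Stage 1: one-hyperparameter-at-a-time sweeps
  sweep_logs <- list()
  stage1_records <- list()
  seen <- character(0)
  for (hp in config$sweep_hps) {
    sl <- stage1_sweep(space, hp, config$candidates[[hp]], config$base_setting,
                       dataset, plan, derive_seed(master_seed, paste0("s1:", hp)))
    sweep_logs[[hp]] <- sl
    for (r in sl$records) {
      k <- setting_key(r$setting)
      if (!k %in% seen) {  # base setting recurs across sweeps; keep first
        seen <- c(seen, k)
        r$cycle_label <- "Stage1"
        stage1_records[[length(stage1_records) + 1L]] <- r
      }
    }
  }
  stage1_log <- search_log(stage1_records, "Stage1", master_seed = master_seed)

  proper <- config$candidates
  for (hp in config$sweep_hps)
    proper[[hp]] <- extract_proper_values(sweep_logs[[hp]], hp)

  # ---- Stage 2: grid over proper values, RTPS estimation
  proper_pool <- setting_pool(space, proper, structural = "uniform")
  s2 <- stage2_grid(proper_pool, dataset, plan, config$stage2_max,
                    derive_seed(master_seed, "s2"), budget_hours = bh)

  logs <- list(Stage1 = stage1_log, Stage2 = s2$log)
  spots <- list()
  best_of <- function(lg) {
    aucs <- vapply(lg$records, `[[`, 0, "mean_test_auc")
    lg$records[[which.max(aucs)]]$setting
  }

  run_ssgs <- function(center, label) {
    spot <- build_sweet_spot_pool(center, proper, config$ssgs_radius, space)
    settings <- neighborhood_settings(spot, limit = config$ssgs_max)
    lg <- eval_settings(settings, dataset, plan,
                        derive_seed(master_seed, label), label, bh)
    lg$pool_descriptor <- spot$pool
    list(spot = spot, log = lg)
  }

  # ---- Stage 3 c1-c3: chained sweet-spot grid searches
  center <- best_of(s2$log)
  for (ci in 1:3) {
    res <- run_ssgs(center, sprintf("Stage3-c%d", ci))
    logs[[sprintf("Stage3-c%d", ci)]] <- res$log
    spots[[length(spots) + 1L]] <- res$spot
    center <- best_of(res$log)
  }

  # ---- Stage 3 c4-c5: OLO reseed outside every previous neighborhood
  # OLO centers must be indexable in the proper lists to form a window
  in_proper <- function(setting)
    all(vapply(names(proper), function(nm) all(setting[[nm]] %in% proper[[nm]]),
               logical(1)))
  poolable <- function(lg) {
    keep <- vapply(lg$records, function(r) in_proper(r$setting), logical(1))
    lg$records <- lg$records[keep]
    lg
  }
  for (ci in 4:5) {
    label <- sprintf("Stage3-c%d", ci)
    reseed <- tryCatch(olo_reseed(lapply(unname(logs), poolable), spots),
                       olo_exhausted = function(e) NULL)
    if (is.null(reseed)) {
      # every evaluated setting sits inside a previous neighborhood:
      # fall back to the last cycle's best (widening would need new evals)
      reseed <- best_of(logs[[length(logs)]])
    }
    res <- run_ssgs(reseed, label)
    logs[[label]] <- res$log
    spots[[length(spots) + 1L]] <- res$spot
  }

  # ---- Stage 3 c6: randomized grid search over the full proper pool
  rgs_settings <- rgs_sample(proper_pool, config$rgs_n,
                             seed = derive_seed(master_seed, "rgs"))
  logs[["Stage3-c6"]] <- eval_settings(rgs_settings, dataset, plan,
                                       derive_seed(master_seed, "Stage3-c6"),
                                       "Stage3-c6", bh)

  all_records <- do.call(c, lapply(unname(logs), `[[`, "records"))
  aucs <- vapply(all_records, `[[`, 0, "mean_test_auc")
  top <- all_records[[which.max(aucs)]]
  top_model <- refit_top(top$setting, dataset, plan,
                         train_seed = derive_seed(master_seed, "top"))
  val_auc <- if (top_model$diverged) NA_real_ else
    auc_score(predict(top_model, dataset$predictors[plan$validation_indices, , drop = FALSE]),
              dataset$outcome[plan$validation_indices])

  summary_df <- do.call(rbind, lapply(names(logs), function(nm) {
    lg <- logs[[nm]]
    a <- vapply(lg$records, `[[`, 0, "mean_test_auc")
    data.frame(cycle = nm, n_settings = length(lg$records),
               best = max(a), all_avg = mean(a),
               trt_hours = sum(vapply(lg$records, `[[`, 0, "wall_seconds")) / 3600)
  }))

  structure(list(logs = logs, proper_values = proper,
                 stage2_budget = s2$budget,
                 best = list(record = top, model = top_model,
                             validation_auc = val_auc),
                 summary = summary_df, master_seed = master_seed, plan = plan),
            class = "three_stage_result")
}

#' @export
print.three_stage_result <- function(x, ...) {
  cat("Three-stage grid search\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Best mean_test_AUC %.5f (%s); validation AUC %.5f\n",
              x$best$record$mean_test_auc, x$best$record$cycle_label,
              x$best$validation_auc))
  invisible(x)
}
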