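#' Top-k group averages of a search log
#'
#' Sorts records by mean_test_AUC (descending; ties by evaluation order)
#' and averages the top-k prefix for each requested k, plus the average
#' over every record ("All").
#'
#' @param log A `search_log`.
#' @param ks Group sizes (each at most the record count); default the
#'   report groups 1, 5, 10, 50, 100.
#' @return A `group_summary`: `cycle_label`, `top_k_averages` (named
#'   numeric), `all_average`, `n`.
#' @export
group_summary <- function(log, ks = c(1, 5, 10, 50, 100)) {
  stopifnot(inherits(log, "search_log"))
  aucs <- vapply(log$records, `[[`, 0, "mean_test_auc")
  if (length(aucs) == 0L) abort("empty log", "domain_error")
  if (any(ks > length(aucs)))
    abort("k exceeds the record count", "domain_error")
  sorted <- aucs[order(-aucs, seq_along(aucs))]
  top <- vapply(ks, function(k) mean(sorted[seq_len(k)]), 0)
  names(top) <- paste0("top", ks)
  structure(list(cycle_label = log$cycle_label, top_k_averages = top,
                 all_average = mean(aucs), n = length(aucs)),
            class = "group_summary")
}

#' Mid-point ("decent model") summary of a search log
#'
#' The mid-point of a cycle is `(0.5 + best mean_test_AUC)/2`; a decent
#' model scores no less than it (ties count). CHS counts the decent
#' settings, TNS the total, and `avg_mean_decent` averages the decent
#' records' mean_test_AUCs.
#'
#' @param log A `search_log`.
#' @return A `midpoint_summary`: `best_mean`, `mid_point`, `chs`, `tns`,
#'   `ratio`, `avg_mean_decent`.
#' @export
midpoint_summary <- function(log) {
  stopifnot(inherits(log, "search_log"))
  aucs <- vapply(log$records, `[[`, 0, "mean_test_auc")
  if (length(aucs) == 0L) abort("empty log", "domain_error")
  best <- max(aucs)
  mid <- (0.5 + best) / 2
  decent <- aucs >= mid
  structure(list(best_mean = best, mid_point = mid,
                 chs = sum(decent), tns = length(aucs),
                 ratio = sum(decent) / length(aucs),
                 avg_mean_decent = mean(aucs[decent])),
            class = "midpoint_summary")
}

#' Relative improvement of the best model over a reference average
#'
#' `100 * (best - reference_avg) / reference_avg`, reported to one
#' decimal -- e.g. the margin of the best model over the all-model average
#' of a randomized-search cycle.
#'
#' @param best Best mean_test_AUC.
#' @param reference_avg Reference average (> 0).
#' @return Percentage, rounded to 1 decimal.
#' @export
relative_improvement <- function(best, reference_avg) {
  if (!is.numeric(reference_avg) || reference_avg <= 0)
    abort("reference_avg must be positive", "domain_error")
  round(100 * (best - reference_avg) / reference_avg, 1)
}

#' RTPS/TNS/TRT accounting for a search log
#'
#' RTPS is the mean wall time per hyperparameter setting, TNS the number
#' of settings in the log, and TRT the summed wall time in hours.
#'
#' @param log A `search_log` with wall times.
#' @return A `budget_estimate`.
#' @export
runtime_accounting <- function(log) {
  stopifnot(inherits(log, "search_log"))
  wall <- vapply(log$records, `[[`, 0, "wall_seconds")
  if (length(wall) == 0L) abort("empty log", "domain_error")
  structure(list(rtps_seconds = mean(wall), tns = length(wall),
                 trt_hours = sum(wall) / 3600,
                 trt_years = sum(wall) / 31536000),
            class = "budget_estimate")
}

#' Export report tables for a set of cycle logs
#'
#' Writes CSV twins of the study report tables: top-k group averages,
#' mid-point group results, and RTPS/TNS/TRT accounting, one row per
#' cycle. AUC-derived values are rounded to 5 decimals, hours to 2.
#'
#' @param logs Named list of `search_log`s (one per cycle).
#' @param out_dir Output directory (created if needed).
#' @param ks Group sizes for the group table (capped at each log's size).
#' @return Invisibly, the list of written paths.
#' @export
report_tables <- function(logs, out_dir, ks = c(1, 5, 10, 50, 100)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grp <- do.call(rbind, lapply(logs, function(lg) {
    use <- ks[ks <= length(lg$records)]
    gs <- group_summary(lg, use)
    row <- as.list(round_half_up(c(gs$top_k_averages, all = gs$all_average), 5))
    as.data.frame(c(list(cycle = lg$cycle_label), row))
  }))
  mid <- do.call(rbind, lapply(logs, function(lg) {
    ms <- midpoint_summary(lg)
    data.frame(cycle = lg$cycle_label,
               best_mean = round_half_up(ms$best_mean, 5),
               mid_point = round_half_up(ms$mid_point, 5), chs = ms$chs,
               tns = ms$tns, ratio = round_half_up(ms$ratio, 5),
               avg_mean_decent = round_half_up(ms$avg_mean_decent, 5))
  }))
  rt <- do.call(rbind, lapply(logs, function(lg) {
    be <- runtime_accounting(lg)
    data.frame(cycle = lg$cycle_label, rtps = round(be$rtps_seconds, 2),
               tns = be$tns, trt_hours = round(be$trt_hours, 2))
  }))
  paths <- file.path(out_dir, c("group_performance.csv", "midpoint_groups.csv",
                                "runtime_accounting.csv"))
  utils::write.csv(grp, paths[1], row.names = FALSE)
  utils::write.csv(mid, paths[2], row.names = FALSE)
  utils::write.csv(rt, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("[%s] %s | all %.5f (n=%d)\n", x$cycle_label,
              paste(sprintf("%s %.5f", names(x$top_k_averages), x$top_k_averages),
                    collapse = " | "),
              x$all_average, x$n))
  invisible(x)
}

#' @export
print.midpoint_summary <- function(x, ...) {
  cat(sprintf("best %.5f, mid-point %.5f, CHS/TNS %d/%d = %.5f, decent avg %.5f\n",
              x$best_mean, x$mid_point, x$chs, x$tns, x$ratio, x$avg_mean_decent))
  invisible(x)
}
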