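test_that("stage1_sweep varies only the target hyperparameter, deterministically", {
  ds <- signal_dataset(seed = 7)
  plan <- make_split(ds, seed = 2)
  lrs <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.08, 0.1, 0.15, 0.2, 0.3)
  base <- make_setting(epochs = 5L)
  log <- stage1_sweep(the_space, "learning_rate", lrs, base, ds, plan, master_seed = 3)
  expect_length(log$records, 10)
  for (i in seq_along(lrs)) {
    s <- log$records[[i]]$setting
    expect_identical(s$learning_rate, lrs[i])
    rest <- s[setdiff(names(s), "learning_rate")]
    expect_identical(rest, base[setdiff(names(base), "learning_rate")])
  }
  log2 <- stage1_sweep(the_space, "learning_rate", lrs, base, ds, plan, master_seed = 3)
  expect_identical(vapply(log$records, `[[`, 0, "mean_test_auc"),
                   vapply(log2$records, `[[`, 0, "mean_test_auc"))
  expect_error(stage1_sweep(the_space, "learning_rate", numeric(0), base, ds, plan),
               class = "domain_error")
})

test_that("an epochs sweep shows the undertraining trend on planted-signal data", {
  ds <- signal_dataset(seed = 7)
  plan <- make_split(ds, seed = 2)
  log <- stage1_sweep(the_space, "epochs", c(5L, 50L),
                      make_setting(learning_rate = 0.002), ds, plan, master_seed = 11)
  aucs <- vapply(log$records, `[[`, 0, "mean_test_auc")
  expect_gte(aucs[2], aucs[1])
})

test_that("proper-value extraction applies the mid-point rule", {
  log <- log_from_aucs(c(0.50, 0.62, 0.74, 0.75))
  log$target_hp <- "epochs"
  vals <- vapply(log$records, function(r) r$setting$epochs, 0L)
  # mid-point of best 0.75 is 0.625: 0.50 and 0.62 fall away
  expect_identical(extract_proper_values(log, "epochs"), vals[3:4])

  flat <- log_from_aucs(rep(0.7, 4))
  flat$target_hp <- "epochs"
  expect_length(extract_proper_values(flat, "epochs"), 4)

  single <- log_from_aucs(0.55)
  single$target_hp <- "epochs"
  expect_length(extract_proper_values(single, "epochs"), 1)

  expect_error(extract_proper_values(log, "dropout"), class = "domain_error")
  mixed <- log_from_aucs(c(0.6, 0.7))
  mixed$records[[2]]$setting$dropout <- 0.3  # second dimension varies too
  mixed$target_hp <- "epochs"
  expect_error(extract_proper_values(mixed, "epochs"), class = "domain_error")
})

test_that("stage2_grid evaluates the enumerated prefix and accounts its runtime", {
  ds <- signal_dataset(seed = 7)
  plan <- make_split(ds, seed = 2)
  cand <- make_candidates(learning_rate = c(0.005, 0.02, 0.05),
                          epochs = c(5L, 10L), n_nodes = c(2L, 6L))
  pool <- setting_pool(the_space, cand, structural = "uniform")
  res <- stage2_grid(pool, ds, plan, max_settings = 12, master_seed = 5)
  expect_identical(res$budget$tns, 12L)
  expect_length(res$log$records, 12)
  wall <- vapply(res$log$records, `[[`, 0, "wall_seconds")
  expect_equal(res$budget$trt_hours, sum(wall) / 3600, tolerance = 0.01)
  expect_equal(res$budget$rtps_seconds, mean(wall))
  # RTPS from a prefix predicts the total within +/-50% on homogeneous settings
  prefix_rtps <- mean(wall[1:6])
  expect_lt(abs(prefix_rtps * 12 - sum(wall)) / sum(wall), 0.5)
})

test_that("sweet-spot windows clip and localize as index neighborhoods", {
  cand <- make_candidates(epochs = c(10L, 20L, 30L, 40L, 50L),
                          learning_rate = c(0.01, 0.05, 0.1))
  best <- make_setting(epochs = 30L, learning_rate = 0.1)
  spot <- build_sweet_spot_pool(best, cand, radius = 1, the_space)
  expect_identical(spot$windows$epochs, c(20L, 30L, 40L))
  expect_identical(spot$windows$learning_rate, c(0.05, 0.1))  # clipped at the end

  spot2 <- build_sweet_spot_pool(make_setting(epochs = 50L, learning_rate = 0.01),
                                 cand, radius = 2, the_space)
  expect_identical(spot2$windows$epochs, c(30L, 40L, 50L))  # clipped, length 3

  spot0 <- build_sweet_spot_pool(best, cand, radius = 0, the_space)
  expect_identical(pool_cardinality(spot0$pool), 1)
  only <- enumerate_pool(spot0$pool)[[1]]
  expect_identical(unclass(only)[names(best)], unclass(best)[names(best)])

  expect_error(build_sweet_spot_pool(best, cand, radius = -1, the_space),
               class = "domain_error")
  expect_error(build_sweet_spot_pool(make_setting(epochs = 15L), cand, 1, the_space),
               class = "domain_error")
})

test_that("OLO reseeding picks the best setting outside every excluded window", {
  cand <- make_candidates(epochs = c(10L, 20L, 30L, 40L, 50L),
                          dropout = c(0, 0.2, 0.4))
  mk_rec <- function(epochs, dropout, auc)
    threestage:::new_trial_record(make_setting(epochs = epochs, dropout = dropout),
                                  rep(auc, 5), 0.1, "t")
  recs <- list(mk_rec(20L, 0, 0.80), mk_rec(30L, 0.2, 0.75),
               mk_rec(50L, 0.4, 0.70), mk_rec(40L, 0.4, 0.72))
  log <- search_log(recs, "t")
  spot <- build_sweet_spot_pool(make_setting(epochs = 20L, dropout = 0),
                                cand, radius = 1, the_space)
  # records 1 and 2 sit inside the window (epochs 10-30, dropout 0-0.2)
  pick <- olo_reseed(list(log), list(spot))
  expect_identical(pick$epochs, 40L)  # 0.72 beats 0.70

  # brute-force filter-then-argmax oracle over random logs
  withr::with_seed(14, {
    for (rep in 1:5) {
      rs <- lapply(1:12, function(i)
        mk_rec(sample(cand$epochs, 1), sample(cand$dropout, 1), runif(1, 0.5, 0.9)))
      keys <- sapply(rs, function(r) threestage:::setting_key(r$setting))
      rs <- rs[!duplicated(keys)]
      lg <- search_log(rs, "t")
      outside <- sapply(rs, function(r)
        !(r$setting$epochs %in% spot$windows$epochs &&
            r$setting$dropout %in% spot$windows$dropout))
      if (!any(outside)) {
        expect_error(olo_reseed(list(lg), list(spot)), class = "olo_exhausted")
      } else {
        aucs <- sapply(rs, `[[`, "mean_test_auc")
        aucs[!outside] <- -Inf
        oracle <- rs[[which.max(aucs)]]$setting
        expect_identical(olo_reseed(list(lg), list(spot)), oracle)
      }
    }
  })

  # everything inside -> exhaustion
  inside_log <- search_log(list(mk_rec(20L, 0.2, 0.9)), "t")
  expect_error(olo_reseed(list(inside_log), list(spot)), class = "olo_exhausted")
  expect_error(olo_reseed(list(), list(spot)), class = "domain_error")
})

test_that("RGS sampling is uniform, unique, exhaustive and seeded", {
  cand <- make_candidates(kernel_init = c("constant", "glorot_normal",
                                          "glorot_uniform", "he_normal"),
                          epochs = c(5L, 10L, 15L, 20L, 25L),
                          dropout = c(0, 0.1, 0.2, 0.3, 0.4),
                          learning_rate = c(0.01, 0.05, 0.1, 0.2, 0.25))
  pool <- setting_pool(the_space, cand, structural = "uniform")  # 500 settings
  s1 <- rgs_sample(pool, 100, seed = 7)
  s2 <- rgs_sample(pool, 100, seed = 7)
  expect_identical(s1, s2)
  keys <- vapply(s1, threestage:::setting_key, character(1))
  expect_identical(anyDuplicated(keys), 0L)

  # n = cardinality returns the entire pool as a set
  tiny <- setting_pool(the_space, make_candidates(dropout = c(0, 0.2), l1 = c(0, 0.01)),
                       structural = "uniform")
  all4 <- rgs_sample(tiny, 4, seed = 1)
  expect_setequal(vapply(all4, threestage:::setting_key, character(1)),
                  vapply(enumerate_pool(tiny), threestage:::setting_key, character(1)))
  expect_error(rgs_sample(tiny, 5, seed = 1), class = "domain_error")

  # marginal uniformity of a 4-value dimension over 10,000 draws
  big <- setting_pool(the_space, make_candidates(
    kernel_init = c("constant", "glorot_normal", "glorot_uniform", "he_normal"),
    epochs = seq(5L, 100L, by = 5L), dropout = seq(0, 0.5, 0.025),
    learning_rate = seq(0.001, 0.3, length.out = 20)), structural = "uniform")
  draws <- rgs_sample(big, 10000, seed = 99)
  counts <- table(vapply(draws, function(s) s$kernel_init, character(1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("search logs reject duplicates and round-trip through JSON lines", {
  rec <- threestage:::new_trial_record(make_setting(), rep(0.6, 5), 0.2, "c")
  expect_error(search_log(list(rec, rec), "c"), class = "domain_error")

  log <- log_from_aucs(c(0.55, 0.72, 0.61), cycle = "Stage3-c2")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_search_log(log, path)
  back <- read_search_log(path)
  expect_identical(back$cycle_label, "Stage3-c2")
  expect_equal(vapply(back$records, `[[`, 0, "mean_test_auc"),
               vapply(log$records, `[[`, 0, "mean_test_auc"))
  expect_identical(vapply(back$records, function(r) r$setting$epochs, 0),
                   vapply(log$records, function(r) as.numeric(r$setting$epochs), 0))
})

test_that("a desk-scale three-stage run emits 8 chained, reproducible cycles", {
  ds <- generate_dataset(demo_dataset_config(n_cases = 160, seed = 31))
  cfg <- demo_search_config()
  cfg$stage2_max <- 8L; cfg$ssgs_max <- 6L; cfg$rgs_n <- 8L  # trim for speed
  res <- run_three_stage(cfg, ds, master_seed = 31)
  expect_named(res$logs, c("Stage1", "Stage2", paste0("Stage3-c", 1:6)))
  expect_length(res$logs, 8)

  # SSGS settings stay within the Cartesian product of the proper values
  for (cyc in paste0("Stage3-c", 1:5)) {
    for (r in res$logs[[cyc]]$records) {
      for (nm in names(res$proper_values))
        expect_true(all(r$setting[[nm]] %in% res$proper_values[[nm]]))
    }
  }
  # the refit top model scores the held-out validation set
  expect_true(is.finite(res$best$validation_auc))
  # full-run determinism from the master seed (timings excluded: wall clock)
  res2 <- run_three_stage(cfg, ds, master_seed = 31)
  keep <- setdiff(names(res$summary), "trt_hours")
  expect_identical(res$summary[keep], res2$summary[keep])
  expect_identical(res$best$record$setting, res2$best$record$setting)
  expect_identical(res$best$record$fold_aucs, res2$best$record$fold_aucs)
})
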