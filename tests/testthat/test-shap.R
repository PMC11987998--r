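test_that("k-means background summarizes the training matrix", {
  withr::with_seed(2, X <- matrix(rnorm(200), 50, 4))
  bg1 <- kmeans_background(X, k = 1)
  expect_equal(unname(bg1$background_values), unname(colMeans(X)))

  bg <- kmeans_background(X, k = 4, seed = 3)
  expect_identical(nrow(bg$centroids), 4L)
  expect_length(bg$background_values, 4)

  # duplicating every row leaves well-separated centroids unchanged
  centers <- matrix(c(0, 0, 10, 10, -10, 5), 3, 2, byrow = TRUE)
  withr::with_seed(4, {
    Xc <- centers[rep(1:3, each = 30), ] + matrix(rnorm(180, 0, 0.1), 90, 2)
  })
  b1 <- kmeans_background(Xc, k = 3, seed = 5)
  b2 <- kmeans_background(rbind(Xc, Xc), k = 3, seed = 5)
  o1 <- b1$centroids[order(b1$centroids[, 1]), ]
  o2 <- b2$centroids[order(b2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-6)

  expect_error(kmeans_background(X, k = 51), class = "domain_error")
})

test_that("exact Shapley reproduces the additive closed form and a hand enumeration", {
  w <- c(2, -1, 0.5, 3)
  pf <- function(M) as.numeric(M %*% w)
  case <- c(a = 1, b = 0.2, c = -1, d = 0.4)
  bgv <- c(0.5, 0.5, 0.5, 0.5)
  phi <- exact_shapley(pf, case, bgv)
  expect_equal(unname(phi), unname(w * (case - bgv)), tolerance = 1e-12)

  # two-feature product game, all four subset values written out:
  # p(00)=0, p(10)=0, p(01)=0, p(11)=1 -> phi = (0.5, 0.5)
  prod2 <- function(M) M[, 1] * M[, 2]
  phi2 <- exact_shapley(prod2, c(x = 1, y = 1), c(0, 0))
  expect_equal(unname(phi2), c(0.5, 0.5), tolerance = 1e-12)

  expect_error(exact_shapley(pf, rep(1, 21), rep(0, 21)), class = "guard_error")
})

test_that("exact Shapley satisfies efficiency, symmetry and dummy", {
  pf <- function(M) M[, 1]^2 + 3 * M[, 1] * M[, 2] + 3 * M[, 1] * M[, 3] + exp(M[, 4])
  case <- c(f1 = 1.2, f2 = 0.7, f3 = 0.7, f4 = -0.5, f5 = 2)
  bgv <- c(0.1, 0.2, 0.2, 0.3, 0.4)
  phi <- exact_shapley(pf, case, bgv)
  # efficiency: attributions sum to full minus all-background prediction
  full <- pf(matrix(case, 1)); base <- pf(matrix(bgv, 1))
  expect_equal(sum(phi), full - base, tolerance = 1e-10)
  # symmetry: f2 and f3 enter identically and share value/background
  expect_equal(phi[["f2"]], phi[["f3"]], tolerance = 1e-10)
  # dummy: f5 never enters the model
  expect_equal(phi[["f5"]], 0, tolerance = 1e-12)
})

test_that("the sampled estimator converges to the exact values", {
  w <- c(1.5, -2, 0.7, 0, 1)
  pf <- function(M) as.numeric(M %*% w)
  case <- c(1, 1, 0, 1, -1)
  bgv <- rep(0.3, 5)
  ex <- exact_shapley(pf, case, bgv)
  # additive game: every permutation contributes the closed form exactly
  sa1 <- sampled_shapley(pf, case, bgv, n_samples = 6000, seed = 1)
  sa2 <- sampled_shapley(pf, case, bgv, n_samples = 6000, seed = 2)
  expect_equal(unname(sa1), unname(ex), tolerance = 1e-8)
  expect_equal(unname(sa2), unname(ex), tolerance = 1e-8)

  # non-additive game: agreement within a few percent of the output range
  pg <- function(M) M[, 1] * M[, 2] + pmax(M[, 3], M[, 4])
  exg <- exact_shapley(pg, c(1, 1, 0.2, 0.9), c(0, 0, 0.5, 0.5))
  sag <- sampled_shapley(pg, c(1, 1, 0.2, 0.9), c(0, 0, 0.5, 0.5),
                         n_samples = 20000, seed = 5)
  expect_lt(max(abs(sag - exg)), 0.05)
  expect_error(sampled_shapley(pg, rep(1, 4), rep(0, 4), n_samples = 6),
               class = "domain_error")
})

test_that("importance ranks features by mean absolute attribution", {
  vals <- rbind(c(0.1, -0.8, 0.05), c(-0.2, 0.7, 0.0), c(0.15, -0.75, -0.05))
  colnames(vals) <- c("a", "b", "c")
  sh <- structure(list(values = vals, base_value = 0.4,
                       importance = colMeans(abs(vals)),
                       feature_names = colnames(vals)),
                  class = "shap_result")
  tab <- importance_table(sh)
  expect_identical(tab$feature, c("b", "a", "c"))
  expect_equal(tab$importance, sort(colMeans(abs(vals)), decreasing = TRUE),
               ignore_attr = TRUE)

  zero <- sh; zero$values[] <- 0
  expect_true(all(importance_table(zero)$importance == 0))
  expect_identical(importance_table(zero)$feature, c("a", "b", "c"))  # declaration order

  # invariance to case order
  perm <- sh; perm$values <- vals[c(3, 1, 2), ]
  expect_identical(importance_table(perm), tab)
})

test_that("shapley_explain attributes a planted additive driver first", {
  withr::with_seed(12, X <- matrix(sample(0:2, 300, replace = TRUE), 100, 3,
                                   dimnames = list(NULL, c("f1", "f2", "f3"))))
  pf <- function(M) 5 * M[, 1] + 0.3 * M[, 2]
  bg <- kmeans_background(X, seed = 1)
  sh <- shapley_explain(pf, X[1:40, ], bg)
  expect_identical(importance_table(sh)$feature[1], "f1")
  # per-case efficiency against the base value
  full <- pf(X[1:40, ])
  expect_equal(rowSums(sh$values), full - sh$base_value, tolerance = 1e-10)
})

test_that("dependence analysis finds interaction partners of the top feature", {
  withr::with_seed(7, {
    x1 <- sample(0:4, 2000, replace = TRUE)   # wide-range driver
    x2 <- sample(0:1, 2000, replace = TRUE)   # binary interaction partner
    noise <- runif(2000)
  })
  X <- cbind(x1 = x1, x2 = x2, noise = noise)
  pf <- function(M) M[, 1] * M[, 2]
  # reference patient at the lowest x1 code so the interaction surfaces in phi
  sh <- shapley_explain(pf, X, c(0, mean(x2), mean(noise)))
  dep <- dependence_analysis(sh, X)
  expect_identical(dep$top_feature, "x1")
  expect_identical(dep$ranking$feature[1], "x2")  # the planted interaction
  expect_lt(abs(dep$ranking$correlation[dep$ranking$feature == "noise"]), 0.05)
  expect_identical(names(dep$triples), c("top_value", "top_phi", "partner_value"))

  # a partner identical to the top attribution column correlates perfectly
  phi1 <- sh$values[, "x1"]
  X2 <- cbind(a = x1, twin = phi1)
  sh2 <- structure(list(values = cbind(a = phi1, twin = 0), base_value = 0,
                        importance = c(mean(abs(phi1)), 0),
                        feature_names = colnames(X2)),
                   class = "shap_result")
  dep2 <- dependence_analysis(sh2, X2)
  expect_equal(dep2$ranking$correlation[1], 1)
  expect_error(dependence_analysis(sh2, X2[, 1, drop = FALSE]), class = "domain_error")
})

test_that("hyperparameter recoding follows the fixed ordinal maps", {
  expect_identical(threestage:::recode_hyperparameter("kernel_init", "he_uniform"), 4)
  expect_identical(threestage:::recode_hyperparameter("kernel_init",
                     c("constant", "glorot_normal", "glorot_uniform", "he_normal")),
                   c(0, 1, 2, 3))
  expect_identical(threestage:::recode_hyperparameter("optimizer", "sgd"), 4)
  expect_identical(threestage:::recode_hyperparameter("activation", "relu"), 0)
})

test_that("hyperparameter importance recovers a planted AUC driver", {
  pool <- setting_pool(the_space, demo_search_config()$candidates,
                       structural = "uniform")
  sets <- rgs_sample(pool, 150, seed = 4)
  withr::with_seed(4, noise <- rnorm(150, 0, 0.02))
  recs <- lapply(seq_along(sets), function(i) {
    lr <- sets[[i]]$learning_rate
    auc <- 0.55 + 0.25 * log(lr / 0.002) / log(0.3 / 0.002) + noise[i]
    threestage:::new_trial_record(sets[[i]], rep(auc, 5), 0.1, "syn")
  })
  log <- search_log(recs, "syn")
  hi <- hyperparameter_importance(log, seed = 4)
  expect_identical(hi$ranking$feature[1], "learning_rate")
  expect_identical(nrow(hi$ranking), 12L)  # 13 dims collapsed to 12 (mstruct)
  expect_true("mstruct" %in% hi$ranking$feature)

  short <- search_log(recs[1:20], "syn")
  expect_error(hyperparameter_importance(short, seed = 1), class = "domain_error")
})

test_that("a constant-AUC log yields zero importances in declaration order", {
  pool <- setting_pool(the_space, demo_search_config()$candidates,
                       structural = "uniform")
  sets <- rgs_sample(pool, 60, seed = 9)
  recs <- lapply(sets, function(s)
    threestage:::new_trial_record(s, rep(0.6, 5), 0.1, "flat"))
  log <- search_log(recs, "flat")
  hi <- suppressWarnings(hyperparameter_importance(log, seed = 2))
  expect_true(all(abs(hi$ranking$importance) < 1e-12))
  expect_identical(hi$ranking$feature,
                   c("mstruct", "activation", "kernel_init", "optimizer",
                     "learning_rate", "momentum", "decay", "dropout", "epochs",
                     "batch_size", "l1", "l2"))
})
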