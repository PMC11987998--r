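#' k-means background data for Shapley estimation
#'
#' Summarizes a training matrix into k representative cluster centroids
#' (k conventionally equal to the number of features); the background
#' value of a feature is the mean of that feature over the k centroids.
#' Background values stand in for "absent" features when evaluating
#' subset predictions.
#'
#' @param training_matrix Numeric case-by-feature matrix.
#' @param k Number of centroids (defaults to the feature count; must not
#'   exceed the row count).
#' @param seed Integer seed for the clustering.
#' @return A `background_data`: `centroids` (k x features),
#'   `background_values` (per-feature centroid means).
#' @export
kmeans_background <- function(training_matrix, k = ncol(training_matrix), seed = 1L) {
  X <- as.matrix(training_matrix)
  if (k > nrow(X)) abort("k must not exceed the number of rows", "domain_error")
  n_distinct <- nrow(unique(X))
  k_eff <- min(k, n_distinct)
  cent <- if (k_eff == 1L) {
    matrix(colMeans(X), 1, ncol(X), dimnames = list(NULL, colnames(X)))
  } else {
    km <- withr::with_seed(seed,
      stats::kmeans(X, centers = k_eff, nstart = 10, iter.max = 100))
    km$centers
  }
  structure(list(centroids = cent, background_values = colMeans(cent), k = k_eff),
            class = "background_data")
}

subset_weights <- function(m) {
  # |S|! (|F|-|S|-1)! / |F|!  for |S| = 0..m-1, via log-factorials
  s <- 0:(m - 1)
  exp(lfactorial(s) + lfactorial(m - s - 1) - lfactorial(m))
}

#' Exact Shapley values by full subset enumeration
#'
#' Evaluates the classical formula
#' \deqn{\phi_i = \sum_{S \subseteq F\setminus\{i\}}
#'   \frac{|S|!\,(|F|-|S|-1)!}{|F|!}\,[p(S \cup \{i\}) - p(S)]}
#' over every subset of `feature_set`. A synthetic sample takes the
#' case's real values on `S` (and on `i` when included) and the
#' background values elsewhere; features outside `feature_set` keep the
#' case's values. All `2^|F|` synthetic samples are scored in one call to
#' `predict_fn`.
#'
#' @param predict_fn Function mapping a case-by-feature matrix to a
#'   numeric score vector.
#' @param case Single feature vector being explained.
#' @param background_values Per-feature background values (see
#'   [kmeans_background()]).
#' @param feature_set Indices of the features to attribute over (at most
#'   20; larger sets must use [sampled_shapley()]).
#' @return Named numeric vector of attributions, one per
#'   `feature_set` member.
#' @export
exact_shapley <- function(predict_fn, case, background_values,
                          feature_set = seq_along(case)) {
  m <- length(feature_set)
  if (m > 20)
    abort("feature_set larger than 20: use sampled_shapley()", "guard_error")
  n_masks <- 2L^m
  bits <- 2L^(seq_len(m) - 1L)
  masks <- 0:(n_masks - 1L)
  # synthetic samples: case values where the bit is set, background otherwise
  Xsyn <- matrix(rep(as.numeric(case), each = n_masks), n_masks, length(case))
  colnames(Xsyn) <- names(case)
  for (j in seq_len(m)) {
    off <- bitwAnd(masks, bits[j]) == 0L
    Xsyn[off, feature_set[j]] <- background_values[feature_set[j]]
  }
  p <- as.numeric(predict_fn(Xsyn))
  pc <- vapply(masks, function(x) sum(bitwAnd(x, bits) > 0L), integer(1))
  w <- subset_weights(m)
  phi <- numeric(m)
  for (j in seq_len(m)) {
    s_masks <- masks[bitwAnd(masks, bits[j]) == 0L]
    phi[j] <- sum(w[pc[s_masks + 1L] + 1L] *
                    (p[s_masks + bits[j] + 1L] - p[s_masks + 1L]))
  }
  names(phi) <- if (!is.null(names(case))) names(case)[feature_set] else
    as.character(feature_set)
  phi
}

#' Sampled Shapley values by permutation Monte Carlo
#'
#' Unbiased estimator of the same attribution: features enter in random
#' order and each feature is credited with its marginal change in the
#' model score, averaged over permutations. `n_samples` counts synthetic
#' samples scored; each permutation costs `|F| + 1` of them.
#'
#' @inheritParams exact_shapley
#' @param n_samples Total synthetic samples (at least `2 * |F|`).
#' @param seed Integer seed.
#' @return Named numeric vector of attributions.
#' @export
sampled_shapley <- function(predict_fn, case, background_values,
                            feature_set = seq_along(case), n_samples = 2000L,
                            seed = 1L) {
  m <- length(feature_set)
  if (n_samples < 2 * m)
    abort("n_samples must be at least 2 * |feature_set|", "domain_error")
  n_perms <- max(1L, as.integer(floor(n_samples / (m + 1L))))
  base <- as.numeric(case)
  bg <- base; bg[feature_set] <- background_values[feature_set]
  rows <- matrix(0, n_perms * (m + 1L), length(case))
  orders <- withr::with_seed(seed,
    lapply(seq_len(n_perms), function(i) sample.int(m)))
  r <- 0L
  for (ord in orders) {
    cur <- bg
    r <- r + 1L; rows[r, ] <- cur
    for (j in ord) {
      cur[feature_set[j]] <- base[feature_set[j]]
      r <- r + 1L; rows[r, ] <- cur
    }
  }
  colnames(rows) <- names(case)
  p <- as.numeric(predict_fn(rows))
  phi <- numeric(m)
  r <- 0L
  for (ord in orders) {
    for (pos in seq_len(m)) {
      phi[ord[pos]] <- phi[ord[pos]] + (p[r + pos + 1L] - p[r + pos])
    }
    r <- r + m + 1L
  }
  phi <- phi / n_perms
  names(phi) <- if (!is.null(names(case))) names(case)[feature_set] else
    as.character(feature_set)
  phi
}

#' Shapley attributions for a set of test cases
#'
#' Computes per-case attributions over every feature, switching from the
#' exact enumerator to the permutation sampler above `exact_max` features.
#' The base value is the model score of the all-background sample.
#'
#' @param predict_fn Score function (matrix in, numeric vector out).
#' @param cases Case-by-feature matrix of test cases.
#' @param background A `background_data` (or a plain named vector of
#'   background values).
#' @param exact_max Feature count above which sampling is used
#'   (default 15).
#' @param n_samples Samples per case for the sampled path.
#' @param seed Integer seed.
#' @return A `shap_result`: `values` (case x feature matrix),
#'   `base_value`, `importance` (per-feature mean absolute attribution),
#'   `feature_names`.
#' @export
shapley_explain <- function(predict_fn, cases, background, exact_max = 15L,
                            n_samples = 2000L, seed = 1L) {
  X <- as.matrix(cases)
  bg <- if (inherits(background, "background_data")) background$background_values
        else background
  m <- ncol(X)
  vals <- matrix(0, nrow(X), m, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(nrow(X))) {
    case <- X[i, ]
    vals[i, ] <- if (m <= exact_max) {
      exact_shapley(predict_fn, case, bg)
    } else {
      sampled_shapley(predict_fn, case, bg, n_samples = n_samples,
                      seed = derive_seed(seed, paste0("case", i)))
    }
  }
  base_row <- matrix(bg, 1, m); colnames(base_row) <- colnames(X)
  structure(list(values = vals,
                 base_value = as.numeric(predict_fn(base_row)),
                 importance = colMeans(abs(vals)),
                 feature_names = colnames(X)),
            class = "shap_result")
}

#' Rank features by mean absolute Shapley value
#'
#' @param shap A `shap_result`.
#' @return Data frame `feature`, `importance`, sorted descending (ties by
#'   declaration order).
#' @export
importance_table <- function(shap) {
  stopifnot(inherits(shap, "shap_result"))
  imp <- colMeans(abs(shap$values))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = shap$feature_names[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Dependence analysis around the most important feature
#'
#' Identifies the top-importance feature, ranks every other feature by the
#' absolute Pearson correlation between its values and the top feature's
#' attribution column, and emits the plotting triples (top-feature value,
#' top-feature attribution, best-partner value).
#'
#' @param shap A `shap_result` for a set of cases.
#' @param cases The matching case-by-feature value matrix.
#' @return List with `top_feature`, `ranking` (feature, correlation,
#'   abs_correlation), and `triples`.
#' @export
dependence_analysis <- function(shap, cases) {
  stopifnot(inherits(shap, "shap_result"))
  X <- as.matrix(cases)
  if (ncol(X) < 2) abort("need at least 2 features", "domain_error")
  top <- importance_table(shap)$feature[1]
  phi_top <- shap$values[, top]
  others <- setdiff(shap$feature_names, top)
  cors <- vapply(others, function(f) {
    if (stats::sd(X[, f]) == 0 || stats::sd(phi_top) == 0) return(0)
    stats::cor(X[, f], phi_top)
  }, 0)
  ord <- order(-abs(cors), seq_along(cors))
  ranking <- data.frame(feature = others[ord], correlation = unname(cors[ord]),
                        abs_correlation = abs(unname(cors[ord])),
                        stringsAsFactors = FALSE)
  partner <- ranking$feature[1]
  list(top_feature = top, ranking = ranking,
       triples = data.frame(top_value = X[, top], top_phi = phi_top,
                            partner_value = X[, partner]))
}

# fixed ordinal recodings for the categorical hyperparameters
KINIT_CODES <- c(constant = 0, glorot_normal = 1, glorot_uniform = 2,
                 he_normal = 3, he_uniform = 4)
ACTIVATION_CODES <- c(relu = 0, sigmoid = 1, softmax = 2, tanh = 3)   # alphabetical
OPTIMIZER_CODES <- c(adagrad = 0, adam = 1, adamax = 2, nadam = 3, sgd = 4)  # alphabetical

recode_hyperparameter <- function(name, values) {
  switch(name,
    kernel_init = unname(KINIT_CODES[tolower(values)]),
    activation  = unname(ACTIVATION_CODES[tolower(values)]),
    optimizer   = unname(OPTIMIZER_CODES[tolower(values)]),
    as.numeric(values))
}

# grid-search log -> numeric hyperparameter feature table; the two
# structural dimensions collapse into one complexity scalar (mstruct =
# total hidden-node count)
log_feature_table <- function(log) {
  df <- log_df(log)
  widths <- vapply(strsplit(as.character(df$n_nodes), "x"),
                   function(w) sum(as.numeric(w)), 0)
  scalar_width <- !grepl("x", as.character(df$n_nodes))
  mstruct <- ifelse(scalar_width, df$n_layers * widths, widths)
  feats <- data.frame(
    mstruct = mstruct,
    activation = recode_hyperparameter("activation", df$activation),
    kernel_init = recode_hyperparameter("kernel_init", df$kernel_init),
    optimizer = recode_hyperparameter("optimizer", df$optimizer),
    learning_rate = df$learning_rate, momentum = df$momentum,
    decay = df$decay, dropout = df$dropout, epochs = df$epochs,
    batch_size = df$batch_size, l1 = df$l1, l2 = df$l2)
  list(features = feats, outcome = df$mean_test_auc)
}

#' Hyperparameters-as-features importance analysis
#'
#' Treats each logged hyperparameter setting as a case and its
#' mean_test_AUC as the outcome: categorical hyperparameters are recoded
#' to ordinals (kernel initializer: constant 0, glorot_normal 1,
#' glorot_uniform 2, he_normal 3, he_uniform 4; activation and optimizer
#' alphabetically), the two structural dimensions collapse into a single
#' complexity feature `mstruct` (total hidden-node count), the table is
#' split 80/20, a 100-tree random-forest regressor is fit on the 80%, and
#' Shapley attributions are computed on the held-out 20% against a
#' k-means background with k equal to the number of hyperparameter
#' features.
#'
#' @param log A `search_log` with at least 50 records.
#' @param seed Integer seed (split, background, sampling).
#' @param exact_max Passed to [shapley_explain()].
#' @return List with `ranking` (the importance table), `shap` (the
#'   `shap_result`), and `surrogate` (the fitted forest).
#' @export
hyperparameter_importance <- function(log, seed = 1L, exact_max = 15L) {
  stopifnot(inherits(log, "search_log"))
  if (length(log$records) < 50L)
    abort("need at least 50 records for the surrogate analysis", "domain_error")
  tab <- log_feature_table(log)
  X <- as.matrix(tab$features)
  y <- tab$outcome
  n <- nrow(X)
  idx_train <- withr::with_seed(derive_seed(seed, "split"),
                                sample.int(n, round(0.8 * n)))
  rf <- withr::with_seed(derive_seed(seed, "forest"),
    randomForest::randomForest(x = as.data.frame(X[idx_train, , drop = FALSE]),
                               y = y[idx_train], ntree = 100))
  bg <- kmeans_background(X[idx_train, , drop = FALSE], k = ncol(X),
                          seed = derive_seed(seed, "bg"))
  predict_fn <- function(M) {
    D <- as.data.frame(M); names(D) <- colnames(X)
    as.numeric(stats::predict(rf, D))
  }
  shap <- shapley_explain(predict_fn, X[-idx_train, , drop = FALSE], bg,
                          exact_max = exact_max, seed = derive_seed(seed, "shap"))
  list(ranking = importance_table(shap), shap = shap, surrogate = rf)
}
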