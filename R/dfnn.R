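# Compact deep feedforward network (DFNN) trainer.
#
# Fully connected, acyclic, >= 1 hidden layer, two softmax output nodes
# trained with cross-entropy. Every tunable dimension of the search space
# is honored: depth, per-layer width, hidden activation, kernel
# initializer, optimizer family, learning rate, momentum (SGD),
# iteration-based learning-rate decay, inverted dropout, epochs, batch
# size, and L1/L2 weight penalties.

ACTIVATIONS <- c("relu", "sigmoid", "softmax", "tanh")
INITIALIZERS <- c("constant", "glorot_normal", "glorot_uniform", "he_normal", "he_uniform")
OPTIMIZERS <- c("sgd", "adam", "adagrad", "nadam", "adamax")

init_weights <- function(fan_in, fan_out, kind) {
  n <- fan_in * fan_out
  w <- switch(kind,
    constant       = rep(0.1, n),  # symmetric (deliberately poor) baseline
    glorot_normal  = stats::rnorm(n, 0, sqrt(2 / (fan_in + fan_out))),
    glorot_uniform = stats::runif(n, -sqrt(6 / (fan_in + fan_out)), sqrt(6 / (fan_in + fan_out))),
    he_normal      = stats::rnorm(n, 0, sqrt(2 / fan_in)),
    he_uniform     = stats::runif(n, -sqrt(6 / fan_in), sqrt(6 / fan_in)),
    abort(sprintf("unsupported kernel initializer '%s'", kind), "configuration_error")
  )
  matrix(w, fan_in, fan_out)
}

#' Build one DFNN from a hyperparameter setting
#'
#' Constructs (and initializes) a fully connected feedforward network whose
#' input width equals the number of predictors and whose output layer has
#' two softmax nodes carrying normalized class scores. Depth, width(s),
#' activation, kernel initializer and all training hyperparameters are
#' taken from the setting; the width entry may be a scalar (applied to all
#' hidden layers) or a per-layer vector.
#'
#' @param setting An `hp_setting` (see [new_setting()]).
#' @param n_features Input width.
#' @param seed Seed for weight initialization.
#' @return An object of class `dfnn` (untrained).
#' @export
build_model <- function(setting, n_features, seed = 1L) {
  L <- setting$n_layers
  widths <- setting$n_nodes
  if (length(widths) == 1L) widths <- rep(widths, L)
  if (length(widths) != L)
    abort("n_nodes must be scalar or one width per hidden layer", "configuration_error")
  if (!setting$activation %in% ACTIVATIONS)
    abort(sprintf("unsupported activation '%s'", setting$activation), "configuration_error")
  if (!setting$optimizer %in% OPTIMIZERS)
    abort(sprintf("unsupported optimizer '%s'", setting$optimizer), "configuration_error")
  dims <- c(n_features, widths, 2L)
  params <- withr::with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = init_weights(dims[i], dims[i + 1L], setting$kernel_init),
           b = rep(0, dims[i + 1L]))
    })
  })
  structure(list(setting = setting, dims = dims, params = params,
                 n_hidden_layers = L, trained = FALSE, diverged = FALSE,
                 center = NULL, scale = NULL),
            class = "dfnn")
}

#' Trainable parameter count of a DFNN
#'
#' Closed form: the sum over consecutive layer pairs of
#' `in * out + out` (weights plus biases).
#'
#' @param model A `dfnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "dfnn"))
  d <- model$dims
  sum(d[-length(d)] * d[-1] + d[-1])
}

act_fwd <- function(Z, kind) {
  switch(kind,
    relu    = pmax(Z, 0),
    sigmoid = 1 / (1 + exp(-Z)),
    tanh    = tanh(Z),
    softmax = {
      E <- exp(Z - apply(Z, 1, max))
      E / rowSums(E)
    })
}

# dL/dZ given dL/dA, using the stored activations A
act_bwd <- function(dA, Z, A, kind) {
  switch(kind,
    relu    = dA * (Z > 0),
    sigmoid = dA * A * (1 - A),
    tanh    = dA * (1 - A^2),
    softmax = A * (dA - rowSums(dA * A)))  # exact softmax Jacobian product
}

forward_pass <- function(params, X, activation, dropout_masks = NULL) {
  L <- length(params)
  Zs <- vector("list", L); As <- vector("list", L); Raw <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[l]]$W, 2, params[[l]]$b, "+")
    A <- if (l < L) act_fwd(Z, activation) else act_fwd(Z, "softmax")
    Raw[[l]] <- A  # pre-dropout activation, needed for exact derivatives
    if (l < L && !is.null(dropout_masks)) A <- A * dropout_masks[[l]]
    Zs[[l]] <- Z; As[[l]] <- A
  }
  list(Z = Zs, A = As, Raw = Raw)
}

make_optimizer <- function(kind, lr, momentum, decay, shapes) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$v <- lapply(shapes, function(s) lapply(s, function(x) x * 0))
  st$m <- lapply(shapes, function(s) lapply(s, function(x) x * 0))
  st$u <- lapply(shapes, function(s) lapply(s, function(x) x * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  function(params, grads) {
    st$t <- st$t + 1
    lr_t <- lr / (1 + decay * st$t)  # iteration-based decay
    for (l in seq_along(params)) {
      for (p in c("W", "b")) {
        g <- grads[[l]][[p]]
        switch(kind,
          sgd = {
            st$v[[l]][[p]] <- momentum * st$v[[l]][[p]] - lr_t * g
            params[[l]][[p]] <- params[[l]][[p]] + st$v[[l]][[p]]
          },
          adagrad = {
            st$v[[l]][[p]] <- st$v[[l]][[p]] + g^2
            params[[l]][[p]] <- params[[l]][[p]] - lr_t * g / (sqrt(st$v[[l]][[p]]) + eps)
          },
          adam = {
            st$m[[l]][[p]] <- b1 * st$m[[l]][[p]] + (1 - b1) * g
            st$v[[l]][[p]] <- b2 * st$v[[l]][[p]] + (1 - b2) * g^2
            mh <- st$m[[l]][[p]] / (1 - b1^st$t)
            vh <- st$v[[l]][[p]] / (1 - b2^st$t)
            params[[l]][[p]] <- params[[l]][[p]] - lr_t * mh / (sqrt(vh) + eps)
          },
          nadam = {
            st$m[[l]][[p]] <- b1 * st$m[[l]][[p]] + (1 - b1) * g
            st$v[[l]][[p]] <- b2 * st$v[[l]][[p]] + (1 - b2) * g^2
            mh <- st$m[[l]][[p]] / (1 - b1^st$t)
            vh <- st$v[[l]][[p]] / (1 - b2^st$t)
            params[[l]][[p]] <- params[[l]][[p]] -
              lr_t * (b1 * mh + (1 - b1) * g / (1 - b1^st$t)) / (sqrt(vh) + eps)
          },
          adamax = {
            st$m[[l]][[p]] <- b1 * st$m[[l]][[p]] + (1 - b1) * g
            st$u[[l]][[p]] <- pmax(b2 * st$u[[l]][[p]], abs(g))
            params[[l]][[p]] <- params[[l]][[p]] -
              (lr_t / (1 - b1^st$t)) * st$m[[l]][[p]] / (st$u[[l]][[p]] + eps)
          })
      }
    }
    params
  }
}

#' Train a DFNN on coded predictors and a binary outcome
#'
#' Mini-batch training with the setting's optimizer, cross-entropy loss on
#' the two softmax output nodes, inverted dropout on hidden activations,
#' and L1/L2 weight penalties. Predictors are standardized internally
#' (center/scale stored in the model). The batch size is clamped to the
#' number of training rows. A non-finite loss marks the model as diverged
#' and stops training instead of aborting, so deliberate extreme-value
#' probes survive a sweep.
#'
#' @param model A `dfnn` from [build_model()].
#' @param X Integer-coded predictor matrix.
#' @param y Binary outcome vector.
#' @param seed Seed governing shuffling and dropout.
#' @return The trained `dfnn` (fields `trained`, `diverged` updated).
#' @export
train_dfnn <- function(model, X, y, seed = 1L) {
  stopifnot(inherits(model, "dfnn"))
  s <- model$setting
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  Y <- cbind(1 - y, y)
  batch <- max(1L, min(as.integer(s$batch_size), n))
  L <- length(model$params)
  params <- model$params
  shapes <- params
  step <- make_optimizer(s$optimizer, s$learning_rate, s$momentum, s$decay, shapes)
  diverged <- FALSE
  withr::with_seed(seed, {
    for (epoch in seq_len(s$epochs)) {
      ord <- sample.int(n)
      snapshot <- params
      epoch_bad <- FALSE
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        nb <- nrow(Xb)
        masks <- if (s$dropout > 0) {
          lapply(seq_len(L - 1L), function(l) {
            keep <- matrix(stats::runif(nb * ncol(params[[l]]$W)) >= s$dropout,
                           nb, ncol(params[[l]]$W))
            keep / (1 - s$dropout)
          })
        } else NULL
        fp <- forward_pass(params, Xb, s$activation, masks)
        P <- fp$A[[L]]
        loss <- -mean(log(rowSums(P * Yb) + 1e-12)) +
          s$l1 * sum(vapply(params, function(p) sum(abs(p$W)), 0)) +
          s$l2 * sum(vapply(params, function(p) sum(p$W^2), 0))
        if (!is.finite(loss)) { epoch_bad <- TRUE; break }
        # backward
        grads <- vector("list", L)
        dZ <- (P - Yb) / nb
        for (l in rev(seq_len(L))) {
          A_prev <- if (l == 1L) Xb else fp$A[[l - 1L]]
          gW <- crossprod(A_prev, dZ) + s$l1 * sign(params[[l]]$W) + 2 * s$l2 * params[[l]]$W
          gb <- colSums(dZ)
          grads[[l]] <- list(W = gW, b = gb)
          if (l > 1L) {
            dA <- dZ %*% t(params[[l]]$W)
            if (!is.null(masks)) dA <- dA * masks[[l - 1L]]
            dZ <- act_bwd(dA, fp$Z[[l - 1L]], fp$Raw[[l - 1L]], s$activation)
          }
        }
        params <- step(params, grads)
        if (any(!vapply(params, function(p) all(is.finite(p$W)) && all(is.finite(p$b)), TRUE))) {
          epoch_bad <- TRUE; break
        }
      }
      if (epoch_bad) {
        params <- snapshot  # keep last finite state
        diverged <- TRUE
        break
      }
    }
  })
  model$params <- params
  model$center <- center
  model$scale <- scale
  model$trained <- TRUE
  model$diverged <- diverged
  model
}

#' Predict class scores from a trained DFNN
#'
#' @param object A trained `dfnn`.
#' @param newdata Predictor matrix.
#' @param type `"positive"` for the positive-class score (default),
#'   `"prob"` for the full two-column normalized score matrix.
#' @param ... Unused.
#' @return Numeric vector or two-column matrix.
#' @export
predict.dfnn <- function(object, newdata, type = c("positive", "prob"), ...) {
  type <- match.arg(type)
  if (!object$trained) abort("model has not been trained", "configuration_error")
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  fp <- forward_pass(object$params, Xs, object$setting$activation)
  P <- fp$A[[length(object$params)]]
  if (type == "prob") P else P[, 2]
}

#' @export
print.dfnn <- function(x, ...) {
  cat(sprintf("DFNN %s | %s/%s/%s | %d parameters%s%s\n",
              paste(x$dims, collapse = "-"), x$setting$activation,
              x$setting$kernel_init, x$setting$optimizer, n_params(x),
              if (x$trained) ", trained" else "",
              if (x$diverged) " (diverged)" else ""))
  invisible(x)
}
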