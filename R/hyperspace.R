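#' Declare one tunable hyperparameter
#'
#' A spec names a dimension of the search space, its kind and its legal
#' domain. Categorical dimensions carry an explicit, ordered, duplicate-free
#' value list; integer and continuous dimensions carry an inclusive range.
#' The two dimensions that determine the network structure (depth and hidden
#' width) are tagged `"structural"`; everything else is `"non_structural"`.
#'
#' @param name Identifier, unique within a space.
#' @param kind One of `"categorical"`, `"integer"`, `"continuous"`.
#' @param domain For categorical, the ordered value list; otherwise
#'   `c(lower, upper)` with `lower <= upper`.
#' @param role `"structural"` or `"non_structural"`.
#' @return An object of class `hp_spec`.
#' @export
hp_spec <- function(name, kind = c("categorical", "integer", "continuous"),
                    domain, role = c("non_structural", "structural")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort("'name' must be a single non-empty string", "domain_error")
  if (kind == "categorical") {
    if (length(domain) == 0L) abort("categorical domain must be non-empty", "domain_error")
    if (anyDuplicated(domain)) abort("categorical domain must be duplicate-free", "domain_error")
  } else {
    if (length(domain) != 2L || !is.numeric(domain) || any(!is.finite(domain) & domain != Inf))
      abort("numeric domain must be c(lower, upper)", "domain_error")
    if (domain[1] > domain[2]) abort("numeric domain must satisfy lower <= upper", "domain_error")
  }
  structure(list(name = name, kind = kind, domain = domain, role = role),
            class = "hp_spec")
}

#' Assemble a hyperparameter space
#'
#' @param specs List of [hp_spec()] objects with unique names; exactly two
#'   must be tagged structural (the layer count and the hidden-node count).
#' @return An object of class `hp_space`.
#' @export
hp_space <- function(specs) {
  stopifnot(all(vapply(specs, inherits, logical(1), "hp_spec")))
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("hyperparameter names must be unique", "domain_error")
  roles <- vapply(specs, `[[`, character(1), "role")
  if (sum(roles == "structural") != 2L)
    abort("a space must carry exactly two structural hyperparameters", "domain_error")
  names(specs) <- nms
  structure(list(specs = specs), class = "hp_space")
}

#' The 13-hyperparameter DFNN search space
#'
#' The default space tuned by the three-stage mechanism: network depth
#' (1-4 hidden layers), hidden-layer width (1-1005 nodes), activation
#' function, kernel initializer, optimizer, learning rate (0.001-0.3),
#' momentum (0-0.9), iteration-based learning-rate decay (0-0.1), dropout
#' rate (0-0.5), epochs (5-2000), batch size (1 to the number of cases),
#' L1 penalty (0-0.03) and L2 penalty (0-0.2).
#'
#' @param n_cases Upper bound for `batch_size` (the dataset size);
#'   defaults to unbounded.
#' @return An `hp_space` of length 13.
#' @export
default_space <- function(n_cases = Inf) {
  hp_space(list(
    hp_spec("n_layers", "integer", c(1, 4), role = "structural"),
    hp_spec("n_nodes", "integer", c(1, 1005), role = "structural"),
    hp_spec("activation", "categorical", c("relu", "sigmoid", "softmax", "tanh")),
    hp_spec("kernel_init", "categorical",
            c("constant", "glorot_normal", "glorot_uniform", "he_normal", "he_uniform")),
    hp_spec("optimizer", "categorical", c("sgd", "adam", "adagrad", "nadam", "adamax")),
    hp_spec("learning_rate", "continuous", c(0.001, 0.3)),
    hp_spec("momentum", "continuous", c(0, 0.9)),
    hp_spec("decay", "continuous", c(0, 0.1)),
    hp_spec("dropout", "continuous", c(0, 0.5)),
    hp_spec("epochs", "integer", c(5, 2000)),
    hp_spec("batch_size", "integer", c(1, n_cases)),
    hp_spec("l1", "continuous", c(0, 0.03)),
    hp_spec("l2", "continuous", c(0, 0.2))
  ))
}

value_in_domain <- function(spec, value) {
  if (spec$kind == "categorical") return(all(value %in% spec$domain))
  if (!is.numeric(value) || any(!is.finite(value))) return(FALSE)
  ok <- all(value >= spec$domain[1] & value <= spec$domain[2])
  if (spec$kind == "integer") ok <- ok && all(value == floor(value))
  ok
}

#' Build and validate one hyperparameter setting
#'
#' A setting is one unique value assignment to every hyperparameter of a
#' space -- the unit of grid-search work. The hidden-width entry may be a
#' vector (one width per hidden layer) or a scalar applied to every layer.
#'
#' @param space An [hp_space()].
#' @param values Named list, one entry per space dimension.
#' @return The validated named list, classed `hp_setting`.
#' @export
new_setting <- function(space, values) {
  stopifnot(inherits(space, "hp_space"))
  nms <- names(space$specs)
  if (!setequal(names(values), nms) || anyDuplicated(names(values)))
    abort("setting must assign every hyperparameter exactly once", "domain_error")
  values <- values[nms]
  for (nm in nms) {
    if (!value_in_domain(space$specs[[nm]], values[[nm]]))
      abort(sprintf("value for '%s' lies outside its domain", nm), "domain_error")
  }
  structure(values, class = "hp_setting")
}

#' Define a pool of hyperparameter settings (PHS)
#'
#' A pool restricts every dimension of a space to a finite, duplicate-free
#' candidate list; the pool is the Cartesian product of those lists. Two
#' structural conventions are supported: `"per_layer"` counts each hidden
#' layer's width independently (a depth-L structure contributes
#' `n_node_candidates^L` structures), while `"uniform"` applies one width to
#' every hidden layer.
#'
#' @param space An [hp_space()].
#' @param candidates Named list of candidate value vectors, one per dimension.
#' @param structural `"per_layer"` or `"uniform"`.
#' @return An object of class `setting_pool`.
#' @export
setting_pool <- function(space, candidates, structural = c("per_layer", "uniform")) {
  structural <- match.arg(structural)
  stopifnot(inherits(space, "hp_space"))
  nms <- names(space$specs)
  if (!setequal(names(candidates), nms))
    abort("candidates must cover every hyperparameter exactly once", "domain_error")
  candidates <- candidates[nms]
  for (nm in nms) {
    cand <- candidates[[nm]]
    if (length(cand) == 0L) abort(sprintf("empty candidate list for '%s'", nm), "domain_error")
    if (anyDuplicated(cand)) abort(sprintf("duplicate candidates for '%s'", nm), "domain_error")
    if (!value_in_domain(space$specs[[nm]], cand))
      abort(sprintf("candidate for '%s' lies outside its domain", nm), "domain_error")
  }
  structure(list(space = space, candidates = candidates, structural = structural),
            class = "setting_pool")
}

structural_names <- function(space) {
  roles <- vapply(space$specs, `[[`, character(1), "role")
  names(space$specs)[roles == "structural"]
}

#' Count distinct network structures
#'
#' Each depth `L` in `layer_options` contributes `n_node_options^L`
#' structures (each hidden layer chooses its width independently), so the
#' total is the sum of those powers. With depths 1-4 and 22 width options
#' this yields 245,410 distinct model structures.
#'
#' @param layer_options Vector of hidden-layer counts (all >= 1).
#' @param n_node_options Number of candidate widths per layer (>= 1).
#' @return Exact count; a double when below 2^53, otherwise the exact
#'   decimal string.
#' @export
structural_count <- function(layer_options, n_node_options) {
  if (length(layer_options) == 0L || any(layer_options < 1) ||
      any(layer_options != floor(layer_options)))
    abort("layer_options must be positive integers", "domain_error")
  if (length(n_node_options) != 1L || n_node_options < 1 ||
      n_node_options != floor(n_node_options))
    abort("n_node_options must be a positive integer", "domain_error")
  n <- big_from_num(n_node_options)
  total <- big_from_num(0)
  for (L in layer_options) total <- big_add(total, big_pow(n, L))
  big_collapse(total)
}

#' Exact size of a setting pool
#'
#' For a `"per_layer"` pool the structural dimensions contribute
#' [structural_count()] of the layer candidates and the width candidate
#' count; a `"uniform"` pool contributes `length(layers) * length(widths)`.
#' Non-structural dimensions multiply in their candidate-list lengths.
#' Arithmetic is exact (no 64-bit overflow).
#'
#' @param pool A [setting_pool()].
#' @return A double when below 2^53, otherwise the exact decimal string.
#' @export
pool_cardinality <- function(pool) {
  stopifnot(inherits(pool, "setting_pool"))
  sn <- structural_names(pool$space)
  layers_nm <- sn[1]; nodes_nm <- sn[2]
  if (pool$structural == "per_layer") {
    struct <- structural_count(pool$candidates[[layers_nm]],
                               length(pool$candidates[[nodes_nm]]))
    total <- if (is.character(struct)) {
      # rebuild exactly from components
      n <- big_from_num(length(pool$candidates[[nodes_nm]]))
      acc <- big_from_num(0)
      for (L in pool$candidates[[layers_nm]]) acc <- big_add(acc, big_pow(n, L))
      acc
    } else big_from_num(struct)
  } else {
    total <- big_mul(big_from_num(length(pool$candidates[[layers_nm]])),
                     big_from_num(length(pool$candidates[[nodes_nm]])))
  }
  for (nm in setdiff(names(pool$candidates), sn))
    total <- big_mul(total, big_from_num(length(pool$candidates[[nm]])))
  big_collapse(total)
}

# odometer enumeration of a Cartesian product of value lists,
# first dimension varying fastest; calls fn(values) for each tuple,
# stops when fn returns FALSE
product_walk <- function(lists, fn) {
  k <- length(lists)
  lens <- lengths(lists)
  idx <- rep(1L, k)
  repeat {
    vals <- vector("list", k)
    for (i in seq_len(k)) vals[[i]] <- lists[[i]][[idx[i]]]
    names(vals) <- names(lists)
    if (!isTRUE(fn(vals))) return(invisible(NULL))
    i <- 1L
    while (i <= k) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= lens[i]) break
      idx[i] <- 1L
      i <- i + 1L
    }
    if (i > k) return(invisible(NULL))
  }
}

#' Enumerate a setting pool in deterministic order
#'
#' Walks the candidate grid in odometer order over candidate indices (first
#' listed dimension varying fastest; for `"per_layer"` pools the per-layer
#' width slots enumerate within each depth block). The order is a fixed,
#' reproducible function of the pool alone.
#'
#' @param pool A [setting_pool()].
#' @param limit Optional maximum number of settings to return.
#' @return List of `hp_setting` objects, no duplicates.
#' @export
enumerate_pool <- function(pool, limit = NULL) {
  stopifnot(inherits(pool, "setting_pool"))
  if (!is.null(limit)) {
    if (limit < 0) abort("limit must be non-negative", "domain_error")
    if (limit == 0) return(list())
  }
  sn <- structural_names(pool$space)
  layers_nm <- sn[1]; nodes_nm <- sn[2]
  out <- vector("list", 0L)
  n_out <- 0L
  take <- function(values) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- structure(values[names(pool$space$specs)], class = "hp_setting")
    is.null(limit) || n_out < limit
  }
  if (pool$structural == "uniform") {
    product_walk(pool$candidates, take)
  } else {
    nonstruct <- pool$candidates[setdiff(names(pool$candidates), sn)]
    for (L in pool$candidates[[layers_nm]]) {
      done <- FALSE
      node_lists <- rep(list(pool$candidates[[nodes_nm]]), L)
      names(node_lists) <- paste0(".w", seq_len(L))
      product_walk(c(node_lists, nonstruct), function(vals) {
        widths <- unlist(vals[seq_len(L)], use.names = FALSE)
        values <- c(stats::setNames(list(L, widths), c(layers_nm, nodes_nm)),
                    vals[-seq_len(L)])
        keep_going <- take(values)
        if (!keep_going) done <<- TRUE
        keep_going
      })
      if (done) break
    }
  }
  out
}

#' Budget arithmetic: total running time for a grid search
#'
#' Converts a mean running time per hyperparameter setting (RTPS, seconds)
#' and a total number of settings (TNS) into the total running time (TRT)
#' in hours, and into years for extrapolations (365-day years,
#' 31,536,000 s).
#'
#' @param rtps_seconds Mean seconds per setting (> 0).
#' @param tns Number of settings (>= 0).
#' @return A `budget_estimate`: list with `rtps_seconds`, `tns`,
#'   `trt_hours`, `trt_years`.
#' @export
estimate_runtime <- function(rtps_seconds, tns) {
  if (!is.numeric(rtps_seconds) || rtps_seconds <= 0)
    abort("rtps_seconds must be positive", "domain_error")
  if (!is.numeric(tns) || tns < 0)
    abort("tns must be non-negative", "domain_error")
  total_s <- rtps_seconds * tns
  structure(list(rtps_seconds = rtps_seconds, tns = tns,
                 trt_hours = total_s / 3600,
                 trt_years = total_s / 31536000),
            class = "budget_estimate")
}

#' Settings affordable within a time budget
#'
#' The inverse of [estimate_runtime()] up to flooring: how many settings a
#' grid search can take in when the total running time is capped.
#'
#' @param rtps_seconds Mean seconds per setting (> 0).
#' @param budget_hours Allowed total running time in hours (> 0).
#' @return Integer number of settings (floor).
#' @export
settings_for_budget <- function(rtps_seconds, budget_hours) {
  if (!is.numeric(rtps_seconds) || rtps_seconds <= 0)
    abort("rtps_seconds must be positive", "domain_error")
  if (!is.numeric(budget_hours) || budget_hours <= 0)
    abort("budget_hours must be positive", "domain_error")
  # epsilon keeps the estimate_runtime round-trip exact under floating point
  floor(budget_hours * 3600 / rtps_seconds + 1e-9)
}

#' @export
print.budget_estimate <- function(x, ...) {
  cat(sprintf("RTPS %.2f s  x  TNS %s  =  TRT %.2f h (%.4g years)\n",
              x$rtps_seconds, format(x$tns, big.mark = ","),
              x$trt_hours, x$trt_years))
  invisible(x)
}

#' @export
print.hp_space <- function(x, ...) {
  cat(sprintf("Hyperparameter space (%d dimensions)\n", length(x$specs)))
  for (s in x$specs) {
    dom <- if (s$kind == "categorical") paste(s$domain, collapse = ", ")
           else sprintf("[%g, %g]", s$domain[1], s$domain[2])
    cat(sprintf("  %-14s %-11s %s%s\n", s$name, s$kind, dom,
                if (s$role == "structural") "  (structural)" else ""))
  }
  invisible(x)
}

spec_to_list <- function(s) {
  list(name = s$name, kind = s$kind, role = s$role,
       domain = if (s$kind == "categorical") as.list(s$domain)
                else list(lower = s$domain[1], upper = s$domain[2]))
}

#' Read/write spaces and pools as YAML
#'
#' Space configs hold one entry per hyperparameter with `kind`, `domain`
#' and `role`; pool configs additionally hold per-dimension `candidates`
#' and the structural convention.
#'
#' @param space,pool Objects to serialize.
#' @param path File path.
#' @return The deserialized object (readers) or `path` invisibly (writers).
#' @export
write_space_yaml <- function(space, path) {
  stopifnot(inherits(space, "hp_space"))
  yaml::write_yaml(list(hyperparameters = lapply(unname(space$specs), spec_to_list)), path)
  invisible(path)
}

#' @rdname write_space_yaml
#' @export
read_space_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$hyperparameters, function(e) {
    dom <- if (e$kind == "categorical") unlist(e$domain)
           else c(e$domain$lower, e$domain$upper)
    hp_spec(e$name, e$kind, dom, e$role %||% "non_structural")
  })
  hp_space(specs)
}

#' @rdname write_space_yaml
#' @export
write_pool_yaml <- function(pool, path) {
  stopifnot(inherits(pool, "setting_pool"))
  yaml::write_yaml(list(
    hyperparameters = lapply(unname(pool$space$specs), spec_to_list),
    candidates = lapply(pool$candidates, as.list),
    structural = pool$structural
  ), path)
  invisible(path)
}

#' @rdname write_space_yaml
#' @export
read_pool_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$hyperparameters, function(e) {
    dom <- if (e$kind == "categorical") unlist(e$domain)
           else c(e$domain$lower, e$domain$upper)
    hp_spec(e$name, e$kind, dom, e$role %||% "non_structural")
  })
  setting_pool(hp_space(specs), lapply(raw$candidates, unlist),
               structural = raw$structural %||% "per_layer")
}
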