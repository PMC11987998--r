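#' @keywords internal
"_PACKAGE"

# Derive a child RNG seed from a master seed and a text salt.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, salt) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((abs(master) %% 2147483647 * 48271 + h * 7919) %% 2147483647)
}

# stop() with a condition class so callers/tests can catch specific failures
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "threestage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report tables use the conventional half-up rounding of most tabulation
#' tools (base R's `round()` rounds half to even, which shifts printed
#' 5-decimal AUC values ending in 5).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # snap away binary representation error (0.629125 is stored just below
  # its decimal value) before applying the half-up rule
  scaled <- round(abs(x) * p, 8)
  sign(x) * floor(scaled + 0.5) / p
}
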