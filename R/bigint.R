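# Minimal exact non-negative integer arithmetic for pool cardinalities.
#
# Cardinalities are contractually exact; products of candidate-list lengths
# can exceed the 2^53 integer range of a double in extreme configurations.
# Internally a number is a little-endian vector of base-1e7 "digits".

BIG_BASE <- 1e7

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x <= 2^53)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
  }
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- floor(s[i] / BIG_BASE)
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0) s <- c(s, big_from_num(carry))
  s
}

big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    carry <- 0
    for (j in seq_along(b)) {
      # a[i], b[j] < 1e7 so the product stays well inside 2^53
      v <- out[i + j - 1] + a[i] * b[j] + carry
      carry <- floor(v / BIG_BASE)
      out[i + j - 1] <- v %% BIG_BASE
    }
    k <- i + length(b)
    while (carry > 0) {
      v <- out[k] + carry
      carry <- floor(v / BIG_BASE)
      out[k] <- v %% BIG_BASE
      k <- k + 1
    }
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_pow <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  out <- big_from_num(1)
  for (i in seq_len(k)) out <- big_mul(out, a)
  out
}

# Collapse to a plain double when exactly representable (< 2^53),
# otherwise to the exact decimal string.
big_collapse <- function(a) {
  v <- sum(a * BIG_BASE^(seq_along(a) - 1))
  if (v <= 2^53) return(v)
  digits <- rev(sprintf("%07.0f", a))
  digits[1] <- sub("^0+", "", digits[1])
  paste(digits, collapse = "")
}
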