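## Minimal non-negative arbitrary-precision integers for the bound recursion.
## A bignum is an integer vector of base-1e6 digits, little-endian, no
## trailing zero digits (zero is the vector 0L). The base keeps every carry
## and convolution partial sum well inside the exact range of doubles.

.BIG_BASE <- 1e6

bigFromNumeric <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) {
    d <- c(d, as.integer(x %% .BIG_BASE))
    x <- floor(x / .BIG_BASE)
  }
  d
}

bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  s <- as.numeric(a) + as.numeric(b)
  carry <- 0
  out <- integer(n)
  for (i in seq_len(n)) {
    v <- s[i] + carry
    out[i] <- as.integer(v %% .BIG_BASE)
    carry <- floor(v / .BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% .BIG_BASE))
    carry <- floor(carry / .BIG_BASE)
  }
  bigTrim(out)
}

## b may be a plain numeric scalar (exact integer < 2^53) or a bignum vector.
bigMul <- function(a, b) {
  if (length(b) == 1L && b[1] < .BIG_BASE) {            # scalar fast path
    if (b[1] == 0) return(0L)
    prod <- as.numeric(a) * as.numeric(b[1])
    carry <- 0
    out <- integer(length(a))
    for (i in seq_along(a)) {
      v <- prod[i] + carry
      out[i] <- as.integer(v %% .BIG_BASE)
      carry <- floor(v / .BIG_BASE)
    }
    while (carry > 0) {
      out <- c(out, as.integer(carry %% .BIG_BASE))
      carry <- floor(carry / .BIG_BASE)
    }
    return(bigTrim(out))
  }
  if (bigIsZero(a) || bigIsZero(b)) return(0L)
  na <- length(a); nb <- length(b)
  acc <- numeric(na + nb)
  for (j in seq_len(nb)) {                               # schoolbook; tables are tiny
    if (b[j] == 0) next
    idx <- j:(j + na - 1L)
    acc[idx] <- acc[idx] + as.numeric(a) * as.numeric(b[j])
    k <- j
    while (acc[k] >= 2^52) {                             # defensive renormalization
      q <- floor(acc[k] / .BIG_BASE)
      acc[k] <- acc[k] %% .BIG_BASE
      acc[k + 1L] <- acc[k + 1L] + q
      k <- k + 1L
    }
  }
  carry <- 0
  out <- integer(length(acc))
  for (i in seq_along(acc)) {
    v <- acc[i] + carry
    out[i] <- as.integer(v %% .BIG_BASE)
    carry <- floor(v / .BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% .BIG_BASE))
    carry <- floor(carry / .BIG_BASE)
  }
  bigTrim(out)
}

bigTrim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0L) n <- n - 1L
  a[seq_len(n)]
}

bigIsZero <- function(a) length(a) == 1L && a[1] == 0L

bigToString <- function(a) {
  a <- bigTrim(a)
  n <- length(a)
  if (n == 1L) return(as.character(a[1]))
  head <- as.character(a[n])
  rest <- vapply(rev(a[seq_len(n - 1L)]), function(d) sprintf("%06d", d), "")
  paste0(head, paste(rest, collapse = ""))
}

## Exact when the value fits in a double; otherwise the closest double.
bigToNumeric <- function(a) sum(as.numeric(a) * .BIG_BASE^(seq_along(a) - 1))

## -1, 0, 1 for a < b, a == b, a > b
bigCompare <- function(a, b) {
  a <- bigTrim(a); b <- bigTrim(b)
  if (length(a) != length(b))
    return(as.integer(sign(length(a) - length(b))))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(as.integer(sign(a[i] - b[i])))
  }
  0L
}
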