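# Internal numeric helpers.  All modular arithmetic is done in doubles; the
# plaintext modulus is capped at 2^26 (see cryptoParams validity) so products
# of two residues stay below 2^53 and remain exact.

.isPrime <- function(n) {
  if (n < 2) return(FALSE)
  if (n %% 2 == 0) return(n == 2)
  k <- 3
  while (k * k <= n) {
    if (n %% k == 0) return(FALSE)
    k <- k + 2
  }
  TRUE
}

.isPow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# extended Euclid; a need not be reduced
.modInv <- function(a, t) {
  a <- a %% t
  if (a == 0) stop("0 has no modular inverse")
  r0 <- t; r1 <- a; s0 <- 0; s1 <- 1
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    tmp <- s0 - q * s1; s0 <- s1; s1 <- tmp
  }
  if (r0 != 1) stop("element not invertible modulo t")
  s0 %% t
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
.useSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Order-sensitive rolling hash of a numeric vector, returned as a decimal
# string.  Used to bind partial decryptions to one ciphertext.
.hashVec <- function(x) {
  p <- 2147483629
  h <- 0
  for (v in x) h <- (h * 131 + (v %% p) + 1) %% p
  sprintf("%.0f", h)
}

.hashString <- function(s) .hashVec(as.numeric(utf8ToInt(s)))

# Deterministic pseudorandom vector over [1, t-1], keyed by arbitrary strings.
.prfVec <- function(keys, len, t) {
  seed <- 0
  for (k in keys) seed <- (seed * 131 + as.numeric(.hashString(k))) %% 2147483399
  .useSeed(seed + 1, sample(t - 1, len, replace = TRUE))
}

# fresh hex token from the current RNG stream
.hexToken <- function() {
  paste(sprintf("%04x", sample(65535L, 4, replace = TRUE)), collapse = "")
}
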