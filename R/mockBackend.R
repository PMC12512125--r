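#' Construct encryption parameters
#'
#' @param t prime plaintext modulus.  All encrypted arithmetic is modulo
#'   \code{t}; it must exceed the total variant count (so match counts never
#'   wrap) and twice the sample count (so ADD-IN residuals never wrap).  The
#'   default is the smallest prime above 2^24, large enough for counts over
#'   several million variants while keeping mock arithmetic exact.
#' @param depthBudget maximum multiplicative depth a ciphertext may
#'   accumulate.  The ADD-IN circuits need 2; the MUL-IN circuits with
#'   balanced cumulative multiplication stay within 12 up to 256 samples.
#' @param slotCount SIMD slots per ciphertext (power of two).
#' @param securityBits nominal security level (informational for the mock).
#' @return a [CryptoParams-class] object.
#' @examples
#' cryptoParams(t = 97, depthBudget = 2L, slotCount = 8L)
#' @export
cryptoParams <- function(t = 16777259, depthBudget = 12L,
                         slotCount = 1024L, securityBits = 128L) {
  new("CryptoParams", t = as.numeric(t), depthBudget = as.integer(depthBudget),
      slotCount = as.integer(slotCount), securityBits = as.integer(securityBits))
}

#' Create a mock homomorphic backend session
#'
#' The mock backend evaluates circuits with exact integer-vector arithmetic
#' modulo \code{t} while doing everything a real leveled scheme would track:
#' key binding, multiplicative-depth accounting against the depth budget
#' (exceeding it raises the same noise-exhaustion error a real backend
#' would), and operation tallies at vector granularity.  A real BFV adapter
#' can implement the same generics against this contract.
#'
#' @param params a [CryptoParams-class].
#' @param seed integer seed for all backend randomness (key ids, key
#'   material).
#' @return a [MockBackend-class].
#' @examples
#' bk <- mockBackend(cryptoParams(t = 97, slotCount = 8L), seed = 1)
#' keys <- keygen(bk)
#' ct <- heEncrypt(bk, c(1, 2, 3), keys$pk)
#' heDecrypt(bk, ct, keys$sk)[1:3]
#' @export
mockBackend <- function(params = cryptoParams(), seed = 1) {
  state <- new.env(parent = emptyenv())
  state$ctMul <- 0; state$ctAdd <- 0; state$slotAdd <- 0
  state$plainMul <- 0; state$plainAdd <- 0; state$maxDepth <- 0
  state$rand <- .useSeed(seed, get(".Random.seed", envir = globalenv()))
  state$keys <- list()
  new("MockBackend", params = params, state = state)
}

# evaluate `code` on the backend's private RNG stream
.bkRng <- function(backend, code) {
  st <- backend@state
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", st$rand, envir = globalenv())
  on.exit({
    st$rand <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  code
}

.checkCt <- function(backend, a) {
  if (!is(a, "CipherVector")) stop("operand is not a CipherVector")
  if (a@backendId != "mock") stop("ciphertext belongs to backend '",
                                  a@backendId, "', not 'mock'")
  if (a@slotCount != backend@params@slotCount)
    stop("ciphertext slot count does not match backend parameters")
  invisible(TRUE)
}

.checkPair <- function(backend, a, b) {
  .checkCt(backend, a); .checkCt(backend, b)
  if (a@backendId != b@backendId || a@slotCount != b@slotCount ||
      a@keyId != b@keyId)
    stop("incompatible ciphertexts: backend, slot count and key must match")
  invisible(TRUE)
}

.newCt <- function(template, payload, depth) {
  new("CipherVector", backendId = template@backendId, keyId = template@keyId,
      slotCount = template@slotCount, depth = as.integer(depth),
      payload = payload)
}

.bumpDepth <- function(backend, d) {
  if (d > backend@params@depthBudget)
    stop("noise budget exhausted: multiplicative depth ", d,
         " exceeds budget ", backend@params@depthBudget)
  st <- backend@state
  if (d > st$maxDepth) st$maxDepth <- d
  d
}

#' Single-party key generation (convenience path)
#'
#' Generates a public/secret key pair bound to the backend parameters.  The
#' committee path ([dkg()]) is the production route; this one exists for
#' circuit development and testing.
#'
#' @param backend a [MockBackend-class].
#' @param seed optional seed; by default key material is drawn from the
#'   backend's own stream.
#' @return list with elements \code{pk} ([PublicKey-class]) and \code{sk}
#'   ([SecretKey-class]).
#' @aliases keygen PublicKey-class SecretKey-class
#' @export
setMethod("keygen", "MockBackend", function(backend, seed = NULL) {
  draw <- function() list(id = .hexToken(),
                          mat = sample(backend@params@t - 1, 1))
  km <- if (is.null(seed)) .bkRng(backend, draw()) else .useSeed(seed, draw())
  backend@state$keys[[km$id]] <- list(type = "single", material = km$mat)
  list(pk = new("PublicKey", keyId = km$id, params = backend@params),
       sk = new("SecretKey", keyId = km$id, material = km$mat))
})

#' Encrypt / decrypt slot vectors
#'
#' \code{heEncrypt} packs a vector of integers (reduced modulo \code{t},
#' right-padded with zeros up to the slot count) into a fresh ciphertext of
#' depth 0.  \code{heDecrypt} inverts it exactly for any in-budget circuit;
#' the secret key must match the key the ciphertext was produced under.
#'
#' @param backend a [MockBackend-class].
#' @param v numeric vector, length at most the slot count.
#' @param ct a [CipherVector-class].
#' @param key a [PublicKey-class] (encrypt) or [SecretKey-class] (decrypt).
#' @return \code{heEncrypt}: a [CipherVector-class]; \code{heDecrypt}: the
#'   full numeric slot vector.
#' @aliases heEncrypt heDecrypt
#' @export
setMethod("heEncrypt", "MockBackend", function(backend, v, key) {
  stopifnot(is(key, "PublicKey"))
  L <- backend@params@slotCount
  if (length(v) > L)
    stop("packing error: vector of length ", length(v),
         " exceeds slot count ", L)
  payload <- c(as.numeric(v), numeric(L - length(v))) %% backend@params@t
  new("CipherVector", backendId = "mock", keyId = key@keyId,
      slotCount = L, depth = 0L, payload = payload)
})

#' @rdname heEncrypt
#' @export
setMethod("heDecrypt", "MockBackend", function(backend, ct, key) {
  .checkCt(backend, ct)
  stopifnot(is(key, "SecretKey"))
  if (ct@keyId != key@keyId)
    stop("secret key does not match the ciphertext's key")
  ct@payload
})

#' Slotwise homomorphic arithmetic
#'
#' Ciphertext-ciphertext addition, subtraction and multiplication with
#' modular slotwise semantics.  Multiplication sets the result depth to
#' \code{max(depths) + 1} and fails with a noise-exhaustion error beyond the
#' depth budget; addition and subtraction keep \code{max(depths)}.  Each call
#' increments the matching instrumentation tally.
#'
#' @param backend a [MockBackend-class].
#' @param a,b compatible [CipherVector-class] operands.
#' @return a [CipherVector-class].
#' @aliases heAdd heSub heMul
#' @export
setMethod("heAdd", "MockBackend", function(backend, a, b) {
  .checkPair(backend, a, b)
  backend@state$ctAdd <- backend@state$ctAdd + 1
  .newCt(a, (a@payload + b@payload) %% backend@params@t, max(a@depth, b@depth))
})

#' @rdname heAdd
#' @export
setMethod("heSub", "MockBackend", function(backend, a, b) {
  .checkPair(backend, a, b)
  backend@state$ctAdd <- backend@state$ctAdd + 1
  .newCt(a, (a@payload - b@payload) %% backend@params@t, max(a@depth, b@depth))
})

#' @rdname heAdd
#' @export
setMethod("heMul", "MockBackend", function(backend, a, b) {
  .checkPair(backend, a, b)
  d <- .bumpDepth(backend, max(a@depth, b@depth) + 1L)
  backend@state$ctMul <- backend@state$ctMul + 1
  .newCt(a, (a@payload * b@payload) %% backend@params@t, d)
})

#' Ciphertext-plaintext arithmetic
#'
#' Addition and multiplication with a plaintext slot vector (recycled if
#' scalar).  These are tallied separately (\code{plainAdditions},
#' \code{plainMultiplications}) and never count toward the
#' ciphertext-operation columns of the circuit complexity formulas; they are
#' used only for padding-mask corrections.  Plaintext multiplication still
#' consumes one depth level (conservative leveled-scheme accounting).
#'
#' @param backend a [MockBackend-class].
#' @param a a [CipherVector-class].
#' @param p numeric plaintext vector (length 1 or slotCount).
#' @return a [CipherVector-class].
#' @aliases heAddPlain heMulPlain
#' @export
setMethod("heAddPlain", "MockBackend", function(backend, a, p) {
  .checkCt(backend, a)
  p <- rep_len(as.numeric(p), a@slotCount)
  backend@state$plainAdd <- backend@state$plainAdd + 1
  .newCt(a, (a@payload + p) %% backend@params@t, a@depth)
})

#' @rdname heAddPlain
#' @export
setMethod("heMulPlain", "MockBackend", function(backend, a, p) {
  .checkCt(backend, a)
  p <- rep_len(as.numeric(p), a@slotCount)
  d <- .bumpDepth(backend, a@depth + 1L)
  backend@state$plainMul <- backend@state$plainMul + 1
  .newCt(a, (a@payload * p) %% backend@params@t, d)
})

#' Cumulative addition / multiplication over a ciphertext list
#'
#' Both perform k-1 pairwise operations over k operands.  \code{heMulMany}
#' uses a balanced binary tree, so the result depth is
#' \code{max(input depths) + ceiling(log2(k))}; this is what lets the
#' multiplication-intensive circuits at 256 samples fit a depth budget of 12.
#' A singleton list is returned unchanged with zero operations counted.
#'
#' @param backend a [MockBackend-class].
#' @param cs non-empty list of compatible [CipherVector-class] objects.
#' @return a [CipherVector-class].
#' @aliases heAddMany heMulMany
#' @export
setMethod("heAddMany", "MockBackend", function(backend, cs) {
  if (length(cs) < 1) stop("heAddMany needs a non-empty ciphertext list")
  Reduce(function(x, y) heAdd(backend, x, y), cs)
})

#' @rdname heAddMany
#' @export
setMethod("heMulMany", "MockBackend", function(backend, cs) {
  if (length(cs) < 1) stop("heMulMany needs a non-empty ciphertext list")
  while (length(cs) > 1) {
    nxt <- vector("list", ceiling(length(cs) / 2))
    j <- 1; i <- 1
    while (i + 1 <= length(cs)) {
      nxt[[j]] <- heMul(backend, cs[[i]], cs[[i + 1]])
      i <- i + 2; j <- j + 1
    }
    if (i == length(cs)) nxt[[j]] <- cs[[i]]
    cs <- nxt
  }
  cs[[1]]
})

#' Total-sum over slots
#'
#' Replaces every slot with the sum of all slot values (the rotate-and-add
#' total sum of SIMD schemes).  Instrumentation attributes
#' \code{nValid - 1} scalar slot additions to the call -- the per-variant
#' accounting used by the circuit complexity formulas -- independent of the
#' rotation strategy a real backend would use.  Depth is unchanged.
#'
#' @param backend a [MockBackend-class].
#' @param ct a [CipherVector-class].
#' @param nValid number of real (non-padding) slots being totalled.
#' @return a [CipherVector-class] with all slots equal.
#' @aliases heSumSlots
#' @export
setMethod("heSumSlots", "MockBackend", function(backend, ct, nValid) {
  .checkCt(backend, ct)
  backend@state$slotAdd <- backend@state$slotAdd + max(nValid - 1, 0)
  .newCt(ct, rep(sum(ct@payload) %% backend@params@t, ct@slotCount), ct@depth)
})

# cyclic slot rotation; a permutation primitive, not an arithmetic op,
# so it is not tallied in the add/mul columns
.rotateSlots <- function(ct, k) {
  L <- ct@slotCount
  k <- ((k %% L) + L) %% L
  if (k == 0) return(ct)
  idx <- c((k + 1):L, 1:k)
  ct@payload <- ct@payload[idx]
  ct
}

.countSnapshot <- function(backend) {
  st <- backend@state
  c(ctMul = st$ctMul, ctAdd = st$ctAdd, slotAdd = st$slotAdd,
    plainMul = st$plainMul, plainAdd = st$plainAdd)
}

.opCountsFromVec <- function(v, maxDepth = 0) {
  new("OpCounts", ctMultiplications = unname(v["ctMul"]),
      ctAdditions = unname(v["ctAdd"]), slotAdditions = unname(v["slotAdd"]),
      plainMultiplications = unname(v["plainMul"]),
      plainAdditions = unname(v["plainAdd"]), maxDepth = maxDepth)
}

#' Read or reset the backend instrumentation
#'
#' @param backend a [MockBackend-class].
#' @return \code{opCounts}: an [OpCounts-class] snapshot of the session
#'   tallies; \code{resetOpCounts} zeroes them (and the depth high-water
#'   mark) and returns the backend invisibly.
#' @aliases opCounts resetOpCounts
#' @export
setMethod("opCounts", "MockBackend", function(backend) {
  .opCountsFromVec(.countSnapshot(backend), backend@state$maxDepth)
})

#' @rdname opCounts
#' @export
setMethod("resetOpCounts", "MockBackend", function(backend) {
  st <- backend@state
  st$ctMul <- 0; st$ctAdd <- 0; st$slotAdd <- 0
  st$plainMul <- 0; st$plainAdd <- 0; st$maxDepth <- 0
  invisible(backend)
})

#' @describeIn CipherVector-class accumulated multiplicative depth
#' @param x a [CipherVector-class]
#' @export
setMethod("depthConsumed", "CipherVector", function(x) x@depth)

setMethod("show", "MockBackend", function(object) {
  cat("MockBackend: t =", object@params@t,
      "| depth budget =", object@params@depthBudget,
      "| slots =", object@params@slotCount, "\n")
  show(opCounts(object))
})

setMethod("show", "OpCounts", function(object) {
  cat("OpCounts: ct mul =", object@ctMultiplications,
      "| ct add =", object@ctAdditions,
      "| slot add =", object@slotAdditions,
      "| plain mul/add =", object@plainMultiplications, "/",
      object@plainAdditions,
      "| max depth =", object@maxDepth, "\n")
})

setMethod("show", "CipherVector", function(object) {
  cat("CipherVector<", object@backendId, ">: ", object@slotCount,
      " slots, depth ", object@depth, ", key ", object@keyId, "\n", sep = "")
})
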