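#' Configure a key-management committee
#'
#' @param nMembers committee size (>= 2).
#' @param quorum members required for decryption.
#' @param mode sharing mode: \code{"additive"} (n-of-n), \code{"shamir"}
#'   (t-of-n polynomial sharing over the plaintext ring) or \code{"auto"}
#'   (additive when quorum equals the committee size, Shamir otherwise).
#' @return a [CommitteeConfig-class].
#' @export
committeeConfig <- function(nMembers, quorum = nMembers,
                            mode = c("auto", "additive", "shamir")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (quorum == nMembers) "additive" else "shamir"
  new("CommitteeConfig", nMembers = as.integer(nMembers),
      quorum = as.integer(quorum), mode = mode)
}

#' Distributed key generation
#'
#' Produces one collective public key and per-member secret shares; the
#' full secret is never materialized.  In the mock backend the shares are
#' an additive sharing (all members sum to the committee secret) or a
#' Shamir polynomial sharing (any quorum of evaluations interpolates it)
#' over the plaintext ring.  Encryption under the collective key works for
#' every data owner; decryption requires at least a quorum of partial
#' decryptions.  Deterministic for a fixed seed.
#'
#' @param backend a [MockBackend-class].
#' @param committee a [CommitteeConfig-class].
#' @param seed integer seed.
#' @return list with \code{pk} ([PublicKey-class]), \code{shares} (list of
#'   [KeyShare-class]) and \code{committee}.
#' @aliases dkg
#' @export
setMethod("dkg", "MockBackend", function(backend, committee, seed) {
  stopifnot(is(committee, "CommitteeConfig"))
  t <- backend@params@t
  n <- committee@nMembers
  q <- committee@quorum
  km <- .useSeed(seed, {
    id <- .hexToken()
    vals <- if (committee@mode == "additive") {
      v <- sample(t, n, replace = TRUE) - 1
      v[n] <- (-sum(v[-n])) %% t          # shares of the zero element
      v
    } else {
      # random polynomial with f(0) = 0, degree quorum - 1
      coef <- c(0, sample(t, q - 1, replace = TRUE) - 1)
      vapply(seq_len(n), function(x) {
        acc <- 0; xp <- 1
        for (cf in coef) { acc <- (acc + cf * xp) %% t; xp <- (xp * x) %% t }
        acc
      }, numeric(1))
    }
    list(id = id, vals = vals)
  })
  backend@state$keys[[km$id]] <- list(type = "collective",
                                      committee = committee)
  shares <- lapply(seq_len(n), function(i)
    new("KeyShare", memberId = i, x = i, value = km$vals[i], keyId = km$id,
        mode = committee@mode, nMembers = n, quorum = q))
  list(pk = new("PublicKey", keyId = km$id, params = backend@params),
       shares = shares, committee = committee)
})

# public per-ciphertext mask vector shared by all members: derived from the
# ciphertext digest and key id, uniform over [1, t-1]
.partialMask <- function(ct, t) {
  d <- .hashVec(ct@payload)
  .prfVec(c(d, ct@keyId), ct@slotCount, t)
}

#' Generate a partial decryption
#'
#' One committee member's contribution: a deterministic function of the
#' ciphertext and the member's secret share, bound by digest to exactly that
#' ciphertext.  A single partial (or any set smaller than the quorum)
#' reveals nothing: the plaintext is blinded by the share times a
#' per-ciphertext pseudorandom mask over the ring.
#'
#' @param backend a [MockBackend-class].
#' @param ct a [CipherVector-class] under the committee's collective key.
#' @param share the member's [KeyShare-class].
#' @return a [PartialDecryption-class].
#' @aliases partialDecrypt
#' @export
setMethod("partialDecrypt", "MockBackend", function(backend, ct, share) {
  .checkCt(backend, ct)
  stopifnot(is(share, "KeyShare"))
  if (ct@keyId != share@keyId)
    stop("protocol error: key share does not match the ciphertext's key")
  t <- backend@params@t
  h <- .partialMask(ct, t)
  w <- if (share@mode == "additive") .modInv(share@nMembers, t) else 1
  payload <- (w * ct@payload + share@value * h) %% t
  new("PartialDecryption", memberId = share@memberId, x = share@x,
      digest = .hashVec(ct@payload), payload = payload, mode = share@mode,
      nMembers = share@nMembers, quorum = share@quorum, keyId = share@keyId)
})

#' Combine partial decryptions into the plaintext
#'
#' Additive mode sums the partials; Shamir mode interpolates at zero with
#' Lagrange weights.  Because the shares encode the zero element, the
#' blinding terms cancel exactly and the true plaintext slot vector remains.
#' Fewer than the quorum, duplicate members, or partials bound to different
#' ciphertexts raise protocol errors.
#'
#' @param partials list of [PartialDecryption-class] for one ciphertext.
#' @param quorum required quorum (defaults to the value embedded in the
#'   partials).
#' @param t plaintext modulus (defaults to none; must be supplied).
#' @return numeric plaintext slot vector.
#' @export
combinePartials <- function(partials, quorum = NULL, t) {
  if (length(partials) == 0) stop("no partial decryptions supplied")
  stopifnot(all(vapply(partials, is, logical(1), "PartialDecryption")))
  p1 <- partials[[1]]
  if (is.null(quorum)) quorum <- p1@quorum
  digs <- vapply(partials, function(p) p@digest, character(1))
  if (length(unique(digs)) != 1 ||
      length(unique(vapply(partials, function(p) p@keyId, character(1)))) != 1)
    stop("protocol error: partial decryptions are bound to different ciphertexts")
  ids <- vapply(partials, function(p) p@memberId, integer(1))
  if (anyDuplicated(ids))
    stop("protocol error: duplicate committee member in partials")
  if (length(partials) < quorum)
    stop("quorum not met: ", length(partials), " partial(s), quorum ", quorum)
  if (p1@mode == "additive") {
    if (length(partials) < p1@nMembers)
      stop("quorum not met: additive sharing requires all ", p1@nMembers,
           " members")
    acc <- Reduce(`+`, lapply(partials, function(p) p@payload))
    return(acc %% t)
  }
  xs <- vapply(partials, function(p) p@x, integer(1))
  lam <- vapply(seq_along(xs), function(i) {
    num <- 1; den <- 1
    for (j in seq_along(xs)) {
      if (j == i) next
      num <- (num * xs[j]) %% t
      den <- (den * ((xs[j] - xs[i]) %% t)) %% t
    }
    (num * .modInv(den, t)) %% t
  }, numeric(1))
  acc <- numeric(length(p1@payload))
  for (i in seq_along(partials))
    acc <- (acc + lam[i] * partials[[i]]@payload) %% t
  acc
}

#' Serialize / deserialize key shares
#'
#' JSON share files, one per committee member, so shares can be distributed
#' out of band.
#'
#' @param share a [KeyShare-class].
#' @param path file path.
#' @export
writeKeyShare <- function(share, path) {
  jsonlite::write_json(list(memberId = share@memberId, x = share@x,
                            value = share@value, keyId = share@keyId,
                            mode = share@mode, nMembers = share@nMembers,
                            quorum = share@quorum),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeKeyShare
#' @export
readKeyShare <- function(path) {
  o <- jsonlite::fromJSON(path)
  new("KeyShare", memberId = as.integer(o$memberId), x = as.integer(o$x),
      value = as.numeric(o$value), keyId = o$keyId, mode = o$mode,
      nMembers = as.integer(o$nMembers), quorum = as.integer(o$quorum))
}

setMethod("show", "CommitteeConfig", function(object) {
  cat("CommitteeConfig:", object@quorum, "of", object@nMembers,
      "members,", object@mode, "sharing\n")
})

setMethod("show", "KeyShare", function(object) {
  cat("KeyShare: member", object@memberId, "of", object@nMembers,
      "(", object@mode, "), key", object@keyId, "\n")
})
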