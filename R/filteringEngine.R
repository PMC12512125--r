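#' Encrypt slot-packed genotype blocks
#'
#' Encrypts every (sample, channel) slot vector of every block under the
#' collective public key.  Validity masks remain plaintext: they describe
#' block padding, not genotypes, and are needed by the evaluating side for
#' the padding correction.
#'
#' @param backend a [MockBackend-class].
#' @param vb a [VariantBlocks-class].
#' @param pk a [PublicKey-class].
#' @return an [EncryptedCohort-class].
#' @export
encryptCohort <- function(backend, vb, pk) {
  stopifnot(is(vb, "VariantBlocks"))
  if (vb@slotCount != backend@params@slotCount)
    stop("block slot count must match backend parameters")
  blocks <- lapply(vb@blocks, function(b) {
    list(first = lapply(seq_along(vb@sampleIds), function(j)
           heEncrypt(backend, b$first[, j], pk)),
         second = lapply(seq_along(vb@sampleIds), function(j)
           heEncrypt(backend, b$second[, j], pk)),
         validMask = b$validMask, blockIndex = b$blockIndex)
  })
  new("EncryptedCohort", blocks = blocks, slotCount = vb@slotCount,
      sampleIds = vb@sampleIds, nVariants = vb@nVariants, keyId = pk@keyId)
}

#' Slotwise equality indicator
#'
#' For bit-valued operands computes \code{1 + (v - q)(q - v)} slotwise:
#' 1 where the variant value equals the query value, 0 elsewhere.  Costs
#' exactly 1 ciphertext multiplication, 2 subtractions and 1 addition.
#'
#' @param backend a [MockBackend-class].
#' @param v,q bit-valued [CipherVector-class] operands (one channel).
#' @param one an encryption of 1 in every slot.
#' @return a [CipherVector-class] indicator.
#' @export
matchIndicator <- function(backend, v, q, one) {
  s1 <- heSub(backend, v, q)
  s2 <- heSub(backend, q, v)
  heAdd(backend, heMul(backend, s1, s2), one)
}

#' Create a masking specification
#'
#' @param seed integer seed for the privacy randomness of ADD-IN outputs.
#' @return a [MaskSpec-class].
#' @export
maskSpec <- function(seed) new("MaskSpec", seed = as.numeric(seed))

# draw all ADD-IN privacy randomness up front: per-block slotwise masks over
# [1, t-1], a block permutation and per-block cyclic rotations
.drawMaskPlan <- function(mask, nBlocks, slotCount, t) {
  .useSeed(mask@seed, list(
    masks = matrix(sample(t - 1, slotCount * max(nBlocks, 1), replace = TRUE),
                   nrow = slotCount),
    perm = sample(max(nBlocks, 1)),
    rots = sample(slotCount, max(nBlocks, 1), replace = TRUE) - 1L))
}

.outcome <- function(method, model, payload, nValid, blockCounts, total,
                     depth) {
  new("FilterOutcome", method = method, model = model, payload = payload,
      validSlotTotal = as.integer(nValid), blockOpCounts = blockCounts,
      totalOpCounts = total, depth = as.integer(depth))
}

.sampleIdx <- function(cohort, ids) {
  idx <- match(ids, cohort@sampleIds)
  if (anyNA(idx)) stop("sample(s) not present in cohort: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

.checkQueryCompat <- function(cohort, encQuery) {
  if (!identical(encQuery@sampleIds, cohort@sampleIds))
    stop("query sample order must match cohort sample order")
  if (encQuery@keyId != cohort@keyId)
    stop("query and cohort are encrypted under different keys")
}

# indicator ciphertexts for every sample of one channel of one block
.channelIndicators <- function(backend, blockChannel, queryChannel, one) {
  lapply(seq_along(blockChannel), function(i)
    matchIndicator(backend, blockChannel[[i]], queryChannel[[i]], one))
}

#' Multiplication-intensive filtering (recessive/dominant)
#'
#' The MUL-IN circuit: per sample and channel an equality indicator of
#' variant versus query code; cumulative (balanced-tree) multiplication of
#' the indicators across samples per channel; product of the two channel
#' results; plaintext validity-mask correction (zeroing padded slots);
#' summation across blocks and over slots.  The single output ciphertext
#' decrypts to the number of variants matching the query pattern, replicated
#' in every slot.  Per block this costs 4s-1 ciphertext multiplications and
#' 6s additions, plus v-1 slot additions for the final total over v
#' variants.
#'
#' @param backend a [MockBackend-class].
#' @param cohort an [EncryptedCohort-class].
#' @param encQuery an [EncryptedQuery-class] over the same samples and key.
#' @param pk the collective [PublicKey-class].
#' @return a [FilterOutcome-class] with method "MUL_IN".
#' @export
filterMulInRD <- function(backend, cohort, encQuery, pk) {
  .checkQueryCompat(cohort, encQuery)
  t <- backend@params@t
  if (t <= cohort@nVariants)
    stop("plaintext modulus must exceed the variant count")
  L <- cohort@slotCount
  one <- heEncrypt(backend, rep(1, L), pk)
  start <- .countSnapshot(backend)
  blockCounts <- list()
  results <- list()
  for (b in cohort@blocks) {
    before <- .countSnapshot(backend)
    perChannel <- lapply(c("first", "second"), function(ch)
      heMulMany(backend,
                .channelIndicators(backend, b[[ch]], slot(encQuery, ch), one)))
    r <- heMul(backend, perChannel[[1]], perChannel[[2]])
    r <- heMulPlain(backend, r, b$validMask)
    results[[length(results) + 1]] <- r
    blockCounts[[length(blockCounts) + 1]] <-
      .opCountsFromVec(.countSnapshot(backend) - before, r@depth)
  }
  if (length(results) == 0) {
    s <- heEncrypt(backend, numeric(L), pk)
  } else {
    agg <- Reduce(function(x, y) heAdd(backend, x, y), results)
    s <- heSumSlots(backend, agg, cohort@nVariants)
  }
  total <- .opCountsFromVec(.countSnapshot(backend) - start, s@depth)
  .outcome("MUL_IN", encQuery@model, list(s), cohort@nVariants, blockCounts,
           total, s@depth)
}

#' Addition-intensive filtering (recessive/dominant)
#'
#' The ADD-IN circuit: the same per-sample indicators, then cumulative
#' addition across samples and channels, subtraction of the encrypted
#' indicator total 2s (one indicator per sample per channel, so a full match
#' leaves exactly 0), a plaintext padding correction making padded slots
#' nonzero for every query, slotwise multiplication by encrypted uniform
#' masks from [1, t-1], and a discarded shuffle (block permutation plus
#' per-block cyclic slot rotation).  Matching variants decrypt to 0; all
#' others to uniform nonzero values in permuted positions.  Per block this
#' costs 2s+1 ciphertext multiplications and 8s additions.
#'
#' @inheritParams filterMulInRD
#' @param mask a [MaskSpec-class] seeding masks and the shuffle.
#' @return a [FilterOutcome-class] with method "ADD_IN"; one ciphertext per
#'   input block.
#' @export
filterAddInRD <- function(backend, cohort, encQuery, pk, mask = maskSpec(1)) {
  .checkQueryCompat(cohort, encQuery)
  t <- backend@params@t
  s <- length(cohort@sampleIds)
  if (t <= 2 * s) stop("plaintext modulus must exceed twice the sample count")
  L <- cohort@slotCount
  plan <- .drawMaskPlan(mask, length(cohort@blocks), L, t)
  one <- heEncrypt(backend, rep(1, L), pk)
  encTotal <- heEncrypt(backend, rep(2 * s, L), pk)
  start <- .countSnapshot(backend)
  blockCounts <- list()
  results <- list()
  bi <- 0
  for (b in cohort@blocks) {
    bi <- bi + 1
    before <- .countSnapshot(backend)
    sums <- lapply(c("first", "second"), function(ch)
      heAddMany(backend,
                .channelIndicators(backend, b[[ch]], slot(encQuery, ch), one)))
    resid <- heSub(backend, heAdd(backend, sums[[1]], sums[[2]]), encTotal)
    resid <- heAddPlain(backend, resid, (1 - b$validMask) * (2 * s + 1))
    masked <- heMul(backend, resid,
                    heEncrypt(backend, plan$masks[, bi], pk))
    results[[length(results) + 1]] <- masked
    blockCounts[[length(blockCounts) + 1]] <-
      .opCountsFromVec(.countSnapshot(backend) - before, masked@depth)
  }
  shuffled <- .applyShuffle(results, plan)
  depth <- if (length(results)) max(vapply(results, slot, integer(1), "depth"))
           else 0L
  total <- .opCountsFromVec(.countSnapshot(backend) - start, depth)
  .outcome("ADD_IN", encQuery@model, shuffled, cohort@nVariants, blockCounts,
           total, depth)
}

#' Multiplication-intensive de novo filtering
#'
#' Per channel: cumulative product of the affected samples' values (presence
#' of the genotype class in every affected), products of (1 - value) over
#' the unaffected samples (absence in every unaffected), product of those
#' two terms; the channel results are then added (each variant can pass at
#' most one channel), padded slots zeroed via the plaintext mask, and the
#' result summed across blocks and slots into an encrypted count.  Per
#' block this costs 2a+2u-2 ciphertext multiplications and 2u+1 additions,
#' plus v-1 slot additions for the final total.
#'
#' @param backend a [MockBackend-class].
#' @param cohort an [EncryptedCohort-class].
#' @param partition a [CohortQuery-class] from [deNovoPartition()].
#' @param pk the collective [PublicKey-class].
#' @return a [FilterOutcome-class] with method "MUL_IN".
#' @export
filterMulInDeNovo <- function(backend, cohort, partition, pk) {
  stopifnot(identical(partition@model, "de_novo"))
  affIdx <- .sampleIdx(cohort, partition@affected)
  unIdx <- .sampleIdx(cohort, partition@unaffected)
  if (length(affIdx) < 1) stop("de novo filtering requires >= 1 affected sample")
  t <- backend@params@t
  if (t <= cohort@nVariants)
    stop("plaintext modulus must exceed the variant count")
  L <- cohort@slotCount
  one <- heEncrypt(backend, rep(1, L), pk)
  start <- .countSnapshot(backend)
  blockCounts <- list()
  results <- list()
  for (b in cohort@blocks) {
    before <- .countSnapshot(backend)
    perChannel <- lapply(c("first", "second"), function(ch) {
      ma <- heMulMany(backend, b[[ch]][affIdx])
      if (length(unIdx) == 0) return(ma)
      mu <- heMulMany(backend, lapply(b[[ch]][unIdx], function(v)
        heSub(backend, one, v)))
      heMul(backend, ma, mu)
    })
    r <- heAdd(backend, perChannel[[1]], perChannel[[2]])
    r <- heMulPlain(backend, r, b$validMask)
    results[[length(results) + 1]] <- r
    blockCounts[[length(blockCounts) + 1]] <-
      .opCountsFromVec(.countSnapshot(backend) - before, r@depth)
  }
  if (length(results) == 0) {
    s <- heEncrypt(backend, numeric(L), pk)
  } else {
    agg <- Reduce(function(x, y) heAdd(backend, x, y), results)
    s <- heSumSlots(backend, agg, cohort@nVariants)
  }
  total <- .opCountsFromVec(.countSnapshot(backend) - start, s@depth)
  .outcome("MUL_IN", "de_novo", list(s), cohort@nVariants, blockCounts,
           total, s@depth)
}

#' Addition-intensive de novo filtering
#'
#' Per channel: cumulative addition over the affected samples' values plus
#' cumulative addition of (1 - value) over the unaffected, minus the
#' encrypted total sample count a+u -- zero exactly when the channel's
#' genotype class is present in every affected and absent from every
#' unaffected sample.  The two channel residuals are multiplied (zero iff
#' either channel passes; exact because the modulus exceeds (a+u)^2), padded
#' slots receive a plaintext nonzero correction, and the result is masked
#' and shuffled as in [filterAddInRD()].  Exactly 2 ciphertext
#' multiplications and 2a+4u additions per block, for any cohort size.
#'
#' @inheritParams filterMulInDeNovo
#' @param mask a [MaskSpec-class].
#' @return a [FilterOutcome-class] with method "ADD_IN".
#' @export
filterAddInDeNovo <- function(backend, cohort, partition, pk,
                              mask = maskSpec(1)) {
  stopifnot(identical(partition@model, "de_novo"))
  affIdx <- .sampleIdx(cohort, partition@affected)
  unIdx <- .sampleIdx(cohort, partition@unaffected)
  if (length(affIdx) < 1) stop("de novo filtering requires >= 1 affected sample")
  a <- length(affIdx); u <- length(unIdx)
  t <- backend@params@t
  if (t <= (a + u)^2)
    stop("plaintext modulus must exceed (a+u)^2 for exact zero residuals")
  L <- cohort@slotCount
  plan <- .drawMaskPlan(mask, length(cohort@blocks), L, t)
  one <- heEncrypt(backend, rep(1, L), pk)
  encAU <- heEncrypt(backend, rep(a + u, L), pk)
  start <- .countSnapshot(backend)
  blockCounts <- list()
  results <- list()
  bi <- 0
  for (b in cohort@blocks) {
    bi <- bi + 1
    before <- .countSnapshot(backend)
    resids <- lapply(c("first", "second"), function(ch) {
      acc <- heAddMany(backend, b[[ch]][affIdx])
      if (u > 0) {
        au <- heAddMany(backend, lapply(b[[ch]][unIdx], function(v)
          heSub(backend, one, v)))
        acc <- heAdd(backend, acc, au)
      }
      heSub(backend, acc, encAU)
    })
    r <- heMul(backend, resids[[1]], resids[[2]])
    r <- heAddPlain(backend, r, (1 - b$validMask) * (a + u + 1))
    masked <- heMul(backend, r, heEncrypt(backend, plan$masks[, bi], pk))
    results[[length(results) + 1]] <- masked
    blockCounts[[length(blockCounts) + 1]] <-
      .opCountsFromVec(.countSnapshot(backend) - before, masked@depth)
  }
  shuffled <- .applyShuffle(results, plan)
  depth <- if (length(results)) max(vapply(results, slot, integer(1), "depth"))
           else 0L
  total <- .opCountsFromVec(.countSnapshot(backend) - start, depth)
  .outcome("ADD_IN", "de_novo", shuffled, cohort@nVariants, blockCounts,
           total, depth)
}

.applyShuffle <- function(blocks, plan) {
  if (length(blocks) == 0) return(blocks)
  out <- blocks[plan$perm[seq_along(blocks)]]
  lapply(seq_along(out), function(i)
    .rotateSlots(out[[i]], plan$rots[i]))
}

#' Mask and shuffle residual blocks
#'
#' Multiplies each residual block slotwise by a fresh encrypted uniform
#' [1, t-1] mask and applies a discarded permutation: random block
#' reordering plus an independent cyclic slot rotation within each block.
#' Zero residuals stay zero; nonzero residuals become uniform over [1, t-1]
#' (the modulus is prime) and lose their positions.
#'
#' @param backend a [MockBackend-class].
#' @param residualBlocks list of [CipherVector-class] residual blocks.
#' @param pk the collective [PublicKey-class].
#' @param mask a [MaskSpec-class].
#' @return list of masked, shuffled [CipherVector-class] blocks.
#' @export
maskAndShuffle <- function(backend, residualBlocks, pk, mask = maskSpec(1)) {
  t <- backend@params@t
  L <- backend@params@slotCount
  plan <- .drawMaskPlan(mask, length(residualBlocks), L, t)
  masked <- lapply(seq_along(residualBlocks), function(i)
    heMul(backend, residualBlocks[[i]],
          heEncrypt(backend, plan$masks[, i], pk)))
  .applyShuffle(masked, plan)
}

#' Decode a MUL-IN count
#'
#' After total-sum every slot carries the same encrypted count; decoding
#' reads slot 1 and verifies the all-slots-equal invariant.
#'
#' @param plain decrypted numeric slot vector of a MUL-IN outcome.
#' @return integer count of variants matching the filter.
#' @export
decodeCountMulIn <- function(plain) {
  if (length(plain) == 0) return(0L)
  if (any(plain != plain[1]))
    stop("integrity error: MUL-IN slots disagree after total-sum")
  as.integer(plain[1])
}

#' Decode an ADD-IN zero count
#'
#' Counts zero slots across all decrypted residual blocks.  Padded slots
#' received a nonzero plaintext correction inside the circuit, so no mask is
#' needed at decode time.
#'
#' @param plainBlocks list of decrypted numeric slot vectors.
#' @param validSlotTotal number of real variants filtered (sanity bound).
#' @return integer count of variants matching the filter.
#' @export
decodeCountAddIn <- function(plainBlocks, validSlotTotal = NULL) {
  z <- sum(vapply(plainBlocks, function(p) sum(p == 0), numeric(1)))
  if (!is.null(validSlotTotal) && z > validSlotTotal)
    stop("integrity error: more zero slots than real variants")
  as.integer(z)
}

#' Decrypt an outcome's payload
#'
#' Convenience for the single-key path: decrypts every payload ciphertext.
#' In the committee setting use [partialDecrypt()]/[combinePartials()]
#' per payload ciphertext instead.
#'
#' @param backend a [MockBackend-class].
#' @param outcome a [FilterOutcome-class].
#' @param sk the [SecretKey-class].
#' @return list of numeric slot vectors.
#' @export
decryptOutcome <- function(backend, outcome, sk) {
  lapply(outcome@payload, function(ct) heDecrypt(backend, ct, sk))
}

setMethod("show", "FilterOutcome", function(object) {
  cat("FilterOutcome:", object@method, "/", object@model, "on",
      object@validSlotTotal, "variants in", length(object@blockOpCounts),
      "block(s); depth", object@depth, "\n")
  show(object@totalOpCounts)
})
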