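#' @import methods
#' @importFrom stats runif
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Encryption-domain parameters
#'
#' Parameters shared by every backend: the plaintext modulus \code{t} (a
#' prime; all encrypted arithmetic is modulo \code{t}), the multiplicative
#' depth budget (longest chain of ciphertext multiplications a circuit may
#' apply before the scheme's noise would make decryption fail), the SIMD slot
#' count of one ciphertext, and the nominal security level (informational;
#' only a real lattice backend uses it).
#'
#' @slot t numeric prime plaintext modulus.
#' @slot depthBudget integer multiplicative depth budget (>= 1).
#' @slot slotCount integer number of SIMD slots (a power of two).
#' @slot securityBits integer nominal security level.
#' @exportClass CryptoParams
setClass("CryptoParams",
  representation(t = "numeric", depthBudget = "integer",
                 slotCount = "integer", securityBits = "integer"))

setValidity("CryptoParams", function(object) {
  msg <- NULL
  if (length(object@t) != 1 || !.isPrime(object@t))
    msg <- c(msg, "plaintext modulus t must be a single prime")
  if (object@t > 2^26)
    msg <- c(msg, "mock arithmetic requires t <= 2^26 (exact double products)")
  if (object@depthBudget < 1L)
    msg <- c(msg, "depthBudget must be >= 1")
  if (!.isPow2(object@slotCount))
    msg <- c(msg, "slotCount must be a power of two")
  if (is.null(msg)) TRUE else msg
})

#' Homomorphic operation tallies
#'
#' Counts of encrypted-domain operations at vector-operation granularity:
#' ciphertext-ciphertext multiplications, ciphertext-ciphertext additions
#' (additions plus subtractions), and scalar slot additions attributed to
#' total-sum (\code{heSumSlots}) calls.  Plaintext-operand operations are
#' tallied separately and never count toward the ciphertext columns.
#'
#' @slot ctMultiplications,ctAdditions,slotAdditions,plainMultiplications,plainAdditions numeric tallies.
#' @slot maxDepth numeric high-water multiplicative depth.
#' @exportClass OpCounts
setClass("OpCounts",
  representation(ctMultiplications = "numeric", ctAdditions = "numeric",
                 slotAdditions = "numeric", plainMultiplications = "numeric",
                 plainAdditions = "numeric", maxDepth = "numeric"))

#' Mock homomorphic backend
#'
#' An exact plaintext stand-in for a BFV-style SIMD integer scheme:
#' "ciphertexts" carry their slot vector reduced modulo \code{t} together
#' with bookkeeping (key binding, accumulated multiplicative depth), and all
#' operations apply true modular semantics while instrumenting operation
#' counts and depth.  Circuits verified on this backend are bit-exact
#' previews of what a real BFV evaluation computes.
#'
#' @slot params a [CryptoParams-class].
#' @slot state environment holding counters, key material and the RNG stream.
#' @exportClass MockBackend
setClass("MockBackend",
  representation(params = "CryptoParams", state = "environment"))

#' @exportClass PublicKey
#' @rdname keygen
setClass("PublicKey", representation(keyId = "character", params = "CryptoParams"))

#' @exportClass SecretKey
#' @rdname keygen
setClass("SecretKey", representation(keyId = "character", material = "numeric"))

#' Encrypted slot vector
#'
#' Opaque handle to one ciphertext: backend tag, key binding, slot count,
#' accumulated multiplicative depth, and backend-specific payload (for the
#' mock backend, the slot values themselves).
#'
#' @slot backendId character backend tag ("mock").
#' @slot keyId character id of the public key the vector is encrypted under.
#' @slot slotCount integer number of slots.
#' @slot depth integer accumulated multiplicative depth.
#' @slot payload numeric backend payload.
#' @exportClass CipherVector
setClass("CipherVector",
  representation(backendId = "character", keyId = "character",
                 slotCount = "integer", depth = "integer", payload = "numeric"))

setValidity("CipherVector", function(object) {
  if (length(object@payload) != object@slotCount)
    "payload length must equal slotCount" else TRUE
})

#' Two-channel genotype bit matrices
#'
#' A \linkS4class{SummarizedExperiment} with exactly two binary assays,
#' \code{firstAllelic} (1 iff the sample carries the variant homozygously)
#' and \code{secondAllelic} (1 iff heterozygously), rows = variants,
#' columns = samples.  The two bits are the encrypted-domain genotype code:
#' hom-ref/missing = (0,0), het = (0,1), hom-alt = (1,0); (1,1) never occurs.
#'
#' @exportClass GenotypeChannels
setClass("GenotypeChannels", contains = "SummarizedExperiment")

setValidity("GenotypeChannels", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!identical(an, c("firstAllelic", "secondAllelic")))
    return("assays must be exactly 'firstAllelic', 'secondAllelic'")
  f <- SummarizedExperiment::assay(object, "firstAllelic")
  s <- SummarizedExperiment::assay(object, "secondAllelic")
  if (!all(f %in% c(0, 1)) || !all(s %in% c(0, 1)))
    return("channel entries must be bits")
  if (any(f * s != 0))
    return("a genotype cannot be homozygous and heterozygous at once")
  TRUE
})

#' Slot-packed variant blocks
#'
#' The two channel matrices partitioned row-wise into fixed-size SIMD blocks.
#' Each block holds, per channel, a slotCount x nSamples matrix (columns are
#' the per-sample slot vectors) plus a validity mask: 1 for a real variant,
#' 0 for zero padding in the final block.
#'
#' @slot blocks list; each element has \code{first}, \code{second}
#'   (slotCount x nSamples numeric matrices), \code{validMask} and
#'   \code{blockIndex}.
#' @slot slotCount integer slots per block.
#' @slot sampleIds character sample ordering.
#' @slot variantInfo data.frame of (chrom, pos, ref, alt) rows in order.
#' @slot nVariants integer number of real (unpadded) variants.
#' @exportClass VariantBlocks
setClass("VariantBlocks",
  representation(blocks = "list", slotCount = "integer",
                 sampleIds = "character", variantInfo = "data.frame",
                 nVariants = "integer"))

#' Inheritance-model query pattern
#'
#' Per-sample target genotype codes for recessive/dominant filtering, or the
#' affected/unaffected partition for the de novo model.  Targets are an
#' nSamples x 2 bit matrix (columns firstAllelic, secondAllelic) and respect
#' the genotype-code invariant (never (1,1)).
#'
#' @slot model character: "recessive", "dominant", "de_novo" or "custom".
#' @slot targets numeric matrix nSamples x 2 (empty for de novo).
#' @slot sampleIds character.
#' @slot affected,unaffected character sample ids (de novo partition).
#' @exportClass CohortQuery
setClass("CohortQuery",
  representation(model = "character", targets = "matrix",
                 sampleIds = "character", affected = "character",
                 unaffected = "character"))

setValidity("CohortQuery", function(object) {
  if (length(object@targets) > 0) {
    if (!all(object@targets %in% c(0, 1)))
      return("query targets must be bits")
    if (any(object@targets[, 1] * object@targets[, 2] != 0))
      return("query target (1,1) is not a valid genotype code")
  }
  TRUE
})

#' Encrypted query
#'
#' One ciphertext per sample per channel, each holding the sample's target
#' bit replicated across every slot, so a single SIMD operation compares the
#' query against all variants of a block at once.  The ciphertexts carry no
#' information about any variant data.
#'
#' @slot model character.
#' @slot first,second list of [CipherVector-class], one per sample.
#' @slot sampleIds character.
#' @slot keyId character key binding.
#' @exportClass EncryptedQuery
setClass("EncryptedQuery",
  representation(model = "character", first = "list", second = "list",
                 sampleIds = "character", keyId = "character"))

#' Encrypted cohort blocks
#'
#' The slot-packed genotype blocks encrypted columnwise: per block, one
#' ciphertext per sample per channel.  Validity masks stay in plaintext on
#' the evaluating side (they describe padding, not genotypes).
#'
#' @slot blocks list of blocks with \code{first}/\code{second} ciphertext
#'   lists, \code{validMask}, \code{blockIndex}.
#' @slot slotCount,nVariants integer.
#' @slot sampleIds character.
#' @slot keyId character.
#' @exportClass EncryptedCohort
setClass("EncryptedCohort",
  representation(blocks = "list", slotCount = "integer",
                 sampleIds = "character", nVariants = "integer",
                 keyId = "character"))

#' Key-management committee configuration
#'
#' @slot nMembers integer committee size (>= 2).
#' @slot quorum integer members required to decrypt (2 <= quorum <= nMembers).
#' @slot mode character: "additive" (n-of-n) or "shamir" (t-of-n);
#'   constructor default "auto" picks additive when quorum == nMembers.
#' @exportClass CommitteeConfig
setClass("CommitteeConfig",
  representation(nMembers = "integer", quorum = "integer", mode = "character"))

setValidity("CommitteeConfig", function(object) {
  msg <- NULL
  if (object@nMembers < 2L) msg <- c(msg, "committee needs >= 2 members")
  if (object@quorum < 2L || object@quorum > object@nMembers)
    msg <- c(msg, "quorum must satisfy 2 <= quorum <= nMembers")
  if (!object@mode %in% c("additive", "shamir"))
    msg <- c(msg, "mode must be 'additive' or 'shamir'")
  if (identical(object@mode, "additive") && object@quorum != object@nMembers)
    msg <- c(msg, "additive sharing is n-of-n: quorum must equal nMembers")
  if (is.null(msg)) TRUE else msg
})

#' Committee member key share
#'
#' Secret material bound to the collective public key.  No single share (or
#' any set smaller than the quorum) can decrypt a ciphertext.
#'
#' @slot memberId integer member index.
#' @slot x integer evaluation point (Shamir) or member index (additive).
#' @slot value numeric secret share over the plaintext ring.
#' @slot keyId character collective key binding.
#' @slot mode character sharing mode.
#' @slot nMembers,quorum integer committee parameters.
#' @exportClass KeyShare
setClass("KeyShare",
  representation(memberId = "integer", x = "integer", value = "numeric",
                 keyId = "character", mode = "character",
                 nMembers = "integer", quorum = "integer"))

#' Partial decryption message
#'
#' One member's contribution to interactive threshold decryption, bound by
#' digest to exactly one ciphertext.
#'
#' @slot memberId,x integer.
#' @slot digest character ciphertext digest the partial is bound to.
#' @slot payload numeric slot vector.
#' @slot mode character sharing mode.
#' @slot nMembers,quorum integer.
#' @slot keyId character.
#' @exportClass PartialDecryption
setClass("PartialDecryption",
  representation(memberId = "integer", x = "integer", digest = "character",
                 payload = "numeric", mode = "character",
                 nMembers = "integer", quorum = "integer", keyId = "character"))

#' Masking / shuffling randomness specification
#'
#' Seed for the privacy randomness of ADD-IN outputs: slotwise masks drawn
#' uniformly from [1, t-1] (never 0, so zeros are exactly preserved) and the
#' discarded output permutation (block reordering + per-block cyclic slot
#' rotation).
#'
#' @slot seed numeric.
#' @exportClass MaskSpec
setClass("MaskSpec", representation(seed = "numeric"))

#' Encrypted filtering outcome
#'
#' Result of one filtering circuit.  MUL-IN: a single ciphertext whose every
#' slot holds the encrypted count of matching variants.  ADD-IN: one masked,
#' shuffled residual ciphertext per input block; matching variants decrypt
#' to 0, all others to uniform nonzero values in permuted positions.
#'
#' @slot method character "MUL_IN" or "ADD_IN".
#' @slot model character inheritance model.
#' @slot payload list of [CipherVector-class] (length 1 for MUL-IN).
#' @slot validSlotTotal integer number of real variants filtered.
#' @slot blockOpCounts list of per-block [OpCounts-class] deltas.
#' @slot totalOpCounts [OpCounts-class] for the whole circuit.
#' @slot depth integer maximum depth of any output ciphertext.
#' @exportClass FilterOutcome
setClass("FilterOutcome",
  representation(method = "character", model = "character", payload = "list",
                 validSlotTotal = "integer", blockOpCounts = "list",
                 totalOpCounts = "OpCounts", depth = "integer"))

setValidity("FilterOutcome", function(object) {
  if (object@method == "MUL_IN" && length(object@payload) != 1L)
    return("MUL-IN outcome carries exactly one ciphertext")
  TRUE
})

#' Synthetic cohort specification
#'
#' Describes a synthetic multi-sample VCF: number of variants, sample roles,
#' the inheritance model and the number of implanted causal rows matching
#' its pattern, the background genotype-code distribution, and the seed.
#' Background rows that accidentally match the model pattern are redrawn, so
#' ground-truth counts are exact by construction.
#'
#' @slot nVariants,nImplanted integer.
#' @slot roles data.frame (sampleId, role).
#' @slot model character.
#' @slot bgProbs numeric length-3 probabilities of codes (ref, het, hom).
#' @slot seed numeric.
#' @exportClass SimSpec
setClass("SimSpec",
  representation(nVariants = "integer", roles = "data.frame",
                 model = "character", nImplanted = "integer",
                 bgProbs = "numeric", seed = "numeric"))

setValidity("SimSpec", function(object) {
  msg <- NULL
  if (object@nImplanted > object@nVariants)
    msg <- c(msg, "nImplanted must be <= nVariants")
  if (length(object@bgProbs) != 3 || abs(sum(object@bgProbs) - 1) > 1e-9 ||
      any(object@bgProbs < 0))
    msg <- c(msg, "bgProbs must be 3 non-negative probabilities summing to 1")
  if (is.null(msg)) TRUE else msg
})

#' End-to-end run manifest
#'
#' Record of one simulated secure analysis: configuration, seeds, per-stage
#' operation counts, depth consumed, and the decoded outcome, sufficient to
#' reproduce the run bit-exactly on the mock backend.
#'
#' @slot fields named list.
#' @exportClass RunManifest
setClass("RunManifest", representation(fields = "list"))
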