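#' Run one secure analysis end to end
#'
#' Orchestrates the full scenario on the mock backend: generate a synthetic
#' cohort VCF, parse and encode it, pack blocks, committee key generation,
#' encrypt cohort and query, run the chosen filtering circuit, collect a
#' quorum of partial decryptions, combine, and decode.  The decoded count is
#' checked against the generator's ground truth before returning.
#'
#' @param spec a [SimSpec-class].
#' @param method "mul-in" (encrypted count) or "add-in" (masked shuffled
#'   residuals).
#' @param params a [CryptoParams-class]; by default the depth budget follows
#'   the method (2 for ADD-IN, 12 for MUL-IN).
#' @param committee a [CommitteeConfig-class] (default 4-of-4).
#' @param seed integer master seed for keys and masks.
#' @return a [RunManifest-class].
#' @examples
#' roles <- cohortRoles(c("M", "F", "P"), c("mother", "father", "proband"))
#' sp <- simSpec(200, roles, "recessive", nImplanted = 3, seed = 7)
#' m <- simulateFiltering(sp, method = "add-in",
#'                        params = cryptoParams(slotCount = 64L))
#' runInfo(m)$decodedCount
#' @export
simulateFiltering <- function(spec, method = c("mul-in", "add-in"),
                              params = NULL,
                              committee = committeeConfig(4, 4), seed = 1) {
  method <- match.arg(method)
  if (is.null(params))
    params <- cryptoParams(depthBudget = if (method == "add-in") 2L else 12L)
  t0 <- proc.time()[["elapsed"]]
  vcf <- generateCohortVcf(spec)
  channels <- readVcfGenotypes(vcf$path)
  vb <- packBlocks(channels, params@slotCount)
  bk <- mockBackend(params, seed = seed)
  keys <- dkg(bk, committee, seed = seed)
  cohort <- encryptCohort(bk, vb, keys$pk)
  query <- switch(spec@model,
                  recessive = recessiveQuery(spec@roles),
                  dominant = dominantQuery(spec@roles),
                  de_novo = deNovoPartition(spec@roles))
  resetOpCounts(bk)
  outcome <- if (spec@model == "de_novo") {
    if (method == "mul-in") filterMulInDeNovo(bk, cohort, query, keys$pk)
    else filterAddInDeNovo(bk, cohort, query, keys$pk,
                           mask = maskSpec(seed + 1))
  } else {
    eq <- encryptQuery(bk, query, keys$pk)
    if (method == "mul-in") filterMulInRD(bk, cohort, eq, keys$pk)
    else filterAddInRD(bk, cohort, eq, keys$pk, mask = maskSpec(seed + 1))
  }
  plains <- lapply(outcome@payload, function(ct) {
    partials <- lapply(keys$shares, function(sh) partialDecrypt(bk, ct, sh))
    combinePartials(partials, t = params@t)
  })
  decoded <- if (method == "mul-in") decodeCountMulIn(plains[[1]])
             else decodeCountAddIn(plains, outcome@validSlotTotal)
  truthCount <- sum(vcf$truth$pass)
  if (decoded != truthCount)
    stop("stage decode: decoded count ", decoded,
         " does not match ground truth ", truthCount)
  oc <- outcome@totalOpCounts
  new("RunManifest", fields = list(
    model = spec@model, method = method,
    nVariants = spec@nVariants, nSamples = nrow(spec@roles),
    slotCount = params@slotCount, t = params@t,
    depthBudget = params@depthBudget,
    committee = list(nMembers = committee@nMembers,
                     quorum = committee@quorum, mode = committee@mode),
    seeds = list(data = spec@seed, run = seed),
    opCounts = list(ctMultiplications = oc@ctMultiplications,
                    ctAdditions = oc@ctAdditions,
                    slotAdditions = oc@slotAdditions,
                    plainMultiplications = oc@plainMultiplications,
                    plainAdditions = oc@plainAdditions),
    depthConsumed = outcome@depth,
    decodedCount = decoded, truthCount = truthCount,
    elapsedSec = proc.time()[["elapsed"]] - t0))
}

#' @describeIn RunManifest-class the manifest fields as a named list
#' @param x a [RunManifest-class]
#' @export
runInfo <- function(x) x@fields

#' Write a run manifest as JSON
#'
#' @param manifest a [RunManifest-class].
#' @param path output path.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest@fields, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

setMethod("show", "RunManifest", function(object) {
  f <- object@fields
  cat("RunManifest:", f$model, "/", f$method, "on", f$nVariants,
      "variants x", f$nSamples, "samples; decoded count", f$decodedCount,
      "(truth", paste0(f$truthCount, ")"), "\n")
})

.expectedCounts <- function(model, method, s, a, u, v) {
  if (model == "de_novo") {
    if (method == "mul-in")
      list(ctMul = 2 * a + 2 * u - 2, ctAdd = 2 * u + 1, slotAdd = v - 1)
    else
      list(ctMul = 2, ctAdd = 2 * a + 4 * u, slotAdd = 0)
  } else {
    if (method == "mul-in")
      list(ctMul = 4 * s - 1, ctAdd = 6 * s, slotAdd = v - 1)
    else
      list(ctMul = 2 * s + 1, ctAdd = 8 * s, slotAdd = 0)
  }
}

# one measured grid cell on a fresh backend; single block (v <= slotCount)
.gridCell <- function(model, method, s, a, u, v, params) {
  bk <- mockBackend(params, seed = 11)
  keys <- keygen(bk)
  if (model == "de_novo") {
    ids <- c(sprintf("A%d", seq_len(a)),
             if (u > 0) sprintf("U%d", seq_len(u)))
    roles <- cohortRoles(ids, c(rep("affected", a), rep("unaffected", u)))
    spec <- simSpec(v, roles, "de_novo", nImplanted = min(2L, v), seed = 5)
  } else {
    # the recessive and dominant circuits are identical up to the target
    # pattern; a dominant cohort covers any sample count s >= 2
    ids <- c("A1", sprintf("U%d", seq_len(s - 1)))
    roles <- cohortRoles(ids, c("affected", rep("unaffected", s - 1)))
    spec <- simSpec(v, roles, "dominant", nImplanted = min(2L, v), seed = 5)
  }
  cohort <- generateCohort(spec)
  vb <- packBlocks(cohort$channels, params@slotCount)
  enc <- encryptCohort(bk, vb, keys$pk)
  query <- if (model == "de_novo") deNovoPartition(roles)
           else dominantQuery(roles)
  outcome <- if (model == "de_novo") {
    if (method == "mul-in") filterMulInDeNovo(bk, enc, query, keys$pk)
    else filterAddInDeNovo(bk, enc, query, keys$pk, maskSpec(3))
  } else {
    eq <- encryptQuery(bk, query, keys$pk)
    if (method == "mul-in") filterMulInRD(bk, enc, eq, keys$pk)
    else filterAddInRD(bk, enc, eq, keys$pk, maskSpec(3))
  }
  bc <- outcome@blockOpCounts[[1]]
  list(ctMul = bc@ctMultiplications, ctAdd = bc@ctAdditions,
       slotAdd = outcome@totalOpCounts@slotAdditions,
       depth = outcome@depth)
}

#' Operation-count benchmark grid
#'
#' Runs every circuit over a grid of cohort sizes, records the per-block
#' instrumented operation counts and the consumed depth, and checks them
#' against the closed-form complexity formulas (recessive/dominant MUL-IN:
#' 4s-1 multiplications, 6s additions, v-1 slot additions; ADD-IN: 2s+1 and
#' 8s; de novo MUL-IN: 2a+2u-2 and 2u+1 plus v-1; de novo ADD-IN: exactly 2
#' multiplications and 2a+4u additions).  Timings are incidental and never
#' asserted.
#'
#' @param sValues sample counts for the recessive/dominant circuits.
#' @param auValues list of c(a, u) pairs for the de novo circuits.
#' @param v variants per cell (at most the slot count: one block).
#' @param params a [CryptoParams-class]; default uses 64 slots and depth 12.
#' @return data.frame with measured and expected counts and a
#'   \code{formulaPass} column.
#' @export
opCountGrid <- function(sValues = c(2, 4, 8, 16),
                        auValues = list(c(2, 2), c(4, 4), c(8, 8), c(16, 16)),
                        v = 64,
                        params = cryptoParams(slotCount = 64L,
                                              depthBudget = 12L)) {
  stopifnot(v <= params@slotCount)
  rows <- list()
  for (method in c("mul-in", "add-in")) {
    for (s in sValues) {
      m <- .gridCell("recessive_dominant", method, s = s, a = 0, u = 0,
                     v = v, params = params)
      e <- .expectedCounts("recessive_dominant", method, s = s, a = 0,
                           u = 0, v = v)
      rows[[length(rows) + 1]] <- data.frame(
        model = "recessive_dominant", method = method, s = s, a = NA, u = NA,
        v = v, ctMul = m$ctMul, ctAdd = m$ctAdd, slotAdd = m$slotAdd,
        depth = m$depth, expMul = e$ctMul, expAdd = e$ctAdd,
        expSlotAdd = e$slotAdd,
        formulaPass = m$ctMul == e$ctMul && m$ctAdd == e$ctAdd &&
          m$slotAdd == e$slotAdd)
    }
    for (au in auValues) {
      m <- .gridCell("de_novo", method, s = 0, a = au[1], u = au[2], v = v,
                     params = params)
      e <- .expectedCounts("de_novo", method, s = 0, a = au[1], u = au[2],
                           v = v)
      rows[[length(rows) + 1]] <- data.frame(
        model = "de_novo", method = method, s = NA, a = au[1], u = au[2],
        v = v, ctMul = m$ctMul, ctAdd = m$ctAdd, slotAdd = m$slotAdd,
        depth = m$depth, expMul = e$ctMul, expAdd = e$ctAdd,
        expSlotAdd = e$slotAdd,
        formulaPass = m$ctMul == e$ctMul && m$ctAdd == e$ctAdd &&
          m$slotAdd == e$slotAdd)
    }
  }
  do.call(rbind, rows)
}

#' Read a backend configuration file
#'
#' YAML or JSON with fields \code{backend} ("mock"), \code{t},
#' \code{depthBudget}, \code{slotCount}, \code{securityBits}, \code{seed}.
#'
#' @param path config file path.
#' @return list with \code{params} (a [CryptoParams-class]), \code{backend}
#'   and \code{seed}.
#' @export
readBackendConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  defaults <- list(backend = "mock", t = 16777259, depthBudget = 12L,
                   slotCount = 1024L, securityBits = 128L, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  if (!identical(cfg$backend, "mock"))
    stop("only the 'mock' backend is available in this build; a BFV ",
         "adapter can implement the same generics")
  list(params = cryptoParams(t = cfg$t, depthBudget = cfg$depthBudget,
                             slotCount = cfg$slotCount,
                             securityBits = cfg$securityBits),
       backend = cfg$backend, seed = cfg$seed)
}

#' Serialize / deserialize a ciphertext container
#'
#' JSON container: header (backend, key id, slot count, depth) + payload.
#'
#' @param ct a [CipherVector-class].
#' @param path file path.
#' @export
writeCipherVector <- function(ct, path) {
  jsonlite::write_json(list(backendId = ct@backendId, keyId = ct@keyId,
                            slotCount = ct@slotCount, depth = ct@depth,
                            payload = ct@payload),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCipherVector
#' @export
readCipherVector <- function(path) {
  o <- jsonlite::fromJSON(path)
  new("CipherVector", backendId = o$backendId, keyId = o$keyId,
      slotCount = as.integer(o$slotCount), depth = as.integer(o$depth),
      payload = as.numeric(o$payload))
}

#' Reproduce candidate counts on externally provided trio VCFs
#'
#' Runs the secure recessive MUL-IN pipeline (committee keys, encrypted
#' cohort and query, threshold decryption) on a real trio VCF whose samples
#' are ordered mother, father, proband, and returns the revealed candidate
#' count.  The exome data this reproduces is distributed with the original
#' study's code repository and is not bundled here; place the trio VCFs
#' under \code{inst/extdata/realdata/} to run it.
#'
#' @param vcfPath path to a trio VCF (rare, high/moderate-impact variants,
#'   GT as first FORMAT key).
#' @param roles a [cohortRoles()] data.frame matching the VCF sample order.
#' @param params a [CryptoParams-class].
#' @param seed integer seed for keys.
#' @return integer candidate-variant count.
#' @export
reproduceTrioCounts <- function(vcfPath,
                                roles = cohortRoles(
                                  c("mother", "father", "proband"),
                                  c("mother", "father", "proband")),
                                params = cryptoParams(), seed = 1) {
  channels <- readVcfGenotypes(vcfPath)
  vb <- packBlocks(channels, params@slotCount)
  bk <- mockBackend(params, seed = seed)
  keys <- dkg(bk, committeeConfig(4, 4), seed = seed)
  cohort <- encryptCohort(bk, vb, keys$pk)
  roles$sampleId <- cohort@sampleIds   # match the file's sample order
  eq <- encryptQuery(bk, recessiveQuery(roles), keys$pk)
  outcome <- filterMulInRD(bk, cohort, eq, keys$pk)
  partials <- lapply(keys$shares, function(sh)
    partialDecrypt(bk, outcome@payload[[1]], sh))
  decodeCountMulIn(combinePartials(partials, t = params@t))
}
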