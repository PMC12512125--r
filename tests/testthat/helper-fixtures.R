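# Shared fixtures: small parameter sets, VCF writers, code-matrix helpers
# and the independent plaintext oracles used across the suite.

smallParams <- function(t = 97, slotCount = 8L, depthBudget = 12L)
  cryptoParams(t = t, slotCount = slotCount, depthBudget = depthBudget)

# write a VCF from a GT string matrix (variants x samples)
writeToyVcf <- function(gt, sampleIds = colnames(gt),
                        path = tempfile(fileext = ".vcf"),
                        format = "GT") {
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(gt)))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds), collapse = "\t"))
  body <- if (nrow(gt) > 0)
    vapply(seq_len(nrow(gt)), function(i)
      paste(c("chr1", 100 + i, ".", "A", "T", ".", "PASS", ".", format,
              gt[i, ]), collapse = "\t"), character(1))
  else character()
  writeLines(c(header, body), path)
  path
}

# genotype code matrix (0 ref / 1 het / 2 hom) -> GenotypeChannels
codesToChannels <- function(codes, sampleIds = colnames(codes)) {
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(codes)))
  genotypeChannels((codes == 2) + 0L, (codes == 1) + 0L,
                   sampleIds = sampleIds)
}

# Independent per-definition filter on genotype codes.  Works directly on
# the 0/1/2 categories and role semantics, with no channel-bit algebra, so
# it is a genuinely separate oracle from referenceFilter().
naiveDefinitionFilter <- function(codes, roles, model) {
  if (model == "de_novo") {
    aff <- roles$role %in% c("affected", "proband")
    return(vapply(seq_len(nrow(codes)), function(i) {
      row <- codes[i, ]
      any(vapply(c(1, 2), function(cl)
        all(row[aff] == cl) && all(row[!aff] != cl), logical(1)))
    }, logical(1)))
  }
  want <- switch(model,
    recessive = vapply(roles$role, function(r) switch(r,
      proband = 2, mother = 1, father = 1, 0), numeric(1)),
    dominant = ifelse(roles$role %in% c("affected", "proband"), 1, 0))
  vapply(seq_len(nrow(codes)), function(i) all(codes[i, ] == want),
         logical(1))
}

# run one cohort through both encrypted methods (single-key decrypt path)
runBothMethods <- function(channels, query, params, seed = 1) {
  vb <- packBlocks(channels, params@slotCount)
  bk <- mockBackend(params, seed = seed)
  keys <- keygen(bk)
  enc <- encryptCohort(bk, vb, keys$pk)
  deNovo <- query@model == "de_novo"
  if (deNovo) {
    outMul <- filterMulInDeNovo(bk, enc, query, keys$pk)
    outAdd <- filterAddInDeNovo(bk, enc, query, keys$pk,
                                mask = maskSpec(seed + 13))
  } else {
    eq <- encryptQuery(bk, query, keys$pk)
    outMul <- filterMulInRD(bk, enc, eq, keys$pk)
    outAdd <- filterAddInRD(bk, enc, eq, keys$pk, mask = maskSpec(seed + 13))
  }
  list(
    mulCount = decodeCountMulIn(heDecrypt(bk, outMul@payload[[1]], keys$sk)),
    addCount = decodeCountAddIn(decryptOutcome(bk, outAdd, keys$sk),
                                outAdd@validSlotTotal),
    outMul = outMul, outAdd = outAdd, backend = bk, keys = keys)
}

trioRoles <- function(extraUnaffected = 0) {
  ids <- c("M", "F", "P",
           if (extraUnaffected > 0) sprintf("U%d", seq_len(extraUnaffected)))
  cohortRoles(ids, c("mother", "father", "proband",
                     rep("unaffected", extraUnaffected)))
}
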