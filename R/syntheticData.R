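#' Specify a synthetic cohort
#'
#' @param nVariants number of variant rows.
#' @param roles a [cohortRoles()] data.frame (trio for recessive;
#'   affected/unaffected cohort for dominant and de novo).
#' @param model inheritance model whose pattern is implanted.
#' @param nImplanted number of causal rows exactly matching the model
#'   pattern.
#' @param bgProbs background per-call probabilities of the genotype codes
#'   (hom-ref, het, hom-alt).  The default (0.90, 0.08, 0.02) is a plausible
#'   post-rarity-filter exome profile; truth counts never depend on it
#'   because background rows matching the pattern are redrawn.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a [SimSpec-class].
#' @export
simSpec <- function(nVariants, roles, model = c("recessive", "dominant",
                                                "de_novo"),
                    nImplanted = 0L, bgProbs = c(0.90, 0.08, 0.02),
                    seed = 1) {
  model <- match.arg(model)
  new("SimSpec", nVariants = as.integer(nVariants), roles = roles,
      model = model, nImplanted = as.integer(nImplanted),
      bgProbs = as.numeric(bgProbs), seed = as.numeric(seed))
}

# model pattern as genotype codes 0 = hom-ref, 1 = het, 2 = hom-alt,
# one per sample; errors if the roles cannot express the pattern
.modelPattern <- function(spec) {
  roles <- spec@roles
  switch(spec@model,
    recessive = {
      q <- recessiveQuery(roles)     # validates the trio
      unname(q@targets[, 1] * 2 + q@targets[, 2])
    },
    dominant = {
      q <- dominantQuery(roles)
      unname(q@targets[, 1] * 2 + q@targets[, 2])
    },
    de_novo = {
      p <- deNovoPartition(roles)
      ifelse(roles$sampleId %in% p@affected, 1, 0)  # shared het, absent else
    })
}

# vectorized definition-level pass check over a code matrix
.rowsPass <- function(codes, spec, pattern) {
  if (spec@model == "de_novo") {
    aff <- spec@roles$sampleId %in% deNovoPartition(spec@roles)@affected
    ch <- function(code) {
      a <- codes[, aff, drop = FALSE]
      u <- codes[, !aff, drop = FALSE]
      rowSums(a == code) == sum(aff) & rowSums(u == code) == 0
    }
    return(ch(1) | ch(2))
  }
  rowSums(codes == matrix(pattern, nrow = nrow(codes), ncol = ncol(codes),
                          byrow = TRUE)) == ncol(codes)
}

#' Generate a synthetic cohort (channel matrices + ground truth)
#'
#' Draws background genotype codes per call from \code{bgProbs}, implants
#' exactly \code{nImplanted} rows matching the model pattern at random
#' positions, and redraws any background row that accidentally matches, so
#' the ground-truth count equals \code{nImplanted} by construction.
#'
#' @param spec a [SimSpec-class].
#' @return list with \code{channels} (a [GenotypeChannels-class]),
#'   \code{truth} (data.frame with per-variant \code{pass} and
#'   \code{implanted} flags) and \code{codes} (the raw code matrix).
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  pattern <- .modelPattern(spec)     # also validates feasibility
  n <- spec@nVariants
  sIds <- spec@roles$sampleId
  nSamp <- length(sIds)
  .useSeed(spec@seed, {
    codes <- matrix(sample(0:2, n * nSamp, replace = TRUE,
                           prob = spec@bgProbs),
                    nrow = n, dimnames = list(NULL, sIds))
    implantAt <- if (spec@nImplanted > 0) sort(sample(n, spec@nImplanted))
                 else integer()
    # redraw background rows that match the pattern by accident
    for (iter in seq_len(1000)) {
      bgPass <- setdiff(which(.rowsPass(codes, spec, pattern)), implantAt)
      if (length(bgPass) == 0) break
      codes[bgPass, ] <- sample(0:2, length(bgPass) * nSamp, replace = TRUE,
                                prob = spec@bgProbs)
    }
    if (length(implantAt))
      codes[implantAt, ] <- matrix(pattern, nrow = length(implantAt),
                                   ncol = nSamp, byrow = TRUE)
    info <- data.frame(
      chrom = paste0("chr", ((seq_len(n) - 1) %% 22) + 1),
      pos = 10000 + seq_len(n) * 17L,
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = character(n))
    info$alt <- vapply(info$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    first <- (codes == 2) + 0L
    second <- (codes == 1) + 0L
    list(channels = genotypeChannels(first, second, variantInfo = info,
                                     sampleIds = sIds),
         truth = data.frame(variant = seq_len(n),
                            pass = seq_len(n) %in% implantAt,
                            implanted = seq_len(n) %in% implantAt),
         codes = codes)
  })
}

#' Generate a synthetic multi-sample VCF with ground truth
#'
#' Writes the cohort of [generateCohort()] as a VCF 4.2 file (GT-only
#' FORMAT) whose \code{##source} header records the full specification and
#' seed; byte-identical for identical specs.
#'
#' @param spec a [SimSpec-class].
#' @param path output VCF path.
#' @param truthPath optional TSV path for the ground-truth table.
#' @return list with \code{path}, \code{truth} and \code{channels}.
#' @export
generateCohortVcf <- function(spec, path = tempfile(fileext = ".vcf"),
                              truthPath = NULL) {
  cohort <- generateCohort(spec)
  codes <- cohort$codes
  info <- as.data.frame(SummarizedExperiment::rowData(cohort$channels))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[codes + 1], nrow = nrow(codes))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf(paste0("##source=cryptMendel(model=%s,nVariants=%d,",
                   "nImplanted=%d,bgProbs=%s,seed=%.0f)"),
            spec@model, spec@nVariants, spec@nImplanted,
            paste(spec@bgProbs, collapse = "|"), spec@seed),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(codes)), collapse = "\t"))
  body <- if (nrow(codes) > 0) {
    apply(cbind(info$chrom, info$pos, ".", info$ref, info$alt, ".", "PASS",
                ".", "GT", gtStr),
          1, paste, collapse = "\t")
  } else character()
  writeLines(c(header, body), path)
  if (!is.null(truthPath))
    utils::write.table(cohort$truth, truthPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(path = path, truth = cohort$truth, channels = cohort$channels)
}

#' Plaintext reference filter
#'
#' Evaluates the filtering circuits' algebra in the clear: for
#' recessive/dominant (or custom) queries a variant passes iff every
#' sample's two-channel code equals its target; for de novo iff one channel
#' is 1 for every affected and 0 for every unaffected sample.  This is the
#' oracle the encrypted path is verified against.
#'
#' @param channels a [GenotypeChannels-class].
#' @param query a [CohortQuery-class] (targets, or a de novo partition).
#' @return logical per-variant pass vector.
#' @export
referenceFilter <- function(channels, query) {
  f <- firstAllelic(channels)
  s <- secondAllelic(channels)
  if (query@model == "de_novo") {
    affIdx <- match(query@affected, colnames(f))
    unIdx <- match(query@unaffected, colnames(f))
    if (anyNA(affIdx) || anyNA(unIdx))
      stop("partition samples not present in channel matrices")
    passCh <- function(m) {
      affAll <- if (length(affIdx)) rowSums(m[, affIdx, drop = FALSE]) ==
        length(affIdx) else rep(TRUE, nrow(m))
      unNone <- if (length(unIdx)) rowSums(m[, unIdx, drop = FALSE]) == 0
        else rep(TRUE, nrow(m))
      affAll & unNone
    }
    return(unname(passCh(f) | passCh(s)))
  }
  idx <- match(query@sampleIds, colnames(f))
  if (anyNA(idx)) stop("query samples not present in channel matrices")
  f <- f[, idx, drop = FALSE]; s <- s[, idx, drop = FALSE]
  # slotwise indicator algebra in the clear: 1 - (v - q)^2 per channel
  indF <- 1 - sweep(f, 2, query@targets[, 1])^2
  indS <- 1 - sweep(s, 2, query@targets[, 2])^2
  unname(rowSums(indF) + rowSums(indS) == 2 * length(idx))
}

setMethod("show", "SimSpec", function(object) {
  cat("SimSpec:", object@nVariants, "variants,", nrow(object@roles),
      "samples,", object@model, "model,", object@nImplanted,
      "implanted, seed", object@seed, "\n")
})
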