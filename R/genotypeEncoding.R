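#' Encode VCF GT tokens as two-channel genotype bits
#'
#' Maps diploid GT tokens to the two-bit encrypted-domain code: the first
#' allelic channel is 1 iff the genotype is a disease-causing homozygote
#' (both alleles non-reference, e.g. "1/1"), the second channel is 1 iff it
#' is a disease-causing heterozygote (exactly one non-reference allele,
#' e.g. "0/1" or "2/0"); homozygous reference and fully missing calls map to
#' (0,0).  The code (1,1) is never produced.
#'
#' Conventions beyond the canonical table: phased "|" separators are treated
#' like "/" (the code is unordered); genotypes with two distinct non-zero
#' alleles (e.g. "1/2") carry a non-reference allele on both chromosomes and
#' encode as homozygous (1,0); half-missing calls ("./1") have one confirmed
#' non-reference allele and encode as heterozygous (0,1).  Both conventions
#' are flagged in the \code{"flagged"} attribute and summarized in a single
#' message.
#'
#' @param gt character vector of diploid GT tokens ("a/b" or "a|b"; allele
#'   symbols are non-negative integers or ".").
#' @return integer matrix with one row per token and columns
#'   \code{firstAllelic}, \code{secondAllelic}; attribute \code{"flagged"}
#'   is a data.frame of tokens encoded under the conventions above.
#' @examples
#' encodeGenotype(c("0/0", "./.", "1/1", "2/0", "0|1"))
#' @export
encodeGenotype <- function(gt) {
  stopifnot(is.character(gt))
  n <- length(gt)
  out <- matrix(0L, nrow = n, ncol = 2,
                dimnames = list(NULL, c("firstAllelic", "secondAllelic")))
  flagged <- list()
  if (n == 0) {
    attr(out, "flagged") <- data.frame(index = integer(), token = character(),
                                       reason = character())
    return(out)
  }
  parts <- strsplit(gt, "[/|]", perl = FALSE)
  for (i in seq_len(n)) {
    al <- parts[[i]]
    if (length(al) != 2) {
      if (length(al) >= 1 && all(grepl("^([0-9]+|\\.)$", al)))
        stop("unsupported ploidy in GT token '", gt[i],
             "': expected two alleles, got ", length(al))
      stop("malformed GT token '", gt[i], "'")
    }
    if (!all(grepl("^([0-9]+|\\.)$", al)))
      stop("malformed GT token '", gt[i], "'")
    missing <- al == "."
    nonzero <- !missing & al != "0" & !grepl("^0+$", al)
    k <- sum(nonzero)
    if (k == 2) {
      out[i, ] <- c(1L, 0L)
      if (al[1] != al[2])
        flagged[[length(flagged) + 1]] <-
          data.frame(index = i, token = gt[i],
                     reason = "distinct non-zero alleles encoded homozygous")
    } else if (k == 1) {
      out[i, ] <- c(0L, 1L)
      if (any(missing))
        flagged[[length(flagged) + 1]] <-
          data.frame(index = i, token = gt[i],
                     reason = "half-missing call encoded heterozygous")
    }
  }
  fl <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(index = integer(), token = character(), reason = character())
  if (nrow(fl) > 0)
    message(nrow(fl), " genotype(s) encoded under non-canonical conventions",
            " (see attr(, 'flagged'))")
  attr(out, "flagged") <- fl
  out
}

#' Construct a GenotypeChannels object
#'
#' @param first,second binary matrices (variants x samples) for the
#'   homozygous and heterozygous channels.
#' @param variantInfo optional data.frame of (chrom, pos, ref, alt) rows.
#' @param sampleIds sample names (defaults to \code{colnames(first)}).
#' @return a [GenotypeChannels-class].
#' @export
genotypeChannels <- function(first, second, variantInfo = NULL,
                             sampleIds = colnames(first)) {
  first <- as.matrix(first); second <- as.matrix(second)
  stopifnot(identical(dim(first), dim(second)))
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(first)))
  rownames(first) <- rownames(second) <- NULL
  colnames(first) <- colnames(second) <- sampleIds
  if (is.null(variantInfo))
    variantInfo <- data.frame(chrom = rep("chr1", nrow(first)),
                              pos = seq_len(nrow(first)),
                              ref = rep("A", nrow(first)),
                              alt = rep("T", nrow(first)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(firstAllelic = first, secondAllelic = second),
    rowData = S4Vectors::DataFrame(variantInfo))
  new("GenotypeChannels", se)
}

#' @describeIn GenotypeChannels-class the homozygous-channel bit matrix
#' @param x a [GenotypeChannels-class]
#' @export
setMethod("firstAllelic", "GenotypeChannels", function(x)
  SummarizedExperiment::assay(x, "firstAllelic"))

#' @describeIn GenotypeChannels-class the heterozygous-channel bit matrix
#' @export
setMethod("secondAllelic", "GenotypeChannels", function(x)
  SummarizedExperiment::assay(x, "secondAllelic"))

#' Read a multi-sample VCF into two-channel genotype matrices
#'
#' Parses the GT field of a VCF 4.x file (plain or bgzipped) and encodes
#' every call with [encodeGenotype()].  Row order follows the file, column
#' order follows the header sample order; FORMAT keys other than GT are
#' ignored.  GT must be the first FORMAT key.
#'
#' @param path VCF file path.
#' @return a [GenotypeChannels-class] with (chrom, pos, ref, alt) in its
#'   rowData.
#' @export
readVcfGenotypes <- function(path) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  nSamp <- max(ncol(vcf@gt) - 1L, 0L)
  sampleIds <- if (nSamp > 0) colnames(vcf@gt)[-1] else character()
  if (nrow(vcf@gt) == 0) {
    return(genotypeChannels(
      matrix(0L, 0, nSamp, dimnames = list(NULL, sampleIds)),
      matrix(0L, 0, nSamp, dimnames = list(NULL, sampleIds)),
      variantInfo = data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character())))
  }
  fmt <- vcf@gt[, "FORMAT"]
  firstKey <- vapply(strsplit(fmt, ":"), `[`, character(1), 1)
  if (!all(firstKey == "GT"))
    stop("format error: GT must be the first FORMAT key on every row")
  gtMat <- vcfR::extract.gt(vcf, element = "GT")
  gtMat[is.na(gtMat)] <- "./."
  enc <- encodeGenotype(as.vector(gtMat))
  first <- matrix(enc[, 1], nrow = nrow(gtMat), ncol = ncol(gtMat),
                  dimnames = dimnames(gtMat))
  second <- matrix(enc[, 2], nrow = nrow(gtMat), ncol = ncol(gtMat),
                   dimnames = dimnames(gtMat))
  info <- data.frame(chrom = vcf@fix[, "CHROM"],
                     pos = as.integer(vcf@fix[, "POS"]),
                     ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"])
  genotypeChannels(first, second, variantInfo = info,
                   sampleIds = colnames(gtMat))
}

#' Pack channel matrices into fixed-size slot blocks
#'
#' Partitions the variant rows into \code{ceiling(nVariants / slotCount)}
#' blocks.  The last block is zero-padded; its validity mask is 0 on padded
#' slots.  Padding uses the all-zero genotype code; downstream circuits
#' neutralize padded slots with the plaintext mask, so no "magic" pad
#' genotype is needed.
#'
#' @param x a [GenotypeChannels-class].
#' @param slotCount slots per block (>= 1).
#' @return a [VariantBlocks-class].
#' @aliases packBlocks
#' @export
setMethod("packBlocks", "GenotypeChannels", function(x, slotCount) {
  slotCount <- as.integer(slotCount)
  if (slotCount < 1L) stop("slotCount must be >= 1")
  f <- firstAllelic(x); s <- secondAllelic(x)
  n <- nrow(f); nSamp <- ncol(f)
  nBlocks <- if (n == 0) 0L else as.integer(ceiling(n / slotCount))
  blocks <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    lo <- (b - 1L) * slotCount + 1L
    hi <- min(b * slotCount, n)
    take <- lo:hi
    pad <- slotCount - length(take)
    padMat <- function(m) rbind(m[take, , drop = FALSE],
                                matrix(0, pad, nSamp))
    blocks[[b]] <- list(first = padMat(f), second = padMat(s),
                        validMask = c(rep(1, length(take)), rep(0, pad)),
                        blockIndex = b - 1L)
  }
  info <- as.data.frame(SummarizedExperiment::rowData(x))
  new("VariantBlocks", blocks = blocks, slotCount = slotCount,
      sampleIds = colnames(f), variantInfo = info, nVariants = as.integer(n))
})

#' Reassemble channel matrices from slot blocks
#'
#' Concatenates blocks in index order and drops masked (padding) slots,
#' reconstructing the original channel matrices exactly.
#'
#' @param x a [VariantBlocks-class].
#' @return a [GenotypeChannels-class].
#' @aliases unpackBlocks
#' @export
setMethod("unpackBlocks", "VariantBlocks", function(x) {
  nSamp <- length(x@sampleIds)
  if (length(x@blocks) == 0) {
    return(genotypeChannels(
      matrix(0L, 0, nSamp, dimnames = list(NULL, x@sampleIds)),
      matrix(0L, 0, nSamp, dimnames = list(NULL, x@sampleIds)),
      variantInfo = x@variantInfo, sampleIds = x@sampleIds))
  }
  ord <- order(vapply(x@blocks, function(b) b$blockIndex, integer(1)))
  f <- do.call(rbind, lapply(x@blocks[ord], function(b)
    b$first[b$validMask == 1, , drop = FALSE]))
  s <- do.call(rbind, lapply(x@blocks[ord], function(b)
    b$second[b$validMask == 1, , drop = FALSE]))
  genotypeChannels(f, s, variantInfo = x@variantInfo, sampleIds = x@sampleIds)
})

#' Write / read the encoded-matrix sidecar
#'
#' Serializes a [GenotypeChannels-class] to a JSON container (header with
#' sample order and variant count plus the two channel matrices) so that
#' encryption can run without re-parsing the VCF.
#'
#' @param x a [GenotypeChannels-class].
#' @param path output/input file path.
#' @return \code{writeEncodedChannels}: the path, invisibly;
#'   \code{readEncodedChannels}: a [GenotypeChannels-class].
#' @export
writeEncodedChannels <- function(x, path) {
  obj <- list(sampleIds = colnames(firstAllelic(x)),
              nVariants = nrow(firstAllelic(x)),
              variantInfo = as.data.frame(SummarizedExperiment::rowData(x)),
              firstAllelic = unname(firstAllelic(x)),
              secondAllelic = unname(secondAllelic(x)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEncodedChannels
#' @export
readEncodedChannels <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  nSamp <- length(obj$sampleIds)
  shape <- function(m) {
    m <- if (is.null(dim(m))) matrix(m, nrow = obj$nVariants, ncol = nSamp)
         else as.matrix(m)
    if (obj$nVariants == 0) m <- matrix(0L, 0, nSamp)
    m
  }
  genotypeChannels(shape(obj$firstAllelic), shape(obj$secondAllelic),
                   variantInfo = as.data.frame(obj$variantInfo),
                   sampleIds = obj$sampleIds)
}

setMethod("show", "VariantBlocks", function(object) {
  cat("VariantBlocks:", object@nVariants, "variants x",
      length(object@sampleIds), "samples in", length(object@blocks),
      "block(s) of", object@slotCount, "slots\n")
})
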