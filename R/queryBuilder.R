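.roleLevels <- c("proband", "mother", "father", "affected", "unaffected")

#' Describe cohort sample roles
#'
#' @param sampleIds character sample names in channel-matrix column order.
#' @param roles character roles, one of \code{proband}, \code{mother},
#'   \code{father}, \code{affected}, \code{unaffected}.
#' @return a validated data.frame (sampleId, role).
#' @export
cohortRoles <- function(sampleIds, roles) {
  stopifnot(length(sampleIds) == length(roles))
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
  bad <- setdiff(roles, .roleLevels)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  data.frame(sampleId = as.character(sampleIds), role = as.character(roles),
             stringsAsFactors = FALSE)
}

.targetQuery <- function(model, roles, targets) {
  dimnames(targets) <- list(roles$sampleId,
                            c("firstAllelic", "secondAllelic"))
  new("CohortQuery", model = model, targets = targets,
      sampleIds = roles$sampleId, affected = character(),
      unaffected = character())
}

#' Build a recessive-model query
#'
#' The recessive pattern: the proband carries the causal variant
#' homozygously (target code (1,0)), both parents are heterozygous carriers
#' (target (0,1)); any additional samples are expected not to carry the
#' disease genotype (target (0,0)).  Requires exactly one proband, one
#' mother and one father among the roles.
#'
#' @param roles a [cohortRoles()] data.frame.
#' @return a [CohortQuery-class].
#' @export
recessiveQuery <- function(roles) {
  counts <- table(factor(roles$role, levels = .roleLevels))
  if (counts["proband"] != 1)
    stop("pedigree error: recessive model requires exactly one proband")
  if (counts["mother"] != 1 || counts["father"] != 1)
    stop("pedigree error: recessive model requires both parents")
  tg <- t(vapply(roles$role, function(r) switch(r,
    proband = c(1, 0), mother = c(0, 1), father = c(0, 1), c(0, 0)),
    numeric(2)))
  .targetQuery("recessive", roles, tg)
}

#' Build a dominant-model query
#'
#' Affected individuals (roles \code{affected} or \code{proband}) are
#' expected heterozygous for the causal variant (target (0,1)); all other
#' samples are expected not to carry it (target (0,0)).  Requires at least
#' one affected sample.
#'
#' @param roles a [cohortRoles()] data.frame.
#' @return a [CohortQuery-class].
#' @export
dominantQuery <- function(roles) {
  aff <- roles$role %in% c("affected", "proband")
  if (!any(aff))
    stop("pedigree error: dominant model requires at least one affected sample")
  tg <- t(vapply(aff, function(a) if (a) c(0, 1) else c(0, 0), numeric(2)))
  .targetQuery("dominant", roles, tg)
}

#' Build a query from researcher-specified target patterns
#'
#' The recessive/dominant circuits are pattern-agnostic; any per-sample
#' genotype-code targets may be filtered for.
#'
#' @param sampleIds character sample names.
#' @param targets numeric matrix nSamples x 2 of target bits (no (1,1) row).
#' @param model label stored on the query (default "custom").
#' @return a [CohortQuery-class].
#' @export
customQuery <- function(sampleIds, targets, model = "custom") {
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) == length(sampleIds), ncol(targets) == 2)
  dimnames(targets) <- list(sampleIds, c("firstAllelic", "secondAllelic"))
  new("CohortQuery", model = model, targets = targets,
      sampleIds = as.character(sampleIds), affected = character(),
      unaffected = character())
}

#' Partition a cohort for the de novo model
#'
#' Affected samples (roles \code{affected} or \code{proband}) versus all
#' remaining samples.  The de novo circuits test for a variant of the same
#' genotype class present in every affected sample and absent from every
#' unaffected one.
#'
#' @param roles a [cohortRoles()] data.frame.
#' @return a [CohortQuery-class] with model "de_novo" and the partition in
#'   its \code{affected}/\code{unaffected} slots.
#' @export
deNovoPartition <- function(roles) {
  aff <- roles$role %in% c("affected", "proband")
  if (!any(aff))
    stop("pedigree error: de novo model requires at least one affected sample")
  new("CohortQuery", model = "de_novo",
      targets = matrix(numeric(0), 0, 2), sampleIds = roles$sampleId,
      affected = roles$sampleId[aff], unaffected = roles$sampleId[!aff])
}

#' Encrypt a query pattern
#'
#' Each per-sample target bit is replicated across every SIMD slot and
#' encrypted, yielding two ciphertexts per sample (one per channel).  The
#' result depends only on the target pattern, never on any variant data.
#'
#' @param backend a [MockBackend-class].
#' @param query a [CohortQuery-class] with targets (recessive/dominant or
#'   custom).
#' @param pk the collective [PublicKey-class].
#' @return an [EncryptedQuery-class].
#' @export
encryptQuery <- function(backend, query, pk) {
  stopifnot(is(query, "CohortQuery"))
  if (length(query@targets) == 0)
    stop("the de novo model uses an affected/unaffected partition, not ",
         "an encrypted target pattern")
  L <- backend@params@slotCount
  encBit <- function(b) heEncrypt(backend, rep(b, L), pk)
  new("EncryptedQuery", model = query@model,
      first = lapply(query@targets[, 1], encBit),
      second = lapply(query@targets[, 2], encBit),
      sampleIds = query@sampleIds, keyId = pk@keyId)
}

setMethod("show", "CohortQuery", function(object) {
  cat("CohortQuery:", object@model, "model,", length(object@sampleIds),
      "samples\n")
  if (object@model == "de_novo")
    cat("  affected:", length(object@affected),
        "| unaffected:", length(object@unaffected), "\n")
})
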