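#' @export
setGeneric("heEncrypt", function(backend, v, key) standardGeneric("heEncrypt"))

#' @export
setGeneric("heDecrypt", function(backend, ct, key) standardGeneric("heDecrypt"))

#' @export
setGeneric("heAdd", function(backend, a, b) standardGeneric("heAdd"))

#' @export
setGeneric("heSub", function(backend, a, b) standardGeneric("heSub"))

#' @export
setGeneric("heMul", function(backend, a, b) standardGeneric("heMul"))

#' @export
setGeneric("heAddPlain", function(backend, a, p) standardGeneric("heAddPlain"))

#' @export
setGeneric("heMulPlain", function(backend, a, p) standardGeneric("heMulPlain"))

#' @export
setGeneric("heAddMany", function(backend, cs) standardGeneric("heAddMany"))

#' @export
setGeneric("heMulMany", function(backend, cs) standardGeneric("heMulMany"))

#' @export
setGeneric("heSumSlots", function(backend, ct, nValid) standardGeneric("heSumSlots"))

#' @export
setGeneric("opCounts", function(backend) standardGeneric("opCounts"))

#' @export
setGeneric("resetOpCounts", function(backend) standardGeneric("resetOpCounts"))

#' @export
setGeneric("keygen", function(backend, seed = NULL) standardGeneric("keygen"))

#' @export
setGeneric("dkg", function(backend, committee, seed) standardGeneric("dkg"))

#' @export
setGeneric("partialDecrypt", function(backend, ct, share) standardGeneric("partialDecrypt"))

#' @export
setGeneric("packBlocks", function(x, slotCount) standardGeneric("packBlocks"))

#' @export
setGeneric("unpackBlocks", function(x) standardGeneric("unpackBlocks"))

#' @export
setGeneric("firstAllelic", function(x) standardGeneric("firstAllelic"))

#' @export
setGeneric("secondAllelic", function(x) standardGeneric("secondAllelic"))

#' @export
setGeneric("depthConsumed", function(x) standardGeneric("depthConsumed"))
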