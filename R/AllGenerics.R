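#' @rdname SampleSignal-class
#' @param x a `SampleSignal`
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SampleSignal-class
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))

#' @rdname SampleSignal-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname CnvCall-class
#' @param x a `CnvCall`
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))

#' @rdname CnvCall-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname CnvCall-class
#' @export
setGeneric("isNoCall", function(x) standardGeneric("isNoCall"))

#' @rdname CnvInterval-class
#' @param x a `CnvInterval`
#' @export
setGeneric("flankWidth", function(x) standardGeneric("flankWidth"))
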