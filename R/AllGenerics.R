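#' @rdname TCRRepertoireSet-class
#' @param x,object a `TCRRepertoireSet`.
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname TCRRepertoireSet-class
#' @export
setGeneric("repertoireSizes", function(x) standardGeneric("repertoireSizes"))

#' @rdname TCRRepertoireSet-class
#' @export
setGeneric("totalAbundances", function(x) standardGeneric("totalAbundances"))

#' @rdname TCRRepertoireSet-class
#' @export
setGeneric("repertoireSequences", function(x) standardGeneric("repertoireSequences"))

#' @rdname TCRRepertoireSet-class
#' @export
setGeneric("repertoireAbundances", function(x) standardGeneric("repertoireAbundances"))

#' @rdname HomologyKernel-class
#' @param x,object a `HomologyKernel`.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname HomologyKernel-class
#' @export
setGeneric("eigenRepair", function(x) standardGeneric("eigenRepair"))

#' @rdname HomologyKernel-class
#' @export
setGeneric("substitutionName", function(x) standardGeneric("substitutionName"))

#' @rdname TCRAssocResult-class
#' @param x,object a `TCRAssocResult`.
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
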