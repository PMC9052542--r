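#' @rdname TCRRepertoireSet-class
#' @export
setMethod("subjectIDs", "TCRRepertoireSet", function(x) x@subjects)

#' @rdname TCRRepertoireSet-class
#' @export
setMethod("repertoireSizes", "TCRRepertoireSet", function(x) {
    structure(vapply(x@sequences, length, integer(1)), names = x@subjects)
})

#' @rdname TCRRepertoireSet-class
#' @export
setMethod("totalAbundances", "TCRRepertoireSet", function(x) {
    structure(vapply(x@abundances, sum, numeric(1)), names = x@subjects)
})

#' @rdname TCRRepertoireSet-class
#' @export
setMethod("repertoireSequences", "TCRRepertoireSet", function(x) {
    structure(x@sequences, names = x@subjects)
})

#' @rdname TCRRepertoireSet-class
#' @export
setMethod("repertoireAbundances", "TCRRepertoireSet", function(x) {
    structure(x@abundances, names = x@subjects)
})

#' @rdname TCRRepertoireSet-class
#' @export
setMethod("length", "TCRRepertoireSet", function(x) length(x@subjects))

#' @rdname TCRRepertoireSet-class
#' @param i numeric, logical or character (subject ID) index.
#' @param j,drop,... unused.
#' @export
setMethod("[", "TCRRepertoireSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        idx <- match(i, x@subjects)
        if (anyNA(idx))
            stop("unknown subject ID(s): ", paste(i[is.na(idx)], collapse = ", "))
        i <- idx
    }
    new("TCRRepertoireSet",
        subjects = x@subjects[i],
        sequences = x@sequences[i],
        abundances = x@abundances[i])
})

setMethod("show", "TCRRepertoireSet", function(object) {
    n <- length(object)
    m <- repertoireSizes(object)
    cat(sprintf("TCRRepertoireSet with %d subject%s\n", n, if (n == 1) "" else "s"))
    cat(sprintf("  unique sequences per subject: %d-%d (median %g)\n",
                min(m), max(m), stats::median(m)))
    cat(sprintf("  total clones: %g\n", sum(totalAbundances(object))))
    invisible(object)
})

setMethod("show", "SubstitutionScheme", function(object) {
    cat(sprintf("SubstitutionScheme %s (gap open %g, extend %g)\n",
                object@name, object@gapOpen, object@gapExtend))
    invisible(object)
})

#' @rdname HomologyKernel-class
#' @export
setMethod("kernelMatrix", "HomologyKernel", function(x) x@matrix)

#' @rdname HomologyKernel-class
#' @export
setMethod("eigenRepair", "HomologyKernel", function(x) x@eigenRepair)

#' @rdname HomologyKernel-class
#' @export
setMethod("substitutionName", "HomologyKernel", function(x) x@scheme@name)

#' @rdname HomologyKernel-class
#' @export
setMethod("dim", "HomologyKernel", function(x) dim(x@matrix))

setMethod("show", "HomologyKernel", function(object) {
    n <- nrow(object@matrix)
    cat(sprintf("HomologyKernel: %d x %d (%s, gap %g/%g)\n", n, n,
                object@scheme@name, object@scheme@gapOpen, object@scheme@gapExtend))
    er <- object@eigenRepair
    if (isTRUE(er$repaired)) {
        cat(sprintf("  PSD repair: %d negative eigenvalue(s) zeroed (most negative %.3g)\n",
                    er$nClipped, er$minEigenvalue))
    } else {
        cat("  raw (no PSD repair applied)\n")
    }
    invisible(object)
})

#' @rdname TCRAssocResult-class
#' @export
setMethod("pValues", "TCRAssocResult", function(x) {
    c(fixed = x@pFixed, random = x@pRandom, combined = x@pCombined)
})

setMethod("show", "TCRAssocResult", function(object) {
    cat(sprintf("TCR repertoire association test (%s trait, mode '%s', n = %d)\n",
                object@traitType, object@mode, object@n))
    if (object@mode %in% c("fixed", "combined"))
        cat(sprintf("  fixed effect   : chi-square = %.4g on %d df, p = %.4g\n",
                    object@statFixed, object@r, object@pFixed))
    if (object@mode %in% c("random", "combined"))
        cat(sprintf("  random effect  : Q = %.4g (%s kernel), p = %.4g\n",
                    object@statRandom, object@schemeName, object@pRandom))
    if (object@mode == "combined")
        cat(sprintf("  Fisher combined: stat = %.4g, p = %.4g\n",
                    object@fisherStat, object@pCombined))
    invisible(object)
})
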