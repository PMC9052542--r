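#' @import methods
NULL

#' The 20 standard amino acids, alphabetical one-letter order
#'
#' Canonical residue ordering shared by the feature matrix and the
#' property-weight matrix.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Hydrophobicity index of the 20 standard amino acids (positive =
#' hydrophobic), named by one-letter code in the [AA_STANDARD] order.
#' Used as the default biochemical property weighting of the amino-acid
#' composition features.
#'
#' @format Named numeric vector of length 20.
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
KYTE_DOOLITTLE <- c(
    A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' TCRRepertoireSet: per-subject CDR3 repertoires
#'
#' Container for n subjects' TCR CDR3 repertoires.  For subject i the
#' repertoire is the set of m_i unique amino-acid sequences a_{i,k}
#' with positive integer clone abundances w_{i,k}.  Subject order is
#' stable and shared with covariate and phenotype containers.
#'
#' @slot subjects character vector of unique subject identifiers.
#' @slot sequences list of character vectors, one per subject, each the
#'   subject's unique CDR3 amino-acid sequences.
#' @slot abundances list of numeric vectors of clone counts, parallel
#'   to `sequences`.
#' @exportClass TCRRepertoireSet
setClass("TCRRepertoireSet",
    slots = c(subjects = "character",
              sequences = "list",
              abundances = "list"))

setValidity("TCRRepertoireSet", function(object) {
    n <- length(object@subjects)
    if (length(object@sequences) != n || length(object@abundances) != n)
        return("subjects, sequences and abundances must have equal length")
    if (anyDuplicated(object@subjects))
        return("subject identifiers must be unique")
    ok <- paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$")
    for (i in seq_len(n)) {
        sq <- object@sequences[[i]]
        w <- object@abundances[[i]]
        if (length(sq) < 1L)
            return(sprintf("subject '%s' has an empty repertoire", object@subjects[i]))
        if (length(sq) != length(w))
            return(sprintf("subject '%s': sequences and abundances differ in length",
                           object@subjects[i]))
        if (anyDuplicated(sq))
            return(sprintf("subject '%s' has duplicated sequences", object@subjects[i]))
        if (!all(grepl(ok, sq)))
            return(sprintf("subject '%s' has sequences outside the 20-letter amino-acid alphabet",
                           object@subjects[i]))
        if (any(!is.finite(w)) || any(w < 1) || any(w != round(w)))
            return(sprintf("subject '%s' has non-positive or non-integer abundances",
                           object@subjects[i]))
    }
    TRUE
})

#' Construct a TCRRepertoireSet
#'
#' @param subjects character vector of subject IDs.
#' @param sequences list of character vectors of unique CDR3 amino-acid
#'   sequences, one element per subject.
#' @param abundances list of positive integer clone counts parallel to
#'   `sequences`.
#' @return A [TCRRepertoireSet-class] object.
#' @examples
#' rs <- TCRRepertoireSet("s1", list(c("CASSLGRGKAFF", "CASSWLIGYTF")),
#'                        list(c(1, 9)))
#' repertoireSizes(rs)
#' @export
TCRRepertoireSet <- function(subjects, sequences, abundances) {
    new("TCRRepertoireSet",
        subjects = as.character(subjects),
        sequences = lapply(sequences, as.character),
        abundances = lapply(abundances, as.numeric))
}

#' SubstitutionScheme: scoring scheme for global alignment
#'
#' An amino-acid substitution matrix together with affine gap
#' penalties.  A gap of length L is charged `gapOpen + (L-1) * gapExtend`.
#'
#' @slot name matrix name, e.g. "BLOSUM62" or "PAM250".
#' @slot matrix symmetric numeric substitution matrix over the 20
#'   standard amino acids.
#' @slot gapOpen non-negative gap opening penalty.
#' @slot gapExtend non-negative gap extension penalty.
#' @exportClass SubstitutionScheme
setClass("SubstitutionScheme",
    slots = c(name = "character",
              matrix = "matrix",
              gapOpen = "numeric",
              gapExtend = "numeric"))

setValidity("SubstitutionScheme", function(object) {
    m <- object@matrix
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        return("substitution matrix must have matching row/column names")
    if (!isSymmetric(unname(m)))
        return("substitution matrix must be symmetric")
    if (!all(AA_STANDARD %in% rownames(m)))
        return("substitution matrix must cover the 20 standard amino acids")
    if (any(diag(m)[AA_STANDARD] <= 0))
        return("all standard-residue self-substitution scores must be positive")
    if (length(object@gapOpen) != 1L || object@gapOpen < 0)
        return("gapOpen must be a single non-negative number")
    if (length(object@gapExtend) != 1L || object@gapExtend < 0)
        return("gapExtend must be a single non-negative number")
    TRUE
})

#' HomologyKernel: repertoire-homology matrix between subjects
#'
#' The n x n abundance-weighted best-match repertoire homology matrix S.
#' The raw matrix is symmetric with unit diagonal; after the eigenvalue
#' repair of [psdProject()] it is positive semi-definite.
#'
#' @slot matrix numeric n x n symmetric matrix with subject IDs as
#'   dimnames.
#' @slot scheme the [SubstitutionScheme-class] used.
#' @slot eigenRepair list describing the PSD repair: `repaired` (logical),
#'   `nClipped` (negative eigenvalues zeroed) and `minEigenvalue`
#'   (most negative raw eigenvalue; NA before repair).
#' @exportClass HomologyKernel
setClass("HomologyKernel",
    slots = c(matrix = "matrix",
              scheme = "SubstitutionScheme",
              eigenRepair = "list"))

setValidity("HomologyKernel", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("kernel matrix must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        return("kernel matrix must carry subject IDs as symmetric dimnames")
    if (!isSymmetric(unname(m), tol = 1e-8))
        return("kernel matrix must be symmetric")
    TRUE
})

#' TCRAssocResult: outcome of a repertoire association test
#'
#' Holds the fixed-effect score test on weighted composition features,
#' the variance-component score test on the homology kernel, and their
#' Fisher combination, depending on the test mode.
#'
#' @slot mode one of "combined", "fixed", "random".
#' @slot traitType "binary" or "continuous".
#' @slot n number of subjects.
#' @slot r number of weighted features (fixed-effect df).
#' @slot dimD total column dimension q+1+r of the extended design.
#' @slot schemeName substitution matrix used for the kernel ("" if none).
#' @slot statFixed chi-square score statistic for the fixed effect.
#' @slot pFixed its p-value.
#' @slot statRandom standardized variance-component score statistic Q.
#' @slot pRandom its p-value.
#' @slot fisherStat Fisher combination statistic -2(log pFixed + log pRandom).
#' @slot pCombined chi-square(4) upper-tail p-value of fisherStat.
#' @exportClass TCRAssocResult
setClass("TCRAssocResult",
    slots = c(mode = "character",
              traitType = "character",
              n = "numeric",
              r = "numeric",
              dimD = "numeric",
              schemeName = "character",
              statFixed = "numeric",
              pFixed = "numeric",
              statRandom = "numeric",
              pRandom = "numeric",
              fisherStat = "numeric",
              pCombined = "numeric"))
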