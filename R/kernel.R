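#' Construct a substitution scheme
#'
#' Loads a named amino-acid substitution matrix (from the Biostrings
#' collection) restricted to the 20 standard residues, together with
#' affine gap penalties.  A gap of length L is charged
#' `gapOpen + (L-1) * gapExtend`; the defaults (10, 0.5) are the
#' EMBOSS needle defaults.
#'
#' @param name "BLOSUM62" or "PAM250" (any matrix shipped with
#'   Biostrings works), ignored if `matrix` is supplied.
#' @param gapOpen,gapExtend non-negative gap penalties.
#' @param matrix optional user substitution matrix (symmetric, with
#'   one-letter dimnames covering [AA_STANDARD]).
#' @return A [SubstitutionScheme-class].
#' @examples
#' substitutionScheme("BLOSUM62")
#' @export
substitutionScheme <- function(name = c("BLOSUM62", "PAM250"),
                               gapOpen = 10, gapExtend = 0.5,
                               matrix = NULL) {
    if (is.null(matrix)) {
        name <- match.arg(name)
        env <- new.env()
        utils::data(list = name, package = "Biostrings", envir = env)
        matrix <- get(name, envir = env)
    } else {
        name <- if (is.character(name)) name[1] else "custom"
    }
    matrix <- matrix[AA_STANDARD, AA_STANDARD]
    storage.mode(matrix) <- "double"
    new("SubstitutionScheme", name = name, matrix = matrix,
        gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

.checkSeqs <- function(x) {
    if (any(nchar(x) == 0L)) stop("empty sequence")
    ok <- grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"), x)
    if (!all(ok))
        stop("sequence(s) outside the standard amino-acid alphabet: ",
             paste(utils::head(x[!ok], 3), collapse = ", "))
    invisible(x)
}

#' Global alignment score between amino-acid sequences
#'
#' Optimal Needleman-Wunsch global alignment score d(a, b) under the
#' scheme's substitution matrix and affine gap penalty; vectorised over
#' pairs.
#'
#' @param a,b character vectors of equal length (recycled if one has
#'   length 1).
#' @param scheme a [SubstitutionScheme-class].
#' @return Numeric vector of alignment scores.
#' @examples
#' alignScore("CASS", "CASS", substitutionScheme("BLOSUM62"))  # 21
#' @export
alignScore <- function(a, b, scheme = substitutionScheme("BLOSUM62")) {
    stopifnot(is(scheme, "SubstitutionScheme"))
    if (length(a) == 1L) a <- rep(a, length(b))
    if (length(b) == 1L) b <- rep(b, length(a))
    .checkSeqs(a); .checkSeqs(b)
    cpp_align_score(a, b, scheme@matrix, rownames(scheme@matrix),
                    scheme@gapOpen, scheme@gapExtend)
}

#' Normalised sequence homology
#'
#' s(a, b) = d(a, b) / sqrt(d(a, a) d(b, b)), where d is the global
#' alignment score.  s(a, a) = 1; s can be negative when the raw
#' alignment score is negative (kept, not clipped).
#'
#' @inheritParams alignScore
#' @return Numeric vector of homologies, each at most 1.
#' @export
sequenceHomology <- function(a, b, scheme = substitutionScheme("BLOSUM62")) {
    d <- alignScore(a, b, scheme)
    daa <- alignScore(a, a, scheme)
    dbb <- alignScore(b, b, scheme)
    bad <- daa <= 0 | dbb <= 0
    if (any(bad))
        stop("non-positive self-alignment score for sequence(s): ",
             paste(utils::head(unique(c(a[daa <= 0], b[dbb <= 0])), 3),
                   collapse = ", "))
    d / sqrt(daa * dbb)
}

#' Repertoire homology between two subjects
#'
#' Abundance-weighted best-match homology: every sequence of one
#' repertoire finds its maximal homology s in the other repertoire,
#' weighted by its clone abundance, in both directions, and the total is
#' normalised by the combined clone count:
#' \deqn{S_{ij} = \frac{\sum_k w_{ik} \max_l s(a_{ik}, a_{jl}) +
#'   \sum_l w_{jl} \max_k s(a_{ik}, a_{jl})}{\sum_k w_{ik} + \sum_l w_{jl}}.}
#' This normalisation is the one under which the matrix is symmetric
#' with unit diagonal for arbitrary abundances.
#'
#' @param ri,rj single-subject [TCRRepertoireSet-class] objects (e.g.
#'   `rs[1]`).
#' @param scheme a [SubstitutionScheme-class].
#' @return A single homology value; 1 when the repertoires coincide.
#' @export
repertoireHomology <- function(ri, rj, scheme = substitutionScheme("BLOSUM62")) {
    stopifnot(is(ri, "TCRRepertoireSet"), is(rj, "TCRRepertoireSet"),
              length(ri) == 1L, length(rj) == 1L)
    cpp_repertoire_homology(ri@sequences[[1]], ri@abundances[[1]],
                            rj@sequences[[1]], rj@abundances[[1]],
                            scheme@matrix, rownames(scheme@matrix),
                            scheme@gapOpen, scheme@gapExtend)
}

#' Build the repertoire-homology kernel
#'
#' Computes the n x n matrix S of pairwise repertoire homologies
#' ([repertoireHomology()]) over all subject pairs (upper triangle,
#' mirrored), with the diagonal set to 1 analytically — within a
#' subject every sequence's best match is itself, with homology 1.
#'
#' @param rs a [TCRRepertoireSet-class] with at least 2 subjects.
#' @param scheme a [SubstitutionScheme-class].
#' @param repair if TRUE, apply [psdProject()] before returning.
#' @return A [HomologyKernel-class] (raw, i.e. unrepaired, unless
#'   `repair = TRUE`).
#' @export
buildKernel <- function(rs, scheme = substitutionScheme("BLOSUM62"),
                        repair = FALSE) {
    stopifnot(is(rs, "TCRRepertoireSet"), length(rs) >= 2L,
              is(scheme, "SubstitutionScheme"))
    S <- cpp_build_kernel(rs@sequences, rs@abundances,
                          scheme@matrix, rownames(scheme@matrix),
                          scheme@gapOpen, scheme@gapExtend)
    dimnames(S) <- list(subjectIDs(rs), subjectIDs(rs))
    k <- new("HomologyKernel", matrix = S, scheme = scheme,
             eigenRepair = list(repaired = FALSE, nClipped = NA_integer_,
                                minEigenvalue = NA_real_))
    if (repair) psdProject(k) else k
}

#' Project a homology kernel to positive semi-definite
#'
#' Eigendecomposes S, zeroes negative eigenvalues and reconstructs
#' S = sum over positive eigenvalues of lambda_k u_k u_k'.  If S is
#' already PSD (minimum eigenvalue >= -tol) it is returned unchanged.
#' The repair report (number of clipped eigenvalues, most negative raw
#' eigenvalue) is stored in the result's `eigenRepair` slot.
#'
#' @param k a [HomologyKernel-class].
#' @param tol negative-eigenvalue tolerance below which repair kicks in.
#' @return A PSD [HomologyKernel-class]; idempotent.
#' @export
psdProject <- function(k, tol = 1e-10) {
    stopifnot(is(k, "HomologyKernel"))
    S <- (k@matrix + t(k@matrix)) / 2
    e <- eigen(S, symmetric = TRUE)
    minEv <- min(e$values)
    if (minEv >= -tol) {
        k@eigenRepair <- list(repaired = FALSE, nClipped = 0L,
                              minEigenvalue = minEv)
        return(k)
    }
    pos <- e$values > 0
    S2 <- e$vectors[, pos, drop = FALSE] %*%
        (e$values[pos] * t(e$vectors[, pos, drop = FALSE]))
    S2 <- (S2 + t(S2)) / 2
    dimnames(S2) <- dimnames(k@matrix)
    new("HomologyKernel", matrix = S2, scheme = k@scheme,
        eigenRepair = list(repaired = TRUE, nClipped = sum(e$values < 0),
                           minEigenvalue = minEv))
}

#' Export / import a homology kernel
#'
#' `writeKernel()` writes the matrix as a TSV with subject IDs as header
#' row and first column, plus a JSON sidecar (`<path>.json`) holding the
#' substitution scheme and the eigen-repair report.  `readKernel()`
#' reverses it.
#'
#' @param k a [HomologyKernel-class].
#' @param path TSV file path (sidecar written next to it).
#' @return `writeKernel`: `path`, invisibly.  `readKernel`: a
#'   [HomologyKernel-class].
#' @export
writeKernel <- function(k, path) {
    stopifnot(is(k, "HomologyKernel"))
    df <- data.frame(subject_id = rownames(k@matrix), k@matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(matrix_name = k@scheme@name,
                 gap_open = k@scheme@gapOpen,
                 gap_extend = k@scheme@gapExtend,
                 eigen_repair = k@eigenRepair)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    S <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(S) <- "double"
    dimnames(S) <- list(ids, ids)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    scheme <- substitutionScheme(meta$matrix_name, meta$gap_open, meta$gap_extend)
    er <- meta$eigen_repair
    new("HomologyKernel", matrix = S, scheme = scheme,
        eigenRepair = list(repaired = isTRUE(er$repaired),
                           nClipped = as.integer(er$nClipped),
                           minEigenvalue = as.numeric(er$minEigenvalue)))
}
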