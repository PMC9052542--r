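#' Abundance-weighted amino-acid counts
#'
#' For each subject, the frequency g_j of amino acid j is the number of
#' occurrences of j across the repertoire's unique sequences, each
#' sequence weighted by its clone abundance:
#' g_j = sum_k w_k * (occurrences of j in sequence k).
#'
#' @param rs a [TCRRepertoireSet-class].
#' @return Integer-valued n x 20 matrix of counts, columns in
#'   [AA_STANDARD] order, rows named by subject.
#' @export
aminoAcidCounts <- function(rs) {
    stopifnot(is(rs, "TCRRepertoireSet"))
    n <- length(rs)
    out <- matrix(0, n, length(AA_STANDARD),
                  dimnames = list(subjectIDs(rs), AA_STANDARD))
    for (i in seq_len(n)) {
        chars <- strsplit(rs@sequences[[i]], "", fixed = TRUE)
        w <- rs@abundances[[i]]
        reps <- rep(w, lengths(chars))
        tab <- tapply(reps, factor(unlist(chars), levels = AA_STANDARD), sum)
        tab[is.na(tab)] <- 0
        out[i, ] <- tab
    }
    out
}

#' Per-subject amino-acid composition features
#'
#' Normalises [aminoAcidCounts()] row-wise to proportions, giving the
#' n x p feature matrix (p = 20) whose i-th row is the amino-acid
#' proportion vector f(R_i).  Rows sum to 1; amino acids absent from a
#' cohort get proportion 0 rather than shrinking p, so the matrix is
#' structured across cohorts.
#'
#' @param rs a [TCRRepertoireSet-class].
#' @return n x 20 matrix of proportions.
#' @export
featureMatrix <- function(rs) {
    counts <- aminoAcidCounts(rs)
    tot <- rowSums(counts)
    if (any(tot <= 0))
        stop("subject(s) with empty amino-acid counts: ",
             paste(rownames(counts)[tot <= 0], collapse = ", "))
    counts / tot
}

#' Default property-weight matrix
#'
#' The p x r matrix W of known biochemical characteristics used to
#' weight the composition features; by default a single column of
#' Kyte-Doolittle hydropathy values, so that W' f(R_i) is the
#' hydrophobicity score of subject i's repertoire weighted by amino-acid
#' proportions.
#'
#' @return 20 x 1 numeric matrix, rows in [AA_STANDARD] order.
#' @export
defaultWeightMatrix <- function() {
    matrix(KYTE_DOOLITTLE[AA_STANDARD], ncol = 1,
           dimnames = list(AA_STANDARD, "kyte_hydrophobicity"))
}

#' Read a property-weight matrix from a TSV file
#'
#' Expects a header, an `amino_acid` column of one-letter codes and one
#' numeric column per characteristic.  Rows are reordered to
#' [AA_STANDARD]; all 20 residues must be present.
#'
#' @param path file path.
#' @return p x r numeric matrix.
#' @export
readWeightMatrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!"amino_acid" %in% names(df))
        stop("weight file lacks an 'amino_acid' column")
    idx <- match(AA_STANDARD, df$amino_acid)
    if (anyNA(idx))
        stop("weight file must list all 20 standard amino acids")
    W <- as.matrix(df[idx, setdiff(names(df), "amino_acid"), drop = FALSE])
    storage.mode(W) <- "double"
    if (any(!is.finite(W))) stop("weight matrix has non-finite entries")
    rownames(W) <- AA_STANDARD
    W
}

#' Property-weighted features
#'
#' Computes the n x r matrix with i-th row W' f(R_i): each biochemical
#' characteristic averaged over the repertoire's amino-acid composition.
#'
#' @param F n x p feature matrix from [featureMatrix()].
#' @param W p x r weight matrix (default [defaultWeightMatrix()]).
#' @return n x r numeric matrix.
#' @export
weightedFeatures <- function(F, W = defaultWeightMatrix()) {
    W <- as.matrix(W)
    if (ncol(F) != nrow(W))
        stop("feature matrix has ", ncol(F), " columns but weight matrix has ",
             nrow(W), " rows")
    F %*% W
}

#' Shannon entropy of clone-abundance distributions
#'
#' The conventional repertoire diversity score: with q_k the proportion
#' of clones carried by the k-th unique sequence,
#' entropy = -sum_k q_k log q_k (natural log).  Zero for a single
#' sequence, log(m) for m uniformly abundant sequences.
#'
#' @param rs a [TCRRepertoireSet-class].
#' @return Named numeric vector, one entropy per subject.
#' @export
shannonEntropy <- function(rs) {
    stopifnot(is(rs, "TCRRepertoireSet"))
    vapply(rs@abundances, function(w) {
        q <- w / sum(w)
        -sum(q * log(q))
    }, numeric(1)) |> stats::setNames(subjectIDs(rs))
}
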