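# Independent oracles used across the suite.

# Exhaustive-path global alignment score: plain tree recursion over all
# monotone alignment paths, charging a gap run of length L as
# open + (L-1) * extend.  Exponential, fine for sequences up to ~6.
bruteAlignScore <- function(a, b, sub, open = 10, ext = 0.5) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    rec <- function(i, j, last) {
        if (i == 0L && j == 0L) return(0)
        best <- -Inf
        if (i > 0L && j > 0L)
            best <- max(best, rec(i - 1L, j - 1L, 0L) + sub[av[i], bv[j]])
        if (i > 0L)
            best <- max(best,
                        rec(i - 1L, j, 1L) - (if (last == 1L) ext else open))
        if (j > 0L)
            best <- max(best,
                        rec(i, j - 1L, 2L) - (if (last == 2L) ext else open))
        best
    }
    rec(length(av), length(bv), 0L)
}

# Brute-force abundance-weighted best-match repertoire homology via an
# explicit double loop over all sequence pairs.  `shom` is a function
# (a, b) -> s value, so the sequence-level scores can come from an
# independent source too.
bruteRepHomology <- function(seqs1, w1, seqs2, w2, shom) {
    m1 <- length(seqs1); m2 <- length(seqs2)
    smat <- matrix(NA_real_, m1, m2)
    for (k in seq_len(m1))
        for (l in seq_len(m2))
            smat[k, l] <- shom(seqs1[k], seqs2[l])
    num <- sum(w1 * apply(smat, 1, max)) + sum(w2 * apply(smat, 2, max))
    num / (sum(w1) + sum(w2))
}

# Dense-matrix variance-component score: forms P0 explicitly and uses
# the textbook trace formulas, independent of the package's low-rank
# computation.  Returns Q.
denseQ <- function(Z, resid, S, sigma2) {
    n <- nrow(Z); d <- ncol(Z)
    P0 <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
    U <- drop(t(resid) %*% S %*% resid)
    trSP0 <- sum(diag(S %*% P0))
    SP0 <- S %*% P0
    trSP0SP0 <- sum(diag(SP0 %*% SP0))
    v <- 2 * sigma2^2 * (trSP0SP0 - trSP0^2 / (n - d))
    (U - trSP0 * sigma2) / sqrt(v)
}

# Random amino-acid string of a given length.
randomPeptide <- function(len) {
    paste(sample(tcrhom::AA_STANDARD, len, replace = TRUE), collapse = "")
}

# Write a long-format repertoire table; rows = list of c(subject, seq, count).
writeToyTable <- function(rows, path,
                          header = c("subject_id", "cdr3_aa", "count")) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- header
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# Substitution matrices restricted to the standard alphabet, for oracles.
aaSubMatrix <- function(name) {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    m <- get(name, envir = env)
    m[tcrhom::AA_STANDARD, tcrhom::AA_STANDARD]
}
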