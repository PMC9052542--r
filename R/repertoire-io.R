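#' Read a long-format repertoire table
#'
#' Reads a delimited text file with one row per (subject, CDR3 sequence)
#' and groups it into a [TCRRepertoireSet-class].  Rows that repeat the
#' same (subject, sequence) pair have their abundances summed.  Subject
#' order is first-appearance order.
#'
#' @param path path to a delimited text file with a header.
#' @param sep field delimiter (tab by default).
#' @param cols named character vector mapping the roles `subject`,
#'   `sequence` and `count` to column names in the file, so that AIRR-
#'   or MiXCR-style exports can be read without conversion.
#' @return A [TCRRepertoireSet-class].
#' @details Validation is strict: a non-positive or non-integer
#'   abundance, or a sequence containing a letter outside the 20
#'   standard amino-acid codes, is an error naming the offending row —
#'   nothing is silently dropped, so cohort composition stays
#'   reproducible.
#' @export
readRepertoireTable <- function(path, sep = "\t",
                                cols = c(subject = "subject_id",
                                         sequence = "cdr3_aa",
                                         count = "count")) {
    need <- c("subject", "sequence", "count")
    if (!all(need %in% names(cols)))
        stop("'cols' must map the roles: ", paste(need, collapse = ", "))
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
        stop("repertoire table '", path, "' is empty")
    missing <- setdiff(unname(cols[need]), names(df))
    if (length(missing))
        stop("repertoire table lacks required column(s): ",
             paste(missing, collapse = ", "))
    subj <- df[[cols[["subject"]]]]
    seqs <- df[[cols[["sequence"]]]]
    cnt <- suppressWarnings(as.numeric(df[[cols[["count"]]]]))
    bad <- which(!is.finite(cnt) | cnt < 1 | cnt != round(cnt))
    if (length(bad))
        stop("non-positive or non-integer abundance at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    ok <- grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"), seqs)
    if (!all(ok))
        stop("sequence with non-standard amino-acid letter at row(s): ",
             paste(utils::head(which(!ok), 5), collapse = ", "))
    order_ids <- unique(subj)
    sequences <- vector("list", length(order_ids))
    abundances <- vector("list", length(order_ids))
    for (i in seq_along(order_ids)) {
        sel <- subj == order_ids[i]
        w <- tapply(cnt[sel], factor(seqs[sel], levels = unique(seqs[sel])), sum)
        sequences[[i]] <- names(w)
        abundances[[i]] <- as.numeric(w)
    }
    TCRRepertoireSet(order_ids, sequences, abundances)
}

#' Write a repertoire set as a long-format table
#'
#' Inverse of [readRepertoireTable()]; round-trips sequences, abundances
#' and subject order exactly.
#'
#' @param rs a [TCRRepertoireSet-class].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeRepertoireTable <- function(rs, path, sep = "\t") {
    df <- data.frame(
        subject_id = rep(rs@subjects, lengths(rs@sequences)),
        cdr3_aa = unlist(rs@sequences, use.names = FALSE),
        count = unlist(rs@abundances, use.names = FALSE),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Drop subjects with too few unique sequences
#'
#' Subjects whose repertoire holds fewer than `minUnique` unique CDR3
#' sequences carry no within-repertoire information and are excluded
#' (the conventional floor is 2).
#'
#' @param rs a [TCRRepertoireSet-class].
#' @param minUnique minimum number of unique sequences to keep a subject.
#' @return The filtered [TCRRepertoireSet-class]; excluded subject IDs
#'   are reported via [message()].
#' @export
filterMinUnique <- function(rs, minUnique = 2) {
    stopifnot(is(rs, "TCRRepertoireSet"), minUnique >= 1)
    keep <- repertoireSizes(rs) >= minUnique
    if (!any(keep))
        stop("no subjects left after filtering at minUnique = ", minUnique)
    if (any(!keep))
        message("filterMinUnique: excluded ", sum(!keep), " subject(s): ",
                paste(rs@subjects[!keep], collapse = ", "))
    rs[which(keep)]
}

#' Join repertoires, covariates and phenotype on subject ID
#'
#' Inner-joins the three inputs in repertoire order.  Subjects missing
#' from any table (or with missing values) are dropped with a reported
#' count.
#'
#' @param rs a [TCRRepertoireSet-class].
#' @param covariates data.frame with a subject-ID column (`idColumn`)
#'   and numeric confounder columns, or NULL for intercept-only designs.
#' @param phenotype named numeric vector (names = subject IDs), or a
#'   two-column data.frame (ID, value).
#' @param idColumn name of the subject-ID column in `covariates` (and
#'   `phenotype` if given as a data.frame).
#' @return list with `repertoires` (reordered [TCRRepertoireSet-class]),
#'   `X` (n x (q+1) design matrix with leading intercept column) and
#'   `y` (numeric phenotype vector in the same order).
#' @export
alignCohort <- function(rs, covariates = NULL, phenotype,
                        idColumn = "subject_id") {
    stopifnot(is(rs, "TCRRepertoireSet"))
    if (is.data.frame(phenotype)) {
        if (!idColumn %in% names(phenotype))
            stop("phenotype data.frame lacks ID column '", idColumn, "'")
        valcol <- setdiff(names(phenotype), idColumn)[1]
        phenotype <- stats::setNames(as.numeric(phenotype[[valcol]]),
                                     as.character(phenotype[[idColumn]]))
    }
    if (is.null(names(phenotype)))
        stop("phenotype must carry subject IDs as names")
    ids <- subjectIDs(rs)
    keep <- ids[ids %in% names(phenotype)[!is.na(phenotype)]]
    if (!is.null(covariates)) {
        if (!idColumn %in% names(covariates))
            stop("covariate table lacks ID column '", idColumn, "'")
        cov_ids <- as.character(covariates[[idColumn]])
        complete <- cov_ids[stats::complete.cases(covariates)]
        keep <- keep[keep %in% complete]
    }
    if (length(keep) == 0L)
        stop("no subjects shared between repertoires, covariates and phenotype")
    dropped <- length(ids) - length(keep)
    if (dropped > 0)
        message("alignCohort: dropped ", dropped,
                " subject(s) missing covariates or phenotype")
    rs2 <- rs[keep]
    y <- unname(phenotype[keep])
    if (is.null(covariates)) {
        X <- matrix(1, length(keep), 1, dimnames = list(keep, "(Intercept)"))
    } else {
        m <- covariates[match(keep, as.character(covariates[[idColumn]])), ,
                        drop = FALSE]
        num <- as.matrix(m[setdiff(names(m), idColumn)])
        storage.mode(num) <- "double"
        X <- cbind("(Intercept)" = 1, num)
        rownames(X) <- keep
    }
    list(repertoires = rs2, X = X, y = y)
}
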