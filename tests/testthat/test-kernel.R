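b62 <- substitutionScheme("BLOSUM62")
p250 <- substitutionScheme("PAM250")

test_that("alignment scores match identity sums and the Biostrings aligner", {
    # self-alignment of CASS under BLOSUM62: C9 + A4 + S4 + S4
    expect_equal(alignScore("CASS", "CASS", b62), 21)
    set.seed(14)
    for (i in 1:25) {
        a <- randomPeptide(sample(3:12, 1))
        b <- randomPeptide(sample(3:12, 1))
        # same affine convention: Biostrings charges open+ext on the first
        # gap position, so gapOpening = open - ext reproduces open+(L-1)ext
        ref <- Biostrings::pairwiseAlignment(
            a, b, substitutionMatrix = "BLOSUM62",
            gapOpening = 9.5, gapExtension = 0.5,
            type = "global", scoreOnly = TRUE)
        expect_equal(alignScore(a, b, b62), ref)
    }
    expect_error(alignScore("", "CASS", b62), "empty|outside the standard")
    expect_error(alignScore("CAXS", "CASS", b62), "outside the standard")
})

test_that("alignment equals the exhaustive-path oracle on short pairs", {
    B62 <- aaSubMatrix("BLOSUM62")
    set.seed(15)
    for (i in 1:60) {
        a <- randomPeptide(sample(1:6, 1))
        b <- randomPeptide(sample(1:6, 1))
        expect_equal(alignScore(a, b, b62), bruteAlignScore(a, b, B62),
                     info = paste(a, b))
    }
    # non-default gap penalties flow through
    sch <- substitutionScheme("BLOSUM62", gapOpen = 4, gapExtend = 2)
    for (i in 1:20) {
        a <- randomPeptide(sample(1:5, 1))
        b <- randomPeptide(sample(1:5, 1))
        expect_equal(alignScore(a, b, sch),
                     bruteAlignScore(a, b, B62, open = 4, ext = 2))
    }
})

test_that("sequence homology is normalised, symmetric, can be negative", {
    set.seed(16)
    seqs <- simulateCDR3(10)
    expect_equal(sequenceHomology(seqs, seqs, b62), rep(1, 10))
    a <- seqs[1:5]; b <- seqs[6:10]
    expect_equal(sequenceHomology(a, b, p250), sequenceHomology(b, a, p250))
    expect_true(all(sequenceHomology(a, b, b62) <= 1))
    # short dissimilar pair under a heavy gap penalty: d < 0, s < 0, kept
    heavy <- substitutionScheme("BLOSUM62", gapOpen = 20, gapExtend = 5)
    expect_lt(alignScore("W", "DDDD", heavy), 0)
    expect_lt(sequenceHomology("W", "DDDD", heavy), 0)
})

test_that("repertoire homology equals the brute-force double loop", {
    # short sequences so the sequence scores can come from the
    # exhaustive-path oracle end to end
    B62 <- aaSubMatrix("BLOSUM62")
    shomOracle <- function(a, b)
        bruteAlignScore(a, b, B62) /
            sqrt(bruteAlignScore(a, a, B62) * bruteAlignScore(b, b, B62))
    set.seed(17)
    for (rep in 1:5) {
        s1 <- unique(replicate(3, randomPeptide(sample(2:5, 1))))
        s2 <- unique(replicate(3, randomPeptide(sample(2:5, 1))))
        w1 <- sample(1:5, length(s1), replace = TRUE)
        w2 <- sample(1:5, length(s2), replace = TRUE)
        ri <- TCRRepertoireSet("i", list(s1), list(w1))
        rj <- TCRRepertoireSet("j", list(s2), list(w2))
        expect_equal(repertoireHomology(ri, rj, b62),
                     bruteRepHomology(s1, w1, s2, w2, shomOracle),
                     tolerance = 1e-12)
    }
    # identical repertoires (and identical singleton sequences) give 1
    ri <- TCRRepertoireSet("i", list("CASSLGRGKAFF"), list(2))
    rj <- TCRRepertoireSet("j", list("CASSLGRGKAFF"), list(5))
    expect_equal(repertoireHomology(ri, rj, b62), 1)
    set.seed(18)
    rs <- simulateRepertoireSet(2)
    same <- TCRRepertoireSet(c("a", "b"),
                             rep(repertoireSequences(rs)[1], 2),
                             rep(repertoireAbundances(rs)[1], 2))
    expect_equal(repertoireHomology(same[1], same[2], p250), 1)
})

test_that("planting a shared sequence never decreases repertoire homology", {
    set.seed(19)
    for (rep in 1:10) {
        rs <- simulateRepertoireSet(2)
        ri <- rs[1]; rj <- rs[2]
        before <- repertoireHomology(ri, rj, b62)
        seqs_j <- repertoireSequences(rj)[[1]]
        shared <- setdiff(repertoireSequences(ri)[[1]], seqs_j)[1]
        if (is.na(shared)) next
        seqs_j[1] <- shared  # shared is absent from seqs_j, so still unique
        rj2 <- TCRRepertoireSet("j2", list(seqs_j),
                                list(repertoireAbundances(rj)[[1]]))
        expect_gte(repertoireHomology(ri, rj2, b62), before - 1e-12)
    }
})

test_that("buildKernel composes pairwise homologies with unit diagonal", {
    set.seed(20)
    rs <- simulateRepertoireSet(3)
    k <- buildKernel(rs, b62)
    S <- kernelMatrix(k)
    expect_identical(rownames(S), subjectIDs(rs))
    expect_equal(diag(S), setNames(rep(1, 3), subjectIDs(rs)))
    for (i in 1:2) for (j in (i + 1):3)
        expect_equal(S[i, j], repertoireHomology(rs[i], rs[j], b62))
    expect_identical(S, t(S))

    # two identical subjects: all-ones 2x2 block
    twin <- TCRRepertoireSet(c("t1", "t2"),
                             rep(repertoireSequences(rs)[1], 2),
                             rep(repertoireAbundances(rs)[1], 2))
    expect_equal(unname(kernelMatrix(buildKernel(twin, b62))),
                 matrix(1, 2, 2))
})

test_that("psdProject clips negative eigenvalues and is idempotent", {
    sch <- b62
    # identity kernel is untouched
    kI <- new("HomologyKernel",
              matrix = diag(3) |> (\(m) {dimnames(m) <- list(letters[1:3], letters[1:3]); m})(),
              scheme = sch,
              eigenRepair = list(repaired = FALSE, nClipped = NA_integer_,
                                 minEigenvalue = NA_real_))
    expect_equal(kernelMatrix(psdProject(kI)), kernelMatrix(kI))

    # 2x2 indefinite case: eigenvalues 2.2 and -0.2; the repair keeps the
    # rank-one part 1.1 * u u' with u = (1, -1)/sqrt(2)
    M <- matrix(c(1, -1.2, -1.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
    k <- new("HomologyKernel", matrix = M, scheme = sch,
             eigenRepair = list(repaired = FALSE, nClipped = NA_integer_,
                                minEigenvalue = NA_real_))
    kp <- psdProject(k)
    expect_true(eigenRepair(kp)$repaired)
    expect_equal(eigenRepair(kp)$nClipped, 1L)
    expect_equal(eigenRepair(kp)$minEigenvalue, -0.2)
    expect_equal(unname(kernelMatrix(kp)),
                 2.2 * tcrossprod(c(1, -1) / sqrt(2)))
    # Frobenius error of the repair equals the clipped eigenvalue mass
    expect_equal(norm(M - kernelMatrix(kp), "F"), sqrt(0.2^2))
    # idempotent
    expect_equal(kernelMatrix(psdProject(kp)), kernelMatrix(kp))
    expect_gte(min(eigen(kernelMatrix(kp), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
})

test_that("kernel TSV + JSON sidecar round-trips", {
    set.seed(21)
    rs <- simulateRepertoireSet(4)
    k <- psdProject(buildKernel(rs, p250))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeKernel(k, path)
    expect_true(file.exists(paste0(path, ".json")))
    k2 <- readKernel(path)
    expect_equal(kernelMatrix(k2), kernelMatrix(k), tolerance = 1e-12)
    expect_identical(substitutionName(k2), "PAM250")
    expect_equal(eigenRepair(k2)$minEigenvalue, eigenRepair(k)$minEigenvalue)
})
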