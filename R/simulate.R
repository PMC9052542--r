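# Synthetic CDR3 repertoire generator: head segment + random middle
# (with 0-2 inserted residues emulating P/N nucleotide addition) + tail
# segment, and cohort-level trait models for type-I-error / power studies.

.CDR3_HEADS <- c(CASS = 0.7, CASR = 0.1, CSAR = 0.1, CAST = 0.1)
.CDR3_TAILS <- c(YF = 0.4, FF = 0.4, HF = 0.1, TF = 0.1)

#' Simulate CDR3 amino-acid sequences
#'
#' Each sequence is a 4-residue head (CASS/CASR/CSAR/CAST with
#' probabilities 0.7/0.1/0.1/0.1), a middle segment of 4-10 residues
#' drawn uniformly with replacement from the 20 amino acids with 0-2
#' additional residues inserted at uniform positions (the P/N-addition
#' analogue), and a 2-residue tail (YF/FF/HF/TF with probabilities
#' 0.4/0.4/0.1/0.1).  Total length is 10-18.
#'
#' @param n number of sequences.
#' @param middleRange integer vector of admissible base middle lengths.
#' @param insertions integer vector of admissible insertion counts,
#'   drawn uniformly.
#' @return Character vector of `n` CDR3 sequences.
#' @export
simulateCDR3 <- function(n = 1, middleRange = 4:10, insertions = 0:2) {
    heads <- sample(names(.CDR3_HEADS), n, replace = TRUE, prob = .CDR3_HEADS)
    tails <- sample(names(.CDR3_TAILS), n, replace = TRUE, prob = .CDR3_TAILS)
    mlen <- middleRange[sample.int(length(middleRange), n, replace = TRUE)]
    nins <- insertions[sample.int(length(insertions), n, replace = TRUE)]
    mids <- vapply(seq_len(n), function(i) {
        mid <- AA_STANDARD[sample.int(20L, mlen[i], replace = TRUE)]
        for (k in seq_len(nins[i])) {
            pos <- sample.int(length(mid) + 1L, 1L) - 1L
            mid <- append(mid, AA_STANDARD[sample.int(20L, 1L)], after = pos)
        }
        paste(mid, collapse = "")
    }, character(1))
    paste0(heads, mids, tails)
}

#' Simulate a cohort of repertoires
#'
#' Per subject, the number of unique sequences m_i is uniform on
#' `uniqueRange` (2-25), sequences are drawn by [simulateCDR3()]
#' (redrawn until unique within the subject) and each clone abundance
#' is uniform on `countRange` (1-5).
#'
#' @param n number of subjects (>= 2).
#' @param uniqueRange integer vector of admissible unique-sequence
#'   counts.
#' @param countRange integer vector of admissible clone abundances.
#' @param prefix subject-ID prefix.
#' @return A [TCRRepertoireSet-class].
#' @export
simulateRepertoireSet <- function(n, uniqueRange = 2:25, countRange = 1:5,
                                  prefix = "S") {
    stopifnot(n >= 2)
    m <- uniqueRange[sample.int(length(uniqueRange), n, replace = TRUE)]
    sequences <- lapply(m, function(mi) {
        s <- unique(simulateCDR3(mi))
        while (length(s) < mi)
            s <- unique(c(s, simulateCDR3(mi - length(s))))
        s
    })
    abundances <- lapply(m, function(mi)
        countRange[sample.int(length(countRange), mi, replace = TRUE)])
    TCRRepertoireSet(sprintf("%s%04d", prefix, seq_len(n)), sequences, abundances)
}

#' Simulate confounding covariates
#'
#' Design matrix `[1, X1, X2]` with X1 ~ Bernoulli(0.5) and
#' X2 ~ N(0, 1).
#'
#' @param n number of subjects.
#' @return n x 3 numeric matrix.
#' @export
simulateCovariates <- function(n) {
    cbind("(Intercept)" = 1,
          X1 = stats::rbinom(n, 1, 0.5),
          X2 = stats::rnorm(n))
}

# Square root of a kernel for drawing N(0, S): eigendecompose, clip
# tiny negatives, return V diag(sqrt(lambda)).
.kernelRoot <- function(kernel) {
    S <- if (is(kernel, "HomologyKernel")) kernelMatrix(kernel) else as.matrix(kernel)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop("generating kernel is not positive semi-definite; apply psdProject()")
    ev <- pmax(e$values, 0)
    e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Simulate a phenotype from the mixed model
#'
#' Linear predictor `X beta + G eta + h` with `h = sqrt(tau2) *
#' kernelRoot z`, `z ~ N(0, I)`.  Continuous traits add N(0, 1) noise;
#' binary traits are Bernoulli draws through the logistic link,
#' redrawn (the trait only, keeping design and random effect fixed)
#' until each class holds at least `ceiling(imbalanceFloor * n)`
#' subjects.
#'
#' @param X covariate design matrix (with intercept column).
#' @param G optional n x r weighted-feature matrix (required when `eta`
#'   is nonzero).
#' @param traitType "binary" or "continuous".
#' @param beta regression coefficients for `X` (default
#'   `c(0.1, 0.5, -0.4)`).
#' @param eta fixed-effect coefficients for `G` (scalar or r-vector);
#'   0 disables the fixed effect.
#' @param tau2 variance of the repertoire random effect; 0 disables it.
#' @param kernelRoot n x n square root of the generating kernel
#'   (see [psdProject()]), required when `tau2 > 0`.
#' @param imbalanceFloor minimum class fraction for binary traits.
#' @param maxRedraw redraw budget before giving up.
#' @return Numeric phenotype vector of length n.
#' @export
simulateTrait <- function(X, G = NULL,
                          traitType = c("binary", "continuous"),
                          beta = c(0.1, 0.5, -0.4),
                          eta = 0, tau2 = 0, kernelRoot = NULL,
                          imbalanceFloor = 0.10, maxRedraw = 1000) {
    traitType <- match.arg(traitType)
    X <- as.matrix(X)
    n <- nrow(X)
    if (length(beta) != ncol(X))
        stop("length(beta) must equal ncol(X)")
    lp <- drop(X %*% beta)
    if (any(eta != 0)) {
        if (is.null(G)) stop("eta != 0 requires the weighted-feature matrix G")
        lp <- lp + drop(as.matrix(G) %*% rep(eta, length.out = ncol(as.matrix(G))))
    }
    if (tau2 > 0) {
        if (is.null(kernelRoot)) stop("tau2 > 0 requires 'kernelRoot'")
        lp <- lp + sqrt(tau2) * drop(kernelRoot %*% stats::rnorm(n))
    }
    if (traitType == "continuous")
        return(lp + stats::rnorm(n))
    prob <- stats::plogis(lp)
    floorCount <- ceiling(imbalanceFloor * n)
    for (k in seq_len(maxRedraw)) {
        y <- stats::rbinom(n, 1, prob)
        if (min(sum(y), n - sum(y)) >= floorCount) return(y)
    }
    stop("could not draw a binary trait with both classes >= ",
         floorCount, " in ", maxRedraw, " attempts")
}

#' Configure a simulation study
#'
#' Bundles and validates the settings of a type-I-error or power study.
#' Effect sizes default to the scenario- and trait-specific values used
#' throughout the package's calibration studies: under `fixed_only`,
#' eta = 1.6 (binary) / 0.8 (continuous); under `random_only`,
#' tau2 = 8 (binary) / 0.8 (continuous); under `both`, eta = 1 and
#' tau2 = 6 (binary) / eta = 0.5 and tau2 = 0.6 (continuous).
#'
#' @param n subjects per replicate.
#' @param traitType "binary" or "continuous".
#' @param scenario "null", "fixed_only", "random_only" or "both".
#' @param replicates number of Monte-Carlo replicates.
#' @param seed RNG seed for the whole study.
#' @param fixedCohort if TRUE (the speed mode) repertoires, covariates
#'   and kernels are drawn once and only the trait is redrawn per
#'   replicate; if FALSE everything is regenerated each replicate.
#' @param generatingScheme substitution matrix behind the generating
#'   kernel of the random effect.
#' @param analysisSchemes substitution matrices used for analysis
#'   kernels (may differ from `generatingScheme`).
#' @param beta covariate coefficients.
#' @param eta,tau2 effect sizes (NULL = scenario default).
#' @param alpha significance level for rejection rates.
#' @param gapOpen,gapExtend alignment gap penalties.
#' @param alternative tail for the variance-component p-value.
#' @param imbalanceFloor minimum binary class fraction.
#' @return A validated list of class `tcrStudyConfig`.
#' @export
studyConfig <- function(n = 200, traitType = c("binary", "continuous"),
                        scenario = c("null", "fixed_only", "random_only", "both"),
                        replicates = 1000, seed = 1,
                        fixedCohort = TRUE,
                        generatingScheme = "BLOSUM62",
                        analysisSchemes = c("BLOSUM62", "PAM250"),
                        beta = c(0.1, 0.5, -0.4),
                        eta = NULL, tau2 = NULL,
                        alpha = 0.05, gapOpen = 10, gapExtend = 0.5,
                        alternative = "greater",
                        imbalanceFloor = 0.10) {
    traitType <- match.arg(traitType)
    scenario <- match.arg(scenario)
    if (is.null(eta))
        eta <- switch(scenario,
                      null = 0, random_only = 0,
                      fixed_only = if (traitType == "binary") 1.6 else 0.8,
                      both = if (traitType == "binary") 1.0 else 0.5)
    if (is.null(tau2))
        tau2 <- switch(scenario,
                       null = 0, fixed_only = 0,
                       random_only = if (traitType == "binary") 8 else 0.8,
                       both = if (traitType == "binary") 6 else 0.6)
    stopifnot(n >= 10, replicates >= 1, tau2 >= 0, alpha > 0, alpha < 1)
    structure(list(n = n, traitType = traitType, scenario = scenario,
                   replicates = replicates, seed = seed,
                   fixedCohort = fixedCohort,
                   generatingScheme = generatingScheme,
                   analysisSchemes = analysisSchemes,
                   beta = beta, eta = eta, tau2 = tau2, alpha = alpha,
                   gapOpen = gapOpen, gapExtend = gapExtend,
                   alternative = alternative,
                   imbalanceFloor = imbalanceFloor),
              class = "tcrStudyConfig")
}

.schemeLabel <- function(name) {
    switch(name, BLOSUM62 = "b62", PAM250 = "p250", tolower(name))
}

#' Run a simulation study
#'
#' Per replicate: simulate repertoires, covariates and trait under the
#' configured scenario, then apply the five methods — the
#' extracted-features test (`fixed`), the homology-kernel-only tests
#' under each analysis scheme (`seq_*`), and the combined mixed-effects
#' tests (`mixed_*`) — and record their p-values.  Rejection rates at
#' `alpha` are reported with binomial Monte-Carlo standard errors.
#'
#' @param config a [studyConfig()] object.
#' @param kernels optional named list of precomputed, PSD-repaired
#'   [HomologyKernel-class] objects (names = scheme names) for the
#'   fixed-cohort mode; also requires `cohort`.
#' @param cohort optional list with `repertoires`, `X` matching
#'   `kernels`, for reusing one simulated cohort across several studies.
#' @return An object of class `tcrStudy`: list with `pvalues`
#'   (replicate x method data.frame, including the H0'-based
#'   variance-component p-values `vc_*` that enter the combination),
#'   `rates` (method, rejections, rate, se) and `config`.
#' @export
runStudy <- function(config, kernels = NULL, cohort = NULL) {
    stopifnot(inherits(config, "tcrStudyConfig"))
    set.seed(config$seed)
    schemes <- config$analysisSchemes
    labels <- vapply(schemes, .schemeLabel, character(1))
    W <- defaultWeightMatrix()

    makeCohort <- function() {
        rs <- simulateRepertoireSet(config$n)
        X <- simulateCovariates(config$n)
        G <- weightedFeatures(featureMatrix(rs), W)
        ks <- lapply(schemes, function(s)
            psdProject(buildKernel(rs, substitutionScheme(
                s, config$gapOpen, config$gapExtend))))
        names(ks) <- schemes
        gen <- if (config$tau2 > 0) {
            gk <- if (config$generatingScheme %in% schemes)
                ks[[config$generatingScheme]]
            else psdProject(buildKernel(rs, substitutionScheme(
                config$generatingScheme, config$gapOpen, config$gapExtend)))
            .kernelRoot(gk)
        } else NULL
        list(rs = rs, X = X, G = G, kernels = ks, root = gen)
    }

    if (config$fixedCohort) {
        if (!is.null(kernels) && !is.null(cohort)) {
            G <- weightedFeatures(featureMatrix(cohort$repertoires), W)
            root <- if (config$tau2 > 0)
                .kernelRoot(kernels[[config$generatingScheme]]) else NULL
            co <- list(rs = cohort$repertoires, X = cohort$X, G = G,
                       kernels = kernels[schemes], root = root)
        } else {
            co <- makeCohort()
        }
    }

    methodCols <- c("fixed", paste0("seq_", labels), paste0("mixed_", labels),
                    paste0("vc_", labels))
    P <- matrix(NA_real_, config$replicates, length(methodCols),
                dimnames = list(NULL, methodCols))
    for (rep_i in seq_len(config$replicates)) {
        if (!config$fixedCohort) co <- makeCohort()
        y <- tryCatch(
            simulateTrait(co$X, co$G, config$traitType, config$beta,
                          config$eta, config$tau2, co$root,
                          config$imbalanceFloor),
            error = function(e) stop("replicate ", rep_i, ": ",
                                     conditionMessage(e)))
        pF <- scoreFixed(co$X, co$G, y, config$traitType)$p
        P[rep_i, "fixed"] <- pF
        for (s in seq_along(schemes)) {
            k <- co$kernels[[schemes[s]]]
            pSeq <- scoreRandom(co$X, NULL, y, k, config$traitType,
                                config$alternative)$p
            pVC <- scoreRandom(co$X, co$G, y, k, config$traitType,
                               config$alternative)$p
            P[rep_i, paste0("seq_", labels[s])] <- pSeq
            P[rep_i, paste0("vc_", labels[s])] <- pVC
            P[rep_i, paste0("mixed_", labels[s])] <- fisherCombine(pF, pVC)$p
        }
    }
    reported <- c("fixed", paste0("seq_", labels), paste0("mixed_", labels))
    rej <- colSums(P[, reported, drop = FALSE] < config$alpha)
    rates <- data.frame(
        method = reported,
        rejections = as.integer(rej),
        rate = rej / config$replicates,
        se = sqrt(pmax(rej / config$replicates *
                       (1 - rej / config$replicates), 0) / config$replicates),
        replicates = config$replicates,
        row.names = NULL)
    structure(list(pvalues = as.data.frame(P), rates = rates,
                   config = config),
              class = "tcrStudy")
}

#' @export
print.tcrStudy <- function(x, ...) {
    cfg <- x$config
    cat(sprintf("Simulation study: scenario '%s', %s trait, n = %d, %d replicates%s\n",
                cfg$scenario, cfg$traitType, cfg$n, cfg$replicates,
                if (cfg$fixedCohort) " (fixed cohort)" else ""))
    cat(sprintf("  eta = %s, tau2 = %g, alpha = %g, generating kernel %s\n",
                paste(cfg$eta, collapse = ","), cfg$tau2, cfg$alpha,
                cfg$generatingScheme))
    df <- x$rates
    df$rate <- sprintf("%.4f", df$rate)
    df$se <- sprintf("%.4f", df$se)
    print(df, row.names = FALSE)
    invisible(x)
}

#' Write study results to disk
#'
#' Writes the rejection-rate table as TSV and a JSON metadata record
#' (configuration echo including the seed) alongside it.
#'
#' @param study a `tcrStudy` from [runStudy()].
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeStudy <- function(study, path) {
    stopifnot(inherits(study, "tcrStudy"))
    utils::write.table(study$rates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(unclass(study$config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
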