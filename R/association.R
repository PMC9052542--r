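# Mixed-effects score tests: a fixed-effect score on property-weighted
# composition features and a variance-component score on the repertoire
# homology kernel, combined by Fisher's method.  Model:
#   E(y_i) = pi( beta' X_i + eta' W' f(R_i) + h(R_i) ),  h ~ N(0, tau^2 S)
# with pi identity (continuous) or logistic (binary).

.IRLS_EPS <- 1e-10
.IRLS_MAXIT <- 100
.MU_CLAMP <- 1e-10

.checkDesign <- function(Z, what = "design matrix") {
    if (qr(Z)$rank < ncol(Z))
        stop(what, " is rank deficient; drop collinear columns")
    invisible(Z)
}

.checkTrait <- function(y, traitType) {
    if (any(!is.finite(y))) stop("phenotype has non-finite values")
    if (traitType == "binary") {
        if (!all(y %in% c(0, 1)))
            stop("binary phenotype must take values in {0, 1}")
        if (length(unique(y)) < 2L)
            stop("binary phenotype has a single class; nothing to test")
    }
    invisible(y)
}

# Null-model fit of y on a design Z: OLS for continuous traits, logistic
# IRLS (glm.fit) for binary.  Returns coefficients, fitted means and the
# diagonal of the working weight matrix.
.fitNull <- function(Z, y, traitType) {
    .checkDesign(Z)
    n <- nrow(Z)
    if (traitType == "continuous") {
        fit <- stats::lm.fit(Z, y)
        mu <- as.numeric(Z %*% fit$coefficients)
        list(coef = fit$coefficients, mu = mu, omega = NULL)
    } else {
        fit <- stats::glm.fit(Z, y, family = stats::binomial(),
                              control = stats::glm.control(
                                  epsilon = .IRLS_EPS, maxit = .IRLS_MAXIT))
        if (!fit$converged)
            stop("logistic null fit did not converge (possible separation)")
        mu <- pmin(pmax(fit$fitted.values, .MU_CLAMP), 1 - .MU_CLAMP)
        list(coef = fit$coefficients, mu = mu, omega = mu * (1 - mu))
    }
}

#' Fixed-effect score test on weighted composition features
#'
#' Score test of eta = 0 in the model with mean
#' pi(beta' X_i + eta' G_i), where G_i = W' f(R_i).  Under the joint
#' null the score is U = sum_i G_i (y_i - mu_i) with mu from the
#' covariate-only null fit, and its covariance is
#' Sigma = G' Gamma G with Gamma = Omega - Omega X (X' Omega X)^-1 X' Omega
#' (Omega the working weight matrix: constant residual variance for
#' continuous traits, mu(1-mu) for binary).  U' Sigma^-1 U is
#' asymptotically chi-square with r = ncol(G) degrees of freedom.
#'
#' @param X n x (q+1) covariate design matrix including the intercept.
#' @param G n x r matrix of property-weighted features.
#' @param y phenotype vector.
#' @param traitType "continuous" or "binary".
#' @return list with `stat`, `df`, `p` and the score vector `U`.
#' @export
scoreFixed <- function(X, G, y, traitType = c("continuous", "binary")) {
    traitType <- match.arg(traitType)
    X <- as.matrix(X); G <- as.matrix(G)
    .checkTrait(y, traitType)
    n <- nrow(X)
    fit <- .fitNull(X, y, traitType)
    resid <- y - fit$mu
    r <- ncol(G)
    if (all(abs(resid) < 1e-14 * max(1, abs(y))))  # perfect null fit
        return(list(stat = 0, df = r, p = 1, U = rep(0, r)))
    omega <- if (traitType == "continuous")
        rep(mean(resid^2), n) else fit$omega
    U <- drop(crossprod(G, resid))
    # Sigma = G' Omega G - (G' Omega X)(X' Omega X)^-1 (X' Omega G)
    GO <- G * omega
    XO <- X * omega
    A <- crossprod(G, GO)
    B <- crossprod(X, GO)
    C <- crossprod(X, XO)
    Sigma <- A - crossprod(B, solve(C, B))
    Sigma <- (Sigma + t(Sigma)) / 2
    # judged against the unprojected scale G' Omega G, so features lying
    # in the covariate span (Sigma ~ 0) are caught even when r = 1
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * mean(diag(A)))
        stop("singular score covariance; check for constant or collinear features")
    stat <- drop(crossprod(U, solve(Sigma, U)))
    list(stat = stat, df = r,
         p = stats::pchisq(stat, df = r, lower.tail = FALSE), U = U)
}

# Trace machinery shared by the variance-component scores.  With
# H = Z (Z'Z)^-1 Z' and P0 = I - H (all products kept low-rank):
#   tr(S P0)      = tr(S) - tr((Z'SZ)(Z'Z)^-1)
#   tr(S P0 S P0) = tr(S^2) - 2 tr((SZ)'(SZ)(Z'Z)^-1) + tr((Z'SZ (Z'Z)^-1)^2)
.kernelTraces <- function(S, Z) {
    ZtZinv <- chol2inv(chol(crossprod(Z)))
    A <- S %*% Z                    # n x d
    C <- crossprod(Z, A)            # Z' S Z, d x d
    trSP0 <- sum(diag(S)) - sum(C * ZtZinv)
    CB <- C %*% ZtZinv
    trSP0SP0 <- sum(S * S) - 2 * sum(crossprod(A) * ZtZinv) + sum(CB * t(CB))
    list(trSP0 = trSP0, trSP0SP0 = trSP0SP0)
}

#' Variance-component score test on the homology kernel
#'
#' Tests tau^2 = 0 in the mixed model, leaving the fixed effects
#' unconstrained: the design Z = [X | G] (or Z = X when `G` is NULL,
#' the random-effect-only model) is fitted under the null, and the
#' quadratic-form score in the residuals is standardised.
#'
#' For continuous traits, with P0 the residual projection of Z and
#' sigma^2 estimated by RSS/(n-d),
#' \deqn{Q = \frac{(y-\hat\mu)' S (y-\hat\mu) - tr(S P_0)\hat\sigma^2}
#'   {\sqrt{2\hat\sigma^4[tr(S P_0 S P_0) - tr(S P_0)^2/(n-d)]}}.}
#' For binary traits the logistic fit is linearised through IRLS working
#' responses: with Omega = diag(mu(1-mu)), Z' = Omega^{1/2} Z and
#' working residuals Omega^{-1/2}(y - mu), the same form applies with
#' daggered quantities.  Q is asymptotically standard normal under the
#' null; the default p-value is the upper tail (tau^2 >= 0, so only
#' inflation of the quadratic form is evidence against the null).
#'
#' @param X n x (q+1) covariate design matrix including the intercept.
#' @param G n x r matrix of weighted features, or NULL for the
#'   random-effect-only model.
#' @param y phenotype vector.
#' @param kernel a [HomologyKernel-class] (PSD-repaired) or a plain
#'   symmetric matrix.
#' @param traitType "continuous" or "binary".
#' @param alternative "greater" (default, one-sided upper tail) or
#'   "two.sided".
#' @return list with `Q`, `p`, `U` (the raw quadratic form), `sigma2`
#'   and `d` (columns of the null design).
#' @export
scoreRandom <- function(X, G = NULL, y, kernel,
                        traitType = c("continuous", "binary"),
                        alternative = c("greater", "two.sided")) {
    traitType <- match.arg(traitType)
    alternative <- match.arg(alternative)
    S <- if (is(kernel, "HomologyKernel")) kernelMatrix(kernel) else as.matrix(kernel)
    X <- as.matrix(X)
    Z <- if (is.null(G)) X else cbind(X, as.matrix(G))
    .checkTrait(y, traitType)
    n <- nrow(Z); d <- ncol(Z)
    if (n <= d) stop("need more subjects than design columns")
    if (nrow(S) != n) stop("kernel dimension does not match the cohort")
    fit <- .fitNull(Z, y, traitType)
    if (traitType == "continuous") {
        resid <- y - fit$mu
        Zs <- Z
    } else {
        sw <- sqrt(fit$omega)
        resid <- (y - fit$mu) / sw   # Omega^{1/2} (y_w - Z gamma)
        Zs <- Z * sw                 # Omega^{1/2} Z
    }
    sigma2 <- sum(resid^2) / (n - d)
    U <- drop(crossprod(resid, S %*% resid))
    tr <- .kernelTraces(S, Zs)
    num <- U - tr$trSP0 * sigma2
    v <- 2 * sigma2^2 * (tr$trSP0SP0 - tr$trSP0^2 / (n - d))
    vscale <- 2 * sigma2^2 * max(abs(tr$trSP0SP0), 1)
    if (!is.finite(v) || v <= vscale * 1e-12) {
        # S proportional to I on the residual space: numerator is also
        # identically zero (U = tr(S P0) sigma2), a 0/0 that resolves to
        # Q = 0; anything else is a genuinely degenerate kernel.
        if (abs(num) <= sigma2 * max(abs(tr$trSP0), 1) * 1e-8) {
            num <- 0; v <- 1
        } else {
            stop("degenerate variance for the quadratic-form score; ",
                 "kernel carries no information beyond the null design")
        }
    }
    Q <- num / sqrt(v)
    p <- switch(alternative,
                greater = stats::pnorm(Q, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(abs(Q), lower.tail = FALSE))
    list(Q = Q, p = p, U = U, sigma2 = sigma2, d = d)
}

#' Combine two independent p-values by Fisher's method
#'
#' The fixed-effect and variance-component scores are independent under
#' the null, so their p-values combine as
#' stat = -2(log p1 + log p2), referred to a chi-square distribution
#' with 4 degrees of freedom.
#'
#' @param p1,p2 p-values in (0, 1]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @return list with `stat` and `p`.
#' @examples
#' fisherCombine(exp(-1), exp(-1))$p  # 3 * exp(-2) ~= 0.40601
#' @export
fisherCombine <- function(p1, p2) {
    ps <- c(p1, p2)
    if (any(ps <= 0)) {
        warning("p-value of 0 clamped to the smallest positive double")
        ps <- pmax(ps, .Machine$double.xmin)
    }
    if (any(ps > 1)) stop("p-values must lie in (0, 1]")
    stat <- -2 * sum(log(ps))
    list(stat = stat, p = stats::pchisq(stat, df = 4, lower.tail = FALSE))
}

#' Test association between TCR repertoires and a phenotype
#'
#' End-to-end mixed-effects score test.  In `mode = "combined"` the
#' fixed-effect score on the property-weighted amino-acid composition
#' and the variance-component score on the repertoire-homology kernel
#' are computed and their independent p-values combined by Fisher's
#' method.  `mode = "fixed"` reports only the composition test (the
#' extracted-features model); `mode = "random"` reports only the kernel
#' test with a covariate-only null design (the sequence-homology-only
#' model).
#'
#' @param rs a [TCRRepertoireSet-class].
#' @param X covariate design matrix including an intercept column, or
#'   NULL for intercept only.
#' @param y phenotype vector aligned with `rs`.
#' @param traitType "binary" or "continuous".
#' @param mode "combined", "fixed" or "random".
#' @param W p x r property-weight matrix (default Kyte-Doolittle
#'   hydropathy).
#' @param kernel optional precomputed [HomologyKernel-class]; if NULL
#'   the kernel is built from `rs` under `scheme` and PSD-repaired.
#' @param scheme [SubstitutionScheme-class] used when building the
#'   kernel.
#' @param alternative tail for the variance-component p-value.
#' @return A [TCRAssocResult-class].
#' @examples
#' set.seed(1)
#' rs <- simulateRepertoireSet(40)
#' X <- simulateCovariates(40)
#' y <- simulateTrait(X, traitType = "continuous")
#' tcrAssocTest(rs, X, y, traitType = "continuous")
#' @export
tcrAssocTest <- function(rs, X = NULL, y,
                         traitType = c("binary", "continuous"),
                         mode = c("combined", "fixed", "random"),
                         W = defaultWeightMatrix(),
                         kernel = NULL,
                         scheme = substitutionScheme("BLOSUM62"),
                         alternative = c("greater", "two.sided")) {
    traitType <- match.arg(traitType)
    mode <- match.arg(mode)
    alternative <- match.arg(alternative)
    stopifnot(is(rs, "TCRRepertoireSet"))
    n <- length(rs)
    if (length(y) != n) stop("phenotype length does not match the cohort")
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    X <- as.matrix(X)
    G <- if (mode == "random") NULL else weightedFeatures(featureMatrix(rs), W)
    needKernel <- mode %in% c("combined", "random")
    if (needKernel && is.null(kernel))
        kernel <- psdProject(buildKernel(rs, scheme))
    schemeName <- if (needKernel) {
        if (is(kernel, "HomologyKernel")) substitutionName(kernel) else scheme@name
    } else ""
    r <- if (is.null(G)) 0L else ncol(G)
    res <- new("TCRAssocResult", mode = mode, traitType = traitType,
               n = n, r = r, dimD = ncol(X) + r, schemeName = schemeName,
               statFixed = NA_real_, pFixed = NA_real_,
               statRandom = NA_real_, pRandom = NA_real_,
               fisherStat = NA_real_, pCombined = NA_real_)
    if (mode %in% c("fixed", "combined")) {
        sf <- scoreFixed(X, G, y, traitType)
        res@statFixed <- sf$stat
        res@pFixed <- sf$p
    }
    if (mode %in% c("random", "combined")) {
        sr <- scoreRandom(X, G, y, kernel, traitType, alternative)
        res@statRandom <- sr$Q
        res@pRandom <- sr$p
    }
    if (mode == "combined") {
        fc <- fisherCombine(res@pFixed, res@pRandom)
        res@fisherStat <- fc$stat
        res@pCombined <- fc$p
    }
    res
}
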