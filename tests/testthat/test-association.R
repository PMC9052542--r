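makeFixture <- function(n, seed = 1) {
    set.seed(seed)
    rs <- simulateRepertoireSet(n)
    X <- simulateCovariates(n)
    G <- weightedFeatures(featureMatrix(rs))
    list(rs = rs, X = X, G = G)
}

test_that("a perfect null fit gives zero score and p = 1", {
    set.seed(23)
    n <- 50
    X1 <- matrix(1, n, 1)
    # intercept-only continuous fit has mean ybar; feeding the fitted
    # means back as the response leaves no residual signal
    y <- rnorm(n)
    muhat <- rep(mean(y), n)
    sf0 <- scoreFixed(X1, cbind(rnorm(n)), muhat, "continuous")
    expect_equal(sf0$stat, 0)
    expect_equal(sf0$p, 1)
})

test_that("continuous fixed-effect score equals the classical Rao form", {
    # with r = 1 the statistic collapses to n (RSS0 - RSS1)/RSS0
    fx <- makeFixture(300, seed = 24)
    y <- drop(fx$X %*% c(0.1, 0.5, -0.4)) + 0.3 * fx$G[, 1] + rnorm(300)
    sf <- scoreFixed(fx$X, fx$G, y, "continuous")
    rss0 <- sum(resid(lm(y ~ fx$X - 1))^2)
    rss1 <- sum(resid(lm(y ~ fx$X + fx$G - 1))^2)
    expect_equal(sf$stat, 300 * (rss0 - rss1) / rss0, tolerance = 1e-10)
})

test_that("binary fixed-effect score matches glm's Rao score test", {
    fx <- makeFixture(250, seed = 25)
    set.seed(26)
    y <- rbinom(250, 1, plogis(drop(fx$X %*% c(0.1, 0.5, -0.4))))
    sf <- scoreFixed(fx$X, fx$G, y, "binary")
    a <- anova(glm(y ~ fx$X - 1, family = binomial()),
               glm(y ~ fx$X + fx$G - 1, family = binomial()), test = "Rao")
    expect_equal(sf$stat, a$Rao[2], tolerance = 1e-4)
    expect_equal(sf$p, a$`Pr(>Chi)`[2], tolerance = 1e-4)
})

test_that("fixed-effect p-values are uniform under residual permutation", {
    fx <- makeFixture(100, seed = 27)
    set.seed(28)
    y <- drop(fx$X %*% c(0.1, 0.5, -0.4)) + rnorm(100)
    ps <- replicate(2000, scoreFixed(fx$X, fx$G[sample(100), , drop = FALSE],
                                     y, "continuous")$p)
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("score covariance annihilates the covariate space", {
    # Gamma X = 0: scores of features lying in the covariate span vanish
    fx <- makeFixture(80, seed = 29)
    set.seed(30)
    y <- rnorm(80)
    for (col in 1:3) {
        expect_error(scoreFixed(fx$X, fx$X[, col, drop = FALSE], y, "continuous"),
                     "singular|collinear")
    }
    yb <- rbinom(80, 1, 0.5)
    expect_error(scoreFixed(fx$X, fx$X[, 2, drop = FALSE], yb, "binary"),
                 "singular|collinear")
})

test_that("variance-component score matches a dense-matrix computation", {
    fx <- makeFixture(60, seed = 31)
    k <- psdProject(buildKernel(fx$rs, substitutionScheme("BLOSUM62")))
    S <- kernelMatrix(k)
    set.seed(32)
    y <- drop(fx$X %*% c(0.1, 0.5, -0.4)) + rnorm(60)
    sr <- scoreRandom(fx$X, fx$G, y, k, "continuous")
    Z <- cbind(fx$X, fx$G)
    fit <- lm.fit(Z, y)
    resid <- y - Z %*% fit$coefficients
    sigma2 <- sum(resid^2) / (60 - ncol(Z))
    expect_equal(sr$Q, denseQ(Z, resid, S, sigma2), tolerance = 1e-8)

    # binary: daggered design and working residuals
    set.seed(33)
    yb <- rbinom(60, 1, plogis(drop(fx$X %*% c(0.1, 0.5, -0.4))))
    srb <- scoreRandom(fx$X, fx$G, yb, k, "binary")
    gfit <- glm.fit(Z, yb, family = binomial(),
                    control = glm.control(epsilon = 1e-10, maxit = 100))
    mu <- gfit$fitted.values
    w <- mu * (1 - mu)
    Zd <- Z * sqrt(w)
    rd <- (yb - mu) / sqrt(w)
    s2d <- sum(rd^2) / (60 - ncol(Z))
    expect_equal(srb$Q, denseQ(Zd, rd, S, s2d), tolerance = 1e-8)
    # IRLS stationarity: weighted residuals orthogonal to weighted design
    expect_lt(max(abs(crossprod(Zd, rd))), 1e-8)
})

test_that("projection identities hold on the fitted null design", {
    fx <- makeFixture(40, seed = 34)
    Z <- cbind(fx$X, fx$G)
    P0 <- diag(40) - Z %*% solve(crossprod(Z)) %*% t(Z)
    expect_equal(sum(diag(P0)), 40 - ncol(Z))
    expect_equal(P0 %*% P0, P0, tolerance = 1e-10)
    expect_lt(max(abs(P0 %*% Z)), 1e-10)
})

test_that("identity kernel degenerates to Q = 0, p = 0.5", {
    fx <- makeFixture(50, seed = 35)
    set.seed(36)
    y <- rnorm(50)
    sr <- scoreRandom(fx$X, fx$G, y, diag(50), "continuous")
    expect_equal(sr$Q, 0)
    expect_equal(sr$p, 0.5)
    yb <- rbinom(50, 1, 0.5)
    srb <- scoreRandom(fx$X, fx$G, yb, diag(50), "binary")
    expect_equal(srb$Q, 0)
    expect_equal(srb$p, 0.5)
})

test_that("Q is increasing in the quadratic form and permutation equivariant", {
    fx <- makeFixture(70, seed = 37)
    k <- psdProject(buildKernel(fx$rs, substitutionScheme("BLOSUM62")))
    set.seed(38)
    yb <- rbinom(70, 1, plogis(drop(fx$X %*% c(0.1, 0.5, -0.4))))
    base <- scoreRandom(fx$X, fx$G, yb, k, "binary")
    # simultaneous relabeling of subjects leaves Q unchanged
    perm <- sample(70)
    S <- kernelMatrix(k)
    permuted <- scoreRandom(fx$X[perm, ], fx$G[perm, , drop = FALSE],
                            yb[perm], S[perm, perm], "binary")
    expect_equal(permuted$Q, base$Q, tolerance = 1e-10)
    # two-sided option: p doubles the smaller tail
    two <- scoreRandom(fx$X, fx$G, yb, k, "binary", alternative = "two.sided")
    expect_equal(two$p, 2 * pnorm(abs(base$Q), lower.tail = FALSE))
})

test_that("variance-component Q is standard normal under the null", {
    fx <- makeFixture(150, seed = 39)
    k <- psdProject(buildKernel(fx$rs, substitutionScheme("BLOSUM62")))
    set.seed(40)
    Q <- replicate(400, {
        y <- drop(fx$X %*% c(0.1, 0.5, -0.4)) + rnorm(150)
        scoreRandom(fx$X, fx$G, y, k, "continuous")$Q
    })
    expect_lt(abs(mean(Q)), 3 / sqrt(400))       # 3 MC SEs of 0
    expect_lt(abs(var(Q) - 1), 0.25)
})

test_that("Fisher combination has its closed form and null distribution", {
    fc <- fisherCombine(1, 1)
    expect_equal(fc$stat, 0)
    expect_equal(fc$p, 1)
    fc <- fisherCombine(exp(-1), exp(-1))
    expect_equal(fc$stat, 4)
    expect_equal(fc$p, (1 + 2) * exp(-2))  # chi-square(4) survival (1+x/2)e^{-x/2}
    expect_warning(fisherCombine(0, 0.5), "clamped")
    expect_error(fisherCombine(0.5, 1.2), "in \\(0, 1\\]")
    set.seed(41)
    pc <- replicate(10000, fisherCombine(runif(1), runif(1))$p)
    expect_gt(ks.test(pc, "punif")$p.value, 0.01)
})

test_that("tcrAssocTest composes the component tests across modes", {
    fx <- makeFixture(80, seed = 42)
    k <- psdProject(buildKernel(fx$rs, substitutionScheme("BLOSUM62")))
    set.seed(43)
    y <- drop(fx$X %*% c(0.1, 0.5, -0.4)) + rnorm(80)
    comb <- tcrAssocTest(fx$rs, fx$X, y, "continuous", kernel = k)
    fix <- tcrAssocTest(fx$rs, fx$X, y, "continuous", mode = "fixed")
    rnd <- tcrAssocTest(fx$rs, fx$X, y, "continuous", mode = "random", kernel = k)
    expect_equal(comb@pFixed, fix@statFixed |> pchisq(1, lower.tail = FALSE))
    expect_equal(comb@pFixed, fix@pFixed)
    # the random-only mode drops the feature columns from the null design
    expect_equal(rnd@dimD, 3)      # q + 1 only
    expect_equal(comb@dimD, 4)     # q + 1 + r
    expect_equal(comb@pCombined,
                 fisherCombine(comb@pFixed, comb@pRandom)$p)
    # the combined random component conditions on the features, so it
    # differs from the random-only p-value in general
    expect_false(isTRUE(all.equal(rnd@pRandom, comb@pRandom)))
    expect_output(show(comb), "Fisher combined")
    expect_named(pValues(comb), c("fixed", "random", "combined"))
    # binary phenotype with a single class is refused
    expect_error(tcrAssocTest(fx$rs, fx$X, rep(1, 80), "binary", kernel = k),
                 "single class")
})
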