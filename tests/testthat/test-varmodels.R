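test_that("family variance records compute log sample variances", {
    sc <- pointMassScenario(nSires = 2L, nDamsPerSire = 1L,
                            nOffspringPerDam = 2L)
    co <- simulateCohort(sc, seed = 1)
    # overwrite the final weights with known values; family 1 = {1, 3}
    W <- SummarizedExperiment::assay(co, "weight")
    cd <- SummarizedExperiment::colData(co)
    W[nrow(W), cd$dam == 1] <- c(1, 3)
    W[nrow(W), cd$dam == 2] <- c(6, 10)
    SummarizedExperiment::assay(co, "weight") <- W
    rec <- familyVarianceRecords(co)
    expect_equal(nrow(rec), 2L)
    expect_equal(rec$y_direct[rec$dam == 1], log(2))
    expect_equal(rec$y_direct[rec$dam == 2], log(8))
    expect_equal(rec$family_size, c(2L, 2L))

    # indirect response: log variance of the partners' final weights
    pm <- partnerMap(co)
    wp <- W[nrow(W), ][pm]
    expect_equal(rec$y_indirect[rec$dam == 1],
                 log(var(wp[cd$dam == 1])))

    # arbitrary perturbations round-trip through the arithmetic
    set.seed(99)
    W[nrow(W), ] <- 100 + rnorm(4)
    SummarizedExperiment::assay(co, "weight") <- W
    rec2 <- familyVarianceRecords(co)
    expect_equal(rec2$y_direct[1], log(var(W[nrow(W), cd$dam == 1])))
})

test_that("family variance records reject degenerate families", {
    scOne <- pointMassScenario(nSires = 2L, nDamsPerSire = 1L,
                               nOffspringPerDam = 1L)
    expect_error(familyVarianceRecords(simulateCohort(scOne, seed = 2)),
                 "at least 2 offspring")
    # zero within-family variance cannot be log-transformed
    sc <- pointMassScenario(nSires = 2L, nDamsPerSire = 1L,
                            nOffspringPerDam = 2L)
    expect_error(familyVarianceRecords(simulateCohort(sc, seed = 3)),
                 "zero within-family variance")
})

test_that("record count is sires x dams and records group by sire", {
    sc <- tinyScenario()
    rec <- familyVarianceRecords(simulateCohort(sc, seed = 4))
    expect_equal(nrow(rec), 4L * 3L)
    expect_equal(unname(table(rec$sire)), array(rep(3L, 4L)))
})

test_that("balanced sire REML equals the ANOVA closed form", {
    # worked two-sire example with an exact interior solution
    rec <- data.frame(sire_id = c("S1", "S1", "S2", "S2"),
                      sire = c(1L, 1L, 2L, 2L),
                      y_direct = c(1, 3, 5, 7))
    fit <- fitSireModel(rec, "direct")
    vc <- varianceComponents(fit)
    expect_equal(vc[["sigma2_e"]], 2, tolerance = 1e-5)
    expect_equal(vc[["sigma2_u"]], 7, tolerance = 1e-4)
    expect_equal(unname(blup(fit)), c(-1.75, 1.75), tolerance = 1e-5)

    # random balanced instances against the closed form and lme4
    for (case in 1:4) {
        set.seed(100 + case)
        s <- sample(8:15, 1)
        n <- sample(5:10, 1)
        sire <- rep(seq_len(s), each = n)
        y <- rnorm(s, sd = 1.5)[sire] + rnorm(s * n)
        oracle <- anovaOneWay(y, sire)
        rec <- data.frame(sire = sire, y_direct = y)
        fit <- fitSireModel(rec, "direct")
        vc <- varianceComponents(fit)
        if (oracle$sigma2s > 0.05) {
            expect_equal(vc[["sigma2_u"]], oracle$sigma2s, tolerance = 1e-3)
            expect_equal(vc[["sigma2_e"]], oracle$sigma2e, tolerance = 1e-3)
            # closed-form BLUP: shrunken deviations of sire means
            shrink <- n * (tapply(y, sire, mean) - mean(y)) /
                (n + oracle$sigma2e / oracle$sigma2s)
            expect_equal(unname(blup(fit)), as.numeric(shrink),
                         tolerance = 1e-3)
        }
        m <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = sire),
                        REML = TRUE)
        expect_equal(vc[["sigma2_u"]],
                     unname(lme4::VarCorr(m)$g[1, 1]), tolerance = 1e-3)
        expect_equal(remlLogLik(fit), as.numeric(stats::logLik(m)),
                     tolerance = 1e-5)
    }
})

test_that("no sire signal gives a vanishing sire variance", {
    # pure noise: the estimate is 0 up to its own Monte-Carlo error
    set.seed(7)
    s <- 30L; n <- 10L
    rec <- data.frame(sire = rep(seq_len(s), each = n),
                      y_direct = rnorm(s * n))
    fit <- fitSireModel(rec, "direct")
    seV <- sqrt(2 * (1 / (n^2 * (s - 1)) + 1 / (n^2 * s * (n - 1))))
    expect_lt(varianceComponents(fit)[["sigma2_u"]], 3 * seV)
    expect_true(isConverged(fit))

    # exactly equal sire means: the between-sire mean square is zero and
    # REML sits on the boundary with all predictions at zero
    set.seed(8)
    recB <- data.frame(sire = rep(seq_len(s), each = n),
                       y_direct = rep(rnorm(n), s))
    fitB <- fitSireModel(recB, "direct")
    expect_equal(varianceComponents(fitB)[["sigma2_u"]], 0)
    expect_true(all(blup(fitB) == 0))
})

test_that("injected sire variance is recovered within Monte-Carlo error", {
    set.seed(21)
    s <- 200L; n <- 20L; v <- 0.5
    sire <- rep(seq_len(s), each = n)
    y <- rnorm(s, sd = sqrt(v))[sire] + rnorm(s * n)
    fit <- fitSireModel(data.frame(sire = sire, y_direct = y), "direct")
    # SE of the ANOVA estimator for a balanced one-way design
    seV <- sqrt(2 * ((1 + n * v)^2 / (n^2 * (s - 1)) +
                     1 / (n^2 * s * (n - 1))))
    expect_lt(abs(varianceComponents(fit)[["sigma2_u"]] - v), 3 * seV)
})

test_that("BLUP shrinkage preserves correlations with external vectors", {
    # balanced design: BLUPs are a common rescaling of sire-mean deviations,
    # so correlations with any external sire-level vector are unchanged
    set.seed(17)
    s <- 12L; n <- 8L
    sire <- rep(seq_len(s), each = n)
    y <- rnorm(s, sd = 1)[sire] + rnorm(s * n, sd = 0.5)
    fit <- fitSireModel(data.frame(sire = sire, y_direct = y), "direct")
    expect_gt(varianceComponents(fit)[["sigma2_u"]], 0)
    sireMeans <- as.numeric(tapply(y, sire, mean))
    ext <- rnorm(s)
    expect_equal(cor(blup(fit), ext), cor(sireMeans, ext), tolerance = 1e-8)
})

test_that("genetic resistance creates inherited variability even at neutral b", {
    rep2 <- runScenario(reducedScenario(2), nReplicates = 1, seed = 31)
    s <- reportSummary(rep2)
    dirAD <- s$mean_r[s$model == "direct-variability" & s$truth == "A_D"]
    expect_lt(dirAD, -0.5)  # strongly negative despite b_bar = 0
})

test_that("no genetic variance in b means no inherited variability", {
    sc <- GrowthScenario(bBar = 0, sigmaAD = 0, sigmaAI = 0, sigmaED = 0,
                         sigmaEI = 0, nSires = 50L, nDamsPerSire = 10L,
                         nOffspringPerDam = 30L)
    rec <- familyVarianceRecords(simulateCohort(sc, seed = 6))
    for (response in c("direct", "indirect")) {
        fit <- fitSireModel(rec, response)
        expect_lt(varianceComponents(fit)[["sigma2_u"]], 0.005)
    }
})
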