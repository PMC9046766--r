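test_that("base population sampling honors the genetic parameters", {
    # degenerate distribution: zero SDs collapse to a point mass at 0
    sc0 <- pointMassScenario(nSires = 5L, nDamsPerSire = 2L)
    pp0 <- sampleBasePopulation(sc0, seed = 1)
    expect_true(all(as.matrix(pp0$sires[c("A_GR", "A_D", "A_I")]) == 0))
    expect_true(all(as.matrix(pp0$dams[c("A_GR", "A_D", "A_I")]) == 0))

    # Monte-Carlo: sample SD of A_D over 10,000 dams within 3 SE of 0.015
    sc <- GrowthScenario()
    pp <- sampleBasePopulation(sc, seed = 2)
    expect_equal(nrow(pp$dams), 10000L)
    se <- 0.015 / sqrt(2 * 10000)
    expect_lt(abs(sd(pp$dams$A_D) - 0.015), 3 * se)
    expect_lt(abs(sd(pp$sires$A_GR) - 1), 3 * 1 / sqrt(2 * 100) + 0.01)

    # each dam mated once, nDamsPerSire dams per sire
    expect_equal(unname(table(pp$dams$sire)), array(rep(100L, 100L)))

    # non-zero genetic correlation is realized in the sample
    corr <- diag(3); corr[2, 3] <- corr[3, 2] <- 0.5
    ppc <- sampleBasePopulation(GrowthScenario(geneticCorr = corr), seed = 3)
    seCor <- (1 - 0.5^2) / sqrt(10000)
    expect_lt(abs(cor(ppc$dams$A_D, ppc$dams$A_I) - 0.5), 3 * seCor)
})

test_that("offspring inherit midparent plus half-variance Mendelian term", {
    # all variances zero: offspring breeding value is exactly midparent
    sc <- pointMassScenario(nSires = 1L, nDamsPerSire = 2L,
                            nOffspringPerDam = 3L)
    pp <- handParents(sc, bvFrame(1, 0, 0), bvFrame(c(0, 0), 0, 0))
    cohort <- sampleOffspring(pp, seed = 4)
    expect_equal(ncol(cohort), 6L)
    cd <- SummarizedExperiment::colData(cohort)
    expect_equal(unname(cd$A_GR), rep(0.5, 6))
    expect_equal(unname(cd$A_D), rep(0, 6))

    # Mendelian term restores the full additive variance in a large cohort
    scBig <- GrowthScenario(nSires = 100L, nDamsPerSire = 20L,
                            nOffspringPerDam = 10L)
    big <- simulateCohort(scBig, seed = 5)
    aGR <- SummarizedExperiment::colData(big)$A_GR
    expect_lt(abs(var(aGR) - 1), 0.08)
    expect_equal(ncol(big), 100L * 20L * 10L)
})

test_that("pairing is a uniform fixed-point-free involution", {
    expect_equal(samplePartnerMap(2, seed = 1), c(2L, 1L))
    for (seed in 1:5) {
        p <- samplePartnerMap(100, seed = seed)
        expect_equal(p[p], 1:100)          # involution
        expect_true(all(p != 1:100))       # no self-pairing
        expect_equal(sort(p), 1:100)       # everyone appears once
    }
    expect_error(samplePartnerMap(5), "even")

    # all 3 perfect matchings of 4 elements appear with frequency ~ 1/3
    key <- vapply(1:1200, function(s) {
        paste(samplePartnerMap(4, seed = s)[1:2], collapse = "")
    }, "")
    freq <- table(key) / 1200
    expect_equal(length(freq), 3L)
    expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("interaction coefficients follow the additive decomposition", {
    expect_equal(interactionCoefficient(-0.05, 0, 0, 0, 0), -0.05)
    # direct and indirect effects of equal size cancel
    expect_equal(interactionCoefficient(-0.05, 0.015, 0, -0.015, 0), -0.05)
    # b is not symmetric between the two orderings of a pair
    bij <- interactionCoefficient(0, AD = 0.01, ED = 0, AI = 0.02, EI = 0)
    bji <- interactionCoefficient(0, AD = 0.03, ED = 0, AI = -0.01, EI = 0)
    expect_equal(bij, 0.03)
    expect_false(isTRUE(all.equal(bij, bji)))
})

test_that("growth recursion reproduces hand-iterated trajectories", {
    # no random effects, b = 0: weight is start + nSteps * muGR everywhere
    sc0 <- pointMassScenario(nSires = 2L, nDamsPerSire = 1L,
                             nOffspringPerDam = 1L)
    co0 <- simulateCohort(sc0, seed = 6)
    expect_equal(unname(finalWeight(co0)), c(110, 110))
    W0 <- SummarizedExperiment::assay(co0, "weight")
    expect_equal(unname(W0[, 1]), seq(10, 110, by = 10))

    # identical pair members: interaction term always zero, equal weights
    expect_equal(W0[, 1], W0[, 2], ignore_attr = TRUE)

    # competition between unequal genotypes: scalar oracle of the recursion
    sc <- pointMassScenario(bBar = -0.05, nSires = 2L, nDamsPerSire = 1L,
                            nOffspringPerDam = 1L)
    pp <- handParents(sc, bvFrame(c(1, 0), 0, 0), bvFrame(c(1, 0), 0, 0))
    cohort <- sampleOffspring(pp, seed = 7)
    cohort <- pairIndividuals(cohort, seed = 7)
    cohort <- simulateGrowth(cohort, seed = 7)
    w <- c(10, 10)
    a <- unname(SummarizedExperiment::colData(cohort)$A_GR)
    oracle <- matrix(NA_real_, 11, 2)
    oracle[1, ] <- w
    for (t in 1:10) {
        w <- w + 10 + a - 0.05 * (rev(w) - w)
        oracle[t + 1, ] <- w
    }
    expect_equal(oracle[2, ], c(21, 20))
    expect_equal(oracle[3, ], c(32.05, 29.95))
    expect_equal(unname(SummarizedExperiment::assay(cohort, "weight")),
                 oracle)
    expect_equal(S4Vectors::metadata(cohort)$nNegativeWeights, 0L)
})

test_that("final-weight variance matches the closed form at b = 0", {
    # Var = nSteps^2 (sigma_A^2 + sigma_Ep^2) + nSteps * sigma_Et^2 = 146 g^2
    sc <- GrowthScenario(bBar = 0, sigmaAD = 0, sigmaAI = 0, sigmaED = 0,
                         sigmaEI = 0, nSires = 100L, nDamsPerSire = 20L,
                         nOffspringPerDam = 10L)
    co <- simulateCohort(sc, seed = 8)
    v <- var(finalWeight(co))
    expect_lt(abs(v - 146), 8)  # 3 x Monte-Carlo SE, family clustering incl.
    expect_lt(abs(mean(finalWeight(co)) - 110), 0.5)
})

test_that("competition amplifies within-pair divergence", {
    scComp <- GrowthScenario(bBar = -0.05, nSires = 50L, nDamsPerSire = 4L,
                             nOffspringPerDam = 10L)
    scNeut <- GrowthScenario(bBar = 0, nSires = 50L, nDamsPerSire = 4L,
                             nOffspringPerDam = 10L)
    diverg <- function(co) {
        w <- finalWeight(co)
        mean(abs(w - w[partnerMap(co)]))
    }
    expect_gt(diverg(simulateCohort(scComp, seed = 9)),
              diverg(simulateCohort(scNeut, seed = 9)))
})

test_that("identical seeds give bit-identical cohorts, stage by stage", {
    sc <- tinyScenario()
    a <- simulateCohort(sc, seed = 10)
    b <- simulateCohort(sc, seed = 10)
    expect_identical(SummarizedExperiment::assay(a, "weight"),
                     SummarizedExperiment::assay(b, "weight"))
    expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                     as.data.frame(SummarizedExperiment::colData(b)))
    # growth stage independently reproducible on the same paired cohort
    seedG <- deriveSeed(10, "growth", 1L)
    again <- simulateGrowth(a, seedG)
    expect_identical(SummarizedExperiment::assay(again, "weight"),
                     SummarizedExperiment::assay(a, "weight"))
    # different seed, different noise
    c <- simulateCohort(sc, seed = 11)
    expect_false(identical(SummarizedExperiment::assay(a, "weight"),
                           SummarizedExperiment::assay(c, "weight")))
})
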