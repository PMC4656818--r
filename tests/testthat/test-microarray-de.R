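test_that("global normalization equalizes column totals per the stated rule", {
    m <- matrix(c(4, 6, 10, 20), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    out <- globalNormalize(m)
    # totals 10 and 30 -> both rescaled to 20: factors 2 and 2/3
    expect_equal(out[, "s1"], c(g1 = 8, g2 = 12))
    expect_equal(out[, "s2"], c(g1 = 20 / 3, g2 = 40 / 3))
    expect_equal(unname(colSums(out)), c(20, 20))

    # already-equal totals: identity
    eq <- matrix(c(1, 9, 4, 6), nrow = 2)
    expect_equal(globalNormalize(eq), eq)

    # random input: totals equal within 1e-9, within-sample structure kept
    set.seed(1)
    r <- matrix(rexp(60), nrow = 10,
                dimnames = list(NULL, paste0("s", 1:6)))
    nr <- globalNormalize(r)
    expect_lt(diff(range(colSums(nr))), 1e-9)
    expect_equal(nr[, 1] / nr[2, 1], r[, 1] / r[2, 1])

    bad <- cbind(a = c(1, 2), b = c(0, 0))
    expect_error(globalNormalize(bad), "b")
})

test_that("log z-scoring standardizes each array with the population sd", {
    m <- cbind(s1 = c(10, 100, 1000), s2 = c(20, 200, 2000))
    z <- logZscore(m)
    # log10 {1,2,3}: population sd sqrt(2/3), so z = {-1,0,1}/sqrt(2/3)
    expect_equal(unname(z[, "s1"]), c(-1, 0, 1) * sqrt(3 / 2))
    # scalar-multiple columns give identical z columns
    expect_equal(z[, "s1"], z[, "s2"], ignore_attr = TRUE)

    set.seed(2)
    r <- matrix(10^runif(50, 1, 4), nrow = 10)
    zr <- logZscore(r)
    expect_lt(max(abs(colMeans(zr))), 1e-9)
    expect_lt(max(abs(sqrt(colMeans(zr^2)) - 1)), 1e-9)

    expect_error(logZscore(cbind(rep(5, 3), c(1, 2, 3))), "constant")
    # intensities below the floor are clipped, not an error
    expect_silent(logZscore(cbind(c(0, 10, 100), c(1, 10, 100))))
})

test_that("ZScoreExperiment carries provenance and validity", {
    sim <- simulateExpressionStudy(50, deFraction = 0, seed = 3)
    zs <- logZscore(globalNormalize(sim$experiment))
    expect_s4_class(zs, "ZScoreExperiment")
    expect_identical(S4Vectors::metadata(zs)$provenance$log, "log10")
    expect_identical(S4Vectors::metadata(zs)$provenance$sd, "population")
    expect_true(validObject(zs))
})

test_that("z-ratio standardizes mean z differences across genes", {
    # d = (1, 0, -1) has sample sd 1, so z-ratios equal d
    zm <- cbind(a = c(1, 0, -1), b = c(0, 0, 0))
    rownames(zm) <- paste0("g", 1:3)
    expect_equal(zRatio(zm, "a", "b"), c(g1 = 1, g2 = 0, g3 = -1))

    # identical groups -> all zero, no division by zero
    zm2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
    expect_equal(unname(zRatio(zm2, "a", "b")), c(0, 0, 0))

    # non-degenerate output has sample sd exactly 1
    set.seed(4)
    zm3 <- matrix(rnorm(400), 100, dimnames = list(NULL, paste0("s", 1:4)))
    zr <- zRatio(zm3, c("s1", "s2"), c("s3", "s4"))
    expect_equal(sd(zr), 1, tolerance = 1e-9)

    # swapping the groups negates every value exactly
    expect_identical(zr, -zRatio(zm3, c("s3", "s4"), c("s1", "s2")))

    expect_error(zRatio(zm3, c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("z-test matches hand arithmetic and handles degenerate input", {
    zm <- matrix(c(1.0, 1.2, -1.0, -0.8), nrow = 1,
                 dimnames = list("g1", c("a1", "a2", "b1", "b2")))
    # statistic = 2.0 / sqrt(0.02/2 + 0.02/2) = 14.142...
    p <- zTest(zm, c("a1", "a2"), c("b1", "b2"))
    expect_lt(p[["g1"]], 1e-9)
    stat <- 2 / sqrt(0.02)
    expect_equal(p[["g1"]], 2 * pnorm(-stat))
    # small-sample reference uses t with n_a + n_b - 2 df
    pt2 <- zTest(zm, c("a1", "a2"), c("b1", "b2"), ref = "t")
    expect_equal(pt2[["g1"]], 2 * pt(-stat, df = 2))

    # equal means with positive variance -> p = 1
    zm2 <- matrix(c(1, -1, -1, 1), nrow = 1,
                  dimnames = list("g", c("a1", "a2", "b1", "b2")))
    expect_equal(unname(zTest(zm2, c("a1", "a2"), c("b1", "b2"))), 1)

    expect_error(zTest(zm, "a1", c("b1", "b2")), ">= 2")
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
    expect_equal(bhFdr(0.03), 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhFdr(c(0.5, NA)), "\\[0, 1\\]")

    set.seed(5)
    for (rep in 1:5) {
        p <- runif(5)
        for (perm in list(1:5, 5:1, sample(5))) {
            expect_equal(bhFdr(p[perm]), bhStepUpOracle(p[perm]))
        }
    }
})

test_that("significance calls apply the z-ratio/p OR gate under the FDR gate", {
    rec <- data.frame(gene_id = c("g1", "g2", "g3"),
                      z_ratio = c(2.0, -0.2, 1.6),
                      p_value = c(0.001, 0.8, 0.2),
                      q_value = c(0.01, 0.9, 0.2))
    out <- callSignificance(rec)
    expect_equal(as.character(out$call), c("up", "ns", "ns"))

    # g3 passes once the FDR gate is disabled (|zr| >= 1.5 suffices)
    out2 <- callSignificance(rec, useFdr = FALSE)
    expect_equal(as.character(out2$call), c("up", "ns", "up"))

    # p-only gating
    out3 <- callSignificance(rec, useZRatio = FALSE, useFdr = FALSE)
    expect_equal(as.character(out3$call), c("up", "ns", "ns"))

    # down call takes the z-ratio sign
    dn <- callSignificance(data.frame(gene_id = "g", z_ratio = -3,
                                      p_value = 1e-4, q_value = 1e-3))
    expect_equal(as.character(dn$call), "down")
})

test_that("the full DE pipeline is antisymmetric in the group labels", {
    sim <- simulateExpressionStudy(100, deFraction = 0.1, effect = 2, seed = 6)
    zs <- logZscore(globalNormalize(sim$experiment))
    geno <- sampleInfo(sim$experiment)$genotype
    a <- colnames(sim$experiment)[geno == "case"]
    b <- colnames(sim$experiment)[geno == "control"]
    expect_identical(zRatio(zs, a, b), -zRatio(zs, b, a))
    expect_equal(zTest(zs, a, b), zTest(zs, b, a))
})
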