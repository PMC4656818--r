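test_that("expression-study generator is seed-deterministic with exact planting", {
    s1 <- simulateExpressionStudy(60, deFraction = 0.1, effect = 2, seed = 9)
    s2 <- simulateExpressionStudy(60, deFraction = 0.1, effect = 2, seed = 9)
    expect_identical(intensities(s1$experiment), intensities(s2$experiment))
    expect_identical(s1$truth, s2$truth)

    s3 <- simulateExpressionStudy(60, deFraction = 0.1, effect = 2, seed = 10)
    expect_false(identical(intensities(s1$experiment),
                           intensities(s3$experiment)))

    # exactly round(nGenes * deFraction) planted, half up / half down, ties up
    expect_equal(nrow(s1$truth$deGenes), 6)
    expect_equal(sum(s1$truth$deGenes$polarity == 1), 3)
    s5 <- simulateExpressionStudy(50, deFraction = 0.1, effect = 1, seed = 1)
    expect_equal(sum(s5$truth$deGenes$polarity == 1), 3)  # 5 planted: 3 up
    expect_true(all(s1$truth$deGenes$gene_id %in% rownames(s1$experiment)))

    expect_true(all(intensities(s1$experiment) > 0))
    expect_s4_class(s1$experiment, "IntensityExperiment")
    expect_true(validObject(s1$experiment))

    # no planted signal
    s0 <- simulateExpressionStudy(20, deFraction = 0, seed = 1)
    expect_equal(nrow(s0$truth$deGenes), 0)

    expect_error(simulateExpressionStudy(5), "nGenes")
    expect_error(simulateExpressionStudy(20, nReplicates = 1), "nReplicates")
    expect_error(simulateExpressionStudy(20, deFraction = 1), "deFraction")
})

test_that("generators leave the caller's RNG stream untouched", {
    set.seed(123); before <- runif(1)
    set.seed(123); invisible(simulateExpressionStudy(20, seed = 77))
    expect_identical(runif(1), before)
})

test_that("planted genes can be forced for coherent cross-tissue signal", {
    a <- simulateExpressionStudy(40, deFraction = 0.1, seed = 1)
    b <- simulateExpressionStudy(40, seed = 2, tissue = "cortex",
                                 plantedGenes = a$truth$deGenes$gene_id)
    expect_identical(b$truth$deGenes$gene_id, a$truth$deGenes$gene_id)
    expect_identical(b$truth$deGenes$polarity, a$truth$deGenes$polarity)
    expect_error(simulateExpressionStudy(40, plantedGenes = "nope"),
                 "plantedGenes")
})

test_that("iTRAQ generator yields exact unit ratios in the noiseless null", {
    sim <- simulateItraqExperiment(25, controlCv = 0, diffFraction = 0,
                                   seed = 4)
    expect_identical(sim$peptides$i114, sim$peptides$i115)
    rec <- aggregateProteinRatios(sim$peptides)
    expect_true(all(rec$r_ctrl == 1))
    expect_true(all(rec$r116 == 1))
    expect_true(all(rec$r117 == 1))

    # planted fold multiplies only the case channels
    simF <- simulateItraqExperiment(25, controlCv = 0, diffFraction = 0.2,
                                    fold = 1.5, seed = 4)
    recF <- aggregateProteinRatios(simF$peptides)
    planted <- recF$protein_id %in% simF$truth$diffProteins$protein_id
    expect_equal(sum(planted), 5)
    expect_true(all(abs(recF$r116[planted] - 1.5) < 1e-12))
    expect_true(all(recF$r116[!planted] == 1))

    expect_identical(simulateItraqExperiment(10, seed = 5)$peptides,
                     simulateItraqExperiment(10, seed = 5)$peptides)
    expect_error(simulateItraqExperiment(10, peptidesPerProtein = 0),
                 "peptidesPerProtein")
    expect_error(simulateItraqExperiment(10, fold = 0), "fold")
})

test_that("pathway generator plants over-representation by construction", {
    uni <- sprintf("g%03d", 1:300)
    de <- uni[1:20]
    sim <- simulatePathwayAnnotation(12, uni, planted = c("pw01", "pw02"),
                                     deGenes = de, enrichmentFactor = 5,
                                     seed = 11)
    expect_s4_class(sim$collection, "PathwayCollection")
    enr <- hypergeometricEnrichment(de, sim$collection, minMembers = 1,
                                    pThreshold = 0.05)
    planted <- enr[enr$pathway_id %in% c("pw01", "pw02"), ]
    expect_true(all(planted$R > 1))

    # empty DE list: every pathway has zero observed members
    counts <- vapply(pathwayList(sim$collection),
                     function(p) length(intersect(p, character())), 0L)
    expect_true(all(counts == 0))

    expect_error(simulatePathwayAnnotation(3, uni, planted = "pw99"),
                 "planted")
    expect_error(simulatePathwayAnnotation(3, uni, deGenes = "absent"),
                 "universe")
    s1 <- simulatePathwayAnnotation(5, uni, seed = 3)
    s2 <- simulatePathwayAnnotation(5, uni, seed = 3)
    expect_identical(pathwayList(s1$collection), pathwayList(s2$collection))
})

test_that("literature-corpus generator validates links and is deterministic", {
    genes <- paste0("g", 1:8)
    links <- data.frame(gene = "g1", keyword = "autism", type = "explicit")
    s1 <- simulateLiteratureCorpus(genes, "autism", links, seed = 2)
    s2 <- simulateLiteratureCorpus(genes, "autism", links, seed = 2)
    expect_identical(documents(s1$corpus), documents(s2$corpus))
    expect_true(all(genes %in% names(documents(s1$corpus))))

    # the explicit keyword occurs verbatim in the linked gene's document only
    hasKw <- grepl("\\bautism\\b", documents(s1$corpus)[genes])
    expect_identical(unname(hasKw), genes == "g1")

    expect_error(simulateLiteratureCorpus(genes, "autism",
        data.frame(gene = "gX", keyword = "autism", type = "explicit")),
        "unknown gene")
    expect_error(simulateLiteratureCorpus(genes, "autism",
        data.frame(gene = "g1", keyword = "adhd", type = "explicit")),
        "unknown keyword")
    expect_error(simulateLiteratureCorpus(genes, "autism",
        data.frame(gene = "g1", keyword = "autism", type = "both")),
        "type")
})

test_that("an unlinked corpus scores every gene at zero", {
    genes <- paste0("g", 1:10)
    sim <- simulateLiteratureCorpus(genes, "autism", seed = 6)
    space <- lsiReduce(buildWeightedMatrix(sim$corpus))
    sc <- keywordGeneScores(space, "autism", genes = genes)
    expect_true(all(abs(sc$cosine) < 1e-9))
    expect_true(all(sc$class == "none"))
})

test_that("null simulation reproduces the standard-normal z-ratio tail", {
    sim <- simulateExpressionStudy(2000, deFraction = 0, effect = 0, seed = 13)
    de <- runDifferentialExpression(sim$experiment)
    frac <- mean(abs(de$z_ratio) >= 1.5)
    target <- 2 * (1 - pnorm(1.5))
    se <- sqrt(target * (1 - target) / 2000)
    expect_lt(abs(frac - target), 3 * se)
})

test_that("downstream sensitivity is monotone in the planted effect size", {
    sens <- vapply(c(0.5, 1, 2, 3), function(eff) {
        hits <- vapply(1:3, function(s) {
            sim <- simulateExpressionStudy(400, deFraction = 0.05,
                                           effect = eff, seed = 100 + s)
            de <- runDifferentialExpression(sim$experiment)
            called <- de$gene_id[de$call != "ns"]
            mean(sim$truth$deGenes$gene_id %in% called)
        }, 0)
        mean(hits)
    }, 0)
    expect_true(all(diff(sens) >= 0))
    expect_gt(sens[4], 0.9)
})
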