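test_that("log-entropy weighting matches hand-computed values", {
    co <- Corpus(c(d1 = "aura aura brain", d2 = "brain cortex"))
    w <- buildWeightedMatrix(co, stopwords = character())
    # 'aura' unique to d1: global weight 1, local log(1+2)
    expect_equal(w["aura", "d1"], log(3))
    expect_equal(w["aura", "d2"], 0)
    # 'brain' uniform across both documents: global weight 0, row muted
    expect_equal(unname(w["brain", ]), c(0, 0))
    # 'cortex' unique to d2
    expect_equal(w["cortex", "d2"], log(2))
    g <- attr(w, "globalWeights")
    expect_equal(unname(g[c("aura", "brain", "cortex")]), c(1, 0, 1))

    expect_error(buildWeightedMatrix(Corpus(c(a = "x"))), "2 documents")
    expect_error(buildWeightedMatrix(Corpus(c(a = "the of", b = "and is"))),
                 "vocabulary")
})

test_that("full-rank latent cosines equal raw weighted-matrix cosines", {
    sim <- simulateLiteratureCorpus(paste0("g", 1:12), c("autism", "adhd"),
        links = data.frame(gene = c("g1", "g2"),
                           keyword = c("autism", "adhd"),
                           type = "explicit"), seed = 51)
    w <- buildWeightedMatrix(sim$corpus)
    space <- lsiReduce(w, k = min(dim(w)))
    expect_lt(max(abs(latentDocCosines(space) - rawColumnCosines(w))), 1e-6)
})

test_that("reconstruction error is non-increasing in k", {
    sim <- simulateLiteratureCorpus(paste0("g", 1:8), "autism", seed = 52)
    w <- buildWeightedMatrix(sim$corpus)
    errs <- vapply(seq_len(min(dim(w))), function(k) {
        sp <- lsiReduce(w, k = k)
        recon <- sp@termVectors %*% t(sp@docVectors)
        sqrt(sum((w - recon)^2))
    }, 0)
    expect_true(all(diff(errs) <= 1e-9))
    expect_error(lsiReduce(w, k = 0), "k must")
    expect_error(lsiReduce(w, k = min(dim(w)) + 1), "k must")
})

test_that("orthogonal documents stay orthogonal in the latent space", {
    co <- Corpus(c(d1 = "alpha beta gamma", d2 = "delta epsilon zeta"))
    sp <- lsiReduce(buildWeightedMatrix(co, stopwords = character()), k = 2)
    expect_equal(latentDocCosines(sp)["d1", "d2"], 0, tolerance = 1e-12)
})

test_that("keyword scores classify by the 0.2/0.1 thresholds, boundary implicit", {
    # crafted 2-d space: doc cosines against the 'kw' axis are exact
    mk <- function(c1) c(c1, sqrt(1 - c1^2))
    space <- new("LsiSpace",
                 termVectors = diag(2),
                 docVectors = rbind(gA = mk(0.5), gB = mk(0.2),
                                    gC = mk(0.15), gD = mk(0.05)),
                 singularValues = c(1, 1),
                 globalWeights = c(kw = 1, other = 1), k = 2L)
    rownames(space@termVectors) <- c("kw", "other")
    sc <- keywordGeneScores(space, "kw")
    expect_identical(sc$subject, c("gA", "gB", "gC", "gD"))
    expect_equal(sc$cosine, c(0.5, 0.2, 0.15, 0.05), tolerance = 1e-12)
    expect_identical(as.character(sc$class),
                     c("explicit", "implicit", "implicit", "none"))

    expect_warning(out <- keywordGeneScores(space, "unseen"),
                   "no in-vocabulary")
    expect_true(all(out$cosine == 0))
    expect_true(all(out$class == "none"))
    expect_error(keywordGeneScores(space, "kw", genes = "gZ"), "unknown")
})

test_that("explicitly planted gene ranks first as explicit", {
    genes <- paste0("g", 1:15)
    sim <- simulateLiteratureCorpus(genes, "autism",
        links = data.frame(gene = "g3", keyword = "autism",
                           type = "explicit"), seed = 53)
    w <- buildWeightedMatrix(sim$corpus)
    sp <- lsiReduce(w, k = ceiling(ncol(w) / 2))
    sc <- keywordGeneScores(sp, "autism", genes = genes)
    expect_identical(sc$subject[1], "g3")
    expect_gt(sc$cosine[1], 0.2)
    expect_identical(as.character(sc$class[1]), "explicit")
})

test_that("implicit links land in the implicit band more often than unlinked", {
    nBand <- uBand <- 0; nU <- 0
    for (s in 1:10) {
        genes <- paste0("g", 1:20)
        sim <- simulateLiteratureCorpus(genes, "autism",
            links = data.frame(gene = c("g1", "g2"), keyword = "autism",
                               type = c("explicit", "implicit")), seed = s)
        w <- buildWeightedMatrix(sim$corpus)
        sp <- lsiReduce(w, k = ceiling(ncol(w) / 2))
        sc <- keywordGeneScores(sp, "autism", genes = genes)
        inBand <- function(x) x >= 0.1 & x <= 0.2
        nBand <- nBand + inBand(sc$cosine[sc$subject == "g2"])
        others <- sc$cosine[!sc$subject %in% c("g1", "g2")]
        uBand <- uBand + sum(inBand(others)); nU <- nU + length(others)
    }
    expect_gt(nBand / 10, uBand / nU)
    expect_gt(nBand, 0)
})

test_that("noun phrases dismantle into word counts with hyphen splitting", {
    out <- dismantleAndCount(c("synaptic plasticity", "synaptic vesicle"))
    expect_identical(out$word, c("synaptic", "plasticity", "vesicle"))
    expect_identical(out$count, c(2L, 1L, 1L))

    hy <- dismantleAndCount("brain-derived")
    expect_setequal(hy$word, c("brain", "derived"))

    expect_equal(nrow(dismantleAndCount(character())), 0)

    # idempotence: re-dismantling the flattened words changes nothing
    once <- dismantleAndCount(c("Synaptic Plasticity!", "long-term memory"))
    twice <- dismantleAndCount(rep(once$word, once$count))
    expect_identical(twice, once)
})

test_that("word score tables standardize counts and attach cosines", {
    tab <- wordScoreTable(c("synaptic vesicle", "synaptic fusion"))
    expect_equal(tab$z_score[tab$word == "synaptic"],
                 max(tab$z_score))
    expect_true(all(is.na(tab$cosine)))

    sim <- simulateLiteratureCorpus(paste0("g", 1:6), "autism", seed = 54)
    sp <- lsiReduce(buildWeightedMatrix(sim$corpus))
    withSpace <- wordScoreTable("autism unknownword", space = sp)
    expect_equal(withSpace$cosine[withSpace$word == "unknownword"], 0)
})

test_that("differential word scores subtract and antisymmetrize", {
    a <- data.frame(word = c("w1", "w2"), count = c(3L, 1L),
                    z_score = c(2.0, -1), cosine = c(0.5, 0.1))
    b <- data.frame(word = c("w2", "w1"), count = c(2L, 2L),
                    z_score = c(0.5, 0.5), cosine = c(0.2, 0.3))
    d <- differentialWordScores(a, b)
    expect_equal(d$d_z_score[d$word == "w1"], 1.5)
    expect_equal(d$d_cosine[d$word == "w2"], -0.1)

    rev <- differentialWordScores(b, a)
    m <- match(d$word, rev$word)
    expect_equal(rev$d_z_score[m], -d$d_z_score)

    same <- differentialWordScores(a, a)
    expect_true(all(same$d_z_score == 0))

    expect_warning(
        none <- differentialWordScores(a,
            data.frame(word = "zz", count = 1L, z_score = 0, cosine = 0)),
        "no word common")
    expect_equal(nrow(none), 0)
})
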