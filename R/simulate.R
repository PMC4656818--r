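#' @include AllGenerics.R
NULL

## Seeds are consumed through a local RNG scope so generators never disturb
## the caller's random stream.
.withSeed <- function(seed, expr) {
    seed <- as.integer(seed)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Simulate a two-genotype intensity-array study with planted DE genes
#'
#' Generates log10-normal intensities for \code{nReplicates} control and
#' \code{nReplicates} case arrays of one tissue: per-gene baselines are
#' normal on the log10 scale (mean \code{baselineMean}, sd
#' \code{baselineSd}) with homoskedastic array noise (sd \code{noiseSd}).
#' \code{round(nGenes * deFraction)} genes carry a planted shift in the case
#' group of \code{effect} standardized units (the shift in log10 space is
#' \code{effect} times the typical per-array log10 sd,
#' \eqn{\sqrt{baselineSd^2 + noiseSd^2}}), half up and half down with ties
#' going to up. The planted truth is returned alongside the data.
#'
#' @param nGenes number of genes (>= 10).
#' @param nReplicates arrays per genotype (>= 2; default 3, the usual
#'   three-animals-per-group design).
#' @param deFraction fraction of genes carrying the planted shift, in
#'   [0, 1).
#' @param effect planted shift in standardized (z) units.
#' @param seed integer seed; fully determines the output.
#' @param tissue tissue label recorded in the sample metadata.
#' @param plantedGenes optional character vector naming the genes to carry
#'   the shift (overrides \code{deFraction}); the first half (ties up) is
#'   planted up, the rest down, so passing the same vector to two tissue
#'   simulations plants a coherently-regulated cross-tissue signal.
#' @param baselineMean,baselineSd,noiseSd log10-scale model parameters.
#' @return list with \code{experiment} (an
#'   \linkS4class{IntensityExperiment}, control then case columns) and
#'   \code{truth} (list with \code{seed} and \code{deGenes}, a data.frame of
#'   \code{gene_id}, \code{polarity}, \code{effect}).
#' @examples
#' sim <- simulateExpressionStudy(100, deFraction = 0.1, effect = 2, seed = 7)
#' sim$experiment
#' head(sim$truth$deGenes)
#' @export
simulateExpressionStudy <- function(nGenes, nReplicates = 3,
                                    deFraction = 0.05, effect = 3, seed = 1,
                                    tissue = "hippocampus",
                                    baselineMean = 2.5, baselineSd = 0.5,
                                    noiseSd = 0.2, plantedGenes = NULL) {
    if (nGenes < 10) stop("nGenes must be >= 10")
    if (nReplicates < 2) stop("nReplicates must be >= 2")
    if (deFraction < 0 || deFraction >= 1)
        stop("deFraction must lie in [0, 1)")
    .withSeed(seed, {
        genes <- sprintf("g%04d", seq_len(nGenes))
        if (is.null(plantedGenes)) {
            nDe <- round(nGenes * deFraction)
            deIdx <- if (nDe > 0) sample(nGenes, nDe) else integer()
        } else {
            deIdx <- match(plantedGenes, genes)
            if (anyNA(deIdx)) stop("plantedGenes must name generated genes")
            nDe <- length(deIdx)
        }
        nUp <- ceiling(nDe / 2)
        polarity <- c(rep(1L, nUp), rep(-1L, nDe - nUp))
        sd0 <- sqrt(baselineSd^2 + noiseSd^2)
        shift <- numeric(nGenes)
        shift[deIdx] <- polarity * effect * sd0

        mu <- stats::rnorm(nGenes, baselineMean, baselineSd)
        nCol <- 2L * nReplicates
        logx <- matrix(stats::rnorm(nGenes * nCol, sd = noiseSd), nGenes) + mu
        caseCols <- nReplicates + seq_len(nReplicates)
        logx[, caseCols] <- logx[, caseCols] + shift
        values <- 10^logx
        dimnames(values) <- list(genes,
            c(paste0("ctrl_", tissue, "_", seq_len(nReplicates)),
              paste0("case_", tissue, "_", seq_len(nReplicates))))
        experiment <- IntensityExperiment(
            values,
            genotype = rep(c("control", "case"), each = nReplicates),
            tissue = tissue)
        truth <- list(seed = as.integer(seed),
                      deGenes = data.frame(
                          gene_id = genes[deIdx],
                          polarity = polarity,
                          effect = rep(effect, nDe)))
        list(experiment = experiment, truth = truth)
    })
}

#' Simulate a 4-plex iTRAQ experiment with planted differential proteins
#'
#' Channels 114 and 115 (pooled controls) are drawn around a common
#' log-normal protein abundance with multiplicative noise of coefficient of
#' variation \code{controlCv}; the case channels 116 and 117 receive the same
#' noise and, for the planted fraction of proteins, a multiplicative
#' \code{fold}. A per-peptide ionization-efficiency factor (shared by all
#' four channels, so it cancels in every ratio) spreads peptide intensities
#' within a protein.
#'
#' @param nProteins number of proteins.
#' @param peptidesPerProtein peptides observed per protein (>= 1; default 3).
#' @param controlCv coefficient of variation of the per-channel noise
#'   (0 gives exact ratios of 1 for unperturbed proteins).
#' @param diffFraction fraction of proteins carrying the fold, in [0, 1).
#' @param fold planted case:control ratio (> 0; < 1 plants down-regulation).
#' @param seed integer seed.
#' @return list with \code{peptides} (data.frame with columns
#'   \code{peptide_id}, \code{protein_id}, \code{i114}, \code{i115},
#'   \code{i116}, \code{i117}) and \code{truth} (list with \code{seed} and
#'   \code{diffProteins}, a data.frame of \code{protein_id}, \code{fold}).
#' @examples
#' sim <- simulateItraqExperiment(20, controlCv = 0, diffFraction = 0,
#'                                seed = 1)
#' all(sim$peptides$i114 == sim$peptides$i115)
#' @export
simulateItraqExperiment <- function(nProteins, peptidesPerProtein = 3,
                                    controlCv = 0.05, diffFraction = 0.1,
                                    fold = 1.5, seed = 1) {
    if (nProteins < 1) stop("nProteins must be >= 1")
    if (peptidesPerProtein < 1) stop("peptidesPerProtein must be >= 1")
    if (fold <= 0) stop("fold must be > 0")
    if (diffFraction < 0 || diffFraction >= 1)
        stop("diffFraction must lie in [0, 1)")
    .withSeed(seed, {
        proteins <- sprintf("P%04d", seq_len(nProteins))
        nDiff <- round(nProteins * diffFraction)
        diffIdx <- if (nDiff > 0) sample(nProteins, nDiff) else integer()
        foldVec <- rep(1, nProteins)
        foldVec[diffIdx] <- fold

        nPep <- nProteins * peptidesPerProtein
        proteinOf <- rep(seq_len(nProteins), each = peptidesPerProtein)
        abundance <- stats::rlnorm(nProteins, meanlog = log(1e4), sdlog = 0.5)
        efficiency <- stats::rlnorm(nPep, meanlog = 0, sdlog = 0.8)
        base <- abundance[proteinOf] * efficiency
        sdlog <- sqrt(log(1 + controlCv^2))
        noise <- function() if (sdlog == 0) rep(1, nPep) else
            stats::rlnorm(nPep, meanlog = 0, sdlog = sdlog)
        peptides <- data.frame(
            peptide_id = sprintf("pep%05d", seq_len(nPep)),
            protein_id = proteins[proteinOf],
            i114 = base * noise(),
            i115 = base * noise(),
            i116 = base * foldVec[proteinOf] * noise(),
            i117 = base * foldVec[proteinOf] * noise())
        truth <- list(seed = as.integer(seed),
                      diffProteins = data.frame(
                          protein_id = proteins[diffIdx],
                          fold = rep(fold, nDiff)))
        list(peptides = peptides, truth = truth)
    })
}

#' Simulate a pathway annotation with planted over-representation
#'
#' Non-planted pathways sample members uniformly from the universe; planted
#' pathways include differential genes at \code{enrichmentFactor} times the
#' background inclusion rate (capped at 1), so with factor > 1 their observed
#' count exceeds the expectation by construction.
#'
#' @param nPathways number of pathways to generate (ids \code{pw01}, ...).
#' @param universe background gene identifiers.
#' @param planted pathway ids (subset of the generated ids) to enrich.
#' @param deGenes differential gene identifiers (subset of the universe).
#' @param enrichmentFactor ratio of planted to background inclusion rate for
#'   differential genes (1 = no enrichment).
#' @param seed integer seed.
#' @param sizeRange integer range of pathway sizes (default 10 to 50).
#' @return list with \code{collection} (a \linkS4class{PathwayCollection})
#'   and \code{truth} (list with \code{seed} and \code{enriched}, the planted
#'   pathway ids).
#' @examples
#' uni <- sprintf("g%03d", 1:200)
#' sim <- simulatePathwayAnnotation(10, uni, planted = "pw01",
#'     deGenes = uni[1:20], enrichmentFactor = 5, seed = 1)
#' sim$collection
#' @export
simulatePathwayAnnotation <- function(nPathways, universe, planted = character(),
                                      deGenes = character(),
                                      enrichmentFactor = 5, seed = 1,
                                      sizeRange = c(10, 50)) {
    if (nPathways < 1) stop("nPathways must be >= 1")
    if (enrichmentFactor <= 0) stop("enrichmentFactor must be > 0")
    universe <- unique(as.character(universe))
    ids <- sprintf("pw%02d", seq_len(nPathways))
    if (!all(planted %in% ids))
        stop("planted pathway ids must be among the generated ids: ",
             paste(setdiff(planted, ids), collapse = ", "))
    if (!all(deGenes %in% universe))
        stop("deGenes must be a subset of the universe")
    nonDe <- setdiff(universe, deGenes)
    .withSeed(seed, {
        sizes <- sample(seq(sizeRange[1], sizeRange[2]), nPathways,
                        replace = TRUE)
        sizes <- pmin(sizes, length(universe))
        pathways <- lapply(seq_len(nPathways), function(i) {
            s <- sizes[i]
            if (ids[i] %in% planted && length(deGenes)) {
                rate <- min(1, enrichmentFactor * s / length(universe))
                nDe <- stats::rbinom(1, length(deGenes), rate)
                nDe <- min(nDe, s)
                c(sample(deGenes, nDe),
                  sample(nonDe, min(s - nDe, length(nonDe))))
            } else {
                sample(universe, s)
            }
        })
        names(pathways) <- ids
        list(collection = PathwayCollection(pathways, universe = universe),
             truth = list(seed = as.integer(seed), enriched = planted))
    })
}

## Fixed composition of the synthetic literature documents (token counts).
## Background vocabulary is organised into shared "topics" (rather than
## per-gene private words) so that document norms survive rank reduction and
## implicit associations come out graded: explicit links score clearly above
## the 0.2 explicit threshold while implicit links land around the 0.1-0.2
## band at moderate truncation; see the methods vignette.
.corpusDesign <- list(contextSize = 12L, topicSize = 12L,
                      nRefDocs = 3L, refKeyword = 2L, refContext = 8L,
                      explicitKeyword = 2L, explicitContext = 6L,
                      explicitTopic = 4L,
                      implicitContext = 3L, implicitTopic = 9L,
                      unlinkedTopic = 12L)

#' Simulate a gene-literature corpus with planted keyword associations
#'
#' Each keyword owns a private context vocabulary that co-occurs with it in a
#' few reference documents. An \emph{explicit} link places the keyword itself
#' (plus context terms) in the gene's document; an \emph{implicit} link
#' places only context terms; every gene additionally draws background
#' filler from one of a handful of shared topic vocabularies, none of which
#' overlaps any keyword's context, so unlinked genes share no vocabulary
#' with the keyword's context. Reference documents are included as
#' additional corpus documents named \code{ref_<keyword>_<i>}.
#'
#' @param genes gene identifiers (one document each).
#' @param keywords keyword terms (single lowercase words).
#' @param links data.frame with columns \code{gene}, \code{keyword},
#'   \code{type} (\code{"explicit"} or \code{"implicit"}); may be empty.
#' @param seed integer seed.
#' @return list with \code{corpus} (a \linkS4class{Corpus}) and \code{truth}
#'   (list with \code{seed} and \code{links}).
#' @examples
#' sim <- simulateLiteratureCorpus(paste0("g", 1:5), "autism",
#'     links = data.frame(gene = "g1", keyword = "autism",
#'                        type = "implicit"), seed = 2)
#' sim$corpus
#' @export
simulateLiteratureCorpus <- function(genes, keywords,
                                     links = data.frame(gene = character(),
                                                        keyword = character(),
                                                        type = character()),
                                     seed = 1) {
    genes <- as.character(genes); keywords <- as.character(keywords)
    if (!length(genes)) stop("need at least one gene")
    if (!length(keywords)) stop("need at least one keyword")
    if (nrow(links)) {
        if (!all(links$gene %in% genes))
            stop("link references unknown gene(s): ",
                 paste(setdiff(links$gene, genes), collapse = ", "))
        if (!all(links$keyword %in% keywords))
            stop("link references unknown keyword(s): ",
                 paste(setdiff(links$keyword, keywords), collapse = ", "))
        if (!all(links$type %in% c("explicit", "implicit")))
            stop("link type must be 'explicit' or 'implicit'")
    }
    dz <- .corpusDesign
    .withSeed(seed, {
        context <- lapply(seq_along(keywords), function(i)
            sprintf("ctx%02d%s", i, letters[seq_len(dz$contextSize)]))
        names(context) <- keywords
        nTopics <- max(2L, min(8L, ceiling(length(genes) / 5)))
        topics <- lapply(seq_len(nTopics), function(t)
            sprintf("top%02d%s", t, letters[seq_len(dz$topicSize)]))
        topicOf <- rep(seq_len(nTopics), length.out = length(genes))

        docs <- character(); docNames <- character()
        for (kw in keywords) {
            for (r in seq_len(dz$nRefDocs)) {
                txt <- c(rep(kw, dz$refKeyword),
                         sample(context[[kw]], dz$refContext))
                docs <- c(docs, paste(sample(txt), collapse = " "))
                docNames <- c(docNames, sprintf("ref_%s_%d", kw, r))
            }
        }
        for (gi in seq_along(genes)) {
            g <- genes[gi]
            topic <- topics[[topicOf[gi]]]
            gLinks <- links[links$gene == g, , drop = FALSE]
            txt <- character()
            if (nrow(gLinks)) {
                for (li in seq_len(nrow(gLinks))) {
                    kw <- gLinks$keyword[li]
                    if (gLinks$type[li] == "explicit") {
                        txt <- c(txt, rep(kw, dz$explicitKeyword),
                                 sample(context[[kw]], dz$explicitContext),
                                 sample(topic, dz$explicitTopic))
                    } else {
                        txt <- c(txt, sample(context[[kw]], dz$implicitContext),
                                 sample(topic, dz$implicitTopic))
                    }
                }
            } else {
                txt <- sample(topic, dz$unlinkedTopic, replace = TRUE)
            }
            docs <- c(docs, paste(sample(txt), collapse = " "))
            docNames <- c(docNames, g)
        }
        names(docs) <- docNames
        list(corpus = Corpus(docs),
             truth = list(seed = as.integer(seed), links = links))
    })
}
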