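#' @include AllGenerics.R
NULL

#' Default analysis thresholds
#'
#' The threshold block used by \code{\link{runFullAnalysis}}: Z-ratio 1.5,
#' Z-test p 0.05, FDR 0.05, iTRAQ ratio limits (0.8, 1.2), enrichment
#' minimum population 2 and p 0.05, semantic explicit/implicit thresholds
#' 0.2/0.1.
#'
#' @return named list of thresholds
#' @export
defaultThresholds <- function() {
    list(zr = 1.5, p = 0.05, fdr = 0.05,
         itraq_lo = 0.8, itraq_hi = 1.2,
         enrich_min = 2, enrich_p = 0.05,
         semantic_explicit = 0.2, semantic_implicit = 0.1)
}

#' Assemble and validate an analysis configuration
#'
#' A configuration is a flat list: input paths (or in-memory objects), the
#' threshold block, a seed and an output directory. Any threshold left out
#' takes its default.
#'
#' @param tissues named list of \linkS4class{IntensityExperiment}s (one per
#'   tissue), case vs control to be compared within each.
#' @param peptides peptide reporter table (data.frame) or NULL to skip the
#'   proteomic arm.
#' @param pathways a \linkS4class{PathwayCollection} or NULL to skip
#'   enrichment.
#' @param corpus a \linkS4class{Corpus} or NULL to skip the semantic arm.
#' @param keywords character vector of interrogation terms (used when
#'   \code{corpus} is given); each term is queried separately.
#' @param thresholds named list overriding \code{\link{defaultThresholds}}.
#' @param seed integer seed recorded in the manifest.
#' @param outputDir directory for result files.
#' @return validated configuration list of class \code{"omicompare_config"}
#' @export
analysisConfig <- function(tissues, peptides = NULL, pathways = NULL,
                           corpus = NULL, keywords = character(),
                           thresholds = list(), seed = 1,
                           outputDir = tempfile("omicompare_")) {
    stopifnot(is.list(tissues), length(tissues) >= 1,
              !is.null(names(tissues)),
              all(vapply(tissues, is, TRUE, "IntensityExperiment")))
    thr <- utils::modifyList(defaultThresholds(), thresholds)
    if (any(vapply(thr, function(v) !is.numeric(v) || v <= 0, TRUE)))
        stop("all thresholds must be positive numbers")
    if (!is.null(pathways)) stopifnot(is(pathways, "PathwayCollection"))
    if (!is.null(corpus)) stopifnot(is(corpus, "Corpus"))
    structure(list(tissues = tissues, peptides = peptides,
                   pathways = pathways, corpus = corpus,
                   keywords = keywords, thresholds = thr,
                   seed = as.integer(seed), outputDir = outputDir),
              class = "omicompare_config")
}

#' Read a flat YAML configuration into an analysisConfig
#'
#' Expected keys: \code{tissues} (named map tissue -> list with
#' \code{matrix} and \code{metadata} TSV paths), optional \code{peptides}
#' (CSV path), \code{pathways} (GMT path), \code{corpus} (JSON-lines path),
#' \code{keywords}, a flat \code{thresholds} map, \code{seed} and
#' \code{output_dir}.
#'
#' @param path YAML file
#' @return configuration list from \code{\link{analysisConfig}}
#' @export
readAnalysisConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    tissues <- lapply(cfg$tissues, function(t)
        readIntensityMatrix(t$matrix, t$metadata))
    analysisConfig(
        tissues = tissues,
        peptides = if (!is.null(cfg$peptides)) readPeptideTable(cfg$peptides),
        pathways = if (!is.null(cfg$pathways)) readGmt(cfg$pathways),
        corpus = if (!is.null(cfg$corpus)) readCorpusJsonl(cfg$corpus),
        keywords = as.character(cfg$keywords %||% character()),
        thresholds = cfg$thresholds %||% list(),
        seed = cfg$seed %||% 1,
        outputDir = cfg$output_dir %||% tempfile("omicompare_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, outputDir, expr) {
    tryCatch(expr, error = function(e) {
        file.create(file.path(outputDir, ".partial"))
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
}

#' Run the full case-versus-control multi-omics analysis
#'
#' Executes, in order: per-tissue Z-ratio differential expression; signed
#' Venn partitioning across tissues; pathway enrichment on each tissue's
#' significant list plus up-only/down-only runs with bimodal classification
#' and polarity scores; iTRAQ protein quantification and calling; the
#' transcript-versus-protein cross-omics overlap (first tissue against the
#' protein calls); and per-keyword latent-semantic rankings. All tables are
#' written under \code{outputDir} and indexed by a \code{manifest.json}
#' recording the package version, seed, thresholds and per-file MD5
#' checksums. A failing stage aborts with the stage name; partial outputs
#' are kept next to a \code{.partial} marker file.
#'
#' @param config configuration from \code{\link{analysisConfig}} (or a YAML
#'   path understood by \code{\link{readAnalysisConfig}}).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @examples
#' res <- runDemoAnalysis(outputDir = tempfile(), seed = 1)
#' names(res$results)
#' @export
runFullAnalysis <- function(config) {
    if (is.character(config)) config <- readAnalysisConfig(config)
    stopifnot(inherits(config, "omicompare_config"))
    thr <- config$thresholds
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    unlink(file.path(out, ".partial"))
    files <- character()
    results <- list()

    ## 1. differential expression per tissue
    de <- .stage("differential_expression", out, {
        lapply(config$tissues, function(x)
            runDifferentialExpression(x, zrThreshold = thr$zr,
                                      pThreshold = thr$p,
                                      fdrThreshold = thr$fdr))
    })
    for (tn in names(de)) {
        f <- file.path(out, paste0("de_", tn, ".tsv"))
        utils::write.table(de[[tn]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
    }
    results$de <- de
    signedSets <- lapply(names(de), function(tn)
        buildSignedSet(de[[tn]], tn))

    ## 2. signed Venn partition across tissues
    if (length(signedSets) >= 2) {
        venn <- .stage("venn_partition", out, vennPartition(signedSets))
        f1 <- file.path(out, "venn_regions.tsv")
        f2 <- file.path(out, "venn_counts.json")
        writeVennRegions(venn, f1, f2)
        files <- c(files, f1, f2)
        results$venn <- venn
    }

    ## 3. enrichment per tissue (all / up-only / down-only + bimodal)
    if (!is.null(config$pathways)) {
        enr <- .stage("enrichment", out, {
            lapply(names(de), function(tn) {
                tab <- de[[tn]]
                sig <- as.character(tab$gene_id[tab$call != "ns"])
                up <- as.character(tab$gene_id[tab$call == "up"])
                down <- as.character(tab$gene_id[tab$call == "down"])
                runOne <- function(lst) {
                    if (length(intersect(lst, universeGenes(config$pathways)))
                        == 0) return(NULL)
                    hypergeometricEnrichment(lst, config$pathways,
                                             minMembers = thr$enrich_min,
                                             pThreshold = thr$enrich_p)
                }
                all <- runOne(sig)
                if (!is.null(all))
                    all$polarity_score <- pathwayPolarityScores(
                        config$pathways, up, down)[all$pathway_id]
                upR <- runOne(up); downR <- runOne(down)
                bim <- if (!is.null(upR) && !is.null(downR))
                    bimodalClassification(upR, downR) else NULL
                list(all = all, up = upR, down = downR, bimodal = bim)
            })
        })
        names(enr) <- names(de)
        for (tn in names(enr)) {
            if (is.null(enr[[tn]]$all)) next
            f <- file.path(out, paste0("enrichment_", tn, ".tsv"))
            tab <- enr[[tn]]$all
            if (!is.null(enr[[tn]]$bimodal))
                tab <- merge(tab, enr[[tn]]$bimodal, by = "pathway_id",
                             all.x = TRUE, sort = FALSE)
            utils::write.table(tab, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <- c(files, f)
        }
        results$enrichment <- enr
    }

    ## 4. iTRAQ protein quantification
    if (!is.null(config$peptides)) {
        prot <- .stage("itraq", out,
            runItraqAnalysis(config$peptides, lo = thr$itraq_lo,
                             hi = thr$itraq_hi))
        f <- file.path(out, "protein_calls.tsv")
        utils::write.table(prot, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        fq <- file.path(out, "itraq_qc.json")
        jsonlite::write_json(list(
            n_proteins = nrow(prot),
            n_qc_pass = sum(prot$qc_pass),
            n_up = sum(prot$call == "up"),
            n_down = sum(prot$call == "down"),
            n_conflict = sum(prot$conflict)), fq, auto_unbox = TRUE)
        files <- c(files, f, fq)
        results$proteins <- prot

        ## 5. cross-omics overlap: first tissue's transcripts vs proteins
        protSet <- SignedGeneSet("protein", {
            sel <- prot$call != "unchanged"
            stats::setNames(ifelse(prot$call[sel] == "up", 1L, -1L),
                            prot$protein_id[sel])
        })
        xo <- .stage("cross_omics", out,
                     crossOmicsOverlap(signedSets[[1]], protSet))
        f <- file.path(out, "cross_omics.tsv")
        utils::write.table(xo$shared, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
        results$crossOmics <- xo
    }

    ## 6. latent-semantic keyword rankings, one query per term
    if (!is.null(config$corpus) && length(config$keywords)) {
        sem <- .stage("semantics", out, {
            space <- lsiReduce(buildWeightedMatrix(config$corpus))
            genes <- intersect(names(documents(config$corpus)),
                               unlist(lapply(de, function(d) d$gene_id)))
            if (!length(genes)) genes <- NULL
            do.call(rbind, lapply(config$keywords, function(kw)
                keywordGeneScores(space, kw, genes = genes,
                                  explicitThreshold = thr$semantic_explicit,
                                  implicitThreshold = thr$semantic_implicit)))
        })
        f <- file.path(out, "semantic_scores.tsv")
        utils::write.table(sem, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
        results$semantics <- sem
    }

    manifest <- list(
        package = "omicompare",
        version = as.character(utils::packageVersion("omicompare")),
        seed = config$seed,
        thresholds = thr,
        files = lapply(stats::setNames(files, basename(files)), function(f)
            list(md5 = unname(tools::md5sum(f)))))
    fm <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE)

    invisible(list(results = results, manifest = manifest,
                   outputDir = out))
}

#' Generate synthetic inputs and run the whole pipeline on them
#'
#' Simulates two tissues (hippocampus, cortex) of a two-genotype array study
#' with a shared planted gene signal, an iTRAQ experiment whose planted
#' proteins overlap the planted transcripts, a pathway annotation enriched
#' for the planted genes, and a literature corpus with explicit links from
#' planted genes to the first keyword; then calls
#' \code{\link{runFullAnalysis}}.
#'
#' @param outputDir results directory.
#' @param seed integer seed controlling every generator.
#' @param nGenes genes per tissue (default 600).
#' @param keywords interrogation terms (default \code{c("autism",
#'   "anxiety")}).
#' @return the \code{\link{runFullAnalysis}} result, plus a \code{truth}
#'   element with every generator's planted truth.
#' @export
runDemoAnalysis <- function(outputDir = tempfile("omicompare_demo_"),
                            seed = 1, nGenes = 600,
                            keywords = c("autism", "anxiety")) {
    hip <- simulateExpressionStudy(nGenes, deFraction = 0.05, effect = 3,
                                   seed = seed, tissue = "hippocampus")
    ctx <- simulateExpressionStudy(nGenes, effect = 3, seed = seed + 1,
                                   tissue = "cortex",
                                   plantedGenes = hip$truth$deGenes$gene_id)
    deGenes <- hip$truth$deGenes$gene_id
    ## proteins named after a subset of the planted (and some unplanted) genes
    upGenes <- hip$truth$deGenes$gene_id[hip$truth$deGenes$polarity > 0]
    itq <- simulateItraqExperiment(60, controlCv = 0.05, diffFraction = 0.2,
                                   fold = 1.5, seed = seed + 2)
    nProt <- length(unique(itq$peptides$protein_id))
    protNames <- unique(itq$peptides$protein_id)
    diffProt <- itq$truth$diffProteins$protein_id
    ## rename planted proteins to planted-up gene symbols so the cross-omics
    ## stage has true common factors
    nShare <- min(length(diffProt), length(upGenes))
    map <- stats::setNames(protNames, protNames)
    map[diffProt[seq_len(nShare)]] <- toupper(upGenes[seq_len(nShare)])
    rest <- setdiff(protNames, diffProt)
    spare <- setdiff(rownames(hip$experiment), deGenes)
    map[rest] <- toupper(spare[seq_along(rest)])
    itq$peptides$protein_id <- unname(map[itq$peptides$protein_id])
    itq$truth$diffProteins$protein_id <-
        unname(map[itq$truth$diffProteins$protein_id])

    pw <- simulatePathwayAnnotation(15, universe = rownames(hip$experiment),
                                    planted = c("pw01", "pw02"),
                                    deGenes = deGenes,
                                    enrichmentFactor = 5, seed = seed + 3)
    linkGenes <- deGenes[seq_len(min(5, length(deGenes)))]
    corpusGenes <- union(linkGenes,
                         rownames(hip$experiment)[seq_len(min(55, nGenes))])
    corp <- simulateLiteratureCorpus(
        corpusGenes,
        keywords,
        links = data.frame(gene = linkGenes, keyword = keywords[1],
                           type = "explicit"),
        seed = seed + 4)

    cfg <- analysisConfig(tissues = list(hippocampus = hip$experiment,
                                         cortex = ctx$experiment),
                          peptides = itq$peptides,
                          pathways = pw$collection,
                          corpus = corp$corpus,
                          keywords = keywords,
                          seed = seed, outputDir = outputDir)
    res <- runFullAnalysis(cfg)
    res$truth <- list(hippocampus = hip$truth, cortex = ctx$truth,
                      itraq = itq$truth, pathways = pw$truth,
                      corpus = corp$truth)
    res
}
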