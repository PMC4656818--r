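#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData
NULL

## ---------------------------------------------------------------------------
## IntensityExperiment
## ---------------------------------------------------------------------------

#' Gene-by-sample intensity matrix with sample metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding nonnegative
#' microarray (or similar) intensities in an assay named \code{"intensity"},
#' with per-sample \code{genotype} (\code{"control"} or \code{"case"}),
#' \code{tissue} and \code{replicate} columns in \code{colData}.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @aliases IntensityExperiment-class
#' @exportClass IntensityExperiment
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
    msg <- character()
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        v <- assay(object, "intensity")
        if (anyNA(v) || any(v < 0))
            msg <- c(msg, "intensities must be nonnegative and non-missing")
    }
    needed <- c("genotype", "tissue", "replicate")
    missing <- setdiff(needed, colnames(colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample (column) names must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an IntensityExperiment
#'
#' @param values numeric gene x sample matrix of nonnegative intensities;
#'   rownames are gene identifiers, colnames are sample identifiers.
#' @param genotype character vector, one of \code{"control"}/\code{"case"}
#'   per sample.
#' @param tissue character vector (recycled) of tissue labels.
#' @param replicate integer vector of replicate indices; defaults to a
#'   within-genotype running index.
#' @return an \linkS4class{IntensityExperiment}
#' @examples
#' m <- matrix(10^runif(60, 1, 3), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' ie <- IntensityExperiment(m, genotype = rep(c("control", "case"), each = 3))
#' ie
#' @export
IntensityExperiment <- function(values, genotype,
                                tissue = "tissue", replicate = NULL) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- paste0("g", seq_len(nrow(values)))
    genotype <- as.character(genotype)
    if (length(genotype) != ncol(values))
        stop("'genotype' must have one entry per sample")
    tissue <- rep_len(as.character(tissue), ncol(values))
    if (is.null(replicate))
        replicate <- stats::ave(seq_along(genotype),
                                paste(genotype, tissue), FUN = seq_along)
    cd <- DataFrame(genotype = genotype, tissue = tissue,
                    replicate = as.integer(replicate),
                    row.names = colnames(values))
    new("IntensityExperiment",
        SummarizedExperiment(assays = list(intensity = values), colData = cd))
}

## ---------------------------------------------------------------------------
## ZScoreExperiment
## ---------------------------------------------------------------------------

#' Per-array standardized log-intensities
#'
#' Holds column-standardized log10 intensities in an assay named \code{"z"}:
#' every column has mean 0 and (population) standard deviation 1. The
#' normalization provenance (log base, sd convention, intensity floor) is kept
#' in \code{metadata()}.
#'
#' @aliases ZScoreExperiment-class
#' @exportClass ZScoreExperiment
setClass("ZScoreExperiment", contains = "SummarizedExperiment")

setValidity("ZScoreExperiment", function(object) {
    msg <- character()
    if (!"z" %in% assayNames(object))
        msg <- c(msg, "assay 'z' is required")
    else {
        z <- assay(object, "z")
        mu <- colMeans(z)
        sdp <- sqrt(colMeans(sweep(z, 2, mu)^2))
        if (any(abs(mu) > 1e-8) || any(abs(sdp - 1) > 1e-8))
            msg <- c(msg, "each column must have mean 0 and population sd 1")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SignedGeneSet
## ---------------------------------------------------------------------------

#' A labelled set of identifiers with expression polarity
#'
#' Polarity is +1 (elevated) or -1 (decreased); identifiers are unique.
#'
#' @slot label single character dataset name (e.g. a tissue or omics layer).
#' @slot polarity named integer vector of +1/-1, names are identifiers.
#' @aliases SignedGeneSet-class
#' @exportClass SignedGeneSet
setClass("SignedGeneSet",
         representation(label = "character", polarity = "integer"))

setValidity("SignedGeneSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L || is.na(object@label))
        msg <- c(msg, "label must be a single non-missing string")
    pol <- object@polarity
    if (length(pol)) {
        if (is.null(names(pol)) || anyDuplicated(names(pol)))
            msg <- c(msg, "polarity must be named with unique identifiers")
        if (!all(pol %in% c(-1L, 1L)))
            msg <- c(msg, "polarity values must be +1 or -1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SignedGeneSet
#'
#' @param label dataset name.
#' @param polarity named numeric/integer vector of +1/-1 per identifier.
#' @return a \linkS4class{SignedGeneSet}
#' @examples
#' SignedGeneSet("hippocampus", c(g1 = 1, g2 = -1))
#' @export
SignedGeneSet <- function(label, polarity = integer()) {
    pol <- as.integer(polarity)
    names(pol) <- names(polarity)
    new("SignedGeneSet", label = as.character(label), polarity = pol)
}

## ---------------------------------------------------------------------------
## VennPartition
## ---------------------------------------------------------------------------

#' Signed Venn partition of several gene lists
#'
#' Every identifier present in any input set is assigned to exactly one
#' region, keyed by which sets contain it and with what polarity (e.g.
#' \code{"hip+&ctx-"}). Each region carries a category: \code{co_up} /
#' \code{co_down} (shared, polarity retained), \code{contra} (shared, any
#' pair of polarities disagrees) or \code{unique_up} / \code{unique_down}
#' (one set only).
#'
#' @slot labels character vector of input set labels, in input order.
#' @slot regions named list, region key -> character vector of identifiers.
#' @slot info data.frame with columns \code{region}, \code{sets},
#'   \code{category}, \code{count}, one row per non-empty region.
#' @aliases VennPartition-class
#' @exportClass VennPartition
setClass("VennPartition",
         representation(labels = "character", regions = "list",
                        info = "data.frame"))

setValidity("VennPartition", function(object) {
    msg <- character()
    ids <- unlist(object@regions, use.names = FALSE)
    if (anyDuplicated(ids))
        msg <- c(msg, "regions must be pairwise disjoint")
    if (nrow(object@info) != length(object@regions))
        msg <- c(msg, "info must have one row per region")
    if (length(object@regions) &&
        !identical(unname(vapply(object@regions, length, 0L)),
                   object@info$count))
        msg <- c(msg, "info counts must match region sizes")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PathwayCollection
## ---------------------------------------------------------------------------

#' A pathway (gene set) collection over a background universe
#'
#' Pathway membership is restricted to the universe at construction, mirroring
#' the usual over-representation setup where the background is the set of
#' genes actually measured on the platform.
#'
#' @slot pathways named list of character vectors (member genes).
#' @slot universe character vector of background gene identifiers.
#' @aliases PathwayCollection-class
#' @exportClass PathwayCollection
setClass("PathwayCollection",
         representation(pathways = "list", universe = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    if (!length(object@universe))
        msg <- c(msg, "universe must be non-empty")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe identifiers must be unique")
    if (length(object@pathways)) {
        if (is.null(names(object@pathways)) ||
            anyDuplicated(names(object@pathways)))
            msg <- c(msg, "pathways must be uniquely named")
        out <- vapply(object@pathways,
                      function(p) !all(p %in% object@universe), TRUE)
        if (any(out))
            msg <- c(msg, "every pathway must be a subset of the universe")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayCollection
#'
#' @param pathways named list of character vectors of member genes.
#' @param universe background gene identifiers; defaults to the union of all
#'   pathway members.
#' @param restrict drop pathway members absent from the universe (default
#'   TRUE; with FALSE, foreign members are an error).
#' @return a \linkS4class{PathwayCollection}
#' @examples
#' PathwayCollection(list(pw1 = c("g1", "g2")), universe = paste0("g", 1:5))
#' @export
PathwayCollection <- function(pathways, universe = NULL, restrict = TRUE) {
    pathways <- lapply(pathways, function(p) unique(as.character(p)))
    if (is.null(universe))
        universe <- unique(unlist(pathways, use.names = FALSE))
    universe <- unique(as.character(universe))
    if (restrict)
        pathways <- lapply(pathways, intersect, y = universe)
    new("PathwayCollection", pathways = pathways, universe = universe)
}

## ---------------------------------------------------------------------------
## Corpus
## ---------------------------------------------------------------------------

#' A gene-to-document text corpus
#'
#' One concatenated free-text document per gene; the vocabulary is derived by
#' tokenization (lowercased, punctuation stripped, split on whitespace and
#' hyphens).
#'
#' @slot documents named character vector, gene identifier -> text.
#' @aliases Corpus-class
#' @exportClass Corpus
setClass("Corpus", representation(documents = "character"))

setValidity("Corpus", function(object) {
    msg <- character()
    d <- object@documents
    if (!length(d))
        msg <- c(msg, "corpus must contain at least one document")
    if (is.null(names(d)) || anyDuplicated(names(d)) || any(!nzchar(names(d))))
        msg <- c(msg, "documents must be uniquely named by gene identifier")
    if (any(!nzchar(d)))
        msg <- c(msg, "documents must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Construct a Corpus
#'
#' @param documents named character vector of document texts.
#' @return a \linkS4class{Corpus}
#' @examples
#' Corpus(c(gA = "synaptic vesicle fusion", gB = "lipid metabolism"))
#' @export
Corpus <- function(documents) {
    new("Corpus", documents = documents)
}

## ---------------------------------------------------------------------------
## LsiSpace
## ---------------------------------------------------------------------------

#' A rank-k latent semantic space over a weighted term-document matrix
#'
#' Produced by \code{\link{lsiReduce}}. Document coordinates are the rows of
#' \eqn{V_k \Sigma_k}, so document-document cosines at full rank equal the raw
#' weighted-matrix cosines; queries are folded in through the term basis
#' \eqn{U_k}.
#'
#' @slot termVectors term x k matrix (rows of \eqn{U_k}).
#' @slot docVectors document x k matrix (rows of \eqn{V_k \Sigma_k}).
#' @slot singularValues length-k numeric.
#' @slot globalWeights named numeric, per-term log-entropy global weight.
#' @slot k integer rank.
#' @aliases LsiSpace-class
#' @exportClass LsiSpace
setClass("LsiSpace",
         representation(termVectors = "matrix", docVectors = "matrix",
                        singularValues = "numeric", globalWeights = "numeric",
                        k = "integer"))

setValidity("LsiSpace", function(object) {
    msg <- character()
    if (ncol(object@termVectors) != object@k ||
        ncol(object@docVectors) != object@k ||
        length(object@singularValues) != object@k)
        msg <- c(msg, "termVectors, docVectors and singularValues must share rank k")
    if (length(msg)) msg else TRUE
})
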