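#' @include AllClasses.R
NULL

#' Accessors for omicompare classes
#'
#' \code{intensities} returns the raw assay of an
#' \linkS4class{IntensityExperiment}; \code{zValues} the standardized assay of
#' a \linkS4class{ZScoreExperiment}; \code{sampleInfo} the sample metadata;
#' \code{setLabel}/\code{polarities} the slots of a
#' \linkS4class{SignedGeneSet}; \code{regionMembers}/\code{regionCounts} the
#' regions of a \linkS4class{VennPartition}; \code{pathwayList}/
#' \code{universeGenes} the slots of a \linkS4class{PathwayCollection};
#' \code{documents} the texts of a \linkS4class{Corpus}.
#'
#' @param x an object of the relevant class
#' @return the slot contents (see above)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "IntensityExperiment",
          function(x) assay(x, "intensity"))

#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname accessors
#' @export
setMethod("zValues", "ZScoreExperiment", function(x) assay(x, "z"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setMethod("sampleInfo", "SummarizedExperiment",
          function(x) as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname accessors
#' @export
setMethod("setLabel", "SignedGeneSet", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("polarities", function(x) standardGeneric("polarities"))

#' @rdname accessors
#' @export
setMethod("polarities", "SignedGeneSet", function(x) x@polarity)

#' @rdname accessors
#' @export
setGeneric("regionMembers", function(x) standardGeneric("regionMembers"))

#' @rdname accessors
#' @export
setMethod("regionMembers", "VennPartition", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @rdname accessors
#' @export
setMethod("regionCounts", "VennPartition", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("pathwayList", function(x) standardGeneric("pathwayList"))

#' @rdname accessors
#' @export
setMethod("pathwayList", "PathwayCollection", function(x) x@pathways)

#' @rdname accessors
#' @export
setGeneric("universeGenes", function(x) standardGeneric("universeGenes"))

#' @rdname accessors
#' @export
setMethod("universeGenes", "PathwayCollection", function(x) x@universe)

#' @rdname accessors
#' @export
setGeneric("documents", function(x) standardGeneric("documents"))

#' @rdname accessors
#' @export
setMethod("documents", "Corpus", function(x) x@documents)

## show methods -------------------------------------------------------------

setMethod("show", "SignedGeneSet", function(object) {
    pol <- object@polarity
    cat("SignedGeneSet '", object@label, "': ", length(pol),
        " identifiers (", sum(pol > 0), " up, ", sum(pol < 0), " down)\n",
        sep = "")
})

setMethod("show", "VennPartition", function(object) {
    cat("VennPartition of ", length(object@labels), " sets (",
        paste(object@labels, collapse = ", "), "): ",
        length(object@regions), " non-empty regions, ",
        sum(object@info$count), " identifiers\n", sep = "")
    tot <- tapply(object@info$count, object@info$category, sum)
    cat(paste0("  ", names(tot), ": ", tot, collapse = "\n"), "\n")
})

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection: ", length(object@pathways), " pathways over a ",
        length(object@universe), "-gene universe\n", sep = "")
})

setMethod("show", "Corpus", function(object) {
    cat("Corpus: ", length(object@documents), " documents, ~",
        sum(lengths(strsplit(object@documents, "\\s+"))), " tokens\n",
        sep = "")
})

setMethod("show", "LsiSpace", function(object) {
    cat("LsiSpace: rank ", object@k, ", ", nrow(object@termVectors),
        " terms x ", nrow(object@docVectors), " documents\n", sep = "")
})
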