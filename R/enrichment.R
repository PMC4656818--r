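#' @include AllGenerics.R
NULL

#' Hypergeometric pathway over-representation
#'
#' For every pathway with at least \code{minMembers} members in
#' \code{geneList}, computes the observed member count \eqn{O}, the expected
#' count \eqn{E = n K / N} (list size \eqn{n}, pathway size \eqn{K}, universe
#' size \eqn{N}), the enrichment ratio \eqn{R = O/E}, and the upper-tail
#' hypergeometric probability of drawing \eqn{\ge O} pathway members in
#' \eqn{n} draws from the universe. A pathway is flagged significant when
#' \eqn{R > 1} and \eqn{p} is below \code{pThreshold}; no multiple-testing
#' correction is applied by default (set \code{adjust = TRUE} for an
#' additional Benjamini-Hochberg column, which then also gates the flag).
#'
#' @param geneList character vector of significant genes; identifiers outside
#'   the universe are dropped with a warning.
#' @param collection a \linkS4class{PathwayCollection}.
#' @param minMembers minimum observed pathway population (default 2).
#' @param pThreshold significance threshold on the raw p (default 0.05).
#' @param adjust also compute BH-adjusted q-values (default FALSE).
#' @return data.frame with columns \code{pathway_id}, \code{pathway_size},
#'   \code{list_size}, \code{O}, \code{E}, \code{R}, \code{p} (and \code{q}
#'   if requested) and \code{significant}, ordered by increasing p.
#' @examples
#' coll <- PathwayCollection(list(pw = paste0("g", 1:5)),
#'                           universe = paste0("g", 1:10))
#' hypergeometricEnrichment(paste0("g", 1:4), coll, minMembers = 2)
#' @export
hypergeometricEnrichment <- function(geneList, collection, minMembers = 2,
                                     pThreshold = 0.05, adjust = FALSE) {
    stopifnot(is(collection, "PathwayCollection"))
    universe <- universeGenes(collection)
    geneList <- unique(as.character(geneList))
    if (!length(geneList)) stop("gene list is empty")
    outside <- setdiff(geneList, universe)
    if (length(outside)) {
        warning(length(outside), " identifier(s) outside the universe dropped")
        geneList <- intersect(geneList, universe)
    }
    if (!length(geneList)) stop("no gene-list members left in the universe")
    N <- length(universe); n <- length(geneList)
    pw <- pathwayList(collection)
    rows <- lapply(names(pw), function(id) {
        K <- length(pw[[id]])
        O <- length(intersect(pw[[id]], geneList))
        if (O < minMembers) return(NULL)
        E <- n * K / N
        data.frame(pathway_id = id, pathway_size = K, list_size = n,
                   O = O, E = E, R = O / E,
                   p = stats::phyper(O - 1, K, N - K, n, lower.tail = FALSE))
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        return(data.frame(pathway_id = character(), pathway_size = integer(),
                          list_size = integer(), O = integer(), E = numeric(),
                          R = numeric(), p = numeric(),
                          significant = logical()))
    res <- res[order(res$p), , drop = FALSE]
    rownames(res) <- NULL
    if (adjust) {
        res$q <- bhFdr(res$p)
        res$significant <- res$R > 1 & res$p < pThreshold & res$q < pThreshold
    } else {
        res$significant <- res$R > 1 & res$p < pThreshold
    }
    res
}

#' Pathway polarity score
#'
#' The percentage of populated pathway members that are elevated minus the
#' percentage that are decreased: \eqn{100 U/(U+D) - 100 D/(U+D)} where
#' \eqn{U} and \eqn{D} count pathway members in the up and down sets. The
#' denominator is the populated membership \eqn{U + D} (members in neither
#' significant list do not dilute the score), so a purely elevated pathway
#' scores +100 and a purely decreased one -100; an unpopulated pathway
#' scores 0.
#'
#' @param members character vector of pathway member genes.
#' @param upSet,downSet disjoint character vectors of up- and down-regulated
#'   genes.
#' @return numeric score in [-100, 100].
#' @examples
#' polarityScore(paste0("g", 1:10), paste0("g", 1:6), paste0("g", 7:8))
#' @export
polarityScore <- function(members, upSet, downSet) {
    if (length(intersect(upSet, downSet)))
        stop("up and down sets must be disjoint")
    U <- length(intersect(members, upSet))
    D <- length(intersect(members, downSet))
    if (U + D == 0) return(0)
    100 * U / (U + D) - 100 * D / (U + D)
}

#' Polarity scores for every pathway in a collection
#'
#' @inheritParams polarityScore
#' @param collection a \linkS4class{PathwayCollection}
#' @return named numeric vector, one score per pathway
#' @export
pathwayPolarityScores <- function(collection, upSet, downSet) {
    stopifnot(is(collection, "PathwayCollection"))
    vapply(pathwayList(collection), polarityScore, 0,
           upSet = upSet, downSet = downSet)
}

#' Bimodal up/down pathway classification
#'
#' Compares enrichment runs performed separately on the up-regulated and
#' down-regulated gene lists: a pathway significant in both runs is
#' \code{bimodal} (populated from both directions), in one run only
#' \code{up_only}/\code{down_only}, otherwise \code{none}.
#'
#' @param upRecords,downRecords enrichment tables from
#'   \code{\link{hypergeometricEnrichment}} run on the up and down lists
#'   against the same collection.
#' @return data.frame with columns \code{pathway_id} and \code{class}.
#' @export
bimodalClassification <- function(upRecords, downRecords) {
    sigU <- upRecords$pathway_id[upRecords$significant]
    sigD <- downRecords$pathway_id[downRecords$significant]
    ids <- union(upRecords$pathway_id, downRecords$pathway_id)
    cls <- ifelse(ids %in% sigU & ids %in% sigD, "bimodal",
           ifelse(ids %in% sigU, "up_only",
           ifelse(ids %in% sigD, "down_only", "none")))
    data.frame(pathway_id = ids,
               class = factor(cls, levels = c("up_only", "down_only",
                                              "bimodal", "none")))
}

#' Read a GMT gene-set file into a PathwayCollection
#'
#' @param path GMT file (tab-separated: set name, description, members).
#' @param universe optional background gene universe; defaults to the union
#'   of all set members.
#' @return a \linkS4class{PathwayCollection}
#' @export
readGmt <- function(path, universe = NULL) {
    PathwayCollection(fgsea::gmtPathways(path), universe = universe)
}

#' Write a PathwayCollection as GMT
#'
#' @param collection a \linkS4class{PathwayCollection}
#' @param path destination file
#' @return invisibly, \code{path}
#' @export
writeGmt <- function(collection, path) {
    stopifnot(is(collection, "PathwayCollection"))
    pw <- pathwayList(collection)
    lines <- vapply(names(pw), function(id)
        paste(c(id, "na", pw[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
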