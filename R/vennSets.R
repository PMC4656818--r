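#' @include AllGenerics.R
NULL

#' Build a signed gene set from differential-expression records
#'
#' Keeps the genes called \code{up} or \code{down} and records their polarity
#' (+1 / -1).
#'
#' @param records data.frame with \code{gene_id} and \code{call} columns (as
#'   produced by \code{\link{runDifferentialExpression}}).
#' @param label dataset name for the resulting set.
#' @return a \linkS4class{SignedGeneSet}
#' @examples
#' rec <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   call = c("up", "down", "ns"))
#' buildSignedSet(rec, "hippocampus")
#' @export
buildSignedSet <- function(records, label) {
    stopifnot(all(c("gene_id", "call") %in% colnames(records)))
    call <- as.character(records$call)
    keep <- call %in% c("up", "down")
    pol <- ifelse(call[keep] == "up", 1L, -1L)
    names(pol) <- as.character(records$gene_id[keep])
    SignedGeneSet(label, pol)
}

#' Signed Venn partition of 2-4 gene sets
#'
#' Assigns every identifier to exactly one region keyed by the sets that
#' contain it and its polarity in each (e.g. \code{"hip+&ctx-"}). Shared
#' identifiers whose polarity is retained across all containing sets fall in
#' \code{co_up}/\code{co_down} regions; identifiers for which any pair of
#' containing sets disagrees in sign are \code{contra}-regulated; identifiers
#' in a single set are \code{unique_up}/\code{unique_down}.
#'
#' @param sets list of 2-4 \linkS4class{SignedGeneSet}s with distinct labels.
#' @return a \linkS4class{VennPartition}
#' @examples
#' a <- SignedGeneSet("A", c(g1 = 1, g2 = -1, g3 = 1))
#' b <- SignedGeneSet("B", c(g1 = 1, g2 = 1, g4 = -1))
#' vennPartition(list(a, b))
#' @export
vennPartition <- function(sets) {
    stopifnot(length(sets) >= 2L, length(sets) <= 4L,
              all(vapply(sets, is, TRUE, "SignedGeneSet")))
    labels <- vapply(sets, setLabel, "")
    if (anyDuplicated(labels)) stop("set labels must be unique")
    ids <- unique(unlist(lapply(sets, function(s) names(polarities(s)))))
    if (!length(ids)) {
        return(new("VennPartition", labels = labels, regions = list(),
                   info = data.frame(region = character(),
                                     sets = character(),
                                     category = character(),
                                     count = integer())))
    }
    pol <- vapply(sets, function(s) {
        p <- polarities(s)
        out <- rep(NA_integer_, length(ids))
        out[match(names(p), ids)] <- p
        out
    }, integer(length(ids)))
    pol <- matrix(pol, nrow = length(ids),
                  dimnames = list(ids, labels))

    keyOf <- function(i) {
        inset <- !is.na(pol[i, ])
        paste0(labels[inset], ifelse(pol[i, inset] > 0, "+", "-"),
               collapse = "&")
    }
    catOf <- function(i) {
        v <- pol[i, !is.na(pol[i, ])]
        if (length(v) == 1L) {
            if (v > 0) "unique_up" else "unique_down"
        } else if (length(unique(v)) > 1L) "contra"
        else if (v[1] > 0) "co_up" else "co_down"
    }
    keys <- vapply(seq_along(ids), keyOf, "")
    cats <- vapply(seq_along(ids), catOf, "")
    regions <- split(ids, keys)
    ord <- order(match(names(regions), unique(keys)))
    regions <- regions[ord]
    info <- data.frame(region = names(regions),
                       sets = vapply(names(regions), function(k)
                           paste(gsub("[+-]$", "",
                                      strsplit(k, "&", fixed = TRUE)[[1]]),
                                 collapse = "&"), ""),
                       category = cats[match(names(regions), keys)],
                       count = unname(vapply(regions, length, 0L)),
                       row.names = NULL)
    new("VennPartition", labels = labels, regions = regions, info = info)
}

#' Totals per regulation category
#'
#' Sums region counts by category (\code{co_up}, \code{co_down},
#' \code{contra}, \code{unique_up}, \code{unique_down}).
#'
#' @param partition a \linkS4class{VennPartition}
#' @return named integer vector (absent categories are 0)
#' @export
categoryCounts <- function(partition) {
    stopifnot(is(partition, "VennPartition"))
    lev <- c("co_up", "co_down", "contra", "unique_up", "unique_down")
    info <- regionCounts(partition)
    out <- vapply(lev, function(l) sum(info$count[info$category == l]), 0L)
    names(out) <- lev
    out
}

#' Transcript-versus-protein overlap with concordance annotation
#'
#' Reconciles identifiers across the two omics layers by case-insensitive
#' symbol equality, partitions the union, and annotates each shared symbol as
#' concordant (same polarity in both layers) or discordant (opposite).
#'
#' @param transcripts,proteins \linkS4class{SignedGeneSet}s; gene and protein
#'   symbols are matched ignoring case (no alias or ortholog mapping).
#' @return list with \code{partition} (a \linkS4class{VennPartition} over the
#'   case-folded identifiers) and \code{shared}, a data.frame with columns
#'   \code{identifier}, \code{transcript_id}, \code{protein_id},
#'   \code{transcript_polarity}, \code{protein_polarity},
#'   \code{concordance}.
#' @examples
#' tr <- SignedGeneSet("transcript", c(wfs1 = 1, slc25a3 = -1))
#' pr <- SignedGeneSet("protein", c(Wfs1 = 1, Slc25a3 = 1))
#' crossOmicsOverlap(tr, pr)$shared
#' @export
crossOmicsOverlap <- function(transcripts, proteins) {
    stopifnot(is(transcripts, "SignedGeneSet"), is(proteins, "SignedGeneSet"))
    fold <- function(s) {
        p <- polarities(s)
        if (anyDuplicated(tolower(names(p))))
            stop("case-folding collapses distinct identifiers in set '",
                 setLabel(s), "'")
        names(p) <- tolower(names(p))
        SignedGeneSet(setLabel(s), p)
    }
    tf <- fold(transcripts); pf <- fold(proteins)
    part <- vennPartition(list(tf, pf))
    shared <- intersect(names(polarities(tf)), names(polarities(pf)))
    tNames <- names(polarities(transcripts))
    pNames <- names(polarities(proteins))
    tp <- unname(polarities(tf)[shared])
    pp <- unname(polarities(pf)[shared])
    sharedDf <- data.frame(
        identifier = shared,
        transcript_id = tNames[match(shared, tolower(tNames))],
        protein_id = pNames[match(shared, tolower(pNames))],
        transcript_polarity = tp,
        protein_polarity = pp,
        concordance = ifelse(tp == pp, "concordant", "discordant"),
        row.names = NULL)
    list(partition = part, shared = sharedDf)
}

#' Write Venn region membership and counts
#'
#' @param partition a \linkS4class{VennPartition}
#' @param membersPath TSV destination for (region_key, identifier) rows.
#' @param countsPath optional JSON destination for the per-region and
#'   per-category counts.
#' @return invisibly, the membership data.frame
#' @export
writeVennRegions <- function(partition, membersPath, countsPath = NULL) {
    regions <- regionMembers(partition)
    df <- data.frame(
        region_key = rep(names(regions), lengths(regions)),
        identifier = unlist(regions, use.names = FALSE))
    utils::write.table(df, membersPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(countsPath)) {
        counts <- as.list(stats::setNames(regionCounts(partition)$count,
                                          regionCounts(partition)$region))
        jsonlite::write_json(list(regions = counts,
                                  categories = as.list(categoryCounts(partition))),
                             countsPath, auto_unbox = TRUE)
    }
    invisible(df)
}
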