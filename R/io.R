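#' @include AllGenerics.R
NULL

#' Read / write gene-by-sample intensity matrices as TSV
#'
#' The TSV dialect is genes as rows (first column \code{gene_id}), one column
#' per sample with the sample id in the header. Sample metadata is supplied
#' separately (or as a companion TSV with columns \code{sample_id},
#' \code{genotype}, \code{tissue}, \code{replicate}).
#'
#' @param path TSV file.
#' @param metadata data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{tissue}, \code{replicate}, or the path of such a
#'   TSV.
#' @return an \linkS4class{IntensityExperiment}
#' @export
readIntensityMatrix <- function(path, metadata) {
    tab <- utils::read.delim(path, check.names = FALSE)
    stopifnot(colnames(tab)[1] == "gene_id")
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- tab$gene_id
    if (is.character(metadata) && length(metadata) == 1L)
        metadata <- utils::read.delim(metadata)
    m <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
    if (anyNA(m$sample_id))
        stop("metadata missing for sample(s): ",
             paste(setdiff(colnames(values), metadata$sample_id),
                   collapse = ", "))
    IntensityExperiment(values, genotype = m$genotype, tissue = m$tissue,
                        replicate = m$replicate)
}

#' @rdname readIntensityMatrix
#' @param x an \linkS4class{IntensityExperiment}
#' @param metaPath optional destination for the sample-metadata TSV
#' @export
writeIntensityMatrix <- function(x, path, metaPath = NULL) {
    stopifnot(is(x, "IntensityExperiment"))
    df <- data.frame(gene_id = rownames(x), intensities(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metaPath)) {
        meta <- cbind(sample_id = colnames(x), sampleInfo(x))
        utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read / write peptide reporter-ion tables as CSV
#'
#' Columns: \code{peptide_id}, \code{protein_id}, \code{i114}, \code{i115},
#' \code{i116}, \code{i117}.
#'
#' @param path CSV file.
#' @return data.frame peptide table
#' @export
readPeptideTable <- function(path) {
    .checkPeptideTable(utils::read.csv(path))
}

#' @rdname readPeptideTable
#' @param tab peptide table data.frame
#' @export
writePeptideTable <- function(tab, path) {
    .checkPeptideTable(tab)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write a gene-document corpus as JSON-lines
#'
#' One JSON object per line with fields \code{gene_id} and \code{text}.
#'
#' @param path JSON-lines file.
#' @return a \linkS4class{Corpus}
#' @export
readCorpusJsonl <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    docs <- vapply(recs, function(r) r$text, "")
    names(docs) <- vapply(recs, function(r) r$gene_id, "")
    Corpus(docs)
}

#' @rdname readCorpusJsonl
#' @param corpus a \linkS4class{Corpus}
#' @export
writeCorpusJsonl <- function(corpus, path) {
    stopifnot(is(corpus, "Corpus"))
    docs <- documents(corpus)
    lines <- vapply(seq_along(docs), function(i)
        jsonlite::toJSON(list(gene_id = names(docs)[i], text = docs[[i]]),
                         auto_unbox = TRUE), "")
    writeLines(lines, path)
    invisible(path)
}
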