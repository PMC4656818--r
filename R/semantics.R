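#' @include AllGenerics.R
NULL

#' Default English stop-word list
#'
#' A small built-in list removed during tokenization; override via the
#' \code{stopwords} argument of the corpus functions.
#'
#' @return character vector of stop words
#' @export
defaultStopwords <- function() {
    c("a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "has",
      "in", "is", "it", "its", "of", "on", "or", "that", "the", "this",
      "to", "was", "were", "which", "with")
}

.tokenize <- function(text, stopwords = defaultStopwords()) {
    text <- tolower(text)
    text <- gsub("-", " ", text, fixed = TRUE)
    text <- gsub("[^a-z0-9 ]", "", text)
    tokens <- strsplit(trimws(gsub("\\s+", " ", text)), " ", fixed = TRUE)
    lapply(tokens, function(tk) tk[nzchar(tk) & !(tk %in% stopwords)])
}

.cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

#' Log-entropy weighted term-document matrix
#'
#' Builds the term x document matrix with local weight \eqn{\log(1 +
#' tf_{ij})} and global weight \eqn{g_i = 1 + \sum_j p_{ij} \log p_{ij} /
#' \log n} where \eqn{p_{ij} = tf_{ij}/gf_i} and \eqn{n} is the number of
#' documents. A term spread uniformly over all documents gets global weight
#' 0 (muted); a term confined to a single document gets weight 1.
#'
#' @param corpus a \linkS4class{Corpus} with at least 2 documents.
#' @param stopwords tokens to discard (default
#'   \code{\link{defaultStopwords}}).
#' @return numeric term x document matrix; the per-term global weights are
#'   attached as attribute \code{"globalWeights"}.
#' @examples
#' co <- Corpus(c(gA = "synapse synapse vesicle", gB = "lipid vesicle"))
#' buildWeightedMatrix(co)
#' @export
buildWeightedMatrix <- function(corpus, stopwords = defaultStopwords()) {
    stopifnot(is(corpus, "Corpus"))
    docs <- documents(corpus)
    if (length(docs) < 2L) stop("need at least 2 documents")
    tokens <- .tokenize(docs, stopwords)
    vocab <- sort(unique(unlist(tokens)))
    if (!length(vocab)) stop("empty vocabulary after tokenization")
    tf <- vapply(tokens, function(tk)
        tabulate(match(tk, vocab), nbins = length(vocab)),
        numeric(length(vocab)))
    tf <- matrix(tf, nrow = length(vocab),
                 dimnames = list(vocab, names(docs)))
    n <- ncol(tf)
    gf <- rowSums(tf)
    p <- tf / gf
    plogp <- ifelse(p > 0, p * log(p), 0)
    global <- 1 + rowSums(plogp) / log(n)
    w <- log(1 + tf) * global
    attr(w, "globalWeights") <- global
    w
}

#' Truncated-SVD latent semantic space
#'
#' Computes the rank-\code{k} singular value decomposition \eqn{W \approx U_k
#' \Sigma_k V_k^T} of a weighted term-document matrix. Documents are
#' represented as rows of \eqn{V_k \Sigma_k}, so at full rank
#' document-document cosines reproduce the raw weighted-matrix cosines
#' exactly.
#'
#' @param w weighted matrix from \code{\link{buildWeightedMatrix}}.
#' @param k number of latent dimensions, between 1 and
#'   \code{min(dim(w))}; default \code{min(300, min(dim(w)))}.
#' @return an \linkS4class{LsiSpace}
#' @export
lsiReduce <- function(w, k = min(300L, min(dim(w)))) {
    k <- as.integer(k)
    if (k < 1L || k > min(dim(w)))
        stop("k must lie in [1, min(terms, documents)]")
    sv <- svd(w, nu = k, nv = k)
    gw <- attr(w, "globalWeights")
    if (is.null(gw)) gw <- stats::setNames(rep(1, nrow(w)), rownames(w))
    d <- sv$d[seq_len(k)]
    term <- sv$u; rownames(term) <- rownames(w)
    doc <- sweep(sv$v, 2, d, `*`); rownames(doc) <- colnames(w)
    new("LsiSpace", termVectors = term, docVectors = doc,
        singularValues = d, globalWeights = gw, k = k)
}

#' Document-document cosine similarities in the latent space
#'
#' @param space an \linkS4class{LsiSpace}
#' @return symmetric document x document cosine matrix
#' @export
latentDocCosines <- function(space) {
    stopifnot(is(space, "LsiSpace"))
    d <- space@docVectors
    nrm <- sqrt(rowSums(d^2))
    nrm[nrm == 0] <- 1
    (d / nrm) %*% t(d / nrm)
}

.foldQuery <- function(space, query, stopwords = defaultStopwords()) {
    tokens <- .tokenize(query, stopwords)[[1]]
    vocab <- rownames(space@termVectors)
    tokens <- tokens[tokens %in% vocab]
    if (!length(tokens)) return(NULL)
    tf <- tabulate(match(tokens, vocab), nbins = length(vocab))
    q <- log(1 + tf) * space@globalWeights[vocab]
    as.numeric(crossprod(space@termVectors, q))   # U_k' q: doc-space coords
}

#' Rank genes by latent-space association with a keyword
#'
#' The query is tokenized, weighted with the stored global weights and folded
#' into the latent space through the term basis; the cosine between the
#' folded query and each gene's document vector is the association score.
#' Scores above 0.2 are classed \code{explicit} (the keyword effectively
#' occurs in the gene's literature), scores in [0.1, 0.2] \code{implicit}
#' (related only through co-occurring vocabulary), anything lower
#' \code{none}. A query with no in-vocabulary token scores every gene 0 with
#' a warning.
#'
#' @param space an \linkS4class{LsiSpace} built from the gene corpus.
#' @param query keyword (or phrase) to score against.
#' @param genes gene identifiers to score; default all documents.
#' @param explicitThreshold,implicitThreshold class boundaries (defaults 0.2
#'   and 0.1; the boundary value 0.2 itself classes as implicit).
#' @return data.frame with columns \code{subject}, \code{query},
#'   \code{cosine}, \code{class}, sorted by descending cosine.
#' @examples
#' sim <- simulateLiteratureCorpus(paste0("g", 1:6), "autism",
#'     links = data.frame(gene = "g1", keyword = "autism",
#'                        type = "explicit"), seed = 1)
#' sp <- lsiReduce(buildWeightedMatrix(sim$corpus))
#' head(keywordGeneScores(sp, "autism", genes = paste0("g", 1:6)), 3)
#' @export
keywordGeneScores <- function(space, query, genes = NULL,
                              explicitThreshold = 0.2,
                              implicitThreshold = 0.1) {
    stopifnot(is(space, "LsiSpace"))
    docs <- rownames(space@docVectors)
    if (is.null(genes)) genes <- docs
    if (!all(genes %in% docs))
        stop("unknown gene document(s): ",
             paste(setdiff(genes, docs), collapse = ", "))
    qv <- .foldQuery(space, query)
    if (is.null(qv)) {
        warning("query '", query, "' has no in-vocabulary term; all scores 0")
        cos <- rep(0, length(genes))
    } else {
        cos <- vapply(genes, function(g)
            .cosine(qv, space@docVectors[g, ]), 0)
    }
    cls <- ifelse(cos > explicitThreshold, "explicit",
           ifelse(cos >= implicitThreshold, "implicit", "none"))
    out <- data.frame(subject = genes, query = query, cosine = unname(cos),
                      class = factor(cls, levels = c("explicit", "implicit",
                                                     "none")))
    out[order(-out$cosine), , drop = FALSE]
}

#' Dismantle noun phrases into word occurrence counts
#'
#' Phrases are split on whitespace and hyphens, lowercased and stripped of
#' punctuation; the count of each resulting word is returned. Stop words are
#' kept: the input is assumed to be curated noun phrases.
#'
#' @param phrases character vector of (noun) phrases.
#' @return data.frame with columns \code{word}, \code{count}, by decreasing
#'   count then alphabetically.
#' @examples
#' dismantleAndCount(c("synaptic plasticity", "synaptic vesicle",
#'                     "brain-derived"))
#' @export
dismantleAndCount <- function(phrases) {
    stopifnot(is.character(phrases))
    if (!length(phrases))
        return(data.frame(word = character(), count = integer()))
    words <- unlist(.tokenize(phrases, stopwords = character()))
    if (!length(words))
        return(data.frame(word = character(), count = integer()))
    tab <- table(words)
    out <- data.frame(word = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$word), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Word score table for a dataset's textual cloud
#'
#' Combines occurrence counts (from \code{\link{dismantleAndCount}}) with a
#' per-word standardized occurrence z-score and, when a latent space and a
#' set of reference documents are supplied, the cosine between each word's
#' term vector and the centroid of those documents' latent vectors (0 for
#' out-of-vocabulary words).
#'
#' @param phrases character vector of noun phrases for one dataset.
#' @param space optional \linkS4class{LsiSpace}.
#' @param docIds optional document identifiers whose latent centroid anchors
#'   the cosine column (default: all documents of \code{space}).
#' @return data.frame with columns \code{word}, \code{count}, \code{z_score},
#'   \code{cosine}.
#' @export
wordScoreTable <- function(phrases, space = NULL, docIds = NULL) {
    counts <- dismantleAndCount(phrases)
    n <- nrow(counts)
    counts$z_score <- if (n > 1 && stats::sd(counts$count) > 0)
        as.numeric(scale(counts$count)) else rep(0, n)
    if (is.null(space)) {
        counts$cosine <- rep(NA_real_, n)
        return(counts)
    }
    stopifnot(is(space, "LsiSpace"))
    if (is.null(docIds)) docIds <- rownames(space@docVectors)
    centroid <- colMeans(space@docVectors[docIds, , drop = FALSE])
    sig <- space@singularValues
    counts$cosine <- vapply(counts$word, function(wd) {
        if (!wd %in% rownames(space@termVectors)) return(0)
        # term in doc-coordinate space: row of U_k scaled by the singular values
        .cosine(space@termVectors[wd, ] * sig, centroid)
    }, 0)
    counts
}

#' Differential word scores between two datasets
#'
#' For words present in both tables, the differences (a minus b) of the
#' occurrence z-scores and cosines, sorted by descending z-score difference.
#'
#' @param a,b word score tables from \code{\link{wordScoreTable}}.
#' @return data.frame with columns \code{word}, \code{d_z_score},
#'   \code{d_cosine}; empty (with a warning) when no word is shared.
#' @export
differentialWordScores <- function(a, b) {
    common <- intersect(a$word, b$word)
    if (!length(common)) {
        warning("no word common to both tables")
        return(data.frame(word = character(), d_z_score = numeric(),
                          d_cosine = numeric()))
    }
    ia <- match(common, a$word); ib <- match(common, b$word)
    out <- data.frame(word = common,
                      d_z_score = a$z_score[ia] - b$z_score[ib],
                      d_cosine = a$cosine[ia] - b$cosine[ib])
    out <- out[order(-out$d_z_score), , drop = FALSE]
    rownames(out) <- NULL
    out
}
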