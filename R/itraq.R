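#' @include AllGenerics.R
NULL

.checkPeptideTable <- function(tab) {
    needed <- c("peptide_id", "protein_id", "i114", "i115", "i116", "i117")
    missing <- setdiff(needed, colnames(tab))
    if (length(missing))
        stop("peptide table lacks column(s): ", paste(missing, collapse = ", "))
    ch <- as.matrix(tab[, c("i114", "i115", "i116", "i117")])
    if (anyNA(ch) || any(ch < 0))
        stop("reporter intensities must be nonnegative and non-missing")
    invisible(tab)
}

#' Protein-level ratios from 4-plex reporter-ion intensities
#'
#' Per peptide, computes the control-channel ratio \code{r_ctrl = i114/i115}
#' and the case-versus-control ratios \code{r116 = i116 / mean(i114, i115)}
#' and \code{r117 = i117 / mean(i114, i115)} (the case channel over the mean
#' of the two pooled-control channels). Peptides with any zero denominator
#' are skipped with a message. Each protein's ratios are the medians across
#' its usable peptides; proteins with fewer than \code{minPeptides} usable
#' peptides (or none) are excluded, the latter with a warning.
#'
#' @param tab data.frame with columns \code{peptide_id}, \code{protein_id},
#'   \code{i114}, \code{i115}, \code{i116}, \code{i117}.
#' @param minPeptides minimum usable peptides per reported protein
#'   (default 1: proteins quantified from a single compliant spectrum are
#'   kept).
#' @return data.frame with columns \code{protein_id}, \code{r_ctrl},
#'   \code{r116}, \code{r117}, \code{n_peptides}.
#' @examples
#' tab <- data.frame(peptide_id = c("p1", "p2"), protein_id = "P1",
#'                   i114 = c(100, 110), i115 = c(100, 90),
#'                   i116 = c(150, 160), i117 = c(140, 150))
#' aggregateProteinRatios(tab)
#' @export
aggregateProteinRatios <- function(tab, minPeptides = 1) {
    .checkPeptideTable(tab)
    if (!nrow(tab)) stop("peptide table is empty")
    ctrlMean <- (tab$i114 + tab$i115) / 2
    usable <- tab$i115 > 0 & ctrlMean > 0
    if (any(!usable))
        message(sum(!usable), " peptide(s) with zero denominator skipped")
    proteins <- unique(as.character(tab$protein_id))
    rows <- lapply(proteins, function(pid) {
        sel <- usable & tab$protein_id == pid
        if (!any(sel)) {
            warning("protein '", pid, "' has no usable peptide; excluded")
            return(NULL)
        }
        if (sum(sel) < minPeptides) return(NULL)
        data.frame(protein_id = pid,
                   r_ctrl = stats::median(tab$i114[sel] / tab$i115[sel]),
                   r116 = stats::median(tab$i116[sel] / ctrlMean[sel]),
                   r117 = stats::median(tab$i117[sel] / ctrlMean[sel]),
                   n_peptides = sum(sel))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(protein_id = character(), r_ctrl = numeric(),
                          r116 = numeric(), r117 = numeric(),
                          n_peptides = integer())
    rownames(out) <- NULL
    out
}

#' Control-channel quality gate
#'
#' A protein passes QC when its pooled-control ratio 114:115 lies strictly
#' inside (\code{lo}, \code{hi}); ratios at exactly the limits fail. Failing
#' proteins are retained in the table (for the QC report) but are never
#' called differential.
#'
#' @param records protein table from \code{\link{aggregateProteinRatios}}.
#' @param lo,hi strict acceptance limits on \code{r_ctrl} (defaults 0.8 and
#'   1.2).
#' @return \code{records} with a logical \code{qc_pass} column.
#' @examples
#' controlQcFilter(data.frame(protein_id = "P1", r_ctrl = c(0.8)))
#' @export
controlQcFilter <- function(records, lo = 0.8, hi = 1.2) {
    stopifnot("r_ctrl" %in% colnames(records), lo < hi)
    records$qc_pass <- records$r_ctrl > lo & records$r_ctrl < hi
    records
}

#' Differential protein calls from case-channel ratios
#'
#' QC-passing proteins are called by where the 116:(control mean) and
#' 117:(control mean) ratios fall relative to the limits. Default mode
#' \code{"any"}: \code{up} if either case ratio exceeds \code{hi}, \code{down}
#' if either falls below \code{lo}; if one channel is above \code{hi} while
#' the other is below \code{lo} the channels contradict each other and the
#' protein is left \code{unchanged} with \code{conflict = TRUE}. Mode
#' \code{"both"} requires the two case channels to be concordantly outside
#' the same limit. Proteins failing QC are always \code{unchanged}.
#'
#' @param records table with \code{r116}, \code{r117} and \code{qc_pass}
#'   (from \code{\link{controlQcFilter}}).
#' @param lo,hi ratio limits (defaults 0.8 and 1.2), strict inequalities.
#' @param channelMode \code{"any"} (default) or \code{"both"}.
#' @return \code{records} with \code{call}
#'   (\code{up}/\code{down}/\code{unchanged}) and logical \code{conflict}
#'   columns.
#' @export
differentialCall <- function(records, lo = 0.8, hi = 1.2,
                             channelMode = c("any", "both")) {
    channelMode <- match.arg(channelMode)
    stopifnot(all(c("r116", "r117", "qc_pass") %in% colnames(records)),
              lo < hi)
    up116 <- records$r116 > hi; up117 <- records$r117 > hi
    dn116 <- records$r116 < lo; dn117 <- records$r117 < lo
    conflict <- (up116 & dn117) | (dn116 & up117)
    call <- rep("unchanged", nrow(records))
    if (channelMode == "any") {
        call[(up116 | up117) & !conflict] <- "up"
        call[(dn116 | dn117) & !conflict] <- "down"
    } else {
        call[up116 & up117] <- "up"
        call[dn116 & dn117] <- "down"
    }
    call[!records$qc_pass] <- "unchanged"
    records$call <- factor(call, levels = c("up", "down", "unchanged"))
    records$conflict <- conflict & records$qc_pass
    records
}

#' Full iTRAQ protein quantification and differential calling
#'
#' Aggregates peptide reporter-ion ratios to protein level, applies the
#' control-channel QC gate and the case-channel differential call.
#'
#' @inheritParams aggregateProteinRatios
#' @inheritParams differentialCall
#' @return data.frame of \code{\link{differentialCall}} output.
#' @examples
#' sim <- simulateItraqExperiment(50, fold = 1.5, seed = 1)
#' table(runItraqAnalysis(sim$peptides)$call)
#' @export
runItraqAnalysis <- function(tab, minPeptides = 1, lo = 0.8, hi = 1.2,
                             channelMode = "any") {
    rec <- aggregateProteinRatios(tab, minPeptides = minPeptides)
    rec <- controlQcFilter(rec, lo = lo, hi = hi)
    differentialCall(rec, lo = lo, hi = hi, channelMode = channelMode)
}
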