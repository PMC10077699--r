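## Per-peak normalized-depth m6A quantification and High-vs-Low
## differential methylation.

#' Normalized read count (SRN/ITR)
#'
#' Library-size normalization of a region read count: the region's summed
#' read number (SRN) divided by the individual's total reads (ITR).  Both
#' IP and input tracks go through the same normalization.
#'
#' @param srn region read count(s).
#' @param itr library total read count(s); must be positive.
#' @return `srn / itr`.
#' @examples
#' normalizedReadCount(500, 1e6)
#' @export
normalizedReadCount <- function(srn, itr) {
    if (any(itr <= 0)) stop("library total (ITR) must be > 0")
    if (any(srn < 0)) stop("region read count (SRN) must be >= 0")
    srn / itr
}

#' Per-peak normalized methylation depth
#'
#' The per-peak m6A statistic: the difference between the library-size
#' normalized IP and input coverage of the peak, divided by peak length:
#' `((SRN_IP/ITR_IP) - (SRN_input/ITR_input)) / length`.  Values can be
#' negative when the input fraction exceeds the IP fraction.
#'
#' @param srnIp,srnInput per-peak read counts (or base-depth sums) of the
#'   IP and input libraries of one sample.
#' @param itrIp,itrInput total reads of the IP and input libraries.
#' @param peakLength peak length(s) in nt.
#' @return numeric vector of normalized depths.
#' @examples
#' normalizedDepth(100, 1e6, 20, 1e6, 200)  # 4e-07
#' @export
normalizedDepth <- function(srnIp, itrIp, srnInput, itrInput, peakLength) {
    if (any(itrIp <= 0) || any(itrInput <= 0))
        stop("library totals must be > 0")
    if (any(peakLength <= 0)) stop("peak length must be > 0")
    (srnIp / itrIp - srnInput / itrInput) / peakLength
}

#' Build a peaks x samples normalized-depth matrix
#'
#' Pairs IP and input count tables by sample name and computes the per-peak
#' normalized depth for every sample, returned as a
#' `SummarizedExperiment` with the peak panel as row ranges and the sample
#' sheet as column data.
#'
#' @param ipCounts,inputCounts integer matrices (panel peaks x samples) with
#'   rownames equal to the panel peak ids.
#' @param ipTotals,inputTotals named numeric vectors of library totals.
#' @param panel a [PeakPanel-class] whose `peak_id`s match the rownames.
#' @param sampleSheet data.frame with columns `sample` and `group`.
#' @return a `SummarizedExperiment` with assay `normdepth`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges
methylationDepthMatrix <- function(ipCounts, inputCounts, ipTotals,
                                   inputTotals, panel, sampleSheet) {
    ids <- peakIds(panel)
    if (!identical(rownames(ipCounts), ids) ||
        !identical(rownames(inputCounts), ids))
        stop("count matrix rownames do not match the panel peak ids")
    samples <- sampleSheet$sample
    if (!all(samples %in% colnames(ipCounts)) ||
        !all(samples %in% colnames(inputCounts)))
        stop("sample sheet samples missing from the count tables")
    if (any(ipTotals[samples] <= 0) || any(inputTotals[samples] <= 0))
        stop("library totals must be > 0")
    len <- width(panel)
    nd <- sweep(ipCounts[, samples, drop = FALSE], 2, ipTotals[samples], "/") -
        sweep(inputCounts[, samples, drop = FALSE], 2,
              inputTotals[samples], "/")
    nd <- nd / len
    SummarizedExperiment(assays = list(normdepth = nd),
                         rowRanges = granges(panel),
                         colData = DataFrame(sampleSheet,
                                             row.names = samples),
                         metadata = list(peak_id = ids))
}

## vectorized two-sample t-test over matrix rows; Welch by default,
## pooled-variance Student optional.  Rows with zero variance in both
## groups and equal means get t = 0, p = 1.
rowTTest <- function(x, isHigh, welch = TRUE) {
    x1 <- x[, isHigh, drop = FALSE]
    x2 <- x[, !isHigh, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples")
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    if (welch) {
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    } else {
        sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
        se2 <- sp2 * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2L, length(m1))
    }
    t <- (m1 - m2) / sqrt(se2)
    p <- 2 * stats::pt(-abs(t), df)
    zero <- se2 == 0
    t[zero] <- ifelse(m1[zero] == m2[zero], 0,
                      sign(m1[zero] - m2[zero]) * Inf)
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
    list(meanHigh = m1, meanLow = m2, t = t, p = p)
}

## log2(high/low) on group means with the non-positive-mean policy:
## means floored at 0 and offset by a pseudo-depth; peaks with both
## means <= 0 get log2fc = 0
log2FoldChange <- function(meanHigh, meanLow, epsilon = 1e-9) {
    bothNonPos <- meanHigh <= 0 & meanLow <= 0
    lfc <- log2((pmax(meanHigh, 0) + epsilon) /
                (pmax(meanLow, 0) + epsilon))
    lfc[bothNonPos] <- 0
    lfc
}

#' Differential methylation between High and Low groups
#'
#' Per panel peak, a two-sided two-sample t-test comparing normalized
#' depths between groups, with `log2fc = log2(mean_High / mean_Low)`
#' (High/Low orientation).  Because normalized depth can be negative, group
#' means are floored at zero and offset by a small pseudo-depth before the
#' ratio; peaks with both means non-positive get `log2fc = 0` and are never
#' significant.  A peak is significant when `p < pThresh` and
#' `|log2fc| > log2(fcThresh)`.  No multiple-testing correction is applied
#' by default (raw p-values); `adjust = "BH"` adds an adjusted column and
#' bases significance on it.
#'
#' @param depth a `SummarizedExperiment` from [methylationDepthMatrix()] or
#'   a peaks x samples numeric matrix.
#' @param groups named character vector sample -> "High"/"Low"; taken from
#'   `colData(depth)$group` when omitted.
#' @param pThresh,fcThresh significance thresholds (p-value and linear fold
#'   change).
#' @param welch logical; Welch t-test (default, matching `t.test`) or
#'   pooled-variance Student.
#' @param epsilon pseudo-depth for the fold-change offset policy.
#' @param adjust "none" (default) or "BH".
#' @return data.frame with columns `peak_id`, `mean_high`, `mean_low`,
#'   `log2fc`, `t_stat`, `p_value`, (optionally `p_adj`), `significant`.
#' @export
differentialMethylation <- function(depth, groups = NULL, pThresh = 0.05,
                                    fcThresh = 1.5, welch = TRUE,
                                    epsilon = 1e-9, adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    if (is(depth, "SummarizedExperiment")) {
        x <- SummarizedExperiment::assay(depth)
        if (is.null(groups))
            groups <- stats::setNames(colData(depth)$group,
                                      colnames(depth))
        rownames(x) <- metadata(depth)$peak_id
    } else {
        x <- as.matrix(depth)
    }
    if (is.null(groups)) stop("'groups' is required for matrix input")
    groups <- groups[colnames(x)]
    if (!all(groups %in% c("High", "Low")))
        stop("groups must be 'High' or 'Low'")
    isHigh <- groups == "High"
    tt <- rowTTest(x, isHigh, welch = welch)
    lfc <- log2FoldChange(tt$meanHigh, tt$meanLow, epsilon)
    p <- tt$p
    res <- data.frame(peak_id = rownames(x),
                      mean_high = tt$meanHigh, mean_low = tt$meanLow,
                      log2fc = lfc, t_stat = tt$t, p_value = p,
                      stringsAsFactors = FALSE, row.names = NULL)
    pUse <- p
    if (adjust == "BH") {
        res$p_adj <- stats::p.adjust(p, method = "BH")
        pUse <- res$p_adj
    }
    res$significant <- pUse < pThresh & abs(lfc) > log2(fcThresh) &
        !(tt$meanHigh <= 0 & tt$meanLow <= 0)
    res
}

#' Aggregate peak-level differential methylation to genes
#'
#' A gene is differentially methylated when at least one of its peaks is
#' significant; its representative statistics (log2fc, p) are those of its
#' minimum-p peak.  Peaks without gene annotation are reported in the
#' `"unannotated"` attribute of the result.
#'
#' @param results data.frame from [differentialMethylation()].
#' @param peakGene named character vector, peak id -> gene id (NA allowed).
#' @return data.frame with columns `gene`, `n_peaks`, `log2fc`, `p_value`,
#'   `significant`; attribute `unannotated` holds peak ids without a gene.
#' @export
aggregateToGenes <- function(results, peakGene) {
    gene <- unname(peakGene[results$peak_id])
    unannot <- results$peak_id[is.na(gene)]
    keep <- !is.na(gene)
    res <- results[keep, , drop = FALSE]
    gene <- gene[keep]
    ord <- order(gene, res$p_value, res$peak_id)
    res <- res[ord, , drop = FALSE]
    gene <- gene[ord]
    first <- !duplicated(gene)
    out <- data.frame(gene = gene[first],
                      n_peaks = as.integer(table(gene)[gene[first]]),
                      log2fc = res$log2fc[first],
                      p_value = res$p_value[first],
                      significant = as.logical(
                          tapply(res$significant, gene, any)[gene[first]]),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "unannotated") <- unannot
    out
}
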