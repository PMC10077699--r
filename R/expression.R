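## Expression filtering, TPM and size-factor normalization, differential
## expression and PCA-based sample screening.
##
## The differential test here is a deliberately simple engine: a two-sided
## t-test on log2(size-factor-normalized counts + 1), with fold changes on
## the same scale.  The analysis contract is the thresholds (raw P < 0.05,
## |log2FC| > log2 1.5), not any particular count model.

#' Filter lowly expressed genes
#'
#' Keeps genes with at least `minCount` reads in at least `minSamples`
#' samples (the usual pre-filter before co-expression and differential
#' analysis).  Idempotent; row order preserved.
#'
#' @param counts genes x samples integer matrix.
#' @param minCount minimum per-sample count (default 10, i.e. "> 9").
#' @param minSamples minimum number of samples reaching `minCount`.
#' @return the filtered count matrix.
#' @export
filterLowExpression <- function(counts, minCount = 10, minSamples = 4) {
    stopifnot(minCount >= 0, minSamples >= 0)
    keep <- rowSums(counts >= minCount) >= minSamples
    counts[keep, , drop = FALSE]
}

#' TPM normalization
#'
#' Transcripts-per-million: per sample, counts are divided by gene length
#' in kb and rescaled so each column sums to one million.
#'
#' @param counts genes x samples matrix.
#' @param geneLengths named vector of gene lengths in nt covering all rows.
#' @return numeric matrix of TPM values.
#' @export
tpmNormalize <- function(counts, geneLengths) {
    len <- geneLengths[rownames(counts)]
    if (any(is.na(len)))
        stop("missing gene length for: ",
             paste(utils::head(rownames(counts)[is.na(len)], 5),
                   collapse = ", "))
    if (any(len <= 0)) stop("gene lengths must be > 0")
    rate <- counts / (len / 1000)
    sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Median-of-ratios size-factor normalization
#'
#' Computes per-sample size factors as the median ratio of counts to the
#' per-gene geometric mean reference, using genes with no zero count.  If
#' no zero-free gene exists, falls back to library-size factors (scaled to
#' geometric mean 1) with a warning.
#'
#' @param counts genes x samples matrix.
#' @return list with `normalized` (counts / factor) and `sizeFactors`.
#' @export
sizeFactorNormalize <- function(counts) {
    zeroFree <- rowSums(counts == 0) == 0
    if (any(zeroFree)) {
        lc <- log(counts[zeroFree, , drop = FALSE])
        ref <- rowMeans(lc)
        sf <- exp(apply(lc - ref, 2, stats::median))
        sf <- sf / exp(mean(log(sf)))   # rescale to geometric mean 1
    } else {
        warning("no zero-free gene; falling back to library-size factors")
        ls <- colSums(counts)
        sf <- ls / exp(mean(log(ls)))
    }
    list(normalized = sweep(counts, 2, sf, "/"), sizeFactors = sf)
}

#' Differential expression between High and Low groups
#'
#' Size-factor-normalizes the counts (unless `normalized = TRUE`), then per
#' gene computes `log2fc = log2(mean_High + 1) - log2(mean_Low + 1)` on
#' normalized counts and a two-sided t-test on `log2(normalized + 1)`.
#' Significance requires `p < pThresh` and `|log2fc| > log2(fcThresh)`.
#'
#' @param counts genes x samples matrix (raw, or pre-normalized with
#'   `normalized = TRUE`).
#' @param groups named character vector sample -> "High"/"Low".
#' @param pThresh,fcThresh significance thresholds.
#' @param pseudocount added before the log transform (default 1).
#' @param welch Welch (default) or pooled-variance t-test.
#' @param normalized set TRUE when `counts` are already normalized.
#' @return data.frame with `gene`, `mean_high`, `mean_low`, `log2fc`,
#'   `t_stat`, `p_value`, `significant`.
#' @export
differentialExpression <- function(counts, groups, pThresh = 0.05,
                                   fcThresh = 1.5, pseudocount = 1,
                                   welch = TRUE, normalized = FALSE) {
    groups <- groups[colnames(counts)]
    if (!all(groups %in% c("High", "Low")))
        stop("groups must be 'High' or 'Low'")
    norm <- if (normalized) counts else sizeFactorNormalize(counts)$normalized
    isHigh <- groups == "High"
    lx <- log2(norm + pseudocount)
    tt <- rowTTest(lx, isHigh, welch = welch)
    mh <- rowMeans(norm[, isHigh, drop = FALSE])
    ml <- rowMeans(norm[, !isHigh, drop = FALSE])
    lfc <- log2(mh + pseudocount) - log2(ml + pseudocount)
    data.frame(gene = rownames(counts), mean_high = mh, mean_low = ml,
               log2fc = lfc, t_stat = tt$t, p_value = tt$p,
               significant = tt$p < pThresh & abs(lfc) > log2(fcThresh),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA-based sample outlier screen
#'
#' PCA on `log2(normalized counts + 1)` (genes centered), retaining the
#' first two principal components.  A sample is flagged as an outlier when
#' its Euclidean distance from the score centroid exceeds
#' `median(dist) + k * MAD(dist)`.
#'
#' @param counts genes x samples matrix (raw counts; size-factor
#'   normalized internally unless `normalized = TRUE`).
#' @param k MAD multiplier (default 3).
#' @param pseudocount added before the log transform.
#' @param normalized set TRUE when `counts` are already normalized.
#' @return data.frame with `sample`, `PC1`, `PC2`, `pvar1`, `pvar2`,
#'   `dist`, `outlier`.
#' @export
pcaOutlierScreen <- function(counts, k = 3, pseudocount = 1,
                             normalized = FALSE) {
    if (ncol(counts) < 3L) stop("need at least 3 samples")
    norm <- if (normalized) counts else sizeFactorNormalize(counts)$normalized
    lx <- log2(norm + pseudocount)
    lx <- lx[apply(lx, 1, stats::sd) > 0, , drop = FALSE]
    if (nrow(lx) == 0L) {
        scores <- matrix(0, ncol(counts), 2)
        pvar <- c(0, 0)
    } else {
        pc <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
        scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
        if (ncol(scores) < 2L) scores <- cbind(scores, 0)
        pvar <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
        pvar[is.na(pvar)] <- 0
    }
    d <- sqrt(rowSums(sweep(scores, 2, colMeans(scores))^2))
    thr <- stats::median(d) + k * stats::mad(d)
    data.frame(sample = colnames(counts), PC1 = scores[, 1],
               PC2 = scores[, 2], pvar1 = pvar[1], pvar2 = pvar[2],
               dist = d, outlier = d > thr,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise sample distance matrix
#'
#' Euclidean distances between samples on `log2(normalized + 1)` values;
#' companion export to the PCA screen for heatmap-style inspection.
#'
#' @inheritParams pcaOutlierScreen
#' @return a symmetric samples x samples matrix.
#' @export
sampleDistanceMatrix <- function(counts, pseudocount = 1,
                                 normalized = FALSE) {
    norm <- if (normalized) counts else sizeFactorNormalize(counts)$normalized
    as.matrix(stats::dist(t(log2(norm + pseudocount))))
}
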