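## Weighted co-expression network: soft-threshold scan, unsigned
## adjacency, topological overlap, static-cut module detection, module
## eigengenes, module-trait statistics and hub-gene screening.
##
## Convention throughout: expression matrices are genes x samples.

#' Soft-threshold (beta) scan for scale-free topology
#'
#' For each candidate power, builds the unsigned adjacency
#' `|cor|^beta`, computes per-gene connectivity `k_i = sum_{j != i} a_ij`,
#' bins `log10 k` into `nBins` equal-count bins and regresses
#' `log10 p(k)` on `log10 mean(k)`; the signed fit index is
#' `-sign(slope) * R^2`.  The chosen power is the smallest candidate whose
#' signed R^2 reaches `fitThresh`, otherwise the candidate maximizing it.
#'
#' @param expr genes x samples numeric matrix (e.g. log2 TPM).
#' @param candidates candidate powers (default 1..20).
#' @param fitThresh signed R^2 threshold (default 0.85).
#' @param nBins connectivity histogram bins (default 10).
#' @return list of class `SoftThresholdScan`: `table` (power, signedR2,
#'   meanK), `beta` (chosen power).
#' @export
pickSoftThreshold <- function(expr, candidates = 1:20, fitThresh = 0.85,
                              nBins = 10L) {
    v <- apply(expr, 1, stats::var)
    if (any(v == 0)) {
        warning(sum(v == 0), " constant gene(s) dropped")
        expr <- expr[v > 0, , drop = FALSE]
    }
    C <- abs(stats::cor(t(expr)))
    diag(C) <- 0
    scan <- t(vapply(candidates, function(beta) {
        a <- C^beta
        k <- rowSums(a)
        c(signedR2 = scaleFreeFit(k, nBins), meanK = mean(k))
    }, c(signedR2 = 0, meanK = 0)))
    tab <- data.frame(power = candidates, signedR2 = scan[, "signedR2"],
                      meanK = scan[, "meanK"])
    ok <- which(tab$signedR2 >= fitThresh)
    beta <- if (length(ok)) tab$power[ok[1L]]
            else tab$power[which.max(tab$signedR2)]
    structure(list(table = tab, beta = beta), class = "SoftThresholdScan")
}

## signed scale-free fit index from a connectivity vector
scaleFreeFit <- function(k, nBins = 10L) {
    k <- k[k > 0]
    if (length(k) < nBins) return(NA_real_)
    br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1L)))
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- as.numeric(table(bin)) / length(k)
    kb <- tapply(k, bin, mean)
    keep <- pk > 0 & !is.na(kb)
    if (sum(keep) < 3L) return(NA_real_)
    fit <- stats::lm(log10(pk[keep]) ~ log10(kb[keep]))
    ## summary() warns on degenerate all-points-on-a-line fits; R^2 = 1
    ## is a legitimate outcome there
    r2 <- suppressWarnings(summary(fit)$r.squared)
    -sign(stats::coef(fit)[2L]) * r2
}

#' @export
print.SoftThresholdScan <- function(x, ...) {
    cat("SoftThresholdScan: chosen beta =", x$beta, "\n")
    print(x$table, row.names = FALSE)
    invisible(x)
}

#' Unsigned network adjacency
#'
#' `a_ij = |pearson(x_i, x_j)|^beta`, with unit diagonal.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @return genes x genes adjacency matrix.
#' @export
adjacencyMatrix <- function(expr, beta) {
    stopifnot(beta >= 1)
    v <- apply(expr, 1, stats::var)
    if (any(v == 0))
        stop("zero-variance gene(s): ",
             paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
    a <- abs(stats::cor(t(expr)))^beta
    diag(a) <- 1
    a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivities `k_i = sum_{j != i} a_ij` and unit diagonal; values lie
#' between 0 and 1 for an adjacency between 0 and 1.
#'
#' @param adj symmetric adjacency matrix with unit diagonal.
#' @param tol asymmetry tolerance.
#' @return the TOM similarity matrix.
#' @export
tomSimilarity <- function(adj, tol = 1e-8) {
    if (max(abs(adj - t(adj))) > tol)
        stop("adjacency is not symmetric")
    a <- adj
    diag(a) <- 0
    num <- a %*% a + a
    k <- rowSums(a)
    denom <- outer(k, k, pmin) + 1 - a
    tom <- num / denom
    diag(tom) <- 1
    dimnames(tom) <- dimnames(adj)
    tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Hierarchical clustering (average linkage) on `1 - TOM`, cut statically
#' at `cutHeightFrac` of the maximal merge height; clusters smaller than
#' `minModuleSize` are assigned label 0 ("grey"/unassigned).  Retained
#' modules are relabelled 1, 2, ... in decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeightFrac static cut height as a fraction of the dendrogram
#'   height (default 0.995).
#' @return named integer vector of module labels.
#' @export
detectModules <- function(tom, minModuleSize = 30L, cutHeightFrac = 0.995) {
    d <- stats::as.dist(1 - tom)
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = cutHeightFrac * max(hc$height))
    sizes <- table(cl)
    big <- names(sizes)[sizes >= minModuleSize]
    labels <- integer(length(cl))
    ord <- big[order(-sizes[big])]
    for (i in seq_along(ord))
        labels[cl == as.integer(ord[i])] <- i
    names(labels) <- rownames(tom)
    labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across
#' samples of the per-gene standardized module submatrix (unit norm),
#' oriented so that its correlation with the module's mean standardized
#' expression is non-negative.
#'
#' @param expr genes x samples matrix.
#' @param labels named integer module labels (0 = unassigned, skipped).
#' @return samples x modules matrix with columns `ME1`, `ME2`, ...
#' @export
computeModuleEigengenes <- function(expr, labels) {
    mods <- sort(unique(labels[labels > 0L]))
    if (!length(mods)) stop("no modules to summarize")
    E <- vapply(mods, function(m) {
        X <- expr[names(labels)[labels == m], , drop = FALSE]
        Z <- t(scale(t(X)))
        Z[is.na(Z)] <- 0          # constant genes contribute nothing
        sv <- svd(Z, nu = 0, nv = 1)
        e <- sv$v[, 1L]
        if (stats::sd(colMeans(Z)) > 0 &&
            stats::cor(e, colMeans(Z)) < 0) e <- -e
        else if (sum(e) < 0 && stats::sd(colMeans(Z)) == 0) e <- -e
        e
    }, numeric(ncol(expr)))
    dimnames(E) <- list(colnames(expr), paste0("ME", mods))
    E
}

## Pearson correlation with the classical two-sided p-value from
## t = r sqrt((n-2)/(1-r^2)) on n-2 df
corWithP <- function(x, y) {
    r <- stats::cor(x, y)
    n <- nrow(as.matrix(x))
    t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(t), n - 2)
    list(r = r, p = p)
}

#' Module-trait correlation
#'
#' Pearson correlation between module eigengenes and sample traits with
#' two-sided p-values on n - 2 degrees of freedom.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits samples x traits numeric matrix/data.frame (same order).
#' @return list with matrices `r` and `p`.
#' @export
moduleTraitCorrelation <- function(eigengenes, traits) {
    traits <- as.matrix(traits)
    if (nrow(traits) != nrow(eigengenes))
        stop("eigengenes and traits must cover the same samples")
    if (nrow(traits) < 3L) stop("need at least 3 samples")
    if (any(apply(traits, 2, stats::sd) == 0))
        stop("zero-variance trait")
    cp <- corWithP(eigengenes, traits)
    list(r = cp$r, p = cp$p)
}

#' Per-gene module membership and gene significance
#'
#' MM is the correlation of a gene's expression with its own module's
#' eigengene (NA for unassigned genes); GS is the absolute correlation of
#' the gene's expression with the trait.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes samples x modules matrix (`ME<label>` columns).
#' @param labels named integer module labels.
#' @param trait numeric trait vector over the same samples.
#' @return data.frame with `gene`, `module`, `MM`, `GS`.
#' @export
geneModuleStats <- function(expr, eigengenes, labels, trait) {
    labels <- labels[rownames(expr)]
    gs <- abs(as.numeric(stats::cor(t(expr), trait)))
    mm <- rep(NA_real_, nrow(expr))
    for (m in sort(unique(labels[labels > 0L]))) {
        idx <- which(labels == m)
        mm[idx] <- as.numeric(stats::cor(t(expr[idx, , drop = FALSE]),
                                         eigengenes[, paste0("ME", m)]))
    }
    data.frame(gene = rownames(expr), module = unname(labels),
               MM = mm, GS = gs, stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen hub genes of a module
#'
#' Hub genes satisfy `|MM| > mmThresh` and `GS > gsThresh` within the
#' named module, returned sorted by GS descending.
#'
#' @param stats data.frame with columns `gene`, `module`, `MM`, `GS` (from
#'   [geneModuleStats()] or an external table).
#' @param module module label to screen; NULL screens all rows.
#' @param mmThresh module-membership threshold (default 0.8).
#' @param gsThresh gene-significance threshold (default 0.2).
#' @return the qualifying rows of `stats`, sorted by GS descending.
#' @export
screenHubGenes <- function(stats, module = NULL, mmThresh = 0.8,
                           gsThresh = 0.2) {
    rows <- if (is.null(module)) stats
            else stats[!is.na(stats$module) & stats$module == module, ,
                       drop = FALSE]
    hub <- rows[!is.na(rows$MM) & abs(rows$MM) > mmThresh &
                rows$GS > gsThresh, , drop = FALSE]
    hub[order(-hub$GS), , drop = FALSE]
}

#' Full weighted co-expression network analysis
#'
#' Chains the soft-threshold scan, adjacency, TOM, module detection,
#' eigengenes, module-trait correlation, MM/GS statistics and hub
#' screening on the module most correlated with the first trait.
#'
#' @param expr genes x samples matrix (e.g. log2(TPM + 1), pre-filtered).
#' @param traits samples x traits numeric matrix/data.frame.
#' @param candidates,fitThresh passed to [pickSoftThreshold()].
#' @param minModuleSize,cutHeightFrac passed to [detectModules()].
#' @param mmThresh,gsThresh passed to [screenHubGenes()].
#' @return a [ModuleResult-class].
#' @export
runNetworkAnalysis <- function(expr, traits, candidates = 1:20,
                               fitThresh = 0.85, minModuleSize = 30L,
                               cutHeightFrac = 0.995, mmThresh = 0.8,
                               gsThresh = 0.2) {
    v <- apply(expr, 1, stats::var)
    expr <- expr[v > 0, , drop = FALSE]
    sft <- pickSoftThreshold(expr, candidates, fitThresh)
    adj <- adjacencyMatrix(expr, sft$beta)
    tom <- tomSimilarity(adj)
    labels <- detectModules(tom, minModuleSize, cutHeightFrac)
    E <- computeModuleEigengenes(expr, labels)
    mt <- moduleTraitCorrelation(E, traits)
    trait1 <- as.matrix(traits)[, 1L]
    st <- geneModuleStats(expr, E, labels, trait1)
    target <- which.max(abs(mt$r[, 1L]))
    targetLabel <- as.integer(sub("ME", "", rownames(mt$r)[target]))
    hubs <- screenHubGenes(st, targetLabel, mmThresh, gsThresh)
    new("ModuleResult", labels = labels, eigengenes = E,
        moduleTraitCor = mt$r, moduleTraitP = mt$p, geneStats = st,
        hubs = hubs$gene, softThreshold = as.numeric(sft$beta))
}
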