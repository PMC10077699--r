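## Co-differential integration of methylation and expression, and
## gene-set over-representation analysis.

#' Co-differential genes and quadrant classes
#'
#' Intersects the significant gene sets of a differential-methylation and
#' a differential-expression table and classifies each shared gene into a
#' quadrant by the signs of the two fold changes: hyper/hypo (m6A up/down
#' in High) x up/down (expression up/down in High).  Genes with a zero
#' fold change in either table are excluded from quadrants and reported in
#' the `"excluded"` attribute.
#'
#' @param dmGenes data.frame with columns `gene`, `log2fc`, `p_value`,
#'   `significant` (e.g. from [aggregateToGenes()]).
#' @param deGenes data.frame with the same columns (e.g. from
#'   [differentialExpression()]).
#' @return data.frame with `gene`, `dm_log2fc`, `dm_p`, `de_log2fc`,
#'   `de_p`, `quadrant`.
#' @export
coDifferential <- function(dmGenes, deGenes) {
    dm <- dmGenes[dmGenes$significant, , drop = FALSE]
    de <- deGenes[deGenes$significant, , drop = FALSE]
    shared <- intersect(dm$gene, de$gene)
    dm <- dm[match(shared, dm$gene), , drop = FALSE]
    de <- de[match(shared, de$gene), , drop = FALSE]
    out <- data.frame(gene = shared,
                      dm_log2fc = dm$log2fc, dm_p = dm$p_value,
                      de_log2fc = de$log2fc, de_p = de$p_value,
                      stringsAsFactors = FALSE, row.names = NULL)
    zero <- out$dm_log2fc == 0 | out$de_log2fc == 0
    excluded <- out$gene[zero]
    out <- out[!zero, , drop = FALSE]
    out$quadrant <- if (nrow(out))
        paste0(ifelse(out$dm_log2fc > 0, "hyper", "hypo"), "-",
               ifelse(out$de_log2fc > 0, "up", "down"))
    else character(0)
    attr(out, "excluded") <- excluded
    out
}

#' Read a GMT gene-set file
#'
#' Tab-separated: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors; names are term ids, with a
#'   `description` attribute on each element.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) {
        genes <- unique(f[-(1:2)])
        attr(genes, "description") <- f[2L]
        genes
    })
    names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
    sets
}

#' Over-representation analysis with step-down correction
#'
#' For each gene set, the raw p-value is the upper-tail hypergeometric
#' probability of observing at least the seen overlap between the query
#' and the set within the universe.  P-values are corrected across terms
#' with the Holm (Bonferroni step-down) procedure by default; terms with
#' adjusted p <= alpha are flagged.
#'
#' @param query character vector of genes of interest (subset of universe).
#' @param universe character vector of all considered genes (e.g. the
#'   post-filter expressed genes).
#' @param geneSets named list of character vectors (see [readGmt()]);
#'   each set is intersected with the universe before testing.
#' @param method "holm" (default) or "bonferroni".
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame with `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`, `p_adj`, `significant`, sorted by raw p.
#' @export
oraEnrichment <- function(query, universe, geneSets,
                          method = c("holm", "bonferroni"), alpha = 0.05) {
    method <- match.arg(method)
    universe <- unique(universe)
    query <- unique(query)
    if (!length(universe) || !length(query))
        stop("empty universe or query")
    if (!all(query %in% universe))
        stop("query genes outside the universe: ",
             paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
    N <- length(universe); n <- length(query)
    rows <- lapply(names(geneSets), function(term) {
        set <- intersect(geneSets[[term]], universe)
        K <- length(set)
        x <- length(intersect(set, query))
        p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = term, overlap = x, term_size = K,
                   query_size = n, universe_size = N, p_value = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p_value, method = method)
    out$significant <- out$p_adj <= alpha
    out[order(out$p_value, out$term), , drop = FALSE]
}

#' Assemble a run report
#'
#' Bundles the stage outputs of a pipeline run into a single manifest:
#' counts of panel peaks, differentially methylated peaks and genes,
#' differentially expressed genes, co-differential genes by quadrant,
#' modules and hub genes, plus the parameters and seed.  Missing stages
#' yield explicit `NA` entries rather than errors.
#'
#' @param panel a [PeakPanel-class] or NULL.
#' @param dmPeaks,dmGenes,deGenes,codiff data.frames from the respective
#'   stages, or NULL.
#' @param moduleResult a [ModuleResult-class] or NULL.
#' @param params named list of run parameters recorded verbatim.
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest as a named list (invisibly when written).
#' @export
buildReport <- function(panel = NULL, dmPeaks = NULL, dmGenes = NULL,
                        deGenes = NULL, codiff = NULL, moduleResult = NULL,
                        params = list(), path = NULL) {
    cnt <- function(x) if (is.null(x)) NA_integer_ else nrow(x)
    quad <- if (is.null(codiff) || !nrow(codiff)) list() else
        as.list(table(codiff$quadrant))
    manifest <- list(
        version = as.character(utils::packageVersion("m6Aflow")),
        n_panel_peaks = if (is.null(panel)) NA_integer_ else length(panel),
        n_dm_peaks = if (is.null(dmPeaks)) NA_integer_
                     else sum(dmPeaks$significant),
        n_dm_genes = if (is.null(dmGenes)) NA_integer_
                     else sum(dmGenes$significant),
        n_de_genes = if (is.null(deGenes)) NA_integer_
                     else sum(deGenes$significant),
        n_codifferential = cnt(codiff),
        codifferential_by_quadrant = quad,
        n_modules = if (is.null(moduleResult)) NA_integer_
                    else length(unique(moduleLabels(moduleResult)[
                        moduleLabels(moduleResult) > 0])),
        n_hub_genes = if (is.null(moduleResult)) NA_integer_
                      else length(hubGenes(moduleResult)),
        soft_threshold = if (is.null(moduleResult)) NA_real_
                         else moduleResult@softThreshold,
        params = params)
    if (!is.null(path)) {
        jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null")
        return(invisible(manifest))
    }
    manifest
}
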