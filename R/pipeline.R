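## Pipeline orchestration: a validated run configuration plus staged
## execution with file outputs, so a whole synthetic study can be analysed
## end to end with one call (or via the thin command-line wrapper in
## inst/scripts/m6aflow.R).

pipelineDefaults <- function() list(
    out_dir = "m6aflow_run",
    seed = 1L,
    n_genes = 2000L,
    n_samples_per_group = 10L,
    n_modules = 4L,
    module_size = 50L,
    frac_methylated = 0.5,
    frac_differential = 0.25,
    dm_log2fc = 2,
    nb_dispersion = 0.05,
    mean_library_size = 2e6,
    trait_module_corr = 0.62,
    peak_width = 100L,
    false_peak_rate = 0.1,
    stop_codon_bias = 0.8,
    p_thresh = 0.05,
    fc_thresh = 1.5,
    min_count = 10L,
    min_samples = 4L,
    mm_thresh = 0.8,
    gs_thresh = 0.2,
    welch = TRUE,
    count_mode = "basedepth",
    soft_threshold = NA,        # NA = scan candidates
    min_module_size = 30L,
    cut_height_frac = 0.995,
    bins_per_region = 30L,
    network_genes = 2500L       # cap on genes entering the network stage
)

#' Build and validate a pipeline run configuration
#'
#' Merges user settings (a YAML file path or a named list) over the
#' defaults, which equal the analysis thresholds of the study design
#' (P < 0.05, fold change 1.5, MM > 0.8, GS > 0.2, low-expression filter
#' of 10 counts in 4 samples).  Unknown keys are rejected.
#'
#' @param config NULL (defaults), a YAML file path, or a named list.
#' @return a validated named list of class `RunConfig`.
#' @export
runConfig <- function(config = NULL) {
    defaults <- pipelineDefaults()
    user <- if (is.null(config)) list()
            else if (is.character(config)) yaml::read_yaml(config)
            else config
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, user)
    if (!cfg$count_mode %in% c("reads", "basedepth"))
        stop("count_mode must be 'reads' or 'basedepth'")
    structure(cfg, class = "RunConfig")
}

stageOrder <- c("simulate", "merge", "quantify", "dm", "de", "annotate",
                "network", "integrate", "report")

requireStageFile <- function(path, stage, madeBy) {
    if (!file.exists(path))
        stop("missing input '", path, "' for stage '", stage,
             "'; run stage '", madeBy, "' first", call. = FALSE)
    path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, reading and writing
#' files under `config$out_dir`:
#' \describe{
#'   \item{simulate}{generate the synthetic study inputs
#'     ([simulateStudy()], [writeSimulation()]).}
#'   \item{merge}{merge per-group peak calls into the reference panel.}
#'   \item{quantify}{per-peak per-sample normalized depth.}
#'   \item{dm}{differential methylation, peak- and gene-level.}
#'   \item{de}{expression filter, TPM, differential expression, PCA
#'     screen.}
#'   \item{annotate}{region assignment, metagene profile, RRACH motif
#'     hits and enrichment.}
#'   \item{network}{co-expression network, modules, eigengenes,
#'     module-trait correlation, hubs.}
#'   \item{integrate}{co-differential genes and quadrants.}
#'   \item{report}{JSON manifest of counts and parameters.}
#' }
#' Each stage logs one line to stderr with its parameters and writes TSV
#' outputs with deterministic content for a fixed seed.
#'
#' @param config NULL, a YAML path, or named list (see [runConfig()]).
#' @param stages character vector of stage names, or "all".
#' @return invisibly, the report manifest (if the report stage ran) or
#'   NULL.
#' @export
runPipeline <- function(config = NULL, stages = "all") {
    cfg <- if (inherits(config, "RunConfig")) config else runConfig(config)
    if (identical(stages, "all")) stages <- stageOrder
    bad <- setdiff(stages, stageOrder)
    if (length(bad))
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stages <- stageOrder[stageOrder %in% stages]
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    log <- function(stage, ...)
        message(sprintf("[m6Aflow] %s: %s", stage, paste0(...)))
    tsv <- function(df, f)
        utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
    simCfg <- simConfig(nGenes = cfg$n_genes,
                        nSamplesPerGroup = cfg$n_samples_per_group,
                        nModules = cfg$n_modules,
                        moduleSize = cfg$module_size,
                        fracMethylated = cfg$frac_methylated,
                        fracDifferential = cfg$frac_differential,
                        dmLog2fc = cfg$dm_log2fc,
                        nbDispersion = cfg$nb_dispersion,
                        meanLibrarySize = cfg$mean_library_size,
                        traitModuleCorr = cfg$trait_module_corr,
                        peakWidth = cfg$peak_width,
                        falsePeakRate = cfg$false_peak_rate,
                        stopCodonBias = cfg$stop_codon_bias,
                        seed = cfg$seed)
    report <- NULL

    if ("simulate" %in% stages) {
        sim <- simulateStudy(simCfg)
        writeSimulation(sim, cfg$out_dir)
        tsv(data.frame(peak_id = names(sim$merip$peakGene),
                       gene = unname(sim$merip$peakGene)), "peak_gene.tsv")
        log("simulate", "seed=", cfg$seed, " genes=", cfg$n_genes,
            " samples/group=", cfg$n_samples_per_group)
    }

    readCounts <- function(f) {
        df <- utils::read.table(f, header = TRUE, sep = "\t",
                                check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        m
    }

    if ("merge" %in% stages) {
        hi <- readBed(requireStageFile(p("peaks_high.bed"), "merge",
                                       "simulate"))
        lo <- readBed(p("peaks_low.bed"))
        panel <- mergePeaks(list(High = hi, Low = lo), maxGap = 0L)
        writeBed(panel, p("panel.bed"))
        vn <- vennCounts(
            peakIds(panel)[vapply(mcols(panel)$sources,
                                  function(s) "High" %in% s, logical(1))],
            peakIds(panel)[vapply(mcols(panel)$sources,
                                  function(s) "Low" %in% s, logical(1))])
        tsv(data.frame(set = names(vn), count = as.integer(vn)),
            "panel_venn.tsv")
        log("merge", length(panel), " panel peaks")
    }

    loadPanel <- function(stage) {
        bed <- readBed(requireStageFile(p("panel.bed"), stage, "merge"))
        gr <- GenomicRanges::sort(granges(bed), ignore.strand = TRUE)
        mcols(gr)$peak_id <- mcols(bed)$name
        mcols(gr)$sources <- IRanges::CharacterList(
            as.list(rep("panel", length(gr))))
        new("PeakPanel", gr)
    }
    loadTotals <- function(stage)
        utils::read.table(requireStageFile(p("library_totals.tsv"), stage,
                                           "simulate"),
                          header = TRUE, sep = "\t")

    if ("quantify" %in% stages) {
        panel <- loadPanel("quantify")
        ip <- readCounts(requireStageFile(p("ip_counts.tsv"), "quantify",
                                          "simulate"))
        input <- readCounts(p("input_counts.tsv"))
        totals <- loadTotals("quantify")
        se <- methylationDepthMatrix(
            ip[peakIds(panel), , drop = FALSE],
            input[peakIds(panel), , drop = FALSE],
            stats::setNames(totals$ip_total, totals$sample),
            stats::setNames(totals$input_total, totals$sample),
            panel,
            data.frame(sample = totals$sample, group = totals$group))
        nd <- SummarizedExperiment::assay(se)
        tsv(data.frame(peak_id = peakIds(panel), nd, check.names = FALSE),
            "normalized_depth.tsv")
        log("quantify", nrow(nd), " peaks x ", ncol(nd), " samples")
    }

    if ("dm" %in% stages) {
        nd <- readCounts(requireStageFile(p("normalized_depth.tsv"), "dm",
                                          "quantify"))
        totals <- loadTotals("dm")
        groups <- stats::setNames(totals$group, totals$sample)
        dmPeaks <- differentialMethylation(nd, groups,
                                           pThresh = cfg$p_thresh,
                                           fcThresh = cfg$fc_thresh,
                                           welch = cfg$welch)
        tsv(dmPeaks, "dm_peaks.tsv")
        pg <- utils::read.table(requireStageFile(p("peak_gene.tsv"), "dm",
                                                 "simulate"),
                                header = TRUE, sep = "\t")
        dmGenes <- aggregateToGenes(dmPeaks,
                                    stats::setNames(pg$gene, pg$peak_id))
        tsv(dmGenes, "dm_genes.tsv")
        log("dm", sum(dmPeaks$significant), " significant peaks, ",
            sum(dmGenes$significant), " DM genes (p<", cfg$p_thresh,
            ", FC>", cfg$fc_thresh, ")")
    }

    if ("de" %in% stages) {
        counts <- readCounts(requireStageFile(p("expr_counts.tsv"), "de",
                                              "simulate"))
        lens <- utils::read.table(p("gene_lengths.tsv"), header = TRUE,
                                  sep = "\t")
        traits <- utils::read.table(p("traits.tsv"), header = TRUE,
                                    sep = "\t")
        filtered <- filterLowExpression(counts, cfg$min_count,
                                        cfg$min_samples)
        tpm <- tpmNormalize(filtered,
                            stats::setNames(lens$length, lens$gene_id))
        tsv(data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE),
            "tpm.tsv")
        groups <- stats::setNames(traits$group, traits$sample)
        deg <- differentialExpression(filtered, groups,
                                      pThresh = cfg$p_thresh,
                                      fcThresh = cfg$fc_thresh,
                                      welch = cfg$welch)
        tsv(deg, "deg.tsv")
        tsv(pcaOutlierScreen(filtered), "pca_scores.tsv")
        log("de", nrow(filtered), "/", nrow(counts), " genes kept, ",
            sum(deg$significant), " DE genes")
    }

    if ("annotate" %in% stages) {
        panel <- loadPanel("annotate")
        models <- readGtfModels(requireStageFile(p("models.gtf"),
                                                 "annotate", "simulate"))
        region <- assignPeakRegion(panel, models)
        tsv(data.frame(peak_id = peakIds(panel), region = region),
            "region_assignment.tsv")
        prof <- metageneProfile(panel, models, cfg$bins_per_region)
        tsv(data.frame(axis = prof$mids, density = prof$density,
                       count = prof$counts), "metagene.tsv")
        seqs <- Biostrings::readDNAStringSet(
            requireStageFile(p("transcripts.fa"), "annotate", "simulate"))
        hits <- scanRRACH(seqs)
        tsv(hits, "motif_hits.tsv")
        log("annotate", sum(region == "3UTR"), "/", length(region),
            " peaks in 3'UTR; ", nrow(hits), " RRACH hits")
    }

    if ("network" %in% stages) {
        tpm <- readCounts(requireStageFile(p("tpm.tsv"), "network", "de"))
        traits <- utils::read.table(p("traits.tsv"), header = TRUE,
                                    sep = "\t")
        lx <- log2(tpm + 1)
        v <- apply(lx, 1, stats::var)
        keep <- utils::head(order(-v), min(cfg$network_genes, nrow(lx)))
        lx <- lx[sort(keep), , drop = FALSE]
        cand <- if (is.na(cfg$soft_threshold)) 1:20
                else as.integer(cfg$soft_threshold)
        mr <- runNetworkAnalysis(lx, traits[, c("IMF", "m6A_A")],
                                 candidates = cand,
                                 minModuleSize = cfg$min_module_size,
                                 cutHeightFrac = cfg$cut_height_frac,
                                 mmThresh = cfg$mm_thresh,
                                 gsThresh = cfg$gs_thresh)
        tsv(data.frame(gene = names(moduleLabels(mr)),
                       module = unname(moduleLabels(mr))), "modules.tsv")
        E <- moduleEigengenes(mr)
        tsv(data.frame(sample = rownames(E), E, check.names = FALSE),
            "eigengenes.tsv")
        mt <- data.frame(module = rownames(mr@moduleTraitCor),
                         mr@moduleTraitCor,
                         stats::setNames(as.data.frame(mr@moduleTraitP),
                                         paste0("p_",
                                                colnames(mr@moduleTraitP))),
                         check.names = FALSE)
        tsv(mt, "module_trait.tsv")
        tsv(geneStats(mr), "gene_stats.tsv")
        tsv(data.frame(gene = hubGenes(mr)), "hubs.tsv")
        log("network", "beta=", mr@softThreshold, ", ",
            length(unique(moduleLabels(mr)[moduleLabels(mr) > 0])),
            " modules, ", length(hubGenes(mr)), " hubs")
    }

    if ("integrate" %in% stages) {
        dmGenes <- utils::read.table(
            requireStageFile(p("dm_genes.tsv"), "integrate", "dm"),
            header = TRUE, sep = "\t")
        deg <- utils::read.table(
            requireStageFile(p("deg.tsv"), "integrate", "de"),
            header = TRUE, sep = "\t")
        codiff <- coDifferential(dmGenes, deg)
        tsv(codiff, "codiff.tsv")
        log("integrate", nrow(codiff), " co-differential genes")
    }

    if ("report" %in% stages) {
        rd <- function(f) if (file.exists(p(f)))
            utils::read.table(p(f), header = TRUE, sep = "\t") else NULL
        panel <- if (file.exists(p("panel.bed"))) loadPanel("report")
                 else NULL
        report <- buildReport(panel = panel, dmPeaks = rd("dm_peaks.tsv"),
                              dmGenes = rd("dm_genes.tsv"),
                              deGenes = rd("deg.tsv"),
                              codiff = rd("codiff.tsv"),
                              moduleResult = NULL,
                              params = unclass(cfg)[names(cfg) != "out_dir"],
                              path = p("report.json"))
        hubs <- rd("hubs.tsv"); mods <- rd("modules.tsv")
        if (!is.null(mods)) {
            report$n_modules <-
                length(unique(mods$module[mods$module > 0]))
            report$n_hub_genes <- if (is.null(hubs)) 0L else nrow(hubs)
            jsonlite::write_json(report, p("report.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 na = "null")
        }
        log("report", "written to ", p("report.json"))
    }
    invisible(report)
}
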