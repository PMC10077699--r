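#' @import methods
#' @importFrom GenomicRanges GRanges granges reduce findOverlaps pintersect
#'   seqnames start end width strand strand<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic MeRIP-seq + RNA-seq study generator.  The
#' defaults emulate the design of a two-group (High/Low intramuscular fat)
#' m6A-seq experiment: 10 samples per group, negative-binomial sequencing
#' noise, planted IP-over-input enrichment at m6A peaks concentrated near
#' stop codons, block-structured co-expression modules, and sample traits
#' correlated with one module's latent factor.
#'
#' @slot nGenes number of genes (one transcript each).
#' @slot nSamplesPerGroup samples per phenotype group.
#' @slot nModules number of planted co-expression modules.
#' @slot moduleSize genes per planted module.
#' @slot fracMethylated fraction of genes carrying a planted m6A peak.
#' @slot fracDifferential fraction of planted peaks that are differentially
#'   methylated between groups.
#' @slot dmLog2fc planted IP-enrichment log2 effect between groups.
#' @slot nbDispersion negative-binomial dispersion (variance = mu + mu^2 * disp).
#' @slot meanLibrarySize mean total reads per library.
#' @slot traitModuleCorr target correlation between trait 1 (IMF %) and the
#'   designated module's latent factor; trait 2 (m6A/A ratio) is generated
#'   with correlation of the opposite sign.
#' @slot peakWidth planted peak width in nt.
#' @slot falsePeakRate per-group fraction of extra false-positive peaks.
#' @slot stopCodonBias probability that a planted site is placed within the
#'   stop-codon-proximal window rather than uniformly on the transcript.
#' @slot seed integer seed; identical config + seed gives identical output.
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    nSamplesPerGroup = "integer",
    nModules = "integer",
    moduleSize = "integer",
    fracMethylated = "numeric",
    fracDifferential = "numeric",
    dmLog2fc = "numeric",
    nbDispersion = "numeric",
    meanLibrarySize = "numeric",
    traitModuleCorr = "numeric",
    peakWidth = "integer",
    falsePeakRate = "numeric",
    stopCodonBias = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- c(fracMethylated = object@fracMethylated,
            fracDifferential = object@fracDifferential,
            falsePeakRate = object@falsePeakRate,
            stopCodonBias = object@stopCodonBias)
    bad <- fr < 0 | fr > 1
    if (any(bad))
        msg <- c(msg, paste0(names(fr)[bad], " must lie in [0,1]"))
    cnt <- c(nGenes = object@nGenes, nSamplesPerGroup = object@nSamplesPerGroup,
             nModules = object@nModules, moduleSize = object@moduleSize,
             peakWidth = object@peakWidth)
    if (any(cnt < 1L))
        msg <- c(msg, paste0(names(cnt)[cnt < 1L], " must be >= 1"))
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (object@meanLibrarySize < 1)
        msg <- c(msg, "meanLibrarySize must be >= 1")
    if (abs(object@traitModuleCorr) >= 1)
        msg <- c(msg, "traitModuleCorr must lie strictly within (-1, 1)")
    if (object@nModules * object@moduleSize > object@nGenes)
        msg <- c(msg, "nModules * moduleSize exceeds nGenes")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nGenes,nSamplesPerGroup,nModules,moduleSize,fracMethylated,fracDifferential,dmLog2fc,nbDispersion,meanLibrarySize,traitModuleCorr,peakWidth,falsePeakRate,stopCodonBias,seed
#'   see the slot documentation of [SimConfig-class].
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(nGenes = 200, seed = 1)
#' @export
simConfig <- function(nGenes = 2000L, nSamplesPerGroup = 10L,
                      nModules = 4L, moduleSize = 50L,
                      fracMethylated = 0.5, fracDifferential = 0.25,
                      dmLog2fc = 2, nbDispersion = 0.05,
                      meanLibrarySize = 2e6, traitModuleCorr = 0.62,
                      peakWidth = 100L, falsePeakRate = 0.1,
                      stopCodonBias = 0.8, seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nSamplesPerGroup = as.integer(nSamplesPerGroup),
        nModules = as.integer(nModules),
        moduleSize = as.integer(moduleSize),
        fracMethylated = as.numeric(fracMethylated),
        fracDifferential = as.numeric(fracDifferential),
        dmLog2fc = as.numeric(dmLog2fc),
        nbDispersion = as.numeric(nbDispersion),
        meanLibrarySize = as.numeric(meanLibrarySize),
        traitModuleCorr = as.numeric(traitModuleCorr),
        peakWidth = as.integer(peakWidth),
        falsePeakRate = as.numeric(falsePeakRate),
        stopCodonBias = as.numeric(stopCodonBias),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes,",
        object@nSamplesPerGroup, "samples/group,",
        object@nModules, "modules x", object@moduleSize, "genes\n")
    cat("  fracMethylated:", object@fracMethylated,
        " fracDifferential:", object@fracDifferential,
        " dmLog2fc:", object@dmLog2fc, "\n")
    cat("  NB dispersion:", object@nbDispersion,
        " mean library:", object@meanLibrarySize,
        " trait-module r:", object@traitModuleCorr,
        " seed:", object@seed, "\n")
})

#' Reference m6A peak panel
#'
#' A `GRanges` subclass holding the merged reference peak panel.  Peaks are
#' sorted, disjoint and non-bookended within a chromosome; metadata columns
#' record a stable `peak_id` and the contributing source sets (`sources`, a
#' CharacterList with e.g. "High"/"Low" provenance).
#'
#' @export
setClass("PeakPanel", contains = "GRanges")

setValidity("PeakPanel", function(object) {
    msg <- character()
    if (length(object)) {
        if (is.null(mcols(object)$peak_id))
            msg <- c(msg, "metadata column 'peak_id' is required")
        else if (anyDuplicated(mcols(object)$peak_id))
            msg <- c(msg, "peak_id values must be unique")
        if (GenomicRanges::isDisjoint(object, ignore.strand = TRUE) == FALSE)
            msg <- c(msg, "panel peaks must be disjoint")
        o <- order(match(as.character(seqnames(object)),
                         GenomeInfoDb::seqlevels(object)), start(object))
        if (!identical(o, seq_along(object)))
            msg <- c(msg, "panel peaks must be sorted by (chrom, start)")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PeakPanel", function(object) {
    cat("PeakPanel with", length(object), "reference peaks on",
        length(unique(as.character(seqnames(object)))), "sequences\n")
    if (length(object)) {
        src <- mcols(object)$sources
        if (!is.null(src)) {
            tab <- table(vapply(src, function(s)
                paste(sort(unique(s)), collapse = "+"), character(1)))
            cat("  provenance:",
                paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
        }
        methods::callNextMethod()
    }
})

#' Peak ids of a panel
#' @param x a [PeakPanel-class].
#' @return character vector of stable peak ids.
#' @export
peakIds <- function(x) {
    stopifnot(is(x, "PeakPanel"))
    as.character(mcols(x)$peak_id)
}

#' Co-expression module analysis result
#'
#' Container for a weighted co-expression network analysis: per-gene module
#' labels (0 = unassigned/grey), module eigengenes (first principal
#' component per module, unit norm, oriented so that correlation with the
#' module's mean expression profile is non-negative), module-trait Pearson
#' correlations with two-sided p-values, per-gene module membership (MM,
#' correlation with own-module eigengene) and gene significance (GS,
#' absolute correlation with the trait), and hub flags.
#'
#' @slot labels named integer vector, gene -> module label.
#' @slot eigengenes samples x modules numeric matrix.
#' @slot moduleTraitCor modules x traits correlation matrix.
#' @slot moduleTraitP modules x traits p-value matrix.
#' @slot geneStats data.frame with columns gene, module, MM, GS.
#' @slot hubs character vector of hub gene ids.
#' @slot softThreshold chosen soft-threshold power (beta).
#' @export
setClass("ModuleResult", representation(
    labels = "integer",
    eigengenes = "matrix",
    moduleTraitCor = "matrix",
    moduleTraitP = "matrix",
    geneStats = "data.frame",
    hubs = "character",
    softThreshold = "numeric"
))

setValidity("ModuleResult", function(object) {
    msg <- character()
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by gene")
    if (length(object@moduleTraitCor) &&
        any(abs(object@moduleTraitCor) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "module-trait correlations must lie in [-1, 1]")
    if (nrow(object@geneStats) &&
        !all(c("gene", "module", "MM", "GS") %in% names(object@geneStats)))
        msg <- c(msg, "geneStats needs columns gene, module, MM, GS")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleResult", function(object) {
    tab <- table(object@labels)
    nm <- sum(names(tab) != "0")
    cat("ModuleResult:", length(object@labels), "genes in", nm,
        "modules (+", if ("0" %in% names(tab)) tab[["0"]] else 0L,
        "unassigned), beta =", object@softThreshold, "\n")
    if (length(object@hubs))
        cat("  hubs:", paste(utils::head(object@hubs, 8), collapse = ", "),
            if (length(object@hubs) > 8) "...\n" else "\n")
})

#' @describeIn ModuleResult-class gene -> module label vector.
#' @param x a `ModuleResult`.
#' @export
moduleLabels <- function(x) { stopifnot(is(x, "ModuleResult")); x@labels }

#' @describeIn ModuleResult-class samples x modules eigengene matrix.
#' @export
moduleEigengenes <- function(x) { stopifnot(is(x, "ModuleResult")); x@eigengenes }

#' @describeIn ModuleResult-class per-gene MM/GS table.
#' @export
geneStats <- function(x) { stopifnot(is(x, "ModuleResult")); x@geneStats }

#' @describeIn ModuleResult-class hub gene ids.
#' @export
hubGenes <- function(x) { stopifnot(is(x, "ModuleResult")); x@hubs }
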