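## Synthetic MeRIP-seq + RNA-seq study generator with known planted truth.
## Every downstream stage (peak merging, normalized-depth quantification,
## differential methylation/expression, metagene, motif, network, hubs,
## integration) can be scored against the truth manifest produced here.

RRACH_R <- c("A", "G")
RRACH_H <- c("A", "C", "T")

## half-width of the stop-codon-proximal window (nt around the CDS/3'UTR
## junction) used both for biased site placement and for scoring
STOP_WINDOW <- 50L

#' Stop-codon window half-width
#'
#' Half-width (nt) of the window centred on the CDS/3'UTR junction used to
#' define "stop-codon proximal" placement of m6A sites.
#' @return integer scalar.
#' @export
stopCodonWindow <- function() STOP_WINDOW

#' Simulate a transcriptome with planted m6A sites
#'
#' Generates one single-exon transcript per gene (5'UTR / CDS / 3'UTR
#' segments, both strands), a random nucleotide sequence per transcript with
#' an RRACH pentamer written at every planted m6A site midpoint, and the
#' planted-truth manifest.  Site placement follows a mixture: with
#' probability `stopCodonBias` the midpoint falls within
#' `stopCodonWindow()` nt of the stop codon (CDS/3'UTR junction), otherwise
#' uniformly on the transcript.  A fraction `fracDifferential` of planted
#' peaks receives a group-differential IP-enrichment effect of
#' `+/- dmLog2fc` (log2).
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `genes` (per-gene table: coordinates,
#'   segment lengths, strand, baseline expression, module assignment),
#'   `peaks` (planted-peak table with transcript and genomic coordinates,
#'   region label, baseline enrichment and group effect), `sequences`
#'   (a `DNAStringSet` of transcript sequences) and `moduleAssignment`
#'   (named integer vector, 0 = background).
#' @examples
#' truth <- simulateTranscriptome(simConfig(nGenes = 50, seed = 1))
#' @export
#' @importFrom Biostrings DNAStringSet
simulateTranscriptome <- function(config) {
    validObject(config)
    set.seed(config@seed)
    n <- config@nGenes
    geneId <- sprintf("gene_%04d", seq_len(n))

    utr5 <- sample(100:300, n, replace = TRUE)
    cds <- 3L * sample(100:300, n, replace = TRUE)
    utr3 <- sample(200:600, n, replace = TRUE)
    txLen <- utr5 + cds + utr3
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- paste0("chr", (seq_len(n) - 1L) %% 5L + 1L)

    ## lay genes along each chromosome with 500 nt gaps
    txStart <- integer(n)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        txStart[idx] <- cumsum(c(1L, utils::head(txLen[idx], -1L) + 500L))
    }
    txEnd <- txStart + txLen - 1L

    baseExpr <- exp(stats::rnorm(n, log(200), 0.7))

    moduleAssignment <- integer(n)
    nMod <- config@nModules * config@moduleSize
    moduleAssignment[seq_len(nMod)] <-
        rep(seq_len(config@nModules), each = config@moduleSize)
    names(moduleAssignment) <- geneId

    genes <- data.frame(gene_id = geneId,
                        transcript_id = sub("gene", "tx", geneId),
                        chrom = chrom, strand = strand,
                        tx_start = txStart, tx_end = txEnd,
                        utr5_len = utr5, cds_len = cds, utr3_len = utr3,
                        tx_len = txLen, base_expr = baseExpr,
                        module = unname(moduleAssignment),
                        stringsAsFactors = FALSE)

    ## sequences
    seqs <- vapply(txLen, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""),
        character(1))

    ## planted peaks
    nMeth <- round(config@fracMethylated * n)
    methIdx <- sort(sample(n, nMeth))
    halfW <- config@peakWidth %/% 2L
    junction <- utr5 + cds        # transcript coordinate of last CDS base
    mids <- integer(nMeth)
    for (i in seq_along(methIdx)) {
        g <- methIdx[i]
        if (stats::runif(1) < config@stopCodonBias) {
            mids[i] <- junction[g] + sample(seq(-STOP_WINDOW, STOP_WINDOW), 1L)
        } else {
            mids[i] <- sample(seq(halfW + 1L, txLen[g] - halfW), 1L)
        }
    }
    txPeakStart <- mids - halfW
    txPeakEnd <- txPeakStart + config@peakWidth - 1L

    ## write an RRACH pentamer at each midpoint (transcript positions
    ## mid-2 .. mid+2)
    pent <- paste0(sample(RRACH_R, nMeth, TRUE), sample(RRACH_R, nMeth, TRUE),
                   "A", "C", sample(RRACH_H, nMeth, TRUE))
    for (i in seq_along(methIdx)) {
        g <- methIdx[i]
        substr(seqs[g], mids[i] - 2L, mids[i] + 2L) <- pent[i]
    }

    region <- ifelse(mids <= utr5[methIdx], "5UTR",
                     ifelse(mids <= junction[methIdx], "CDS", "3UTR"))

    ## genomic projection (single exon)
    gs <- txStart[methIdx]; ge <- txEnd[methIdx]
    plus <- strand[methIdx] == "+"
    gStart <- ifelse(plus, gs + txPeakStart - 1L, ge - txPeakEnd + 1L)
    gEnd <- ifelse(plus, gs + txPeakEnd - 1L, ge - txPeakStart + 1L)

    nDm <- round(config@fracDifferential * nMeth)
    effect <- numeric(nMeth)
    if (nDm > 0) {
        dmIdx <- sample(nMeth, nDm)
        effect[dmIdx] <- sample(c(-1, 1), nDm, TRUE) * config@dmLog2fc
    }

    peaks <- data.frame(site_id = sprintf("site_%04d", seq_len(nMeth)),
                        gene_id = geneId[methIdx],
                        chrom = chrom[methIdx], strand = strand[methIdx],
                        tx_mid = mids, tx_start = txPeakStart,
                        tx_end = txPeakEnd,
                        gstart = gStart, gend = gEnd,
                        region = region, pentamer = pent,
                        baseline_enrichment = stats::runif(nMeth, 3, 6),
                        group_effect = effect,
                        is_dm = effect != 0,
                        stringsAsFactors = FALSE)

    sequences <- DNAStringSet(seqs)
    names(sequences) <- genes$transcript_id
    list(genes = genes, peaks = peaks, sequences = sequences,
         moduleAssignment = moduleAssignment, config = config)
}

#' Simulate MeRIP-seq peak calls and IP/input count tables
#'
#' Per-group peak calls cover every planted peak (with a small per-group
#' start jitter) plus a configurable fraction of false-positive peaks; the
#' calls are merged into a reference panel and negative-binomial IP and
#' input counts are drawn over the panel intervals.  Input counts have mean
#' proportional to gene expression and library size; IP counts are
#' additionally multiplied by the peak's baseline enrichment and, for High
#' samples, by `2^group_effect`.
#'
#' @param truth output of [simulateTranscriptome()].
#' @param config the same [SimConfig-class].
#' @return list with `panel` ([PeakPanel-class]), `groupPeaks` (list of two
#'   GRanges of per-group calls), `ipCounts` / `inputCounts` (panel peaks x
#'   samples integer matrices), `ipTotals` / `inputTotals` (named library
#'   totals), `sampleSheet`, `peakGene` (panel peak id -> gene id or NA),
#'   `peakEffect` (panel peak id -> planted group effect), and analytic mean
#'   matrices `expectedIp` / `expectedInput` for validation.
#' @export
simulateMeripCounts <- function(truth, config) {
    set.seed(config@seed + 1000L)
    pk <- truth$peaks
    planted <- GRanges(pk$chrom, IRanges(pk$gstart, pk$gend))
    mcols(planted)$site_id <- pk$site_id

    makeGroupCalls <- function() {
        jit <- sample(seq(-10L, 10L), nrow(pk), replace = TRUE)
        calls <- GRanges(pk$chrom,
                         IRanges(pmax(1L, pk$gstart + jit), pk$gend + jit))
        nFP <- round(config@falsePeakRate * nrow(pk))
        if (nFP > 0) {
            g <- truth$genes[sample(nrow(truth$genes), nFP, replace = TRUE), ]
            halfW <- config@peakWidth %/% 2L
            mid <- g$tx_start + halfW +
                floor(stats::runif(nFP) * (g$tx_len - config@peakWidth))
            fp <- GRanges(g$chrom,
                          IRanges(mid - halfW, width = config@peakWidth))
            calls <- c(calls, fp)
        }
        GenomicRanges::sort(calls, ignore.strand = TRUE)
    }
    groupPeaks <- list(High = makeGroupCalls(), Low = makeGroupCalls())
    panel <- mergePeaks(groupPeaks, maxGap = 0L)

    ## map panel peaks back to planted sites and genes
    ids <- peakIds(panel)
    ovP <- findOverlaps(panel, planted)
    siteOf <- rep(NA_integer_, length(panel))
    siteOf[queryHits(ovP)] <- subjectHits(ovP)   # last hit wins; rare ties
    geneGr <- GRanges(truth$genes$chrom,
                      IRanges(truth$genes$tx_start, truth$genes$tx_end))
    ovG <- findOverlaps(panel, geneGr, select = "first")
    peakGene <- ifelse(is.na(siteOf),
                       truth$genes$gene_id[ovG],
                       pk$gene_id[siteOf])
    enrich <- ifelse(is.na(siteOf), 1, pk$baseline_enrichment[siteOf])
    effect <- ifelse(is.na(siteOf), 0, pk$group_effect[siteOf])
    names(peakGene) <- names(effect) <- ids

    nPer <- config@nSamplesPerGroup
    samples <- c(sprintf("High_%02d", seq_len(nPer)),
                 sprintf("Low_%02d", seq_len(nPer)))
    group <- rep(c("High", "Low"), each = nPer)
    highInd <- as.numeric(group == "High")

    ipTotals <- round(config@meanLibrarySize *
                      stats::runif(length(samples), 0.85, 1.15))
    inputTotals <- round(config@meanLibrarySize *
                         stats::runif(length(samples), 0.85, 1.15))
    names(ipTotals) <- names(inputTotals) <- samples

    baseOf <- truth$genes$base_expr[match(peakGene, truth$genes$gene_id)]
    baseOf[is.na(baseOf)] <- stats::median(truth$genes$base_expr)
    q <- baseOf * (width(panel) / 100) / config@meanLibrarySize

    expectedInput <- outer(q, inputTotals)
    expectedIp <- (q * enrich) %o% ipTotals *
        2^(effect %o% highInd)
    dimnames(expectedInput) <- dimnames(expectedIp) <- list(ids, samples)

    size <- 1 / config@nbDispersion
    draw <- function(mu) {
        m <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                    nrow = nrow(mu), dimnames = dimnames(mu))
        storage.mode(m) <- "integer"
        m
    }
    inputCounts <- draw(expectedInput)
    ipCounts <- draw(expectedIp)

    list(panel = panel, groupPeaks = groupPeaks,
         ipCounts = ipCounts, inputCounts = inputCounts,
         ipTotals = ipTotals, inputTotals = inputTotals,
         sampleSheet = data.frame(sample = samples, group = group,
                                  stringsAsFactors = FALSE),
         peakGene = peakGene, peakEffect = effect,
         expectedIp = expectedIp, expectedInput = expectedInput)
}

#' Simulate module-structured expression counts and sample traits
#'
#' Genes of each planted module share a latent factor (per-gene loadings in
#' (0,1), a subset above 0.9 designated as true hubs in the trait-linked
#' module); background genes are independent noise.  Counts are negative
#' binomial around `base_expr * 2^z` scaled by library size.  Trait 1
#' (IMF %) is generated as `rho * f1 + sqrt(1-rho^2) * noise` so its
#' population correlation with the first module's factor is
#' `traitModuleCorr`; trait 2 (m6A/A ratio) uses `trait2Corr` of the
#' opposite sign, mirroring the opposite trends of fat content and global
#' m6A level.  A fraction of genes receives a planted expression shift of
#' `+/- deLog2fc` between High and Low groups.
#'
#' @param truth output of [simulateTranscriptome()].
#' @param config the same [SimConfig-class].
#' @param fracDE fraction of genes with a planted expression difference.
#' @param deLog2fc magnitude of the planted expression log2 fold change.
#' @param trait2Corr target correlation of trait 2 with the module factor;
#'   must have sign opposite to `traitModuleCorr`.
#' @return list with `counts` (genes x samples integer matrix),
#'   `geneLengths`, `traits` (data.frame: sample, group, IMF, m6A_A),
#'   `deTruth` (named planted log2 fold changes, 0 = null gene),
#'   `loadings` (named per-gene factor loadings) and `hubTruth` (ids of
#'   trait-linked module genes with loading > 0.9).
#' @export
simulateExpression <- function(truth, config, fracDE = 0.1, deLog2fc = 2,
                               trait2Corr = -0.51) {
    if (abs(config@traitModuleCorr) >= 1 || abs(trait2Corr) >= 1)
        stop("trait-module correlations must lie strictly within (-1, 1)")
    if (sign(trait2Corr) == sign(config@traitModuleCorr))
        stop("trait2Corr must have the opposite sign of traitModuleCorr")
    set.seed(config@seed + 2000L)
    g <- truth$genes
    n <- nrow(g)
    nPer <- config@nSamplesPerGroup
    nSamp <- 2L * nPer
    samples <- c(sprintf("High_%02d", seq_len(nPer)),
                 sprintf("Low_%02d", seq_len(nPer)))
    group <- rep(c("High", "Low"), each = nPer)

    ## module latent factors: orthogonalized against the group indicator
    ## (co-expression axes are kept separate from the differential-
    ## expression axis so each planted effect is identifiable) and
    ## standardized to unit sample sd so planted loadings and trait
    ## correlations are realized in the drawn sample
    grpInd0 <- rep(c(1, 0), each = nPer)
    f <- matrix(stats::rnorm(config@nModules * nSamp), config@nModules)
    ## Gram-Schmidt against intercept, group and each other: planted
    ## modules are mutually orthogonal axes in the drawn sample
    base <- cbind(1, grpInd0)
    Q <- qr.Q(qr(cbind(base, t(f))))[, -(1:2), drop = FALSE]
    f <- t(Q) * sqrt(nSamp - 1)
    loadings <- numeric(n)
    names(loadings) <- g$gene_id
    z <- matrix(stats::rnorm(n * nSamp), n, nSamp,
                dimnames = list(g$gene_id, samples))
    for (m in seq_len(config@nModules)) {
        idx <- which(g$module == m)
        nHub <- ceiling(0.2 * length(idx))
        lam <- c(stats::runif(nHub, 0.92, 0.99),
                 stats::runif(length(idx) - nHub, 0.75, 0.9))
        loadings[idx] <- lam
        z[idx, ] <- lam %o% f[m, ] + sqrt(1 - lam^2) * z[idx, , drop = FALSE]
    }

    deTruth <- numeric(n)
    names(deTruth) <- g$gene_id
    nDE <- round(fracDE * n)
    if (nDE > 0) {
        deIdx <- sample(n, nDE)
        deTruth[deIdx] <- sample(c(-1, 1), nDE, TRUE) * deLog2fc
    }

    lib <- round(config@meanLibrarySize *
                 stats::runif(nSamp, 0.85, 1.15))
    highInd <- as.numeric(group == "High")
    mu <- (g$base_expr * 2^z) *
        2^(deTruth %o% highInd) *
        rep(lib / config@meanLibrarySize, each = n)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config@nbDispersion),
                     n, nSamp, dimnames = dimnames(z))
    storage.mode(counts) <- "integer"

    ## traits: noise is residualized against the module factor (so the
    ## factor-trait sample correlation equals the target exactly) and
    ## against the group indicator (so the planted association, not a
    ## chance group confound, drives module-trait statistics)
    grpInd <- as.numeric(group == "High")
    traitNoise <- function() {
        d <- stats::rnorm(nSamp)
        d <- stats::residuals(stats::lm(d ~ f[1, ] + grpInd))
        (d - mean(d)) / stats::sd(d)
    }
    rho <- config@traitModuleCorr
    imfZ <- rho * f[1, ] + sqrt(1 - rho^2) * traitNoise()
    m6aZ <- trait2Corr * f[1, ] + sqrt(1 - trait2Corr^2) * traitNoise()
    traits <- data.frame(sample = samples, group = group,
                         IMF = 2.6 + 1.2 * imfZ,
                         m6A_A = 0.2 + 0.04 * m6aZ,
                         stringsAsFactors = FALSE)

    hubTruth <- g$gene_id[g$module == 1L & loadings > 0.9]
    geneLengths <- stats::setNames(g$tx_len, g$gene_id)
    list(counts = counts, geneLengths = geneLengths, traits = traits,
         deTruth = deTruth, loadings = loadings, hubTruth = hubTruth,
         moduleFactor = f)
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper chaining [simulateTranscriptome()],
#' [simulateMeripCounts()] and [simulateExpression()].
#'
#' @param config a [SimConfig-class].
#' @param ... passed to [simulateExpression()].
#' @return list with elements `truth`, `merip`, `expression`.
#' @export
simulateStudy <- function(config, ...) {
    truth <- simulateTranscriptome(config)
    merip <- simulateMeripCounts(truth, config)
    expression <- simulateExpression(truth, config, ...)
    list(truth = truth, merip = merip, expression = expression,
         config = config)
}

#' Write a simulated study to disk
#'
#' Writes the standard pipeline input files: `transcripts.fa`,
#' `models.gtf` (1-based closed), `peaks_high.bed` / `peaks_low.bed`
#' (0-based half-open), `ip_counts.tsv` / `input_counts.tsv` (panel
#' intervals x samples), `library_totals.tsv`, `expr_counts.tsv`,
#' `gene_lengths.tsv`, `traits.tsv` and `truth.json`.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
#' @importFrom Biostrings writeXStringSet
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeXStringSet(sim$truth$sequences, p("transcripts.fa"))
    writeGtfModels(sim$truth$genes, p("models.gtf"))
    writeBed(sim$merip$groupPeaks$High, p("peaks_high.bed"))
    writeBed(sim$merip$groupPeaks$Low, p("peaks_low.bed"))
    writeCountsTsv <- function(m, f)
        utils::write.table(data.frame(peak_id = rownames(m), m,
                                      check.names = FALSE),
                           p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    writeCountsTsv(sim$merip$ipCounts, "ip_counts.tsv")
    writeCountsTsv(sim$merip$inputCounts, "input_counts.tsv")
    totals <- data.frame(sample = names(sim$merip$ipTotals),
                         group = sim$merip$sampleSheet$group,
                         ip_total = unname(sim$merip$ipTotals),
                         input_total = unname(sim$merip$inputTotals))
    utils::write.table(totals, p("library_totals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = rownames(sim$expression$counts),
                                  sim$expression$counts, check.names = FALSE),
                       p("expr_counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(gene_id = names(sim$expression$geneLengths),
                                  length = unname(sim$expression$geneLengths)),
                       p("gene_lengths.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sim$expression$traits, p("traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth <- list(peaks = sim$truth$peaks,
                  moduleAssignment = as.list(sim$truth$moduleAssignment),
                  deTruth = as.list(sim$expression$deTruth),
                  hubTruth = sim$expression$hubTruth,
                  peakEffect = as.list(sim$merip$peakEffect))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(dir)
}

## GTF writer for the generator's single-exon models (exon + CDS rows,
## 1-based closed, attributes gene_id/transcript_id)
writeGtfModels <- function(genes, path) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                    genes$gene_id, genes$transcript_id)
    cdsStart <- ifelse(genes$strand == "+",
                       genes$tx_start + genes$utr5_len,
                       genes$tx_end - genes$utr5_len - genes$cds_len + 1L)
    cdsEnd <- cdsStart + genes$cds_len - 1L
    rows <- rbind(
        data.frame(chrom = genes$chrom, src = "m6Aflow", feature = "exon",
                   start = genes$tx_start, end = genes$tx_end, score = ".",
                   strand = genes$strand, frame = ".", attr = attr),
        data.frame(chrom = genes$chrom, src = "m6Aflow", feature = "CDS",
                   start = cdsStart, end = cdsEnd, score = ".",
                   strand = genes$strand, frame = "0", attr = attr))
    rows <- rows[order(rows$chrom, rows$start), ]
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
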