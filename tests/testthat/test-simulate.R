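smallConfig <- function(...) {
    args <- utils::modifyList(
        list(nGenes = 120L, nSamplesPerGroup = 4L, nModules = 2L,
             moduleSize = 20L, seed = 1L), list(...))
    do.call(simConfig, args)
}

test_that("configuration invariants are enforced", {
    expect_error(simConfig(nModules = 10, moduleSize = 50, nGenes = 100),
                 "exceeds")
    expect_error(simConfig(fracMethylated = 1.2), "0,1")
    expect_error(simConfig(traitModuleCorr = 1), "within")
    expect_error(simConfig(nbDispersion = 0), "> 0")
})

test_that("the generator is byte-identical under a fixed seed", {
    a <- simulateStudy(smallConfig())
    b <- simulateStudy(smallConfig())
    expect_identical(as.character(a$truth$sequences),
                     as.character(b$truth$sequences))
    expect_identical(a$truth$peaks, b$truth$peaks)
    expect_identical(a$merip$ipCounts, b$merip$ipCounts)
    expect_identical(a$expression$counts, b$expression$counts)
    expect_identical(a$expression$traits, b$expression$traits)
})

test_that("different seeds change values but not schemas", {
    a <- simulateStudy(smallConfig(seed = 1))
    b <- simulateStudy(smallConfig(seed = 2))
    expect_false(identical(a$merip$ipCounts, b$merip$ipCounts))
    ## schemas agree: same samples, same table shapes (panel size may vary)
    expect_identical(colnames(a$merip$ipCounts), colnames(b$merip$ipCounts))
    expect_identical(colnames(a$expression$counts),
                     colnames(b$expression$counts))
    expect_identical(dim(a$expression$counts), dim(b$expression$counts))
    expect_identical(names(a$merip), names(b$merip))
})

test_that("full stop-codon bias places every site in the stop window", {
    truth <- simulateTranscriptome(smallConfig(stopCodonBias = 1))
    junction <- with(truth$genes,
                     utr5_len + cds_len)[match(truth$peaks$gene_id,
                                               truth$genes$gene_id)]
    expect_true(all(abs(truth$peaks$tx_mid - junction) <= stopCodonWindow()))
    expect_true(all(truth$peaks$region %in% c("CDS", "3UTR")))
})

test_that("planted peaks stay inside their transcript and carry RRACH", {
    truth <- simulateTranscriptome(smallConfig(stopCodonBias = 0.5))
    len <- truth$genes$tx_len[match(truth$peaks$gene_id,
                                    truth$genes$gene_id)]
    expect_true(all(truth$peaks$tx_start >= 1))
    expect_true(all(truth$peaks$tx_end <= len))
    ## the pentamer written at each midpoint is found by the motif scanner
    for (i in seq_len(nrow(truth$peaks))) {
        p <- truth$peaks[i, ]
        s <- as.character(truth$sequences[[match(p$gene_id,
                                                 truth$genes$gene_id)]])
        pent <- substr(s, p$tx_mid - 2L, p$tx_mid + 2L)
        expect_identical(pent, p$pentamer)
        hits <- scanRRACH(pent)
        expect_true(0L %in% hits$offset)
    }
})

test_that("count tables are integer, non-negative, with planted structure", {
    cfg <- smallConfig()
    sim <- simulateStudy(cfg)
    expect_true(is.integer(sim$merip$ipCounts))
    expect_true(all(sim$merip$ipCounts >= 0))
    expect_true(all(sim$expression$counts >= 0))
    expect_identical(rownames(sim$merip$ipCounts), peakIds(sim$merip$panel))
    ## per-group calls cover every planted peak
    planted <- GenomicRanges::GRanges(sim$truth$peaks$chrom,
        IRanges::IRanges(sim$truth$peaks$gstart, sim$truth$peaks$gend))
    ov <- GenomicRanges::countOverlaps(planted, sim$merip$groupPeaks$High)
    expect_true(all(ov > 0))
})

test_that("observed counts track analytic means as dispersion vanishes", {
    cfg <- smallConfig(nGenes = 300L, nSamplesPerGroup = 10L,
                       nbDispersion = 1e-4, seed = 3)
    truth <- simulateTranscriptome(cfg)
    merip <- simulateMeripCounts(truth, cfg)
    relErr <- abs(sum(merip$ipCounts) - sum(merip$expectedIp)) /
        sum(merip$expectedIp)
    expect_lt(relErr, 0.01)
    relErrIn <- abs(sum(merip$inputCounts) - sum(merip$expectedInput)) /
        sum(merip$expectedInput)
    expect_lt(relErrIn, 0.01)
})

test_that("a null effect gives a balanced High/Low depth ratio", {
    cfg <- smallConfig(nGenes = 400L, nSamplesPerGroup = 10L,
                       dmLog2fc = 0, seed = 5)
    truth <- simulateTranscriptome(cfg)
    merip <- simulateMeripCounts(truth, cfg)
    se <- methylationDepthMatrix(merip$ipCounts, merip$inputCounts,
                                 merip$ipTotals, merip$inputTotals,
                                 merip$panel, merip$sampleSheet)
    nd <- SummarizedExperiment::assay(se)
    isHigh <- merip$sampleSheet$group == "High"
    lr <- log2(pmax(rowMeans(nd[, isHigh]), 1e-12) /
               pmax(rowMeans(nd[, !isHigh]), 1e-12))
    expect_lt(abs(mean(lr)), 0.05)
})

test_that("traits realize the planted factor correlations", {
    cfg <- smallConfig(nGenes = 200L, nSamplesPerGroup = 10L,
                       traitModuleCorr = 0.9, seed = 4)
    truth <- simulateTranscriptome(cfg)
    ex <- simulateExpression(truth, cfg)
    f1 <- ex$moduleFactor[1, ]
    expect_equal(cor(ex$traits$IMF, f1), 0.9, tolerance = 1e-10)
    expect_equal(cor(ex$traits$m6A_A, f1), -0.51, tolerance = 1e-10)
    expect_equal(nrow(ex$traits), 20L)
    expect_false(anyNA(ex$traits))
    ## opposite trait signs are enforced
    expect_error(simulateExpression(truth, cfg, trait2Corr = 0.3),
                 "opposite")
})

test_that("zero-noise module genes are perfectly correlated", {
    cfg <- smallConfig(nSamplesPerGroup = 10L, seed = 9)
    truth <- simulateTranscriptome(cfg)
    ex <- simulateExpression(truth, cfg)
    idx <- names(which(truth$moduleAssignment == 1))
    lam <- ex$loadings[idx]
    z <- log2(ex$counts[idx, ] + 1)
    ## genes with the highest loadings correlate strongly in-module
    top <- names(sort(lam, decreasing = TRUE))[1:4]
    C <- cor(t(z[top, ]))
    expect_true(all(C[upper.tri(C)] > 0.5))
})

test_that("written simulation files round-trip", {
    dir <- tempfile("sim")
    sim <- simulateStudy(smallConfig())
    writeSimulation(sim, dir)
    expected <- c("transcripts.fa", "models.gtf", "peaks_high.bed",
                  "peaks_low.bed", "ip_counts.tsv", "input_counts.tsv",
                  "library_totals.tsv", "expr_counts.tsv",
                  "gene_lengths.tsv", "traits.tsv", "truth.json")
    expect_true(all(file.exists(file.path(dir, expected))))
    seqs <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
    expect_identical(as.character(seqs),
                     as.character(sim$truth$sequences))
    models <- readGtfModels(file.path(dir, "models.gtf"))
    expect_equal(length(models), nrow(sim$truth$genes))
    ## GTF round trip preserves segment lengths
    m <- models[[sim$truth$genes$transcript_id[1]]]
    segs <- segmentTranscript(m)
    g1 <- sim$truth$genes[1, ]
    expect_equal(segs$end[segs$region == "5UTR"] -
                 segs$start[segs$region == "5UTR"] + 1L, g1$utr5_len)
    expect_equal(segs$end[segs$region == "CDS"] -
                 segs$start[segs$region == "CDS"] + 1L, g1$cds_len)
})
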