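plusModel <- list(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                  strand = "+",
                  exons = matrix(c(1, 300), 1,
                                 dimnames = list(NULL, c("start", "end"))),
                  cds_start = 101, cds_end = 200)
minusModel <- within(plusModel, strand <- "-")

test_that("transcript segmentation is strand-aware and tiles the mRNA", {
    segsP <- segmentTranscript(plusModel)
    expect_equal(segsP$region, c("5UTR", "CDS", "3UTR"))
    expect_equal(segsP$start, c(1, 101, 201))
    expect_equal(segsP$end, c(100, 200, 300))

    ## same genomic geometry on the minus strand swaps the UTR ends:
    ## transcript position 1 is the genomically rightmost base
    segsM <- segmentTranscript(minusModel)
    expect_equal(segsM$region, c("5UTR", "CDS", "3UTR"))
    expect_equal(segsM$start, c(1, 101, 201))
    expect_equal(segsM$end, c(100, 200, 300))
    ## and the 5'UTR maps to the genomically rightmost 100 bases
    g <- m6Aflow:::txToGenomic(minusModel, 1, 100)
    expect_equal(unname(g[1, ]), c(201, 300))

    ## two-exon transcript with CDS spanning the junction
    two <- list(gene_id = "g2", transcript_id = "t2", chrom = "chr1",
                strand = "+",
                exons = matrix(c(1, 100, 201, 300), 2, byrow = TRUE,
                               dimnames = list(NULL, c("start", "end"))),
                cds_start = 51, cds_end = 250)
    segs2 <- segmentTranscript(two)
    expect_equal(sum(segs2$end - segs2$start + 1), 200)
    expect_equal(segs2$end[segs2$region == "CDS"] -
                 segs2$start[segs2$region == "CDS"] + 1, 100)

    bad <- within(plusModel, cds_end <- 400)
    expect_error(segmentTranscript(bad), "CDS outside exons")
})

test_that("peak region assignment uses maximal overlap with 3UTR priority", {
    models <- structure(list(t1 = plusModel), class = "TranscriptModels")
    inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(220, 260))
    expect_equal(assignPeakRegion(inside, models), "3UTR")
    ## 30 nt in CDS (171..200), 70 nt in 3UTR (201..270)
    straddle <- GenomicRanges::GRanges("chr1", IRanges::IRanges(171, 270))
    expect_equal(assignPeakRegion(straddle, models), "3UTR")
    ## exact 50/50 tie CDS vs 3UTR resolves to 3UTR by priority
    tie <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
    expect_equal(assignPeakRegion(tie, models), "3UTR")
    ## 50/50 tie 5UTR vs CDS resolves to 5UTR
    tie2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
    expect_equal(assignPeakRegion(tie2, models), "5UTR")
    none <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 50))
    expect_equal(assignPeakRegion(none, models), "intron/other")
})

test_that("metagene density integrates to one and localizes planted peaks", {
    models <- structure(list(t1 = plusModel), class = "TranscriptModels")
    ## peaks centred on the stop codon (CDS/3'UTR junction at 200)
    stopPeaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(rep(181, 20), rep(220, 20)))
    prof <- metageneProfile(stopPeaks, models, binsPerRegion = 30)
    expect_equal(sum(prof$density * (3 / length(prof$density))), 1)
    peakBin <- which.max(prof$density)
    expect_lte(abs(prof$mids[peakBin] - 2), 2 * (1 / 30))
    expect_equal(prof$nUnmapped, 0L)

    ## an off-transcript peak is counted and excluded
    mix <- suppressWarnings(
        c(stopPeaks, GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 40))))
    expect_equal(metageneProfile(mix, models)$nUnmapped, 1L)

    ## uniform midpoints give a roughly flat profile
    set.seed(15)
    mids <- sample(5:295, 400, replace = TRUE)
    unif <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mids, mids + 1))
    pu <- metageneProfile(unif, models, binsPerRegion = 10)
    chisq <- sum((pu$counts - mean(pu$counts))^2 / mean(pu$counts))
    expect_lt(chisq, qchisq(0.999, length(pu$counts) - 1))
})

test_that("the generator's planted stop-codon bias shows in the metagene", {
    cfg <- simConfig(nGenes = 300, stopCodonBias = 0.9, seed = 17)
    truth <- simulateTranscriptome(cfg)
    models <- makeTranscriptModels(truth$genes)
    peaks <- GenomicRanges::GRanges(truth$peaks$chrom,
        IRanges::IRanges(truth$peaks$gstart, truth$peaks$gend))
    prof <- metageneProfile(peaks, models, binsPerRegion = 30)
    expect_equal(sum(prof$density * (3 / 90)), 1)
    ## the modal bin sits within 2 bins of the CDS/3'UTR junction (axis 2)
    expect_lte(abs(prof$mids[which.max(prof$density)] - 2), 2 / 30 + 1e-9)
})

test_that("scanRRACH matches the consensus and a sliding-window oracle", {
    expect_equal(scanRRACH("AGACT")$offset, 0L)
    expect_equal(scanRRACH("GGACA")$offset, 0L)
    expect_equal(nrow(scanRRACH("TTTTTT")), 0L)
    ## U is treated as T; N never matches
    expect_equal(scanRRACH("AGACU")$offset, 0L)
    expect_equal(nrow(scanRRACH("NGACT")), 0L)
    expect_equal(nrow(scanRRACH("AGNCT")), 0L)
    ## overlapping hits are all reported
    hits <- scanRRACH("GGACAGGACA")  # offsets 0 and 5
    expect_equal(hits$offset, c(0L, 5L))

    set.seed(19)
    for (rep in 1:50) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.28, 0.02)),
                   collapse = "")
        expect_identical(scanRRACH(s)$offset, rrachOracle(s))
    }
})

test_that("dinucleotide shuffling preserves doublet counts exactly", {
    set.seed(23)
    for (rep in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                   collapse = "")
        sh <- shuffleDinucleotide(s)
        expect_identical(dinucCounts(sh), dinucCounts(s))
        expect_identical(nchar(sh), nchar(s))
    }
})

test_that("motif enrichment is extreme for RRACH repeats and calm on null", {
    rich <- rep(paste(rep("GGACT", 20), collapse = ""), 5)
    enr <- motifEnrichment(rich, nShuffles = 100, seed = 1)
    ## dinucleotide-preserving shuffles of a pure motif repeat retain much
    ## of its motif density, so the fold is modest but the p-value floors
    expect_gt(enr$fold, 1)
    expect_equal(enr$pValue, 1 / 101)

    set.seed(27)
    null <- vapply(1:5, function(i)
        paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = ""), character(1))
    enr0 <- motifEnrichment(null, nShuffles = 100, seed = 2)
    expect_gt(enr0$pValue, 0.01)
    expect_lt(abs(log2(enr0$fold)), 1)
    expect_error(motifEnrichment(character()), "empty")
    expect_error(motifEnrichment("ACGT", nShuffles = 10), ">= 100")
})

test_that("segmentation lengths always sum to the mature length", {
    cfg <- simConfig(nGenes = 60, nModules = 2, moduleSize = 10, seed = 29)
    truth <- simulateTranscriptome(cfg)
    models <- makeTranscriptModels(truth$genes)
    for (m in models[1:20]) {
        segs <- segmentTranscript(m)
        expect_equal(sum(segs$end - segs$start + 1),
                     sum(m$exons[, "end"] - m$exons[, "start"] + 1))
    }
})
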