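## Transcript-region segmentation, peak region assignment, metagene
## density profiling, and RRACH motif scanning/enrichment.
##
## Coordinates: GTF is 1-based closed and is kept that way internally
## (matching the package's GRanges convention).  Transcript ("mature")
## coordinates are 1-based over the concatenated exons, 5' to 3' on the
## coding strand; on the minus strand position 1 is the genomically
## rightmost exonic base.

#' Read transcript models from a GTF-like file
#'
#' Parses `exon` and `CDS` features (1-based closed) with
#' `gene_id`/`transcript_id` attributes into a list of transcript models.
#'
#' @param path GTF file path.
#' @return a list of class `TranscriptModels`; each element has
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `exons` (2-column
#'   matrix of start/end, sorted), `cds_start`, `cds_end` (genomic bounds,
#'   NA if non-coding).
#' @export
readGtfModels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
    names(df)[c(1, 3, 4, 5, 7, 9)] <-
        c("chrom", "feature", "start", "end", "strand", "attr")
    df <- df[df$feature %in% c("exon", "CDS"), ]
    getAttr <- function(a, key)
        sub(paste0('.*', key, ' "([^"]+)".*'), "\\1", a)
    df$transcript_id <- getAttr(df$attr, "transcript_id")
    df$gene_id <- getAttr(df$attr, "gene_id")
    models <- lapply(split(df, df$transcript_id), function(d) {
        ex <- d[d$feature == "exon", c("start", "end"), drop = FALSE]
        ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
        cds <- d[d$feature == "CDS", ]
        model <- list(gene_id = d$gene_id[1],
                      transcript_id = d$transcript_id[1],
                      chrom = d$chrom[1], strand = d$strand[1],
                      exons = ex,
                      cds_start = if (nrow(cds)) min(cds$start) else NA,
                      cds_end = if (nrow(cds)) max(cds$end) else NA)
        validateModel(model)
        model
    })
    structure(models, class = "TranscriptModels")
}

#' Build transcript models directly from a generator gene table
#' @param genes the `genes` data.frame from [simulateTranscriptome()].
#' @return a `TranscriptModels` list (see [readGtfModels()]).
#' @export
makeTranscriptModels <- function(genes) {
    models <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        cdsStart <- if (g$strand == "+") g$tx_start + g$utr5_len
                    else g$tx_end - g$utr5_len - g$cds_len + 1L
        list(gene_id = g$gene_id, transcript_id = g$transcript_id,
             chrom = g$chrom, strand = g$strand,
             exons = matrix(c(g$tx_start, g$tx_end), 1,
                            dimnames = list(NULL, c("start", "end"))),
             cds_start = cdsStart, cds_end = cdsStart + g$cds_len - 1L)
    })
    names(models) <- genes$transcript_id
    structure(models, class = "TranscriptModels")
}

validateModel <- function(m) {
    ex <- m$exons
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
        stop("overlapping exons in transcript ", m$transcript_id)
    if (!is.na(m$cds_start)) {
        inExon <- function(p) any(p >= ex[, 1L] & p <= ex[, 2L])
        if (!inExon(m$cds_start) || !inExon(m$cds_end))
            stop("CDS outside exons in transcript ", m$transcript_id)
    }
    invisible(TRUE)
}

## genomic position -> mature transcript coordinate (NA if intronic /
## outside); strand-aware
genomicToTx <- function(model, gpos) {
    ex <- model$exons
    w <- ex[, 2L] - ex[, 1L] + 1L
    cumBefore <- cumsum(c(0L, w))[-(nrow(ex) + 1L)]
    out <- rep(NA_integer_, length(gpos))
    for (i in seq_len(nrow(ex))) {
        in_i <- gpos >= ex[i, 1L] & gpos <= ex[i, 2L]
        out[in_i] <- cumBefore[i] + (gpos[in_i] - ex[i, 1L] + 1L)
    }
    if (model$strand == "-") {
        L <- sum(w)
        out <- L - out + 1L
    }
    out
}

matureLength <- function(model)
    sum(model$exons[, 2L] - model$exons[, 1L] + 1L)

#' Segment a transcript into 5'UTR / CDS / 3'UTR
#'
#' Maps the genomic CDS bounds into mature-transcript coordinates and
#' returns the three regions as transcript-coordinate intervals (1-based
#' closed) that tile the mature transcript.  Strand-aware: on the minus
#' strand the 5'UTR is the genomically rightmost UTR.
#'
#' @param model one element of a `TranscriptModels` list.
#' @return data.frame with columns `region` ("5UTR", "CDS", "3UTR"),
#'   `start`, `end` (transcript coordinates); zero-width regions omitted.
#' @export
segmentTranscript <- function(model) {
    validateModel(model)
    L <- matureLength(model)
    if (is.na(model$cds_start))
        return(data.frame(region = "3UTR", start = 1L, end = L))
    b <- sort(genomicToTx(model, c(model$cds_start, model$cds_end)))
    segs <- data.frame(region = c("5UTR", "CDS", "3UTR"),
                       start = c(1L, b[1L], b[2L] + 1L),
                       end = c(b[1L] - 1L, b[2L], L),
                       stringsAsFactors = FALSE)
    segs[segs$end >= segs$start, , drop = FALSE]
}

## genomic intervals (GRanges-free matrix) of a transcript-coordinate
## interval, split across exons
txToGenomic <- function(model, txStart, txEnd) {
    ex <- model$exons
    w <- ex[, 2L] - ex[, 1L] + 1L
    L <- sum(w)
    if (model$strand == "-") {
        r <- c(L - txEnd + 1L, L - txStart + 1L)
        txStart <- r[1L]; txEnd <- r[2L]
    }
    cumBefore <- cumsum(c(0L, w))
    out <- NULL
    for (i in seq_len(nrow(ex))) {
        exTxStart <- cumBefore[i] + 1L
        exTxEnd <- cumBefore[i + 1L]
        s <- max(txStart, exTxStart); e <- min(txEnd, exTxEnd)
        if (s <= e)
            out <- rbind(out, c(ex[i, 1L] + (s - exTxStart),
                                ex[i, 1L] + (e - exTxStart)))
    }
    out
}

## keep the longest transcript per gene
longestPerGene <- function(models) {
    lens <- vapply(models, matureLength, numeric(1))
    genes <- vapply(models, `[[`, character(1), "gene_id")
    keep <- unlist(lapply(split(seq_along(models), genes), function(idx)
        idx[which.max(lens[idx])]))
    structure(models[sort(keep)], class = "TranscriptModels")
}

#' Assign peaks to transcript regions
#'
#' For each peak, computes its overlap (nt) with the 5'UTR, CDS and 3'UTR
#' of the longest transcript of every overlapping gene and returns the
#' label with the maximal total overlap; ties are broken by the priority
#' 3UTR > 5UTR > CDS.  Peaks overlapping no exonic region get
#' "intron/other".
#'
#' @param peaks a `GRanges` (or [PeakPanel-class]) of peaks.
#' @param models a `TranscriptModels` list.
#' @return character vector of region labels, one per peak.
#' @export
assignPeakRegion <- function(peaks, models) {
    models <- longestPerGene(models)
    regGr <- regionGRanges(models)
    priority <- c("3UTR" = 3L, "5UTR" = 2L, "CDS" = 1L)
    labels <- rep("intron/other", length(peaks))
    ## peaks on sequences without any model are expected (-> intron/other);
    ## silence the disjoint-seqlevels notice
    ov <- suppressWarnings(
        findOverlaps(granges(peaks), regGr, ignore.strand = TRUE))
    if (length(ov)) {
        w <- width(pintersect(granges(peaks)[queryHits(ov)],
                              regGr[subjectHits(ov)], ignore.strand = TRUE))
        reg <- mcols(regGr)$region[subjectHits(ov)]
        key <- paste(queryHits(ov), reg)
        agg <- tapply(w, key, sum)
        qh <- as.integer(sub(" .*", "", names(agg)))
        rg <- sub(".* ", "", names(agg))
        best <- tapply(seq_along(agg), qh, function(idx) {
            o <- idx[order(-agg[idx], -priority[rg[idx]])]
            rg[o[1L]]
        })
        labels[as.integer(names(best))] <- unname(best)
    }
    labels
}

## all region segments of all models as one GRanges with mcols region
regionGRanges <- function(models) {
    parts <- lapply(models, function(m) {
        segs <- segmentTranscript(m)
        do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
            g <- txToGenomic(m, segs$start[i], segs$end[i])
            data.frame(chrom = m$chrom, start = g[, 1L], end = g[, 2L],
                       region = segs$region[i], stringsAsFactors = FALSE)
        }))
    })
    df <- do.call(rbind, parts)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr)$region <- df$region
    gr
}

#' Metagene profile of peak positions
#'
#' Maps each peak midpoint to mature-transcript coordinates of the longest
#' transcript of its gene, rescales the position within its region (5'UTR,
#' CDS or 3'UTR) to the unit interval, and histograms the positions on a concatenated
#' axis of three equal-width regions with `binsPerRegion` bins each.  The
#' density is normalized to unit area over the axis of length 3.  Peaks
#' whose midpoint overlaps no transcript are counted and excluded.
#'
#' @param peaks a `GRanges` of peaks.
#' @param models a `TranscriptModels` list.
#' @param binsPerRegion bins per region (default 30).
#' @return list of class `MetageneProfile` with `density` (length
#'   `3 * binsPerRegion`), `mids` (bin midpoints on the 0..3 axis),
#'   `counts`, `regionCounts` (peaks per region), `nMapped`, `nUnmapped`.
#' @export
metageneProfile <- function(peaks, models, binsPerRegion = 30L) {
    models <- longestPerGene(models)
    mid <- (start(peaks) + end(peaks)) %/% 2L
    midGr <- GRanges(seqnames(peaks), IRanges(mid, mid))
    exGr <- GRanges(vapply(models, `[[`, character(1), "chrom"),
                    IRanges(vapply(models, function(m) min(m$exons[, 1L]),
                                   numeric(1)),
                            vapply(models, function(m) max(m$exons[, 2L]),
                                   numeric(1))))
    hit <- suppressWarnings(findOverlaps(midGr, exGr, select = "first"))
    pos <- rep(NA_real_, length(peaks))
    for (i in which(!is.na(hit))) {
        m <- models[[hit[i]]]
        txp <- genomicToTx(m, mid[i])
        if (is.na(txp)) next
        segs <- segmentTranscript(m)
        j <- which(txp >= segs$start & txp <= segs$end)[1L]
        if (is.na(j)) next
        rel <- (txp - segs$start[j] + 0.5) /
            (segs$end[j] - segs$start[j] + 1L)
        offset <- match(segs$region[j], c("5UTR", "CDS", "3UTR")) - 1L
        pos[i] <- offset + rel
    }
    mapped <- pos[!is.na(pos)]
    if (!length(mapped)) stop("no peak maps to any transcript")
    nb <- 3L * binsPerRegion
    breaks <- seq(0, 3, length.out = nb + 1L)
    cnt <- as.integer(table(cut(mapped, breaks, include.lowest = TRUE)))
    dens <- cnt / (length(mapped) * (3 / nb))
    regionCounts <- table(factor(c("5UTR", "CDS", "3UTR")[ceiling(
        pmax(mapped, 1e-9))], levels = c("5UTR", "CDS", "3UTR")))
    structure(list(density = dens,
                   mids = (breaks[-1L] + breaks[-(nb + 1L)]) / 2,
                   counts = cnt, regionCounts = regionCounts,
                   nMapped = length(mapped),
                   nUnmapped = sum(is.na(pos))),
              class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
    cat("MetageneProfile:", x$nMapped, "peaks mapped,", x$nUnmapped,
        "unmapped\n")
    cat("  region counts:",
        paste(names(x$regionCounts), x$regionCounts, sep = "=",
              collapse = ", "), "\n")
    cat("  peak bin at axis position", x$mids[which.max(x$density)],
        "(0-1 = 5'UTR, 1-2 = CDS, 2-3 = 3'UTR)\n")
    invisible(x)
}

#' Scan sequences for the RRACH m6A consensus
#'
#' Finds all (overlapping) occurrences of the m6A consensus pentamer RRACH
#' (R = A/G, H = A/C/U) on the coding strand.  U is treated as T; N never
#' matches.
#'
#' @param seqs a character vector, `DNAStringSet`, or single string.
#' @return data.frame with `seq_id`, `offset` (0-based), `pentamer`.
#' @examples
#' scanRRACH("AGACT")   # one hit at offset 0
#' @export
#' @importFrom Biostrings DNAString matchPattern
scanRRACH <- function(seqs) {
    if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- if (length(seqs) == 1L) "seq1"
                       else paste0("seq", seq_along(seqs))
    seqs <- chartr("uU", "tT", seqs)
    hits <- lapply(names(seqs), function(id) {
        s <- toupper(seqs[[id]])
        if (nchar(s) < 5L)
            return(NULL)
        m <- matchPattern("RRACH", DNAString(s), fixed = "subject")
        if (length(m) == 0L) return(NULL)
        data.frame(seq_id = id, offset = BiocGenerics::start(m) - 1L,
                   pentamer = as.character(m), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, hits)
    if (is.null(out))
        out <- data.frame(seq_id = character(), offset = integer(),
                          pentamer = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle of a nucleotide sequence that exactly preserves its
#' dinucleotide (and hence mononucleotide) counts, via a random Eulerian
#' path on the dinucleotide transition graph (Altschul-Erickson style).
#'
#' @param seq a single sequence string.
#' @return a shuffled string with identical dinucleotide counts.
#' @export
shuffleDinucleotide <- function(seq) {
    s <- strsplit(toupper(seq), "")[[1L]]
    n <- length(s)
    if (n <= 3L) return(seq)
    verts <- unique(s)
    from <- s[-n]; to <- s[-1L]
    out <- split(to, factor(from, verts))
    last <- s[n]
    repeat {
        ## choose a candidate terminal edge for every non-final vertex and
        ## accept if those edges form an arborescence toward the final one
        lastEdge <- vapply(verts, function(v) {
            if (v == last || !length(out[[v]])) NA_character_
            else sample(out[[v]], 1L)
        }, character(1))
        reach <- stats::setNames(verts == last, verts)
        for (k in seq_along(verts)) {     # fixed-point over <=|V| rounds
            reach <- stats::setNames(vapply(verts, function(v)
                reach[[v]] || (!is.na(lastEdge[[v]]) &&
                               isTRUE(reach[[lastEdge[[v]]]])),
                logical(1)), verts)
        }
        active <- vapply(verts, function(v)
            v == last || length(out[[v]]) > 0L, logical(1))
        if (all(reach[active])) break
    }
    perm <- lapply(verts, function(v) {
        e <- out[[v]]
        if (!length(e)) return(e)
        if (is.na(lastEdge[[v]])) return(sample(e))
        i <- match(lastEdge[[v]], e)
        c(sample(e[-i]), e[i])
    })
    names(perm) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    res <- character(n)
    res[1L] <- s[1L]
    cur <- s[1L]
    for (i in 2:n) {
        nxt <- perm[[cur]][ptr[[cur]]]
        ptr[[cur]] <- ptr[[cur]] + 1L
        res[i] <- nxt
        cur <- nxt
    }
    paste(res, collapse = "")
}

#' RRACH motif enrichment against a dinucleotide-shuffle null
#'
#' Observed statistic: mean RRACH hits per nucleotide over the peak
#' sequences.  Null: the same statistic on `nShuffles` replicates in which
#' every sequence is shuffled preserving dinucleotide counts.  The
#' empirical p-value is `(1 + #{null >= observed}) / (1 + nShuffles)`.
#'
#' @param peakSeqs character vector or `DNAStringSet` of peak sequences.
#' @param nShuffles number of shuffle replicates (>= 100).
#' @param seed integer seed for the shuffles.
#' @return list with `observed`, `expected` (mean null density), `fold`,
#'   `pValue`, `nullDensities`.
#' @export
motifEnrichment <- function(peakSeqs, nShuffles = 200L, seed = 1L) {
    if (is(peakSeqs, "DNAStringSet")) peakSeqs <- as.character(peakSeqs)
    if (!length(peakSeqs) || any(!nzchar(peakSeqs)))
        stop("empty sequences")
    if (nShuffles < 100L) stop("nShuffles must be >= 100")
    set.seed(seed)
    totalNt <- sum(nchar(peakSeqs))
    density <- function(ss) nrow(scanRRACH(ss)) / totalNt
    obs <- density(peakSeqs)
    null <- vapply(seq_len(nShuffles), function(i)
        density(vapply(peakSeqs, shuffleDinucleotide, character(1))),
        numeric(1))
    expected <- mean(null)
    list(observed = obs, expected = expected,
         fold = if (expected > 0) obs / expected else Inf,
         pValue = (1 + sum(null >= obs)) / (1 + nShuffles),
         nullDensities = null)
}
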