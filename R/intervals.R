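## Interval arithmetic for peak panels.  Internal convention: GRanges,
## 1-based closed.  BED files (0-based half-open) are converted at the
## boundary by readBed()/writeBed().

#' Read a BED3+ file into a GRanges
#'
#' Plain tab-separated BED with no header; 0-based half-open coordinates are
#' converted to the package's internal 1-based closed convention.  A fourth
#' column, when present, is kept as metadata column `name`.
#'
#' @param path file path.
#' @return a `GRanges`.
#' @export
readBed <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    names(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4L) names(df)[4] <- "name"
    if (ncol(df) >= 6L) names(df)[6] <- "strand"
    bad <- df$start >= df$end
    if (any(bad))
        stop("malformed interval (start >= end) in ", path, " at line(s) ",
             paste(which(bad), collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = if ("strand" %in% names(df) &&
                               all(df$strand %in% c("+", "-", ".")))
                      df$strand else "*")
    if ("name" %in% names(df)) mcols(gr)$name <- df$name
    gr
}

#' Write a GRanges as BED
#'
#' Converts back to 0-based half-open coordinates.  If a `name` (or
#' `peak_id`) metadata column exists it is written as column 4.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- mcols(gr)$peak_id
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     stringsAsFactors = FALSE)
    if (!is.null(nm)) df$name <- nm
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Merge peak sets into a reference panel
#'
#' Combines peak calls (e.g. per-group MACS2 output) into a reference m6A
#' peak panel, merging overlapping and bookended intervals as
#' `bedtools merge -d <maxGap>` would.  Provenance records which input sets
#' contributed to each merged peak.  Strand is ignored (broad peaks are
#' unstranded).
#'
#' @param peakSets a named `list` of `GRanges` (names become provenance
#'   labels), or a single `GRanges`.
#' @param maxGap maximum gap (nt) between intervals that still merges them;
#'   0 merges overlapping and bookended intervals.
#' @return a [PeakPanel-class] with `peak_id` and `sources` metadata.
#' @examples
#' hi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' lo <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8, 20))
#' mergePeaks(list(High = hi, Low = lo))
#' @export
mergePeaks <- function(peakSets, maxGap = 0L) {
    if (is(peakSets, "GRanges"))
        peakSets <- list(peaks = peakSets)
    stopifnot(is.list(peakSets), maxGap >= 0)
    if (is.null(names(peakSets)))
        names(peakSets) <- paste0("set", seq_along(peakSets))
    for (nm in names(peakSets)) {
        gr <- peakSets[[nm]]
        if (any(width(gr) < 1L))
            stop("malformed interval (start >= end) in set '", nm, "'")
    }
    all <- unlist(GenomicRanges::GRangesList(lapply(peakSets, granges)),
                  use.names = FALSE)
    src <- rep(names(peakSets), lengths(peakSets))
    strand(all) <- "*"
    merged <- reduce(all, min.gapwidth = maxGap + 1L, ignore.strand = TRUE)
    merged <- GenomeInfoDb::sortSeqlevels(merged)
    merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
    ov <- findOverlaps(merged, all)
    sources <- unname(split(src[subjectHits(ov)],
                            factor(queryHits(ov), seq_along(merged))))
    sources <- lapply(sources, function(s) sort(unique(s)))
    mcols(merged)$peak_id <- sprintf("peak_%05d", seq_along(merged))
    mcols(merged)$sources <- IRanges::CharacterList(sources)
    new("PeakPanel", merged)
}

#' Sum of per-base read depth over a region
#'
#' The `samtools bedcov` statistic: for a region and a set of read
#' intervals, the sum over bases of the region of the number of reads
#' covering that base.  Equivalently the total overlap length between the
#' reads and the region.
#'
#' @param reads `GRanges` of read intervals.
#' @param regions `GRanges` of one or more regions.
#' @return integer vector, one per region.
#' @export
coverageSum <- function(reads, regions) {
    if (length(reads) == 0L)
        return(integer(length(regions)))
    ov <- findOverlaps(regions, reads, ignore.strand = TRUE)
    if (length(ov) == 0L)
        return(integer(length(regions)))
    w <- width(pintersect(regions[queryHits(ov)], reads[subjectHits(ov)],
                          ignore.strand = TRUE))
    out <- integer(length(regions))
    agg <- tapply(w, queryHits(ov), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
    out
}

#' Two-set Venn counts
#'
#' @param setA,setB vectors of identifiers.
#' @return named integer vector `c(uniqueA, shared, uniqueB)`.
#' @examples
#' vennCounts(c(1, 2, 3), c(3, 4))
#' @export
vennCounts <- function(setA, setB) {
    a <- unique(setA); b <- unique(setB)
    shared <- length(intersect(a, b))
    c(uniqueA = length(a) - shared, shared = shared,
      uniqueB = length(b) - shared)
}
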