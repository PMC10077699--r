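## Independent brute-force oracles shared across test files.  These stay
## deliberately naive (per-base loops, triple loops, enumeration) so they
## are independent of the implementation paths they check.

## union of intervals via a per-base boolean mask (1-based closed)
maskMergeOracle <- function(starts, ends, maxCoord = max(ends) + 2L) {
    mask <- logical(maxCoord)
    for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
    r <- rle(mask)
    stops <- cumsum(r$lengths)
    begins <- stops - r$lengths + 1L
    cbind(start = begins[r$values], end = stops[r$values])
}

## bedcov: per-base depth sum of reads over one region (1-based closed)
coverageSumOracle <- function(rStarts, rEnds, regStart, regEnd) {
    total <- 0L
    for (b in regStart:regEnd)
        total <- total + sum(rStarts <= b & rEnds >= b)
    total
}

## TOM via explicit triple loop
tomOracle <- function(adj) {
    a <- adj
    diag(a) <- 0
    n <- nrow(a)
    k <- rowSums(a)
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    dimnames(out) <- dimnames(adj)
    out
}

## upper-tail hypergeometric by complete enumeration of all draws
hyperOracle <- function(overlap, termSize, universeSize, querySize) {
    draws <- utils::combn(universeSize, querySize)
    inTerm <- colSums(draws <= termSize)   # term = first termSize ids
    mean(inTerm >= overlap)
}

## sliding-window RRACH matcher
rrachOracle <- function(s) {
    s <- chartr("uU", "tT", toupper(s))
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < 5L) return(integer())
    hits <- integer()
    for (i in seq_len(n - 4L)) {
        w <- ch[i:(i + 4L)]
        if (w[1] %in% c("A", "G") && w[2] %in% c("A", "G") &&
            w[3] == "A" && w[4] == "C" && w[5] %in% c("A", "C", "T"))
            hits <- c(hits, i - 1L)
    }
    hits
}

dinucCounts <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
}

## adjusted Rand index between two labelings
adjustedRandIndex <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sc <- function(x) sum(choose(x, 2))
    e <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
    (sc(tab) - e) / ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 - e)
}

randomGRanges <- function(n, chroms = c("chr1", "chr2"), maxStart = 500L,
                          maxWidth = 60L) {
    st <- sample(maxStart, n, replace = TRUE)
    GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                           IRanges::IRanges(st, st + sample(maxWidth, n,
                                                            replace = TRUE)))
}
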