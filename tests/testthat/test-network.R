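## block-structured expression for clustering tests: nBlocks blocks of
## blockSize genes with within-block correlation ~r, plus noise genes
makeBlocks <- function(nBlocks = 3, blockSize = 50, nNoise = 50,
                       nSamples = 20, r = 0.9, seed = 1) {
    set.seed(seed)
    lam <- sqrt(r)
    ## factors orthogonalized so across-block correlation is exactly zero,
    ## as the construction stipulates
    f0 <- matrix(rnorm(nBlocks * nSamples), nSamples, nBlocks)
    f0 <- qr.Q(qr(cbind(1, f0)))[, -1, drop = FALSE] * sqrt(nSamples - 1)
    X <- lapply(seq_len(nBlocks), function(b) {
        t(vapply(seq_len(blockSize), function(i)
            lam * f0[, b] + sqrt(1 - lam^2) * rnorm(nSamples),
            numeric(nSamples)))
    })
    noise <- matrix(rnorm(nNoise * nSamples), nNoise, nSamples)
    m <- rbind(do.call(rbind, X), noise)
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    colnames(m) <- paste0("s", seq_len(nSamples))
    list(expr = m,
         truth = c(rep(seq_len(nBlocks), each = blockSize),
                   rep(0L, nNoise)))
}

test_that("soft-threshold scan honours forced candidates and bounds", {
    b <- makeBlocks(seed = 3)
    forced <- pickSoftThreshold(b$expr, candidates = 7)
    expect_equal(forced$beta, 7)
    scan <- pickSoftThreshold(b$expr, candidates = c(2, 4, 6, 8))
    ok <- !is.na(scan$table$signedR2)
    expect_true(all(abs(scan$table$signedR2[ok]) <= 1))
    expect_true(scan$beta %in% c(2, 4, 6, 8))
    ## constant rows are dropped with a warning
    withConst <- rbind(b$expr, const = rep(1, ncol(b$expr)))
    expect_warning(pickSoftThreshold(withConst, candidates = 6),
                   "constant")
})

test_that("soft-threshold scan matches an independent re-implementation", {
    b <- makeBlocks(nBlocks = 2, blockSize = 30, nNoise = 40, seed = 5)
    cands <- c(1, 3, 5, 7, 9)
    scan <- pickSoftThreshold(b$expr, candidates = cands, nBins = 10)
    ## independent: recompute the signed fit index from first principles
    C <- abs(cor(t(b$expr)))
    diag(C) <- 0
    ref <- vapply(cands, function(beta) {
        k <- rowSums(C^beta)
        k <- k[k > 0]
        br <- unique(quantile(k, seq(0, 1, length.out = 11)))
        bin <- cut(k, br, include.lowest = TRUE)
        pk <- as.numeric(table(bin)) / length(k)
        kb <- tapply(k, bin, mean)
        fit <- lm(log10(pk) ~ log10(as.numeric(kb)))
        -sign(coef(fit)[2]) * suppressWarnings(summary(fit)$r.squared)
    }, numeric(1))
    expect_equal(scan$table$signedR2, unname(ref), tolerance = 1e-10)
})

test_that("adjacency obeys the power law and hand-computed values", {
    x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
    expect_equal(adjacencyMatrix(x, 1)["g1", "g2"], 1)
    set.seed(7)
    y <- matrix(rnorm(5 * 12), 5, dimnames = list(paste0("g", 1:5), NULL))
    a2 <- adjacencyMatrix(y, 2)
    a6 <- adjacencyMatrix(y, 6)
    off <- upper.tri(a2)
    expect_true(all(a6[off] <= a2[off] + 1e-12))
    ## hand check against |cor|^beta
    C <- abs(cor(t(y)))
    expect_equal(a2[off], (C^2)[off])
    zv <- rbind(y, const = rep(3, 12))
    expect_error(adjacencyMatrix(zv, 2), "zero-variance")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
    ## no shared neighbours, no direct links -> zero overlap
    a0 <- diag(4)
    expect_true(all(tomSimilarity(a0)[upper.tri(a0)] == 0))
    ## complete graph of 3 with unit adjacency -> TOM 1 everywhere
    a1 <- matrix(1, 3, 3)
    expect_true(all(tomSimilarity(a1) == 1))
    set.seed(9)
    for (rep in 1:10) {
        n <- sample(5:15, 1)
        r <- abs(cor(matrix(rnorm(n * 10), ncol = n)))
        tom <- tomSimilarity(r)
        expect_equal(tom, tomOracle(r), tolerance = 1e-12)
        expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
        expect_equal(tom, t(tom))
    }
    asym <- matrix(c(1, 0.5, 0.2, 1), 2)
    expect_error(tomSimilarity(asym), "symmetric")
})

test_that("planted blocks are detected and noise stays grey", {
    b <- makeBlocks(nBlocks = 3, blockSize = 50, nNoise = 60, seed = 11)
    tom <- tomSimilarity(adjacencyMatrix(b$expr, 6))
    labels <- detectModules(tom, minModuleSize = 30)
    expect_equal(length(labels), nrow(b$expr))
    expect_equal(sum(table(labels)), nrow(b$expr))
    inBlock <- b$truth > 0
    expect_gte(adjustedRandIndex(labels[inBlock], b$truth[inBlock]), 0.95)
    ## pure-noise data stays mostly unassigned
    noise <- makeBlocks(nBlocks = 1, blockSize = 2, nNoise = 150, seed = 13)
    tn <- tomSimilarity(adjacencyMatrix(noise$expr, 6))
    ln <- detectModules(tn, minModuleSize = 30)
    expect_gte(mean(ln == 0), 0.5)
})

test_that("module eigengenes are unit norm, oriented and stable", {
    b <- makeBlocks(nBlocks = 2, blockSize = 40, nNoise = 0, seed = 15)
    labels <- setNames(b$truth, rownames(b$expr))
    E <- computeModuleEigengenes(b$expr, labels)
    expect_equal(colnames(E), c("ME1", "ME2"))
    expect_equal(unname(colSums(E^2)), c(1, 1))
    ## orientation: positively correlated with module mean expression
    for (m in 1:2) {
        zm <- t(scale(t(b$expr[labels == m, ])))
        expect_gte(cor(E[, m], colMeans(zm)), 0)
    }
    ## a module of identical genes reproduces that profile exactly
    prof <- rnorm(10)
    ident <- matrix(rep(prof, 5), 5, byrow = TRUE,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
    Ei <- computeModuleEigengenes(ident, setNames(rep(1L, 5),
                                                  rownames(ident)))
    expect_equal(abs(cor(Ei[, 1], prof)), 1, tolerance = 1e-9)
    ## duplicating a member barely moves the eigengene
    dup <- rbind(b$expr[labels == 1, ], b$expr[1, , drop = FALSE])
    rownames(dup)[nrow(dup)] <- "dup"
    Ed <- computeModuleEigengenes(dup, setNames(rep(1L, nrow(dup)),
                                                rownames(dup)))
    expect_gte(abs(cor(Ed[, 1], E[, 1])), 0.99)
})

test_that("module-trait correlation reproduces the textbook formula", {
    b <- makeBlocks(nBlocks = 1, blockSize = 30, nNoise = 0, seed = 17)
    labels <- setNames(b$truth, rownames(b$expr))
    E <- computeModuleEigengenes(b$expr, labels)
    mt <- moduleTraitCorrelation(E, data.frame(t = E[, 1]))
    expect_equal(unname(mt$r[1, 1]), 1)
    expect_lt(mt$p[1, 1], 1e-10)

    x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
    expect_equal(unname(moduleTraitCorrelation(matrix(x), matrix(y))$r[1, 1]),
                 1)
    ## 5-sample toy against the closed form
    set.seed(19)
    e5 <- matrix(rnorm(5)); t5 <- rnorm(5)
    mt5 <- moduleTraitCorrelation(e5, matrix(t5))
    r <- cor(e5[, 1], t5)
    tt <- r * sqrt(3 / (1 - r^2))
    expect_equal(unname(mt5$r[1, 1]), r)
    expect_equal(unname(mt5$p[1, 1]), 2 * pt(-abs(tt), 3))
    expect_error(moduleTraitCorrelation(e5, matrix(rep(1, 5))),
                 "zero-variance")
})

test_that("MM and GS follow their definitions including the GS sign", {
    b <- makeBlocks(nBlocks = 1, blockSize = 20, nNoise = 5, seed = 21)
    labels <- setNames(b$truth, rownames(b$expr))
    E <- computeModuleEigengenes(b$expr, labels)
    ## plant a gene equal to the eigengene and genes tied to the trait
    trait <- rnorm(ncol(b$expr))
    expr2 <- rbind(b$expr, me = E[, 1], tr = trait, ntr = -trait)
    labels2 <- setNames(c(b$truth, 1L, 1L, 1L), rownames(expr2))
    st <- geneModuleStats(expr2, E, labels2, trait)
    expect_equal(st$MM[st$gene == "me"], 1, tolerance = 1e-9)
    expect_equal(st$GS[st$gene == "tr"], 1, tolerance = 1e-9)
    expect_equal(st$GS[st$gene == "ntr"], 1, tolerance = 1e-9)
    expect_true(all(is.na(st$MM[st$module == 0])))
    expect_true(all(st$GS >= 0 & st$GS <= 1 + 1e-12))
})

test_that("hub screening applies both thresholds and sorts by GS", {
    tab <- ldmHubCandidates()
    hubs <- screenHubGenes(tab)
    expect_equal(nrow(hubs), 12L)
    expect_equal(hubs$gene[1], "ADIPOQ")
    expect_equal(hubs$GS, sort(tab$GS, decreasing = TRUE))
    ## boundary behaviour
    extra <- rbind(tab,
                   data.frame(gene_stable_id = "X1", gene = "LOWMM",
                              MM = 0.5, GS = 0.9, module = 1L),
                   data.frame(gene_stable_id = "X2", gene = "LOWGS",
                              MM = 0.95, GS = 0.1, module = 1L))
    hubs2 <- screenHubGenes(extra)
    expect_false(any(c("LOWMM", "LOWGS") %in% hubs2$gene))
    ## negative MM passes on absolute value
    neg <- within(tab, MM <- -MM)
    expect_equal(nrow(screenHubGenes(neg)), 12L)
})
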