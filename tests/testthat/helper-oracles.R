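# Independent reference implementations used as oracles. They deliberately
# share no code with the package: the color transition is looked up in the
# written-out 4x4 matrix (the package XORs 2-bit base codes), and mapping is
# a vectorised full scan over every reference position.

oracleColorMatrix <- matrix(
    c(0, 1, 2, 3,
      1, 0, 3, 2,
      2, 3, 0, 1,
      3, 2, 1, 0), 4, 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))

oracleEncode <- function(seq, primer) {
    ch <- c(primer, strsplit(seq, "")[[1]])
    paste(vapply(seq_len(length(ch) - 1L), function(i)
        as.character(oracleColorMatrix[ch[i], ch[i + 1L]]), ""),
        collapse = "")
}

# Transition colors of a reference string; NA where a non-ACGT base touches.
oracleRefColors <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    ok <- ch %in% rownames(oracleColorMatrix)
    n <- length(ch) - 1L
    out <- rep(NA_integer_, n)
    both <- ok[-length(ok)] & ok[-1L]
    out[both] <- oracleColorMatrix[cbind(ch[-length(ch)][both],
                                         ch[-1L][both])]
    out
}

# Full-scan color-space mapper over a concatenated (60-N spacer) genome.
# Returns global 1-based positions; informative colors = colors[-1].
oracleMapRead <- function(colors, genomeSeqs, maxMM = 2L, spacer = 60L) {
    refseq <- paste0(paste0(genomeSeqs, strrep("N", spacer)),
                     collapse = "")
    refc <- oracleRefColors(refseq)
    q <- as.integer(strsplit(colors, "")[[1]])[-1L]
    m <- length(q)
    np <- length(refc) - m + 1L
    if (np < 1L) return(data.frame(gpos = integer(), strand = character(),
                                   mm = integer()))
    mmF <- integer(np); mmR <- integer(np)
    qr <- rev(q)
    for (i in seq_len(m)) {
        w <- refc[i:(i + np - 1L)]
        mmF <- mmF + ifelse(is.na(w), 1L, as.integer(w != q[i]))
        mmR <- mmR + ifelse(is.na(w), 1L, as.integer(w != qr[i]))
    }
    pf <- which(mmF <= maxMM); pr <- which(mmR <= maxMM)
    rbind(data.frame(gpos = pf, strand = rep("+", length(pf)),
                     mm = mmF[pf]),
          data.frame(gpos = pr, strand = rep("-", length(pr)),
                     mm = mmR[pr]))
}

# Pairwise same-strand overlap check by plain arithmetic (no IRanges).
oracleAnyOverlap <- function(scaffold, strand, start, end) {
    for (i in seq_along(start)) {
        j <- which(scaffold == scaffold[i] & strand == strand[i] &
                   seq_along(start) > i)
        if (any(start[j] <= end[i] & end[j] >= start[i])) return(TRUE)
    }
    FALSE
}

# Step-up BH by the textbook definition.
oracleBH <- function(p, q = 0.05) {
    m <- length(p)
    o <- order(p)
    thresh <- seq_len(m) / m * q
    passing <- which(p[o] <= thresh)
    reject <- logical(m)
    if (length(passing)) reject[o[seq_len(max(passing))]] <- TRUE
    reject
}

# Random color read of given length (primer transition included).
randomColors <- function(len) {
    paste(sample(0:3, len, replace = TRUE), collapse = "")
}

# Flip `k` colors of a read at distinct positions among the informative
# colors (positions 2..len), returning the mutated color string.
flipColors <- function(colors, k) {
    ch <- strsplit(colors, "")[[1]]
    pos <- sample(seq(2L, length(ch)), k)
    for (p in pos)
        ch[p] <- as.character((as.integer(ch[p]) +
                               sample(1:3, 1)) %% 4L)
    paste(ch, collapse = "")
}

# Small deterministic toy dataset shared across tests.
toyFixture <- function(nGenes = 12L, seed = 421L, depth = 1.5e4, ...) {
    toy <- makeToyGenome(nGenes = nGenes, nScaffolds = 2L, seed = seed)
    truth <- assignExpressionProfiles(toy$genes, seed = seed + 1L, ...)
    sim <- simulateTags(toy$genome, toy$genes, truth,
                        libraryParams(depth = depth), sample = 1L,
                        seed = seed + 2L)
    ref <- concatenateReference(toy$genome)
    list(toy = toy, truth = truth, sim = sim, ref = ref)
}
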