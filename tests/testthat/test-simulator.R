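test_that("seeded generation is byte-reproducible", {
    a <- makeToyGenome(nGenes = 20, nScaffolds = 2, seed = 1)
    b <- makeToyGenome(nGenes = 20, nScaffolds = 2, seed = 1)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$genes, b$genes)

    ta <- assignExpressionProfiles(a$genes, seed = 2)
    tb <- assignExpressionProfiles(b$genes, seed = 2)
    expect_identical(trueTpm(ta), trueTpm(tb))

    sa <- simulateTags(a$genome, a$genes, ta, libraryParams(depth = 5e3,
                       colorErrorRate = 0.02), seed = 3)
    sb <- simulateTags(b$genome, b$genes, tb, libraryParams(depth = 5e3,
                       colorErrorRate = 0.02), seed = 3)
    expect_identical(sa$reads, sb$reads)
    expect_identical(sa$truthHits, sb$truthHits)
})

test_that("forced gaps are printed exactly", {
    toy <- makeToyGenome(nGenes = 2, nScaffolds = 1, fixedGap = 8000L,
                         seed = 7)
    g <- GenomicRanges::sort(toy$genes, ignore.strand = TRUE)
    expect_equal(GenomicRanges::start(g)[2] - GenomicRanges::end(g)[1] - 1L,
                 8000L)

    toy2 <- makeToyGenome(nGenes = 2, nScaffolds = 1, fixedGap = 1500L,
                          seed = 7)
    g2 <- GenomicRanges::sort(toy2$genes, ignore.strand = TRUE)
    expect_equal(GenomicRanges::start(g2)[2] -
                 GenomicRanges::end(g2)[1] - 1L, 1500L)
})

test_that("scaffolds are at least 10 kb and hold only A/C/G/T", {
    toy <- makeToyGenome(nGenes = 4, nScaffolds = 2, seed = 9)
    expect_true(all(Biostrings::width(toy$genome) >= 10000L))
    freq <- Biostrings::alphabetFrequency(toy$genome)
    expect_equal(sum(freq[, c("A", "C", "G", "T")]),
                 sum(Biostrings::width(toy$genome)))
})

test_that("genes that cannot fit on a fixed-length scaffold are an error", {
    expect_error(makeToyGenome(nGenes = 10, nScaffolds = 1,
                               scaffoldLength = 5000L, seed = 1),
                 "do not fit")
})

test_that("expression truth satisfies its invariants", {
    ids <- sprintf("g%03d", 1:300)
    tr <- assignExpressionProfiles(ids, nPatterns = 3, fractionNull = 0.7,
                                   seed = 13)
    tpm <- trueTpm(tr)
    expect_true(all(abs(colSums(tpm) - 1e6) < 1e-3))
    expect_true(all(tpm >= 0))
    expect_setequal(setdiff(unique(patternLabels(tr)), "null"),
                    c("P1", "P2", "P3"))
    # null genes are genuinely flat across time
    nul <- patternLabels(tr) == "null"
    expect_true(all(abs(tpm[nul, ] - tpm[nul, 1]) < 1e-9))
    # pattern genes change substantially
    fold <- apply(tpm[!nul, ], 1, max) / apply(tpm[!nul, ], 1, min)
    expect_true(all(fold > 1.5))

    allNull <- assignExpressionProfiles(ids, fractionNull = 1, seed = 14)
    expect_true(all(patternLabels(allNull) == "null"))
    tpn <- trueTpm(allNull)
    expect_true(all(abs(tpn - tpn[, 1]) < 1e-9))
})

test_that("EcoP15I digestion yields 25 bp tags with 2-nt overhangs", {
    insert <- "ACGTACGTACGTACGTACGTACGTA"   # 25 bp
    s <- paste0("GG", "CAGCAG", insert, "TT", "GGGG")
    d <- digestEcoP15I(s)
    expect_equal(nrow(d), 1L)
    expect_equal(d$tag, insert)
    expect_equal(nchar(d$tag), 25L)
    expect_equal(d$overhang, "TT")
    expect_equal(nchar(d$overhang), 2L)
    expect_equal(d$orientation, "+")
    expect_equal(d$site_pos, 3L)

    # reverse site: tag taken 3' of the site in site orientation
    rs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    dr <- digestEcoP15I(rs)
    expect_equal(dr$orientation, "-")
    expect_equal(dr$tag, insert)
    expect_equal(dr$overhang, "TT")

    expect_equal(nrow(digestEcoP15I("ACGTACGTACGT")), 0L)
    expect_warning(d3 <- digestEcoP15I(paste0("CAGCAG", "ACGTACGTACGTACG")),
                   "dropped")
    expect_equal(nrow(d3), 0L)
})

test_that("tag counts are Poisson at the configured depth", {
    fx <- toyFixture(nGenes = 20, depth = 5e4, seed = 101)
    lambda <- 5e4 * trueTpm(fx$truth)[, 1] / 1e6
    z <- (fx$sim$trueCounts - lambda) / sqrt(pmax(lambda, 1))
    expect_true(mean(abs(z) <= 4) >= 0.99)
    expect_equal(sum(lambda), 5e4, tolerance = 1e-6)
})

test_that("a pure TSS peak puts every tag of a gene on one position", {
    fx <- toyFixture(nGenes = 8, depth = 5e3, seed = 111,
                     tssPeakWeight = 1)
    th <- fx$sim$truthHits
    perGene <- tapply(th$pos, th$gene_id, function(p)
        length(unique(p)))
    expect_true(all(perGene == 1L))
})

test_that("error-free reads map back uniquely to their recorded origin", {
    fx <- toyFixture(nGenes = 10, depth = 5e3, seed = 121)
    hits <- mapColorReads(fx$sim$reads, fx$ref)
    expect_equal(nrow(hits), nrow(fx$sim$reads))  # all unique, all mapped
    m <- merge(fx$sim$truthHits, hits, by = "read_id")
    expect_true(all(m$pos.x == m$pos.y & m$strand.x == m$strand.y &
                    m$scaffold.x == m$scaffold.y))
})

test_that("reads are antisense to their transcript unless disabled", {
    fx <- toyFixture(nGenes = 8, depth = 4e3, seed = 131)
    gstrand <- setNames(as.character(GenomicRanges::strand(fx$toy$genes)),
                        S4Vectors::mcols(fx$toy$genes)$gene_id)
    th <- fx$sim$truthHits
    expect_true(all(th$strand != gstrand[th$gene_id]))

    sense <- simulateTags(fx$toy$genome, fx$toy$genes, fx$truth,
                          libraryParams(depth = 4e3, antisense = FALSE),
                          seed = 131)
    expect_true(all(sense$truthHits$strand ==
                    gstrand[sense$truthHits$gene_id]))
})

test_that("homopolymer fixture reads are caught by the low-info filter", {
    fx <- toyFixture(nGenes = 8, depth = 2e3, seed = 141)
    sim <- simulateTags(fx$toy$genome, fx$toy$genes, fx$truth,
                        libraryParams(depth = 2e3, homopolymerReads = 25L),
                        seed = 142)
    res <- filterLowInformation(sim$reads)
    expect_equal(res$report$n_removed, 25L)
    expect_true(all(grepl("lowinfo", res$removed$id)))
})

test_that("color errors hit the configured fraction of colors", {
    fx <- toyFixture(nGenes = 8, depth = 8e3, seed = 151)
    noisy <- simulateTags(fx$toy$genome, fx$toy$genes, fx$truth,
                          libraryParams(depth = 8e3,
                                        colorErrorRate = 0.05),
                          seed = 151)
    clean <- simulateTags(fx$toy$genome, fx$toy$genes, fx$truth,
                          libraryParams(depth = 8e3), seed = 151)
    a <- do.call(rbind, strsplit(noisy$reads$colors, ""))
    b <- do.call(rbind, strsplit(clean$reads$colors, ""))
    expect_equal(mean(a != b), 0.05, tolerance = 0.1)
})
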