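tinyRef <- function(len = 400L, seed = 81L) {
    withr::with_seed(seed, {
        concatenateReference(Biostrings::DNAStringSet(
            c(chr = paste(sample(c("A", "C", "G", "T"), len,
                                 replace = TRUE), collapse = ""))))
    })
}

hitRow <- function(read, gpos, strand, mm)
    data.frame(read = read, gpos = gpos, strand = strand, mm = mm)

test_that("fractional accumulation implements the 1/n best-hit rule", {
    ref <- tinyRef()
    hits <- rbind(
        hitRow(1L, 50L, "-", 0L),                    # unique -> +1.0
        hitRow(2L, 80L, "-", 1L), hitRow(2L, 120L, "-", 1L),  # tie -> 0.5
        hitRow(3L, 200L, "-", 0L), hitRow(3L, 240L, "-", 1L),
        hitRow(3L, 260L, "-", 1L))   # least-mismatch location wins alone
    ta <- accumulateTags(hits, ref, positionMode = "start")
    minus <- strandTrack(ta, "-")
    expect_equal(minus[50], 1.0)
    expect_equal(minus[80], 0.5)
    expect_equal(minus[120], 0.5)
    expect_equal(minus[200], 1.0)
    expect_equal(minus[240], 0)
    expect_equal(minus[260], 0)
    expect_equal(totalMapped(ta), 3)

    # cross-strand ties share the split: strands are different positions
    ta2 <- accumulateTags(rbind(hitRow(1L, 90L, "+", 1L),
                                hitRow(1L, 90L, "-", 1L)),
                          ref, positionMode = "start")
    expect_equal(strandTrack(ta2, "+")[90], 0.5)
    expect_equal(strandTrack(ta2, "-")[90], 0.5)
})

test_that("unique-only mode discards multi-hit reads entirely", {
    ref <- tinyRef()
    hits <- rbind(hitRow(1L, 50L, "-", 0L),
                  hitRow(2L, 80L, "-", 1L), hitRow(2L, 120L, "-", 1L))
    ta <- accumulateTags(hits, ref, mode = "unique",
                         positionMode = "start")
    expect_equal(totalMapped(ta), 1)
    expect_equal(ta@stats$n_discarded, 1L)
})

test_that("the tss position convention records the transcript 5'-most base", {
    ref <- tinyRef()
    # plus-strand mapped tag: transcript runs minus; 5'-most base = right end
    ta <- accumulateTags(hitRow(1L, 100L, "+", 0L), ref, tagLength = 25L)
    expect_equal(strandTrack(ta, "+")[124], 1.0)
    # minus-strand mapped tag: transcript runs plus; 5'-most base = left end
    ta2 <- accumulateTags(hitRow(1L, 100L, "-", 0L), ref, tagLength = 25L)
    expect_equal(strandTrack(ta2, "-")[100], 1.0)
})

test_that("mass is conserved and abutting regions partition their total", {
    fx <- toyFixture()
    hits <- mapColorReads(fx$sim$reads, fx$ref)
    ta <- accumulateTags(hits, fx$ref)
    expect_equal(totalMapped(ta), length(unique(hits$read)),
                 tolerance = 1e-9)

    reg <- GenomicRanges::GRanges("scaffold_1",
                                  IRanges::IRanges(c(1L, 2001L),
                                                   c(2000L, 5000L)),
                                  strand = "+")
    whole <- GenomicRanges::GRanges("scaffold_1",
                                    IRanges::IRanges(1L, 5000L),
                                    strand = "+")
    expect_equal(sum(countRegions(ta, reg, "both")),
                 countRegions(ta, whole, "both"))
})

test_that("antisense counting recovers the truth; sense returns nothing", {
    fx <- toyFixture()
    hits <- mapColorReads(fx$sim$reads, fx$ref)
    ta <- accumulateTags(hits, fx$ref)
    reg <- extendGeneModels(fx$toy$genes)
    anti <- countRegions(ta, reg, "antisense")
    sens <- countRegions(ta, reg, "sense")
    truth <- fx$sim$trueCounts[names(anti)]
    expect_equal(unname(anti), unname(truth))
    # sense counting finds nothing for genes whose region does not overlap
    # an opposite-strand neighbor's region (overlap lets a region see the
    # neighbor's antisense tags on its own strand)
    isPlus <- as.character(GenomicRanges::strand(reg)) == "+"
    clean <- logical(length(reg))
    clean[isPlus] <- !IRanges::overlapsAny(reg[isPlus], reg[!isPlus],
                                           ignore.strand = TRUE)
    clean[!isPlus] <- !IRanges::overlapsAny(reg[!isPlus], reg[isPlus],
                                            ignore.strand = TRUE)
    expect_true(any(clean))
    expect_equal(sum(sens[clean]), 0)
})

test_that("TPM follows count / total x 1e6 and sums to 1e6 per sample", {
    expect_equal(computeTpm(50, 1e6), 50)
    expect_equal(computeTpm(0, 1e6), 0)
    expect_error(computeTpm(5, 0), "totalMapped")
    fx <- toyFixture()
    ta <- accumulateTags(mapColorReads(fx$sim$reads, fx$ref), fx$ref)
    track <- strandTrack(ta, "+") + strandTrack(ta, "-")
    expect_equal(sum(computeTpm(track, totalMapped(ta))), 1e6,
                 tolerance = 1e-3)
})

test_that("binned tracks conserve totals and locate the TSS peak", {
    ref <- tinyRef()
    plus <- numeric(460); plus[101:200] <- 1.0
    ta <- new("TagArray", plus = plus, minus = numeric(460),
              reference = ref, totalMapped = 100, stats = list())
    region <- GenomicRanges::GRanges("chr", IRanges::IRanges(101L, 200L),
                                     strand = "-")
    b <- binnedTrack(ta, region, 10L)   # gene on -, antisense -> + track
    expect_equal(b$count, rep(10, 10))
    expect_equal(sum(b$count), countRegions(ta, region, "antisense")[[1]])

    # a 5'-peak simulation puts the argmax bin at the annotated TSS
    fx <- toyFixture(tssPeakWeight = 0.9)
    ta2 <- accumulateTags(mapColorReads(fx$sim$reads, fx$ref), fx$ref)
    g <- fx$toy$genes[which.max(fx$sim$trueCounts)]
    tss <- if (as.character(GenomicRanges::strand(g)) == "+")
        GenomicRanges::start(g) else GenomicRanges::end(g)
    reg <- GenomicRanges::resize(GenomicRanges::granges(g),
                                 GenomicRanges::width(g) + 200L,
                                 fix = "center")
    b2 <- binnedTrack(ta2, reg, 25L)
    peak <- b2[which.max(b2$count), ]
    expect_true(peak$start <= tss && tss <= peak$end)
})

test_that("bedGraph output reproduces the accumulated totals", {
    fx <- toyFixture()
    ta <- accumulateTags(mapColorReads(fx$sim$reads, fx$ref), fx$ref)
    path <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraph(ta, path, strand = "-")
    ln <- readLines(path)
    expect_match(ln[1], "0-based")
    tab <- read.table(text = ln[-(1:2)], sep = "\t")
    expect_equal(sum((tab$V3 - tab$V2) * tab$V4),
                 sum(strandTrack(ta, "-")), tolerance = 1e-9)
})
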