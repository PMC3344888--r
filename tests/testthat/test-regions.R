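grFromTable <- function(tab, lens) {
    g <- GenomicRanges::GRanges(tab$scaffold,
                                IRanges::IRanges(tab$start, tab$end),
                                strand = tab$strand,
                                seqlengths = lens)
    S4Vectors::mcols(g)$gene_id <- tab$id
    g
}

test_that("GFF3 gene models round-trip through write and parse", {
    toy <- makeToyGenome(nGenes = 15, nScaffolds = 2, seed = 61)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeToyGenome(toy$genome, toy$genes, gffPath = gff)
    gm <- readGeneModels(gff)
    orig <- GenomicRanges::sort(toy$genes, ignore.strand = TRUE)
    expect_equal(length(gm), length(orig))
    expect_identical(S4Vectors::mcols(gm)$gene_id,
                     S4Vectors::mcols(orig)$gene_id)
    expect_identical(GenomicRanges::start(gm), GenomicRanges::start(orig))
    expect_identical(GenomicRanges::end(gm), GenomicRanges::end(orig))
    expect_identical(as.character(GenomicRanges::strand(gm)),
                     as.character(GenomicRanges::strand(orig)))
    expect_identical(unname(lapply(S4Vectors::mcols(gm)$exons, identity)),
                     unname(lapply(S4Vectors::mcols(orig)$exons,
                                   identity)))
})

test_that("GFF3 parsing keeps 1-based inclusive coordinates", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA"), gff)
    gm <- readGeneModels(gff)
    expect_equal(GenomicRanges::start(gm), 101L)  # 0-based start would be 100
    expect_equal(GenomicRanges::end(gm), 200L)
    expect_equal(GenomicRanges::width(gm), 100L)
})

test_that("malformed GFF3 is reported with line numbers", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA",
                 "chr1\tsrc\tgene\t300\t250\t.\t+\t.\tID=gB"), gff)
    expect_error(readGeneModels(gff), "line\\(s\\): 3")

    writeLines(c("##gff-version 3", "chr1\tgene only"), gff)
    expect_error(readGeneModels(gff), "fields\\): 2")

    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA",
                 "chr1\tsrc\tgene\t301\t400\t.\t+\t.\tID=gA"), gff)
    expect_error(readGeneModels(gff), "duplicate gene_id")

    writeLines("##gff-version 3", gff)
    expect_equal(length(readGeneModels(gff)), 0L)
})

test_that("an isolated gene is extended 2 kb at the 5' end and 1 kb at the 3'", {
    lens <- c(chr = 50000L)
    g <- grFromTable(data.frame(scaffold = "chr", id = c("plus", "minus"),
                                start = c(10001L, 30001L),
                                end = c(12000L, 32000L),
                                strand = c("+", "-")), lens)
    r <- extendGeneModels(g)
    expect_equal(GenomicRanges::start(r), c(10001L - 2000L, 30001L - 1000L))
    expect_equal(GenomicRanges::end(r), c(12000L + 1000L, 32000L + 2000L))
    expect_equal(S4Vectors::mcols(r)$five_ext, c(2000L, 2000L))
    expect_equal(S4Vectors::mcols(r)$three_ext, c(1000L, 1000L))
})

test_that("a short same-strand gap is split 1:2 into abutting regions", {
    lens <- c(chr = 50000L)
    g <- grFromTable(data.frame(scaffold = "chr", id = c("up", "down"),
                                start = c(10000L, 13500L),
                                end = c(11999L, 15000L),
                                strand = "+"), lens)   # gap = 1500
    r <- extendGeneModels(g)
    expect_equal(S4Vectors::mcols(r)$three_ext[1], 500L)   # floor(1500/3)
    expect_equal(S4Vectors::mcols(r)$five_ext[2], 1000L)
    expect_equal(GenomicRanges::end(r)[1] + 1L, GenomicRanges::start(r)[2])

    # minus strand mirror: 5' faces left gene's right side
    GenomicRanges::strand(g) <- "-"
    r2 <- extendGeneModels(g)
    expect_equal(S4Vectors::mcols(r2)$five_ext[1], 1000L)
    expect_equal(S4Vectors::mcols(r2)$three_ext[2], 500L)
    expect_equal(GenomicRanges::end(r2)[1] + 1L, GenomicRanges::start(r2)[2])
})

test_that("the split rule is continuous at the 3 kb threshold", {
    lens <- c(chr = 60000L)
    mk <- function(gap) grFromTable(
        data.frame(scaffold = "chr", id = c("a", "b"),
                   start = c(10000L, 12000L + gap),
                   end = c(11999L, 14000L + gap), strand = "+"), lens)
    at <- extendGeneModels(mk(3000L))    # split branch: 1000 + 2000
    above <- extendGeneModels(mk(3001L)) # full-cap branch
    expect_equal(S4Vectors::mcols(at)$three_ext[1], 1000L)
    expect_equal(S4Vectors::mcols(at)$five_ext[2], 2000L)
    expect_equal(S4Vectors::mcols(above)$three_ext[1], 1000L)
    expect_equal(S4Vectors::mcols(above)$five_ext[2], 2000L)
})

test_that("extensions are clipped at scaffold boundaries", {
    lens <- c(chr = 20000L)
    g <- grFromTable(data.frame(scaffold = "chr", id = "edge",
                                start = 501L, end = 900L, strand = "-"),
                     lens)
    r <- extendGeneModels(g)
    expect_equal(GenomicRanges::start(r), 1L)
    expect_equal(S4Vectors::mcols(r)$three_ext, 500L)
    expect_true(S4Vectors::mcols(r)$three_clipped)
    expect_false(S4Vectors::mcols(r)$five_clipped)
})

test_that("overlapping same-strand input genes are rejected by name", {
    lens <- c(chr = 20000L)
    g <- grFromTable(data.frame(scaffold = "chr", id = c("gX", "gY"),
                                start = c(1000L, 1500L),
                                end = c(2000L, 2500L), strand = "+"),
                     lens)
    expect_error(extendGeneModels(g), "gX.*gY")
})

test_that("randomized annotations never produce same-strand overlaps", {
    withr::with_seed(71, {
        for (rep in 1:30) {
            n <- sample(3:12, 1)
            start <- sort(sample(seq(1000L, 80000L, by = 50L), n))
            width <- sample(300:2500, n, replace = TRUE)
            end <- pmin(start + width, c(start[-1] - 1L, 100000L))
            keep <- end - start > 50L
            tab <- data.frame(scaffold = "chr", id = paste0("g", 1:n),
                              start = start, end = end,
                              strand = sample(c("+", "-"), n,
                                              replace = TRUE))[keep, ]
            g <- grFromTable(tab, c(chr = 100000L))
            r <- extendGeneModels(g)
            expect_false(oracleAnyOverlap(
                as.character(GenomicRanges::seqnames(r)),
                as.character(GenomicRanges::strand(r)),
                GenomicRanges::start(r), GenomicRanges::end(r)))
            # every region contains its gene; caps respected
            expect_true(all(GenomicRanges::start(r) <= tab$start &
                            GenomicRanges::end(r) >= tab$end))
            expect_true(all(S4Vectors::mcols(r)$five_ext <= 2000L))
            expect_true(all(S4Vectors::mcols(r)$three_ext <= 1000L))
            expect_true(all(GenomicRanges::width(r) >=
                            GenomicRanges::width(g)))
        }
    })
})
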