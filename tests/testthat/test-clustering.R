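separatedProfiles <- function(nPerGroup = 12L, nGroups = 9L, sd = 0.05,
                              seed = 261L, nDim = 6L) {
    # group centers laid out on a 3x3 grid in two profile dimensions, so a
    # 3x3 topology can in principle represent every group by one node
    withr::with_seed(seed, {
        gx <- ((seq_len(nGroups) - 1L) %% 3L) * 5
        gy <- ((seq_len(nGroups) - 1L) %/% 3L) * 5
        prof <- do.call(rbind, lapply(seq_len(nGroups), function(k) {
            center <- c(gx[k], gy[k], rep(0, nDim - 2L))
            matrix(rnorm(nPerGroup * nDim, center, sd),
                   nPerGroup, nDim, byrow = TRUE)
        }))
        rownames(prof) <- sprintf("gene%03d", seq_len(nrow(prof)))
        list(profiles = prof,
             labels = rep(seq_len(nGroups), each = nPerGroup))
    })
}

test_that("well-separated groups occupy distinct SOM nodes", {
    fx <- separatedProfiles()
    som <- somCluster(fx$profiles, seed = 5)
    asg <- somAssignment(som)
    expect_equal(length(asg), nrow(fx$profiles))
    # each input group lands on exactly one node, and no two share a node
    nodesPerGroup <- tapply(asg, fx$labels, function(x)
        length(unique(x)))
    expect_true(all(nodesPerGroup == 1L))
    expect_equal(length(unique(asg)), 9L)
    expect_equal(adjustedRand(asg, fx$labels), 1)
})

test_that("SOM training is deterministic given the seed", {
    fx <- separatedProfiles(sd = 0.5)
    a <- somCluster(fx$profiles, seed = 42)
    b <- somCluster(fx$profiles, seed = 42)
    expect_identical(somCodebook(a), somCodebook(b))
    expect_identical(somAssignment(a), somAssignment(b))
    r <- somCluster(fx$profiles, seed = 42, init = "random")
    expect_identical(somAssignment(r),
                     somAssignment(somCluster(fx$profiles, seed = 42,
                                              init = "random")))
})

test_that("degenerate constant input collapses onto one node with a warning", {
    prof <- matrix(1, 20, 4, dimnames = list(paste0("g", 1:20), NULL))
    expect_warning(som <- somCluster(prof, seed = 1), "identical")
    expect_equal(length(unique(somAssignment(som))), 1L)
})

test_that("assignments partition the input and reports aggregate them", {
    fx <- separatedProfiles(nPerGroup = 3L, sd = 0.3)
    som <- somCluster(fx$profiles, seed = 9)
    rep <- clusterReport(som, fx$profiles)
    expect_equal(sum(rep$summary$n), nrow(fx$profiles))
    expect_setequal(unlist(rep$members), rownames(fx$profiles))
    k <- which(rep$summary$n == 1L)
    if (length(k)) {
        g <- rep$members[[k[1]]]
        expect_equal(rep$centroids[k[1], ], fx$profiles[g, ],
                     ignore_attr = TRUE)
    }
    occupied <- which(rep$summary$n > 1L)[1]
    expect_equal(rep$centroids[occupied, ],
                 colMeans(fx$profiles[rep$members[[occupied]], ,
                                      drop = FALSE]),
                 ignore_attr = TRUE)
})

test_that("adjusted Rand agrees with the mclust implementation", {
    withr::with_seed(271, {
        for (i in 1:5) {
            a <- sample(1:4, 60, replace = TRUE)
            b <- sample(1:3, 60, replace = TRUE)
            expect_equal(adjustedRand(a, b),
                         mclust::adjustedRandIndex(a, b),
                         ignore_attr = TRUE)
        }
        expect_equal(adjustedRand(1:10, 1:10), 1)
    })
})

test_that("planted temporal patterns are recovered by the SOM", {
    aris <- vapply(1:3, function(s) {
        ids <- sprintf("g%04d", 1:800)
        truth <- assignExpressionProfiles(ids, fractionNull = 0.7,
                                          effectSize = 4,
                                          seed = 300 + s)
        se <- simulateCountMatrix(truth, depth = 5e6, nReplicates = 3,
                                  seed = 400 + s)
        de <- suppressMessages(runDifferentialExpression(se))
        sig <- de$table$gene_id[de$table$significant]
        prof <- replicateMeanProfiles(
            de$logNormalized[sig, , drop = FALSE],
            SummarizedExperiment::colData(se)$timepoint)
        som <- somCluster(prof, seed = s)
        adjustedRand(somAssignment(som),
                     patternLabels(truth)[match(sig, ids)])
    }, numeric(1))
    expect_gte(median(aris), 0.8)
})

test_that("Spearman average-linkage trees order items as constructed", {
    prof <- rbind(A = c(1, 2, 3, 4, 5),
                  B = c(2, 4, 6, 8, 10),     # rho(A, B) = 1
                  C = c(3, 1, 4, 1, 5))      # scrambled
    hc <- buildProfileTree(prof, axis = "genes")
    # A and B merge first at height 0; C joins last
    expect_equal(hc$merge[1, ], c(-1, -2))
    expect_equal(hc$height[1], 0)
    expect_equal(hc$merge[2, ], c(-3, 1))

    # anti-correlated profiles sit at the maximal distance 2
    prof2 <- rbind(A = c(1, 2, 3, 4, 5), B = c(5, 4, 3, 2, 1),
                   C = c(1, 3, 2, 5, 4))
    hc2 <- buildProfileTree(prof2, axis = "genes")
    expect_equal(max(hc2$height), mean(c(2, 1 - cor(prof2["B", ],
        prof2["C", ], method = "spearman"))))

    expect_warning(buildProfileTree(rbind(prof, D = rep(1, 5))),
                   "constant")
})

test_that("condition trees pair adjacent time points of a smooth course", {
    ids <- sprintf("g%04d", 1:400)
    truth <- assignExpressionProfiles(ids, fractionNull = 0.5,
                                      effectSize = 6, seed = 281)
    se <- simulateCountMatrix(truth, depth = 2e6, nReplicates = 1,
                              seed = 282)
    tpm <- SummarizedExperiment::assays(se)$tpm
    hc <- buildProfileTree(log2(tpm + 1), axis = "conditions")
    cd <- cophenetic(hc)
    m <- as.matrix(cd)
    labs <- hc$labels
    # each time point is copheneticly closer to a neighbor than to the
    # far end of the course
    t1 <- which(labs == "t1_r1"); t6 <- which(labs == "t6_r1")
    t2 <- which(labs == "t2_r1")
    expect_lt(m[t1, t2], m[t1, t6])
})

test_that("trees export to Newick and read back with ape", {
    prof <- matrix(rnorm(40), 8, 5,
                   dimnames = list(paste0("g", 1:8), NULL))
    hc <- buildProfileTree(prof)
    path <- withr::local_tempfile(fileext = ".nwk")
    writeNewick(hc, path)
    tr <- ape::read.tree(path)
    expect_setequal(tr$tip.label, paste0("g", 1:8))
})
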