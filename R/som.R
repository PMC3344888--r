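#' @include diffexpr.R
NULL

#' Self-organizing-map clustering of expression profiles
#'
#' Trains a rectangular SOM (default 3 x 3) over per-gene time-course
#' profiles with the classic online algorithm: at each iteration one
#' profile is drawn at random, its best-matching unit (BMU, smallest
#' Euclidean distance) located, and every node codebook is pulled toward
#' the profile with a Gaussian neighborhood kernel centred on the BMU. The
#' learning rate decays linearly from \code{learningRate} to 0.01 and the
#' neighborhood radius from \code{max(shape)/2} to 0.5 over the
#' iterations. Codebooks are initialised deterministically on a grid
#' spanned by the first two principal components (random-profile
#' initialisation is available as a fallback), so results are fully
#' reproducible given the seed. The final assignment maps every gene to
#' its BMU; ties resolve to the lowest node index.
#'
#' @param profiles numeric genes x time points matrix (finite values;
#'   typically the replicate-averaged, median-normalized, log-transformed
#'   profiles of significant genes).
#' @param shape grid (rows, cols); default \code{c(3, 3)}.
#' @param nIterations online updates (default 2000).
#' @param learningRate initial learning rate (default 0.5).
#' @param radius initial neighborhood radius in grid units; default
#'   \code{max(shape)/2}.
#' @param radiusFinal final neighborhood radius (default 0.5).
#' @param seed random seed for the sampling schedule (and random init).
#' @param init \code{"pca"} (default, deterministic) or \code{"random"}.
#' @return a \linkS4class{SOMGrid}.
#' @export
somCluster <- function(profiles, shape = c(3L, 3L), nIterations = 2000L,
                       learningRate = 0.5, radius = NULL,
                       radiusFinal = 0.5, seed = 1L,
                       init = c("pca", "random")) {
    init <- match.arg(init)
    profiles <- as.matrix(profiles)
    if (anyNA(profiles) || any(!is.finite(profiles)))
        stop("profiles must be finite (no NA/NaN/Inf)")
    shape <- as.integer(shape)
    nNodes <- prod(shape)
    n <- nrow(profiles)
    if (n < nNodes)
        stop("need at least ", nNodes, " profiles for a ",
             paste(shape, collapse = "x"), " grid")
    if (is.null(radius)) radius <- max(shape) / 2
    gridRow <- (seq_len(nNodes) - 1L) %/% shape[2L] + 1L
    gridCol <- (seq_len(nNodes) - 1L) %% shape[2L] + 1L
    gridD2 <- outer(gridRow, gridRow, "-")^2 + outer(gridCol, gridCol, "-")^2

    degenerate <- all(apply(profiles, 2L, function(v) var(v) == 0))
    if (degenerate)
        warning("all profiles identical; every gene lands on one node")

    center <- colMeans(profiles)
    codebook <- withr::with_seed(seed, {
        cb <- if (init == "pca" && !degenerate) {
            pr <- prcomp(profiles, center = TRUE)
            u1 <- pr$rotation[, 1L] * pr$sdev[1L]
            u2 <- if (ncol(pr$rotation) >= 2L)
                pr$rotation[, 2L] * pr$sdev[2L] else 0 * u1
            xs <- if (shape[2L] > 1L)
                seq(-2, 2, length.out = shape[2L]) else 0
            ys <- if (shape[1L] > 1L)
                seq(-2, 2, length.out = shape[1L]) else 0
            t(vapply(seq_len(nNodes), function(k)
                center + xs[gridCol[k]] * u1 + ys[gridRow[k]] * u2,
                numeric(ncol(profiles))))
        } else {
            profiles[sample.int(n, nNodes), , drop = FALSE]
        }
        ord <- sample.int(n, nIterations, replace = TRUE)
        for (it in seq_len(nIterations)) {
            frac <- if (nIterations > 1L) (it - 1L) / (nIterations - 1L)
                    else 0
            lr <- learningRate * (1 - frac) + 0.01 * frac
            sg <- radius * (1 - frac) + radiusFinal * frac
            x <- profiles[ord[it], ]
            d2 <- rowSums(sweep(cb, 2L, x)^2)
            bmu <- which.min(d2)
            h <- exp(-gridD2[, bmu] / (2 * sg^2))
            cb <- cb + (lr * h) * (matrix(x, nNodes, ncol(cb),
                                          byrow = TRUE) - cb)
        }
        cb
    })
    d2 <- outer(rowSums(profiles^2), rowSums(codebook^2), "+") -
        2 * profiles %*% t(codebook)
    assignment <- as.integer(max.col(-d2, ties.method = "first"))
    names(assignment) <- rownames(profiles)
    new("SOMGrid", codebook = codebook, assignment = assignment,
        shape = shape,
        params = list(nIterations = nIterations,
                      learningRate = learningRate, radius = radius,
                      radiusFinal = radiusFinal, seed = seed, init = init))
}

#' @rdname SOMGrid-class
#' @export
setMethod("somAssignment", "SOMGrid", function(x)
    setNames(x@assignment, names(x@assignment)))

#' @rdname SOMGrid-class
#' @export
setMethod("somCodebook", "SOMGrid", function(x) x@codebook)

setMethod("show", "SOMGrid", function(object) {
    cat("SOMGrid", paste(object@shape, collapse = "x"), "with",
        length(object@assignment), "profiles assigned;",
        "occupied nodes:", length(unique(object@assignment)), "\n")
})

#' Per-cluster summary of a trained SOM
#'
#' For every grid node: the member count, mean member profile (the "green
#' line" drawn through a cluster) and the member gene ids.
#'
#' @param som a \linkS4class{SOMGrid}.
#' @param profiles the matrix the SOM was trained on.
#' @return list with \code{summary} (data.frame: node, row, col, n),
#'   \code{centroids} (node x time point matrix of mean member profiles,
#'   NA for empty nodes) and \code{members} (list of gene-id vectors).
#' @export
clusterReport <- function(som, profiles) {
    nNodes <- prod(som@shape)
    asg <- somAssignment(som)
    stopifnot(length(asg) == nrow(profiles))
    centroids <- matrix(NA_real_, nNodes, ncol(profiles),
                        dimnames = list(NULL, colnames(profiles)))
    members <- vector("list", nNodes)
    for (k in seq_len(nNodes)) {
        sel <- asg == k
        members[[k]] <- rownames(profiles)[sel]
        if (any(sel))
            centroids[k, ] <- colMeans(profiles[sel, , drop = FALSE])
    }
    list(summary = data.frame(
             node = seq_len(nNodes),
             row = (seq_len(nNodes) - 1L) %/% som@shape[2L] + 1L,
             col = (seq_len(nNodes) - 1L) %% som@shape[2L] + 1L,
             n = vapply(members, length, integer(1))),
         centroids = centroids, members = members)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovery of planted temporal patterns by the SOM.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (scalar).
#' @export
adjustedRand <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    n <- length(a)
    sumnij <- sum(choose(tab, 2))
    sumai <- sum(choose(rowSums(tab), 2))
    sumbj <- sum(choose(colSums(tab), 2))
    expected <- sumai * sumbj / choose(n, 2)
    maxidx <- (sumai + sumbj) / 2
    if (maxidx == expected)   # degenerate: no chance-corrected spread
        return(as.numeric(sumnij == expected))
    (sumnij - expected) / (maxidx - expected)
}

#' Write SOM assignments as TSV
#'
#' @param som a \linkS4class{SOMGrid}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSomAssignments <- function(som, path) {
    asg <- somAssignment(som)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# fiveDGE SOM assignments (node row/col are 1-based)", con)
    write.table(data.frame(gene_id = names(asg), node = asg,
                           row = (asg - 1L) %/% som@shape[2L] + 1L,
                           col = (asg - 1L) %% som@shape[2L] + 1L),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
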