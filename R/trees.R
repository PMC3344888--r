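#' @include som.R
NULL

#' Spearman / average-linkage tree of genes or conditions
#'
#' Hierarchical clustering with dissimilarity 1 - Spearman rank
#' correlation and average-linkage agglomeration, for gene trees (rows) or
#' condition trees (columns). Items with zero variance have undefined rank
#' correlations and are dropped with a warning.
#'
#' @param mat numeric genes x samples (or genes x time points) matrix.
#' @param axis \code{"genes"} (cluster rows, default) or
#'   \code{"conditions"} (cluster columns).
#' @return an \code{hclust} object (labels = item names).
#' @export
buildProfileTree <- function(mat, axis = c("genes", "conditions")) {
    axis <- match.arg(axis)
    items <- if (axis == "genes") t(mat) else mat  # items in columns
    keep <- apply(items, 2L, function(v) var(v) > 0)
    if (any(!keep))
        warning(sum(!keep), " constant item(s) dropped (undefined rank ",
                "correlation): ",
                paste(colnames(items)[!keep], collapse = ", "))
    items <- items[, keep, drop = FALSE]
    if (ncol(items) < 2L) stop("need at least 2 items with variance")
    rho <- cor(items, method = "spearman")
    hclust(as.dist(1 - rho), method = "average")
}

#' Write a tree in Newick format
#'
#' @param hc an \code{hclust} object (e.g. from
#'   \code{\link{buildProfileTree}}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}
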