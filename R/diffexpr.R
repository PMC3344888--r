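#' @include qc.R
NULL

#' Per-gene median normalization
#'
#' Divides every gene's values by that gene's median across all samples, so
#' profiles describe relative change around 1 regardless of absolute
#' expression (scale-invariant: multiplying a gene by c > 0 leaves its
#' normalized profile unchanged). Genes whose median is zero carry no
#' usable profile and are excluded; their ids are attached as attribute
#' \code{"excluded"} and reported via a message.
#'
#' @param mat numeric genes x samples matrix (e.g. TPM).
#' @return normalized matrix (possibly fewer rows), with attribute
#'   \code{"excluded"}.
#' @export
normalizePerGene <- function(mat) {
    med <- apply(mat, 1L, median)
    drop <- med <= 0 | is.na(med)
    if (any(drop))
        message(sum(drop), " gene(s) with zero median excluded from ",
                "normalization")
    out <- mat[!drop, , drop = FALSE] / med[!drop]
    attr(out, "excluded") <- rownames(mat)[drop]
    out
}

#' Logarithmic conversion with a pseudo-value
#'
#' \code{log2(x + pseudo)}. The default pseudo-value of 0.01 on the
#' median-normalized scale keeps zeros finite two decades below the
#' per-gene median while leaving values near 1 essentially untouched.
#'
#' @param mat numeric matrix with non-negative entries.
#' @param pseudo pseudo-value added before the log (default 0.01).
#' @return log2-transformed matrix.
#' @export
logTransformMatrix <- function(mat, pseudo = 0.01) {
    if (any(mat < 0, na.rm = TRUE)) stop("negative values cannot be logged")
    log2(mat + pseudo)
}

.welchRow <- function(y, g) {
    if (all(y == y[1])) return(c(0, 1, 1))          # degenerate: constant
    res <- tryCatch(oneway.test(y ~ g, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res) || is.na(res$p.value))
        return(c(NA_real_, NA_real_, 1))            # zero-variance group
    c(unname(res$statistic), res$p.value, 0)
}

#' Welch heteroscedastic one-way ANOVA per gene
#'
#' Parametric one-way ANOVA not assuming equal variances across groups
#' (Welch's F with Welch-Satterthwaite degrees of freedom), applied to each
#' row. Rows that are entirely constant get F = 0, p = 1 and a degenerate
#' flag; rows where a zero-variance group makes the statistic undefined
#' get NA with the flag set.
#'
#' @param mat numeric genes x samples matrix (normalized, logged).
#' @param groups factor of group membership (time points), one per column;
#'   every group needs at least 2 values.
#' @return \code{DataFrame} with columns \code{F}, \code{p},
#'   \code{degenerate}.
#' @export
welchAnova <- function(mat, groups) {
    groups <- as.factor(groups)
    if (length(groups) != ncol(mat))
        stop("groups must have one entry per column")
    if (nlevels(droplevels(groups)) < 2L)
        stop("need at least 2 groups")
    if (any(table(groups) < 2L))
        stop("every group needs at least 2 replicates")
    res <- t(apply(mat, 1L, .welchRow, g = groups))
    DataFrame(F = res[, 1], p = res[, 2], degenerate = res[, 3] == 1,
              row.names = rownames(mat))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjusted q values with rejection flags at the given
#' FDR level.
#'
#' @param p numeric p values in [0, 1] (NA allowed).
#' @param fdr FDR level (default 0.05).
#' @return list with \code{q} (adjusted values) and \code{reject} (logical).
#' @export
bhFdr <- function(p, fdr = 0.05) {
    q <- p.adjust(p, method = "BH")
    list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Time-course differential expression
#'
#' The fixed pipeline for extracting genes whose tag abundance changes over
#' time: per-gene median normalization, logarithmic conversion, Welch
#' one-way ANOVA across time points, then Benjamini-Hochberg FDR at the
#' given level (in that order).
#'
#' @param x \code{SummarizedExperiment} with a \code{tpm} assay and a
#'   \code{timepoint} column in \code{colData}, or a TPM matrix (then
#'   \code{timepoints} is required).
#' @param timepoints factor of time points per sample (taken from
#'   \code{colData} when \code{x} is a \code{SummarizedExperiment}).
#' @param fdr FDR level (default 0.05).
#' @param pseudo pseudo-value for the log (default 0.01).
#' @return list with \code{table} (\code{DataFrame}: gene_id, F, p, q,
#'   significant, degenerate), \code{normalized} (median-normalized TPM),
#'   \code{logNormalized} and \code{excluded} (zero-median gene ids).
#' @export
runDifferentialExpression <- function(x, timepoints = NULL, fdr = 0.05,
                                      pseudo = 0.01) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(timepoints)) timepoints <- colData(x)$timepoint
        x <- assays(x)$tpm
    }
    if (is.null(timepoints))
        stop("timepoints are required for a plain matrix")
    norm <- normalizePerGene(x)
    lg <- logTransformMatrix(norm, pseudo)
    wa <- welchAnova(lg, timepoints)
    adj <- bhFdr(wa$p, fdr)
    tab <- DataFrame(gene_id = rownames(norm), F = wa$F, p = wa$p,
                     q = adj$q, significant = adj$reject,
                     degenerate = wa$degenerate)
    list(table = tab, normalized = norm, logNormalized = lg,
         excluded = attr(norm, "excluded"))
}

#' Average replicate columns per time point
#'
#' Collapses a genes x samples matrix to genes x time points by averaging
#' replicates — the per-gene profile plotted over the time course and fed
#' to the SOM.
#'
#' @param mat numeric genes x samples matrix.
#' @param timepoints factor of time points per column.
#' @return genes x time points matrix, columns in factor-level order.
#' @export
replicateMeanProfiles <- function(mat, timepoints) {
    timepoints <- as.factor(timepoints)
    lv <- levels(droplevels(timepoints))
    out <- vapply(lv, function(l)
        rowMeans(mat[, timepoints == l, drop = FALSE]),
        numeric(nrow(mat)))
    colnames(out) <- lv
    out
}
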