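#' @include trees.R
NULL

#' Default pipeline configuration
#'
#' All analysis constants of the 5'-DGE pipeline with their standard
#' values: up to 2 color mismatches in mapping, removal of reads with 3 or
#' fewer non-0 colors, 2 kb 5' / 1 kb 3' region extension with a 3 kb
#' same-strand gap threshold, antisense counting, 5 percent FDR and a 3x3
#' SOM grid.
#'
#' @return named list of defaults.
#' @export
dgeDefaults <- function() {
    list(maxMismatches = 2L, lowInfoThreshold = 3L, fiveExt = 2000L,
         threeExt = 1000L, gapThreshold = 3000L,
         strandConvention = "antisense", fdr = 0.05, pseudo = 0.01,
         somShape = c(3L, 3L), tagLength = 25L, spacerN = 60L,
         minTpm = 1, positionMode = "tss", skipFirstColor = TRUE,
         seedK = 8L, seed = 1L)
}

#' Resolve a run configuration
#'
#' Merges, in increasing precedence: package defaults, an optional YAML
#' config file, and explicit overrides (e.g. command-line flags).
#'
#' @param path optional YAML file of key-value settings.
#' @param overrides named list taking precedence over the file.
#' @return resolved configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- dgeDefaults()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        unknown <- setdiff(names(user), names(cfg))
        if (length(unknown))
            stop("unknown config key(s): ", paste(unknown, collapse = ", "))
        cfg[names(user)] <- user
    }
    cfg[names(overrides)] <- overrides
    cfg
}

.stageOrder <- c("filter", "map", "count", "qc", "de", "cluster")

#' Run the 5'-DGE analysis pipeline
#'
#' Orchestrates filter (low-information removal), map (color-space
#' alignment), count (fractional accumulation, region counting, TPM), qc
#' (mapping statistics, replicate correlations), de (median normalization,
#' Welch ANOVA, BH FDR) and cluster (SOM on significant genes, Spearman /
#' average-linkage trees). Stages can be re-run selectively by passing a
#' previous \code{state}: outputs already present in the state are reused
#' by stages that are not requested, making reruns resumable and
#' idempotent.
#'
#' @param genome \code{DNAStringSet}, or a FASTA path.
#' @param genes \code{GRanges} of gene models, or a GFF3 path.
#' @param reads named list (one entry per sample) of color-read
#'   data.frames or csfasta paths.
#' @param sampleSheet data.frame with columns \code{sample},
#'   \code{timepoint}, \code{replicate}.
#' @param config list from \code{\link{dgeDefaults}} /
#'   \code{\link{readRunConfig}}.
#' @param outdir optional output directory; when given, count tables, DE
#'   results, SOM assignments, trees, the resolved configuration and a
#'   JSON run manifest are written there.
#' @param stages which stages to execute (default: all, in order).
#' @param state a previous return value to resume from.
#' @return list (the pipeline state): \code{reference}, \code{regions},
#'   \code{filtered}, \code{hits}, \code{tagArrays}, \code{counts}
#'   (\code{SummarizedExperiment}), \code{qc}, \code{de}, \code{som},
#'   \code{trees}, \code{manifest}.
#' @export
runPipeline <- function(genome, genes, reads, sampleSheet,
                        config = dgeDefaults(), outdir = NULL,
                        stages = .stageOrder, state = list()) {
    stopifnot(all(stages %in% .stageOrder))
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    if (is.character(genes)) genes <- readGeneModels(genes)
    samples <- sampleSheet$sample
    stopifnot(!is.null(samples), all(samples %in% names(reads)))
    reads <- lapply(reads[samples], function(r)
        if (is.character(r)) readCsfasta(r) else r)

    state$reference <- concatenateReference(genome, config$spacerN)
    if (length(seqlengths(genes)) == 0L || anyNA(seqlengths(genes)))
        GenomeInfoDb::seqlengths(genes) <-
            scaffoldLengths(state$reference)[seqlevels(genes)]
    state$regions <- extendGeneModels(genes, config$fiveExt,
                                      config$threeExt, config$gapThreshold)
    state$genes <- genes

    if ("filter" %in% stages)
        state$filtered <- lapply(reads, filterLowInformation,
                                 threshold = config$lowInfoThreshold)
    .need(state, "filtered", "filter")

    if ("map" %in% stages)
        state$hits <- lapply(state$filtered, function(f)
            mapColorReads(f$kept, state$reference, config$maxMismatches,
                          config$skipFirstColor, config$seedK))
    .need(state, "hits", "map")

    if ("count" %in% stages) {
        state$tagArrays <- lapply(state$hits, accumulateTags,
                                  reference = state$reference,
                                  mode = "fractional",
                                  positionMode = config$positionMode,
                                  tagLength = config$tagLength)
        cd <- DataFrame(timepoint = factor(sampleSheet$timepoint),
                        replicate = sampleSheet$replicate,
                        row.names = samples)
        state$counts <- buildCountTable(state$tagArrays, state$regions,
                                        colData = cd,
                                        convention =
                                            config$strandConvention)
    }
    .need(state, "counts", "count")

    if ("qc" %in% stages) {
        st <- lapply(samples, function(s) {
            f <- state$filtered[[s]]
            mappingStats(nTotal = f$report$n_input,
                         nMapped = state$tagArrays[[s]]@stats$n_reads,
                         nLowInfo = f$report$n_removed,
                         nUnique = state$tagArrays[[s]]@stats$n_unique)
        })
        stats <- do.call(rbind, st)
        stats$sample <- samples
        reps <- split(samples, sampleSheet$timepoint)
        cors <- list()
        for (tp in names(reps)) {
            ss <- reps[[tp]]
            if (length(ss) < 2L) next
            prs <- utils::combn(ss, 2L)
            for (k in seq_len(ncol(prs)))
                cors[[length(cors) + 1L]] <- data.frame(
                    timepoint = tp, sample_a = prs[1L, k],
                    sample_b = prs[2L, k],
                    r2 = tryCatch(replicateCorrelation(
                        state$counts, prs[1L, k], prs[2L, k],
                        minTpm = config$minTpm),
                        error = function(e) NA_real_))
        }
        state$qc <- list(mappingStats = stats,
                         replicateR2 = if (length(cors))
                             do.call(rbind, cors) else NULL)
    }

    if ("de" %in% stages)
        state$de <- runDifferentialExpression(
            state$counts, fdr = config$fdr, pseudo = config$pseudo)
    if ("cluster" %in% stages) {
        .need(state, "de", "de")
        sig <- state$de$table$gene_id[state$de$table$significant]
        tps <- colData(state$counts)$timepoint
        prof <- replicateMeanProfiles(
            state$de$logNormalized[sig, , drop = FALSE], tps)
        state$som <- if (length(sig) >= prod(config$somShape))
            somCluster(prof, shape = config$somShape, seed = config$seed)
        else NULL
        state$trees <- list(
            conditions = buildProfileTree(
                assays(state$counts)$tpm[
                    rownames(state$de$logNormalized), , drop = FALSE],
                axis = "conditions"),
            genes = if (length(sig) >= 3L)
                buildProfileTree(prof, axis = "genes") else NULL)
    }

    state$manifest <- list(
        samples = samples,
        config = config,
        counters = if (!is.null(state$tagArrays))
            lapply(state$tagArrays, function(ta) ta@stats) else NULL,
        n_significant = if (!is.null(state$de))
            sum(state$de$table$significant) else NA)

    if (!is.null(outdir)) .writePipelineOutputs(state, outdir, config)
    state
}

.need <- function(state, field, stage) {
    if (is.null(state[[field]]))
        stop("pipeline state lacks '", field, "'; run the '", stage,
             "' stage first")
    invisible(TRUE)
}

.writePipelineOutputs <- function(state, outdir, config) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeCountTable(state$counts, file.path(outdir, "counts.tsv"),
                    assay = "counts")
    writeCountTable(state$counts, file.path(outdir, "tpm.tsv"),
                    assay = "tpm")
    writeExtendedRegions(state$regions,
                         bedPath = file.path(outdir, "regions.bed"),
                         auditPath = file.path(outdir,
                                               "regions_audit.tsv"))
    if (!is.null(state$de)) {
        con <- file(file.path(outdir, "diffexpr.tsv"), "w")
        writeLines("# fiveDGE differential expression (Welch ANOVA + BH)",
                   con)
        write.table(as.data.frame(state$de$table), con, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        close(con)
    }
    if (!is.null(state$som))
        writeSomAssignments(state$som, file.path(outdir, "som.tsv"))
    if (!is.null(state$trees)) {
        if (!is.null(state$trees$conditions))
            writeNewick(state$trees$conditions,
                        file.path(outdir, "conditions.nwk"))
        if (!is.null(state$trees$genes))
            writeNewick(state$trees$genes, file.path(outdir, "genes.nwk"))
    }
    yaml::write_yaml(config, file.path(outdir, "config.yaml"))
    jsonlite::write_json(state$manifest,
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(outdir)
}
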