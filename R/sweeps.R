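#' Gap-size parameter sweep
#'
#' Runs the pipeline once per gap size on fixed inputs and returns one
#' metrics row per gap size.  The gap size is the pipeline's main
#' parameter: too small leaves repeat-broken small contigs as anchors that
#' block closure, too large re-assembles needlessly much of the genome.
#'
#' @param reads named `DNAStringSet`.
#' @param reference single-sequence reference.
#' @param gapSizes numeric vector of gap sizes (bases), non-empty.
#' @param cfg base [PipelineConfig]; its `gapSize` is overridden per run.
#' @param mappings optional precomputed [MappedReads] reused across runs.
#' @param verbose forwarded to [runPipeline].
#' @return A `data.frame` with a `gap_size` column plus the
#'   [AssemblyMetrics] columns, one row per gap size.
#' @export
sweepGapSize <- function(reads, reference, gapSizes,
                         cfg = PipelineConfig(), mappings = NULL,
                         verbose = FALSE) {
    if (length(gapSizes) == 0L) stop("gapSizes must be non-empty")
    if (any(gapSizes < 0)) stop("gap sizes must be >= 0")
    if (is.null(mappings)) {
        reference <- .as_seqset(reference)
        if (is.null(names(reference))) names(reference) <- "ref"
        mappings <- mapReads(.as_seqset(reads), reference, cfg@mapper)
    }
    rows <- lapply(gapSizes, function(g) {
        cfg@gapSize <- as.integer(g)
        res <- runPipeline(reads, reference, cfg, mappings = mappings,
                           verbose = verbose)
        cbind(data.frame(gap_size = g), as.data.frame(metrics(res)))
    })
    do.call(rbind, rows)
}

#' Coverage sweep on a simulated genome
#'
#' The coverage-requirement experiment: how much data does the method need
#' before the genome assembles into a single contig?  For each seed, one
#' read set is simulated at the highest requested coverage and the lower
#' levels are nested random subsamples of it — the in-silico analogue of
#' subsampling a real sequencing run, which also keeps the coverage
#' response free of between-dataset sampling noise.
#'
#' @param truth a [SimTruth] from [makeGenome].
#' @param coverages numeric vector of fold coverages.
#' @param simCfg base [ReadSimConfig]; `coverage` and `seed` are
#'   overridden per run.
#' @param cfg a [PipelineConfig].
#' @param seeds integer vector of simulation seeds (replicates).
#' @param verbose forwarded to [runPipeline].
#' @return A `data.frame` with `coverage` and `seed` columns plus the
#'   [AssemblyMetrics] columns, one row per coverage x seed.
#' @export
sweepCoverage <- function(truth, coverages, simCfg = ReadSimConfig(),
                          cfg = PipelineConfig(), seeds = 1L,
                          verbose = FALSE) {
    if (length(coverages) == 0L) stop("coverages must be non-empty")
    L <- Biostrings::width(truthGenome(truth))[1L]
    rows <- list()
    empty_row <- function(cv, sd) data.frame(
        coverage = cv, seed = sd, genome_size = L, total_length = 0,
        contig_number = 0L, ng50 = NA_real_, lg50 = NA_integer_,
        gap_fill_number = 0L, gap_fill_length = 0)
    for (sd in seeds) {
        simCfg@coverage <- max(coverages)
        simCfg@seed <- as.integer(sd)
        sim <- simulateReads(truth, simCfg)
        n_full <- length(sim$reads)
        perm <- withr::with_seed(as.integer(sd) + 7L,
                                 sample.int(max(n_full, 1L)))
        for (cv in coverages) {
            n_c <- min(n_full, round(cv * L / simCfg@meanLen))
            if (n_c == 0L) {
                rows[[length(rows) + 1L]] <- empty_row(cv, sd)
                next
            }
            reads <- sim$reads[sort(perm[seq_len(n_c)])]
            res <- runPipeline(reads, truthGenome(truth), cfg,
                               verbose = verbose)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(coverage = cv, seed = sd),
                as.data.frame(metrics(res)))
        }
    }
    do.call(rbind, rows)
}
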