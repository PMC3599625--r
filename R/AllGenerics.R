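#' @importFrom BiocGenerics strand start end width
NULL

#' @describeIn ContigSet-class contig sequences as a `DNAStringSet`.
#' @param x,object a `ContigSet`.
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
setMethod("contigSeqs", "ContigSet", function(x) x@seqs)

#' @describeIn ContigSet-class per-contig metadata (`DataFrame`).
#' @export
setGeneric("contigInfo", function(x) standardGeneric("contigInfo"))
setMethod("contigInfo", "ContigSet", function(x) x@info)

#' @describeIn ContigSet-class provenance labels.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
setMethod("provenance", "ContigSet", function(x) x@info$provenance)

#' @describeIn ContigSet-class reference placements of the placed contigs
#'   as a `GRanges` (unplaced contigs are dropped).
#' @export
setGeneric("contigRanges", function(x) standardGeneric("contigRanges"))
setMethod("contigRanges", "ContigSet", function(x) {
    has <- !is.na(x@info$ref_start) & !is.na(x@info$ref_end) &
        !is.na(x@info$ref_id)
    GenomicRanges::GRanges(
        seqnames = x@info$ref_id[has],
        ranges = IRanges::IRanges(start = x@info$ref_start[has],
                                  end = x@info$ref_end[has],
                                  names = rownames(x@info)[has]))
})

setMethod("length", "ContigSet", function(x) length(x@seqs))

setMethod("names", "ContigSet", function(x) names(x@seqs))

setMethod("width", "ContigSet", function(x) Biostrings::width(x@seqs))

setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@seqs))
    new("ContigSet", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

#' @export
#' @method c ContigSet
c.ContigSet <- function(...) {
    sets <- list(...)
    stopifnot(all(vapply(sets, is, logical(1), "ContigSet")))
    new("ContigSet",
        seqs = do.call(c, lapply(sets, contigSeqs)),
        info = do.call(rbind, lapply(sets, contigInfo)))
}

setMethod("show", "ContigSet", function(object) {
    n <- length(object)
    cat("ContigSet with", n, "contig(s)\n")
    if (n) {
        w <- width(object)
        cat("  total length:", sum(w), "bases; longest:", max(w), "\n")
        cat("  provenance:",
            paste(sprintf("%s=%d", names(table(provenance(object))),
                          as.integer(table(provenance(object)))),
                  collapse = ", "), "\n")
    }
})

#' @describeIn SimTruth-class the simulated genome (`DNAStringSet`).
#' @param x,object a `SimTruth`.
#' @export
setGeneric("truthGenome", function(x) standardGeneric("truthGenome"))
setMethod("truthGenome", "SimTruth", function(x) x@genome)

#' @describeIn SimTruth-class planted repeat intervals (`GRanges`).
#' @export
setGeneric("truthRepeats", function(x) standardGeneric("truthRepeats"))
setMethod("truthRepeats", "SimTruth", function(x) x@repeats)

#' @describeIn SimTruth-class true read origins (`DataFrame`).
#' @export
setGeneric("readOrigins", function(x) standardGeneric("readOrigins"))
setMethod("readOrigins", "SimTruth", function(x) x@readOrigins)

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", Biostrings::width(object@genome)[1L], "base genome,",
        length(object@repeats), "planted repeat interval(s),",
        nrow(object@readOrigins), "read origin(s)\n")
})

#' Convert assembly metrics to a one-row data.frame
#'
#' @param x an `AssemblyMetrics` object.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return A one-row `data.frame` with the metric columns.
#' @export
#' @method as.data.frame AssemblyMetrics
as.data.frame.AssemblyMetrics <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(genome_size = x@genomeSize, total_length = x@totalLength,
               contig_number = x@contigNumber, ng50 = x@ng50, lg50 = x@lg50,
               gap_fill_number = x@gapFillNumber,
               gap_fill_length = x@gapFillLength)
}

setMethod("show", "AssemblyMetrics", function(object) {
    cat("AssemblyMetrics\n")
    df <- as.data.frame.AssemblyMetrics(object)
    for (nm in colnames(df)) cat(sprintf("  %-16s %s\n", nm, df[[nm]]))
})

setMethod("show", "ReassemblyResult", function(object) {
    cat("ReassemblyResult\n")
    cat("  mapped reads: ", length(object@mappings), "\n", sep = "")
    cat("  anchors:      ", length(object@anchors), "\n", sep = "")
    cat("  repeat regions: ", length(object@regions), "\n", sep = "")
    cat("  final contigs:  ", length(object@final), "\n", sep = "")
    show(object@metrics)
})

#' @describeIn ReassemblyResult-class final merged contigs.
#' @param x,object a `ReassemblyResult`.
#' @export
setGeneric("finalContigs", function(x) standardGeneric("finalContigs"))
setMethod("finalContigs", "ReassemblyResult", function(x) x@final)

#' @describeIn ReassemblyResult-class anchor contigs.
#' @export
setGeneric("anchorContigs", function(x) standardGeneric("anchorContigs"))
setMethod("anchorContigs", "ReassemblyResult", function(x) x@anchors)

#' @describeIn ReassemblyResult-class repeat regions.
#' @export
setGeneric("repeatRegions", function(x) standardGeneric("repeatRegions"))
setMethod("repeatRegions", "ReassemblyResult", function(x) x@regions)

#' @describeIn ReassemblyResult-class assembly metrics.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
setMethod("metrics", "ReassemblyResult", function(x) x@metrics)
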