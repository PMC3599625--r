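#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
NULL

## ---------------------------------------------------------------------------
## Parameter objects
## ---------------------------------------------------------------------------

#' Parameters of the built-in seed-and-extend read mapper
#'
#' @slot k seed k-mer length.
#' @slot minIdentity minimum alignment identity (matches / alignment columns)
#'   for a placement to be reported.
#' @slot minAlignedFraction minimum fraction of the read that must be aligned.
#' @slot band half-width of the alignment window padding around the seeded
#'   diagonal, in bases.
#'
#' @export
setClass("MapperParams",
    representation(k = "integer", minIdentity = "numeric",
                   minAlignedFraction = "numeric", band = "integer"))

setValidity("MapperParams", function(object) {
    msg <- NULL
    if (object@k < 5L || object@k > 31L)
        msg <- c(msg, "k must be in [5, 31]")
    if (object@minIdentity <= 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must be in (0, 1]")
    if (object@minAlignedFraction <= 0 || object@minAlignedFraction > 1)
        msg <- c(msg, "minAlignedFraction must be in (0, 1]")
    if (object@band < 1L) msg <- c(msg, "band must be positive")
    if (is.null(msg)) TRUE else msg
})

#' @rdname MapperParams-class
#' @param k,minIdentity,minAlignedFraction,band see the class slots.
#' @return A `MapperParams` object.
#' @examples
#' MapperParams(k = 13)
#' @export
MapperParams <- function(k = 15L, minIdentity = 0.9,
                         minAlignedFraction = 0.9, band = 30L) {
    new("MapperParams", k = as.integer(k), minIdentity = minIdentity,
        minAlignedFraction = minAlignedFraction, band = as.integer(band))
}

#' Pipeline configuration
#'
#' Holds the tunable parameters of the re-assembly pipeline.  `gapSize` is
#' the central one: anchor contigs shorter than `gapSize` are discarded and
#' their reference footprint is marked as a repeat region to be re-assembled
#' locally.
#'
#' @slot gapSize contig-length threshold (bases, default 500).
#' @slot minDepth minimum pileup depth for anchor-contig calling.
#' @slot flank bases added on each side of a repeat region when binning
#'   reads; `NA` means "use the mean read length", resolved at run time.
#' @slot maxIters cap on assemble/recruit iterations per repeat region.
#' @slot minOverlap minimum end overlap (bases) for merging sequences.
#' @slot maxMergeMismatchFrac maximum mismatch fraction inside an overlap.
#' @slot editOverlaps when `TRUE`, end overlaps are detected with an
#'   indel-tolerant alignment instead of the substitution-only scan.
#' @slot circular attempt an extra end-to-end overlap between the first and
#'   last final contig (circular genomes).
#' @slot mapper a [MapperParams] object.
#'
#' @export
setClass("PipelineConfig",
    representation(gapSize = "integer", minDepth = "integer",
                   flank = "integer", maxIters = "integer",
                   minOverlap = "integer", maxMergeMismatchFrac = "numeric",
                   editOverlaps = "logical", circular = "logical",
                   mapper = "MapperParams"))

setValidity("PipelineConfig", function(object) {
    msg <- NULL
    if (object@gapSize < 0L) msg <- c(msg, "gapSize must be >= 0")
    if (object@minDepth < 1L) msg <- c(msg, "minDepth must be positive")
    if (!is.na(object@flank) && object@flank < 0L)
        msg <- c(msg, "flank must be >= 0")
    if (object@maxIters < 1L) msg <- c(msg, "maxIters must be positive")
    if (object@minOverlap < 1L) msg <- c(msg, "minOverlap must be positive")
    if (object@maxMergeMismatchFrac < 0 || object@maxMergeMismatchFrac >= 1)
        msg <- c(msg, "maxMergeMismatchFrac must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname PipelineConfig-class
#' @param gapSize,minDepth,flank,maxIters,minOverlap,maxMergeMismatchFrac,editOverlaps,circular,mapper
#'   see the class slots.
#' @return A `PipelineConfig` object.
#' @examples
#' PipelineConfig(gapSize = 1000)
#' @export
PipelineConfig <- function(gapSize = 500L, minDepth = 3L, flank = NA_integer_,
                           maxIters = 10L, minOverlap = 40L,
                           maxMergeMismatchFrac = 0.02, editOverlaps = FALSE,
                           circular = FALSE, mapper = MapperParams()) {
    new("PipelineConfig", gapSize = as.integer(gapSize),
        minDepth = as.integer(minDepth), flank = as.integer(flank),
        maxIters = as.integer(maxIters), minOverlap = as.integer(minOverlap),
        maxMergeMismatchFrac = maxMergeMismatchFrac,
        editOverlaps = editOverlaps, circular = circular, mapper = mapper)
}

#' Read-simulation configuration
#'
#' Error model for pyrosequencing-style (454/IonTorrent) single-end reads:
#' per-base substitution / insertion / deletion probabilities, with indel
#' rates multiplied inside homopolymer runs of length >= 3 — the dominant
#' error mode of that chemistry.
#'
#' @slot coverage fold coverage (>= 0).
#' @slot meanLen,lenSd read-length distribution (truncated normal, min 30).
#' @slot subRate,insRate,delRate per-base error probabilities.
#' @slot homopolymerMultiplier factor (>= 1) applied to indel rates inside
#'   homopolymer runs of length >= 3.
#' @slot seed RNG seed.
#' @slot circular emulate a circular template by appending the first
#'   `meanLen` bases before sampling read start positions.
#'
#' @export
setClass("ReadSimConfig",
    representation(coverage = "numeric", meanLen = "integer", lenSd = "numeric",
                   subRate = "numeric", insRate = "numeric", delRate = "numeric",
                   homopolymerMultiplier = "numeric", seed = "integer",
                   circular = "logical"))

setValidity("ReadSimConfig", function(object) {
    msg <- NULL
    rates <- c(object@subRate, object@insRate, object@delRate)
    if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0, 1]")
    if (object@coverage < 0) msg <- c(msg, "coverage must be >= 0")
    if (object@meanLen < 30L) msg <- c(msg, "meanLen must be >= 30")
    if (object@homopolymerMultiplier < 1)
        msg <- c(msg, "homopolymerMultiplier must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ReadSimConfig-class
#' @param coverage,meanLen,lenSd,subRate,insRate,delRate,homopolymerMultiplier,seed,circular
#'   see the class slots.
#' @return A `ReadSimConfig` object.
#' @examples
#' ReadSimConfig(coverage = 15, subRate = 0, insRate = 0, delRate = 0)
#' @export
ReadSimConfig <- function(coverage = 10, meanLen = 400L, lenSd = 60,
                          subRate = 0.001, insRate = 0.005, delRate = 0.005,
                          homopolymerMultiplier = 3, seed = 1L,
                          circular = FALSE) {
    new("ReadSimConfig", coverage = coverage, meanLen = as.integer(meanLen),
        lenSd = lenSd, subRate = subRate, insRate = insRate,
        delRate = delRate, homopolymerMultiplier = homopolymerMultiplier,
        seed = as.integer(seed), circular = circular)
}

#' Specification of a planted repeat family
#'
#' @slot kind one of `"dispersed"`, `"tandem"`, `"inverted"`.
#' @slot unitLength repeat-unit length in bases.
#' @slot copies number of copies (`inverted` requires exactly 2).
#' @slot divergence per-copy substitution fraction in [0, 0.05].
#'
#' @export
setClass("RepeatSpec",
    representation(kind = "character", unitLength = "integer",
                   copies = "integer", divergence = "numeric"))

setValidity("RepeatSpec", function(object) {
    msg <- NULL
    if (!object@kind %in% c("dispersed", "tandem", "inverted"))
        msg <- c(msg, "kind must be dispersed, tandem or inverted")
    if (object@unitLength < 1L) msg <- c(msg, "unitLength must be >= 1")
    if (object@copies < 2L) msg <- c(msg, "copies must be >= 2")
    if (object@kind == "inverted" && object@copies != 2L)
        msg <- c(msg, "inverted repeats have exactly 2 copies")
    if (object@divergence < 0 || object@divergence > 0.05)
        msg <- c(msg, "divergence must be in [0, 0.05]")
    if (is.null(msg)) TRUE else msg
})

#' @rdname RepeatSpec-class
#' @param kind,unitLength,copies,divergence see the class slots.
#' @return A `RepeatSpec` object.
#' @examples
#' RepeatSpec("dispersed", 2000, copies = 3)
#' @export
RepeatSpec <- function(kind, unitLength, copies = 2L, divergence = 0) {
    new("RepeatSpec", kind = kind, unitLength = as.integer(unitLength),
        copies = as.integer(copies), divergence = divergence)
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Set of contigs with optional reference placement
#'
#' A `DNAStringSet` of consensus sequences plus per-contig metadata:
#' reference placement (1-based closed coordinates, `NA` when unplaced),
#' provenance (`anchor`, `repeat_resolved` or `merged`) and mean pileup
#' depth.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot info a [S4Vectors::DataFrame] with columns `ref_id`, `ref_start`,
#'   `ref_end`, `provenance`, `depth_mean`.
#'
#' @export
setClass("ContigSet",
    representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("ContigSet", function(object) {
    msg <- NULL
    need <- c("ref_id", "ref_start", "ref_end", "provenance", "depth_mean")
    if (!all(need %in% colnames(object@info)))
        msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
    else {
        if (nrow(object@info) != length(object@seqs))
            msg <- c(msg, "info rows must match number of sequences")
        if (length(object@seqs) && any(Biostrings::width(object@seqs) < 1L))
            msg <- c(msg, "contig sequences must be non-empty")
        bad_prov <- !object@info$provenance %in%
            c("anchor", "repeat_resolved", "merged")
        if (any(bad_prov)) msg <- c(msg, "unknown provenance label")
        has <- !is.na(object@info$ref_start) & !is.na(object@info$ref_end)
        if (any(has & object@info$ref_start > object@info$ref_end))
            msg <- c(msg, "ref_start must be <= ref_end")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname ContigSet-class
#' @param seqs contig sequences (`DNAStringSet` or character).
#' @param ref_id,ref_start,ref_end optional reference placement (1-based
#'   closed); recycled to the number of contigs.
#' @param provenance provenance label(s).
#' @param depth_mean mean pileup depth per contig.
#' @param ids contig identifiers (default: names of `seqs` or `contig_<i>`).
#' @return A `ContigSet` object.
#' @examples
#' ContigSet(c(a = "ACGTACGT"), provenance = "anchor")
#' @export
ContigSet <- function(seqs, ref_id = NA_character_, ref_start = NA_integer_,
                      ref_end = NA_integer_, provenance = "anchor",
                      depth_mean = NA_real_, ids = NULL) {
    seqs <- .as_seqset(seqs)
    n <- length(seqs)
    if (is.null(ids)) {
        ids <- if (!is.null(names(seqs)) && all(nzchar(names(seqs))))
            names(seqs) else paste0("contig_", seq_len(n))
    }
    names(seqs) <- ids
    info <- S4Vectors::DataFrame(
        ref_id = rep(as.character(ref_id), length.out = n),
        ref_start = rep(as.integer(ref_start), length.out = n),
        ref_end = rep(as.integer(ref_end), length.out = n),
        provenance = rep(as.character(provenance), length.out = n),
        depth_mean = rep(as.numeric(depth_mean), length.out = n),
        row.names = ids)
    new("ContigSet", seqs = seqs, info = info)
}

#' Reads mapped to a reference
#'
#' A [GenomicRanges::GRanges] subclass with one range per mapped read and
#' required metadata columns `read_id`, `identity` (matches / alignment
#' columns), `cigar` (read-vs-reference, `NA` when unknown) and `seq` (the
#' read sequence already in reference orientation, i.e. reverse-complemented
#' for minus-strand placements).
#'
#' @export
setClass("MappedReads", contains = "GRanges")

setValidity("MappedReads", function(object) {
    msg <- NULL
    need <- c("read_id", "identity", "cigar", "seq")
    if (!all(need %in% colnames(S4Vectors::mcols(object))))
        msg <- c(msg, paste("required mcols:", paste(need, collapse = ", ")))
    if (any(!as.character(BiocGenerics::strand(object)) %in% c("+", "-")))
        msg <- c(msg, "strand must be + or -")
    idn <- S4Vectors::mcols(object)$identity
    if (length(idn) && any(!is.na(idn) & (idn < 0 | idn > 1)))
        msg <- c(msg, "identity must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @rdname MappedReads-class
#' @param gr a `GRanges` carrying the required metadata columns.
#' @return A `MappedReads` object.
#' @export
MappedReads <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    for (col in c("read_id", "cigar", "seq"))
        if (!col %in% colnames(mc))
            mc[[col]] <- rep(NA_character_, length(gr))
    if (!"identity" %in% colnames(mc))
        mc$identity <- rep(NA_real_, length(gr))
    S4Vectors::mcols(gr) <- mc
    new("MappedReads", gr)
}

#' Repeat regions of a reference
#'
#' A [GenomicRanges::GRanges] subclass; each range is a maximal reference
#' interval not covered by an anchor contig.  Metadata columns: `region_id`,
#' `read_ids` (a `CharacterList` of binned read identifiers) and `flank`
#' (bases added around the region when binning).
#'
#' @export
setClass("RepeatRegions", contains = "GRanges")

setValidity("RepeatRegions", function(object) {
    need <- c("region_id", "read_ids", "flank")
    if (!all(need %in% colnames(S4Vectors::mcols(object))))
        return(paste("required mcols:", paste(need, collapse = ", ")))
    TRUE
})

#' @rdname RepeatRegions-class
#' @param gr a `GRanges` of repeat intervals.
#' @return A `RepeatRegions` object.
#' @export
RepeatRegions <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    if (!"region_id" %in% colnames(mc))
        mc$region_id <- paste0("region_", seq_along(gr))
    if (!"read_ids" %in% colnames(mc))
        mc$read_ids <- IRanges::CharacterList(rep(list(character(0)), length(gr)))
    if (!"flank" %in% colnames(mc)) mc$flank <- NA_integer_
    S4Vectors::mcols(gr) <- mc
    new("RepeatRegions", gr)
}

#' Ground truth of a simulated genome
#'
#' @slot genome a single-sequence `DNAStringSet`.
#' @slot repeats a `GRanges` of planted repeat intervals with metadata
#'   columns `family`, `kind` and `copy`.
#' @slot readOrigins a `DataFrame` mapping `read_id` to the true forward
#'   strand start (1-based), strand and error-free length.
#'
#' @export
setClass("SimTruth",
    representation(genome = "DNAStringSet", repeats = "GRanges",
                   readOrigins = "DataFrame"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    if (length(object@genome) != 1L)
        msg <- c(msg, "genome must hold exactly one sequence")
    else {
        L <- Biostrings::width(object@genome)[1L]
        if (length(object@repeats) &&
            (any(BiocGenerics::start(object@repeats) < 1L) ||
             any(BiocGenerics::end(object@repeats) > L)))
            msg <- c(msg, "repeat intervals must lie within the genome")
    }
    if (is.null(msg)) TRUE else msg
})

#' Assembly evaluation metrics
#'
#' Totals, NG50/LG50 and gap-filling counts for one assembly.  NG50 is the
#' contig length at which the descending cumulative contig length first
#' reaches 50% of the genome size; LG50 is the number of contigs needed to
#' reach it.  Both are `NA` when the assembly never reaches the threshold.
#'
#' @slot genomeSize,totalLength bases.
#' @slot contigNumber number of contigs.
#' @slot ng50 NG50 in bases, or `NA` when undefined.
#' @slot lg50 LG50 count, or `NA` when undefined.
#' @slot gapFillNumber number of pre-existing inter-anchor gaps completely
#'   covered by a final contig.
#' @slot gapFillLength total bases of those gaps.
#'
#' @export
setClass("AssemblyMetrics",
    representation(genomeSize = "numeric", totalLength = "numeric",
                   contigNumber = "integer", ng50 = "numeric",
                   lg50 = "integer", gapFillNumber = "integer",
                   gapFillLength = "numeric"))

#' Result of a full pipeline run
#'
#' @slot final final merged contigs ([ContigSet]).
#' @slot anchors anchor contigs ([ContigSet]).
#' @slot regions repeat regions ([RepeatRegions]).
#' @slot regionContigs per-region re-assembled contigs (list of [ContigSet]).
#' @slot mappings the read-to-reference mapping used ([MappedReads]).
#' @slot metrics an [AssemblyMetrics].
#' @slot config the [PipelineConfig] used.
#'
#' @export
setClass("ReassemblyResult",
    representation(final = "ContigSet", anchors = "ContigSet",
                   regions = "RepeatRegions", regionContigs = "list",
                   mappings = "MappedReads", metrics = "AssemblyMetrics",
                   config = "PipelineConfig"))
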