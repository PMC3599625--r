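#' NG(X): contig length at which X% of the genome is covered
#'
#' Sort the contig lengths in decreasing order; NG(X) is the first length
#' at which the running total reaches `genomeSize * x / 100`.  `NA` when
#' the assembly never reaches the threshold (reported as a distinguished
#' marker, never 0).
#'
#' @param lengths contig lengths in bases (non-negative).
#' @param genomeSize genome size in bases (> 0).
#' @param x percent threshold in (0, 100].
#' @return NG(X) in bases, or `NA`.
#' @examples
#' ngx(c(10, 8, 6), 20, 50)   # 10
#' @export
ngx <- function(lengths, genomeSize, x = 50) {
    if (any(lengths < 0)) stop("contig lengths must be non-negative")
    if (genomeSize <= 0) stop("genomeSize must be positive")
    if (x <= 0 || x > 100) stop("x must be in (0, 100]")
    s <- sort(lengths, decreasing = TRUE)
    cum <- cumsum(s)
    hit <- which(cum >= genomeSize * x / 100)
    if (length(hit) == 0L) NA_real_ else s[hit[1L]]
}

#' LG(X): number of contigs needed to cover X% of the genome
#'
#' @inheritParams ngx
#' @return The contig count, or `NA` when the threshold is unreachable.
#' @examples
#' lgx(c(4, 4, 4), 20, 50)   # 3
#' @export
lgx <- function(lengths, genomeSize, x = 50) {
    if (any(lengths < 0)) stop("contig lengths must be non-negative")
    if (genomeSize <= 0) stop("genomeSize must be positive")
    if (x <= 0 || x > 100) stop("x must be in (0, 100]")
    s <- sort(lengths, decreasing = TRUE)
    cum <- cumsum(s)
    hit <- which(cum >= genomeSize * x / 100)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
}

## reference projection of final contigs: stored placement when available,
## otherwise estimated by mapping both contig ends onto the reference
.contig_projections <- function(final, reference) {
    info <- contigInfo(final)
    starts <- info$ref_start
    ends <- info$ref_end
    miss <- which(is.na(starts) | is.na(ends))
    if (length(miss)) {
        refset <- .as_seqset(reference)
        params <- MapperParams()
        idx <- indexReference(refset, params@k)
        for (i in miss) {
            s <- as.character(contigSeqs(final))[i]
            w <- min(nchar(s), 500L)
            head_hit <- mapRead(substr(s, 1L, w), idx, params)
            tail_hit <- mapRead(substr(s, nchar(s) - w + 1L, nchar(s)),
                                idx, params)
            if (is.null(head_hit) || is.null(tail_hit)) {
                warning("final contig ", names(final)[i],
                        " could not be placed on the reference; ",
                        "skipped in gap-filling statistics")
                next
            }
            starts[i] <- min(BiocGenerics::start(head_hit),
                             BiocGenerics::start(tail_hit))
            ends[i] <- max(BiocGenerics::end(head_hit),
                           BiocGenerics::end(tail_hit))
        }
    }
    keep <- !is.na(starts) & !is.na(ends)
    IRanges::IRanges(starts[keep], ends[keep])
}

#' Gap-filling statistics
#'
#' A pre-existing inter-anchor gap (a reference interval between two
#' consecutive anchor contigs) counts as filled when some final contig's
#' reference projection covers it entirely.  Returns the count of filled
#' gaps and their total length in bases.
#'
#' @param anchors anchor [ContigSet] with reference coordinates.
#' @param final final [ContigSet].
#' @param reference the reference sequence (used to place any final contig
#'   lacking stored coordinates).
#' @return A list with `number`, `length`, and `gaps` (the inter-anchor
#'   gap `IRanges` with a `filled` metadata column).
#' @export
gapFillStats <- function(anchors, final, reference) {
    if (length(anchors) < 2L)
        return(list(number = 0L, length = 0, gaps = IRanges::IRanges()))
    ainfo <- contigInfo(anchors)
    air <- IRanges::reduce(IRanges::IRanges(ainfo$ref_start, ainfo$ref_end))
    if (length(air) < 2L)
        return(list(number = 0L, length = 0, gaps = IRanges::IRanges()))
    gaps <- IRanges::gaps(air)   # inter-anchor only (no reference ends)
    proj <- .contig_projections(final, reference)
    filled <- IRanges::overlapsAny(gaps, proj, type = "within")
    S4Vectors::mcols(gaps)$filled <- filled
    list(number = sum(filled), length = sum(IRanges::width(gaps)[filled]),
         gaps = gaps)
}

#' Compute the full assembly metric set
#'
#' @param final final [ContigSet].
#' @param anchors anchor [ContigSet] (for the gap-filling columns).
#' @param reference reference sequence.
#' @param genomeSize genome size override (default: reference length).
#' @return An [AssemblyMetrics].
#' @export
assemblyMetrics <- function(final, anchors, reference, genomeSize = NULL) {
    refset <- .as_seqset(reference)
    if (is.null(genomeSize))
        genomeSize <- Biostrings::width(refset)[1L]
    lens <- as.numeric(width(final))
    gf <- gapFillStats(anchors, final, refset)
    new("AssemblyMetrics",
        genomeSize = as.numeric(genomeSize),
        totalLength = sum(lens),
        contigNumber = length(final),
        ng50 = ngx(lens, genomeSize, 50),
        lg50 = as.integer(lgx(lens, genomeSize, 50)),
        gapFillNumber = as.integer(gf$number),
        gapFillLength = as.numeric(gf$length))
}

#' Alignment identity between two long sequences
#'
#' Banded alignment (match +1, mismatch -2, gap -3) with free end gaps by
#' default, so unassembled termini do not count against identity; the
#' value is matches divided by aligned columns.  Suitable for
#' assembly-vs-truth comparison at chromosome scale.
#'
#' @param a,b sequences (character or `DNAString`).
#' @param band extra band half-width around the length-difference diagonal
#'   (default scales with sequence length).
#' @param freeEnds allow unpenalised end gaps (default `TRUE`).
#' @return A list with `identity`, `matches` and `columns`.
#' @examples
#' globalIdentity("ACGTACGTAC", "ACGTACGAAC")$identity
#' @export
globalIdentity <- function(a, b, band = NULL, freeEnds = TRUE) {
    a <- .as_seq_char(.as_seqset(a)); b <- .as_seq_char(.as_seqset(b))
    if (identical(a, b))
        return(list(identity = 1, matches = nchar(a), columns = nchar(a)))
    if (is.null(band))
        band <- max(200L, as.integer(ceiling(0.02 * max(nchar(a), nchar(b)))))
    st <- banded_align_stats_cpp(a, b, as.integer(band), freeEnds)
    list(identity = if (st$columns > 0) st$matches / st$columns else 0,
         matches = st$matches, columns = st$columns)
}
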