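#' Build a k-mer index of a reference sequence
#'
#' Maps every forward-strand k-mer to all of its start positions (1-based).
#' K-mers containing N are skipped.
#'
#' @param reference single sequence (`DNAStringSet`, `DNAString` or
#'   character).
#' @param k k-mer length.
#' @return An object of class `KmerIndex` (used by [mapRead]).
#' @examples
#' idx <- indexReference("ACGTACGT", k = 4)
#' @export
indexReference <- function(reference, k = 15L) {
    refset <- .as_seqset(reference)
    seq <- .as_seq_char(refset)
    k <- as.integer(k)
    if (nchar(seq) < k)
        stop("reference (", nchar(seq), " bases) is shorter than k = ", k)
    structure(list(env = kmerPositions(seq, k), k = k, seq = seq,
                   length = nchar(seq),
                   ref_id = if (!is.null(names(refset))) names(refset)[1L]
                            else "ref"),
              class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
    cat("KmerIndex: k =", x$k, "over", x$length, "bases (",
        length(ls(x$env)), "distinct k-mers )\n")
    invisible(x)
}

## positions (1-based estimated ref starts) voted by seed k-mers of `read`,
## clustered within `band`; returns a data.frame of cluster starts + votes
.seed_clusters <- function(read, idx, band) {
    rl <- nchar(read)
    k <- idx$k
    if (rl < k) return(NULL)
    offs <- unique(c(seq(1L, rl - k + 1L,
                         by = max(1L, (rl - k) %/% 24L + 1L)), rl - k + 1L))
    kmers <- substring(read, offs, offs + k - 1L)
    hits <- mget(kmers, envir = idx$env, ifnotfound = list(NULL))
    est <- unlist(mapply(function(pos, off)
        if (is.null(pos)) NULL else pos - off + 1L,
        hits, offs, SIMPLIFY = FALSE), use.names = FALSE)
    if (is.null(est) || length(est) == 0L) return(NULL)
    est <- sort(est)
    grp <- cumsum(c(1L, diff(est) > band))
    starts <- vapply(split(est, grp), function(g)
        as.integer(round(stats::median(g))), integer(1))
    votes <- as.integer(table(grp))
    ord <- order(-votes, starts)
    data.frame(start = starts[ord], votes = votes[ord])
}

.submat_cache <- new.env(parent = emptyenv())
.submat <- function() {
    if (is.null(.submat_cache$mat))
        .submat_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2)
    .submat_cache$mat
}

.align_window <- function(read, idx, est_start, band) {
    rl <- nchar(read)
    ws <- max(1L, est_start - band)
    we <- min(idx$length, est_start + rl - 1L + band)
    if (we - ws + 1L < rl %/% 2L) return(NULL)
    ## exact-placement fast path
    if (est_start >= 1L && est_start + rl - 1L <= idx$length &&
        substr(idx$seq, est_start, est_start + rl - 1L) == read)
        return(list(ref_start = est_start, ref_end = est_start + rl - 1L,
                    identity = 1, cigar = paste0(rl, "M"), score = rl,
                    aligned_frac = 1))
    window <- substr(idx$seq, ws, we)
    aln <- banded_read_align_cpp(read, window, band)
    if (aln$columns == 0L) return(NULL)
    list(ref_start = ws + aln$ref_start - 1L,
         ref_end = ws + aln$ref_end - 1L,
         identity = aln$matches / aln$columns, cigar = aln$cigar,
         score = aln$score, aligned_frac = aln$read_bases / rl)
}

## fast reverse complement for a single character scalar (hot path)
.rc1 <- function(x) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

## core placement search on plain characters; returns a list or NULL
.map_read_core <- function(read, idx, params) {
    rl <- nchar(read)
    best <- NULL
    for (str in c("+", "-")) {
        oriented <- if (str == "+") read else .rc1(read)
        cl <- .seed_clusters(oriented, idx, params@band)
        if (is.null(cl)) next
        take <- seq_len(min(nrow(cl), 4L))
        for (i in take) {
            hit <- .align_window(oriented, idx, cl$start[i], params@band)
            if (is.null(hit)) next
            ## a placement must qualify before it can compete: clipped
            ## wrong-locus hits must not shadow a full-length placement
            if (hit$identity < params@minIdentity ||
                hit$aligned_frac < params@minAlignedFraction) next
            hit$strand <- str
            hit$seq <- oriented
            if (is.null(best) ||
                hit$identity > best$identity + 1e-12 ||
                (abs(hit$identity - best$identity) <= 1e-12 &&
                 (hit$ref_start < best$ref_start ||
                  (hit$ref_start == best$ref_start &&
                   str == "+" && best$strand == "-"))))
                best <- hit
            ## any other perfect placement would carry equal seed votes and
            ## sort later (larger start), so the first perfect hit wins
            if (best$identity >= 1) break
        }
    }
    best
}

#' Map one read to an indexed reference
#'
#' Seed-and-extend: seed k-mers of both read orientations are looked up in
#' the index, co-linear hits vote for candidate placements, and each
#' candidate is extended by global-in-read alignment against the reference
#' window (match +1, mismatch -2, gap -3).  The best-identity placement
#' meeting `minIdentity` and `minAlignedFraction` is reported; ties are
#' broken towards the smallest `ref_start`, then the `+` strand.
#'
#' @param read one read (character or `DNAString`), or a named length-1
#'   `DNAStringSet`.
#' @param idx a `KmerIndex` from [indexReference].
#' @param params a [MapperParams] (its `k` must match the index).
#' @param id read identifier used in the output.
#' @return A one-row [MappedReads], or `NULL` when unmapped.
#' @export
mapRead <- function(read, idx, params = MapperParams(), id = "read") {
    if (is(read, "DNAStringSet") && !is.null(names(read))) id <- names(read)[1L]
    read <- .as_seq_char(.as_seqset(read))
    if (params@k != idx$k)
        stop("params@k (", params@k, ") does not match the index (", idx$k, ")")
    best <- .map_read_core(read, idx, params)
    if (is.null(best)) return(NULL)
    gr <- GenomicRanges::GRanges(
        seqnames = idx$ref_id,
        ranges = IRanges::IRanges(best$ref_start, best$ref_end),
        strand = best$strand, read_id = id, identity = best$identity,
        cigar = best$cigar, seq = best$seq)
    GenomeInfoDb::seqlengths(gr) <- idx$length
    MappedReads(gr)
}

#' Map a read set to a reference
#'
#' @param reads named `DNAStringSet` of reads.
#' @param reference single reference sequence (or a prebuilt `KmerIndex`).
#' @param params a [MapperParams].
#' @param verbose emit a progress message per 5000 reads.
#' @return A [MappedReads] with one range per mapped read, in input read
#'   order (unmapped reads are absent).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr = paste(
#'     sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")))
#' reads <- Biostrings::DNAStringSet(c(r1 = substr(as.character(ref), 51, 250)))
#' mapReads(reads, ref)
#' @export
mapReads <- function(reads, reference, params = MapperParams(),
                     verbose = FALSE) {
    idx <- if (inherits(reference, "KmerIndex")) reference
           else indexReference(reference, params@k)
    out <- vector("list", length(reads))
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
    chars <- as.character(reads)
    for (i in seq_along(chars)) {
        hit <- .map_read_core(chars[i], idx, params)
        if (!is.null(hit)) { hit$id <- ids[i]; out[[i]] <- hit }
        if (verbose && i %% 5000L == 0L)
            message("  mapped ", i, "/", length(chars), " reads")
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) {
        gr <- GenomicRanges::GRanges(read_id = character(0),
                                     identity = numeric(0),
                                     cigar = character(0),
                                     seq = character(0))
        return(MappedReads(gr))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = idx$ref_id,
        ranges = IRanges::IRanges(
            vapply(out, function(x) x$ref_start, numeric(1)),
            vapply(out, function(x) x$ref_end, numeric(1))),
        strand = vapply(out, function(x) x$strand, ""),
        read_id = vapply(out, function(x) x$id, ""),
        identity = vapply(out, function(x) x$identity, numeric(1)),
        cigar = vapply(out, function(x) x$cigar, ""),
        seq = vapply(out, function(x) x$seq, ""))
    GenomeInfoDb::seqlengths(gr) <- idx$length
    MappedReads(gr)
}
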