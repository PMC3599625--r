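#' Best suffix/prefix overlap between two sequences
#'
#' Finds the longest match between the 3' end of `a` and the 5' start of
#' `b`, allowing substitutions up to `maxMismatchFrac` of the overlap
#' length but no indels (the default, `mode = "substitution"`).  Both `b`
#' and its reverse complement are considered, preferring the `+`
#' orientation on ties.  `mode = "edit"` instead detects the overlap with
#' an indel-tolerant ends-free alignment (useful for uncorrected
#' homopolymer-indel-rich reads); its `mismatches` field then counts edits.
#'
#' @param a,b sequences (character or `DNAString`).
#' @param minOverlap minimum qualifying overlap length in bases.
#' @param maxMismatchFrac maximum mismatch (or edit) fraction within the
#'   overlap.
#' @param mode `"substitution"` (default) or `"edit"`.
#' @return A list with `length`, `mismatches` and `orientation` (`"+"` or
#'   `"-"`), or `NULL` when no overlap qualifies.
#' @examples
#' bestOverlap("ACGTACGTAA", "GTAATTTT", minOverlap = 4)
#' @export
bestOverlap <- function(a, b, minOverlap = 40L, maxMismatchFrac = 0.02,
                        mode = c("substitution", "edit")) {
    mode <- match.arg(mode)
    a <- .as_seq_char(.as_seqset(a)); b <- .as_seq_char(.as_seqset(b))
    if (mode == "substitution") {
        fwd <- overlap_scan_cpp(a, b, as.integer(minOverlap), maxMismatchFrac)
        rev <- overlap_scan_cpp(a, revComp(b), as.integer(minOverlap),
                                maxMismatchFrac)
        if (fwd[1L] == 0L && rev[1L] == 0L) return(NULL)
        if (fwd[1L] >= rev[1L])
            list(length = fwd[1L], mismatches = fwd[2L], orientation = "+")
        else
            list(length = rev[1L], mismatches = rev[2L], orientation = "-")
    } else {
        fwd <- .edit_overlap(a, b, minOverlap, maxMismatchFrac)
        rev <- .edit_overlap(a, revComp(b), minOverlap, maxMismatchFrac)
        if (is.null(fwd) && is.null(rev)) return(NULL)
        if (is.null(rev) || (!is.null(fwd) && fwd$length >= rev$length))
            c(fwd, orientation = "+")
        else c(rev, orientation = "-")
    }
}

## indel-tolerant suffix/prefix overlap (alignment anchored at a's 3' end
## and b's 5' start, free elsewhere); `length` counts alignment columns
## and `mismatches` counts edits
.edit_overlap <- function(a, b, minOverlap, maxMismatchFrac) {
    r <- overlap_edit_cpp(a, b, as.integer(minOverlap), maxMismatchFrac)
    if (r$columns == 0L) return(NULL)
    list(length = r$columns, mismatches = r$edits,
         a_suffix_len = r$a_suffix_len, b_prefix_len = r$b_prefix_len)
}

## best merge candidate of focal contig `i` against contigs `js`:
## 4 junction layouts per pair (i->j, j->i, i->rc(j), rc(j)->i), preferring
## '+' layouts on overlap-length ties.  Returns a data.frame.
.pair_candidates <- function(i, js, seqs, rcs, minOverlap, frac) {
    if (length(js) == 0L)
        return(data.frame(j = integer(0), len = integer(0), mm = integer(0),
                          combo = integer(0)))
    targets <- seqs[js]
    m1 <- overlap_scan_suffix_cpp(seqs[i], targets, minOverlap, frac) # i->j
    m2 <- overlap_scan_prefix_cpp(targets, seqs[i], minOverlap, frac) # j->i
    m3 <- overlap_scan_suffix_cpp(seqs[i], rcs[js], minOverlap, frac) # i->rc j
    m4 <- overlap_scan_prefix_cpp(rcs[js], seqs[i], minOverlap, frac) # rc j->i
    lens <- cbind(m1[, 1L], m2[, 1L], m3[, 1L], m4[, 1L])
    mms <- cbind(m1[, 2L], m2[, 2L], m3[, 2L], m4[, 2L])
    combo <- max.col(lens, ties.method = "first")
    sel <- cbind(seq_along(js), combo)
    data.frame(j = js, len = lens[sel], mm = mms[sel], combo = combo)
}

## splice two sequences given a qualifying suffix(a)/prefix(b) overlap;
## the left (first) sequence wins inside the overlap
.splice <- function(a, b, ov_len) {
    paste0(a, substr(b, ov_len + 1L, nchar(b)))
}

#' Greedy overlap-layout-consensus assembly of a read set
#'
#' Repeatedly merges the sequence pair with the longest qualifying end
#' overlap (ties: larger combined length, then lexicographically smallest
#' id pair) until no pair qualifies.  The merged sequence takes the first
#' (left) sequence's bases inside the overlap and both non-overlapping
#' flanks.  Fully deterministic.
#'
#' @param reads a named `DNAStringSet` (or character vector).
#' @param minOverlap minimum qualifying overlap in bases.
#' @param maxMismatchFrac maximum mismatch fraction within an overlap.
#' @return A [ContigSet] sorted by decreasing length, provenance
#'   `repeat_resolved`.
#' @examples
#' tmpl <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
#' reads <- substring(tmpl, seq(1, 41, 10), seq(20, 60, 10))
#' greedyAssemble(reads, minOverlap = 5)
#' @export
greedyAssemble <- function(reads, minOverlap = 40L, maxMismatchFrac = 0.02) {
    reads <- .as_seqset(reads)
    if (length(reads) == 0L) stop("reads must be non-empty")
    seqs <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
    names(seqs) <- NULL
    rcs <- revComp(seqs)
    active <- rep(TRUE, length(seqs))
    minOverlap <- as.integer(minOverlap)

    ## best candidate per (unordered) pair, stored per focal index
    cand <- data.frame(j = integer(0), len = integer(0), mm = integer(0),
                       combo = integer(0), i = integer(0))
    add_cands <- function(i, js) {
        df <- .pair_candidates(i, js, seqs, rcs, minOverlap, maxMismatchFrac)
        df <- df[df$len > 0L, , drop = FALSE]
        if (nrow(df)) { df$i <- i; cand <<- rbind(cand, df) }
    }
    idxs <- which(active)
    for (p in seq_along(idxs)) {
        i <- idxs[p]
        js <- idxs[idxs > i]
        add_cands(i, js)
    }
    counter <- 0L
    while (nrow(cand) > 0L) {
        tot <- nchar(seqs)[cand$i] + nchar(seqs)[cand$j]
        id_pair <- pmin(ids[cand$i], ids[cand$j])
        id_pair2 <- pmax(ids[cand$i], ids[cand$j])
        ord <- order(-cand$len, -tot, id_pair, id_pair2)
        top <- cand[ord[1L], ]
        i <- top$i; j <- top$j
        merged <- switch(top$combo,
            .splice(seqs[i], seqs[j], top$len),
            .splice(seqs[j], seqs[i], top$len),
            .splice(seqs[i], rcs[j], top$len),
            .splice(rcs[j], seqs[i], top$len))
        counter <- counter + 1L
        seqs <- c(seqs, merged)
        rcs <- c(rcs, revComp(merged))
        ids <- c(ids, sprintf("ctg%d", counter))
        active[c(i, j)] <- FALSE
        active <- c(active, TRUE)
        new_i <- length(seqs)
        cand <- cand[cand$i != i & cand$j != i &
                     cand$i != j & cand$j != j, , drop = FALSE]
        add_cands(new_i, setdiff(which(active), new_i))
    }
    out <- seqs[active]
    names(out) <- ids[active]
    out <- out[order(-nchar(out), names(out))]
    ContigSet(out, provenance = "repeat_resolved",
              ids = paste0("rcontig_", seq_along(out)))
}
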