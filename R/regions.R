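## ---------------------------------------------------------------------------
## pileup consensus machinery (shared by anchor calling and contig polishing)
## ---------------------------------------------------------------------------

.CODE <- local({
    v <- rep(NA_integer_, 128L)
    v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
    v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
    v
})

## per-column base counts (5 x L: A,C,G,T,deletion) plus the inserted
## strings (with the column they precede) from the cigar-projected reads
.pileup_data <- function(starts, cigars, seqs, L) {
    idx_all <- vector("list", length(starts))
    ins_pos <- integer(0); ins_str <- character(0)
    for (i in seq_along(starts)) {
        cig <- cigars[i]; sq <- seqs[i]
        if (is.na(cig) || is.na(sq)) next
        ops <- GenomicAlignments::explodeCigarOps(cig)[[1L]]
        lens <- GenomicAlignments::explodeCigarOpLengths(cig)[[1L]]
        rp <- starts[i]; qp <- 1L
        pos <- integer(0); code <- integer(0)
        for (j in seq_along(ops)) {
            l <- lens[j]
            switch(ops[j],
                M = , "=" = , X = {
                    cd <- .CODE[utf8ToInt(substr(sq, qp, qp + l - 1L))]
                    pos <- c(pos, rp:(rp + l - 1L)); code <- c(code, cd)
                    rp <- rp + l; qp <- qp + l
                },
                I = {
                    if (rp >= 1L && rp <= L) {
                        ins_pos <- c(ins_pos, rp)
                        ins_str <- c(ins_str, substr(sq, qp, qp + l - 1L))
                    }
                    qp <- qp + l
                },
                D = , N = {
                    pos <- c(pos, rp:(rp + l - 1L))
                    code <- c(code, rep.int(5L, l))
                    rp <- rp + l
                },
                S = { qp <- qp + l },
                H = NULL)
        }
        keep <- !is.na(code) & pos >= 1L & pos <= L
        idx_all[[i]] <- (pos[keep] - 1L) * 5L + code[keep]
    }
    idx <- unlist(idx_all, use.names = FALSE)
    list(counts = matrix(tabulate(idx, nbins = 5L * L), nrow = 5L),
         ins_pos = ins_pos, ins_str = ins_str)
}

## majority call over columns [s, e] of the pileup; ties broken towards the
## reference base, then alphabetically (A<C<G<T), with deletion last.
## Columns where deletion wins contribute no base; positions where more
## than half of the covering reads insert a string get the modal insertion
## spliced in (this restores bases an error-bearing draft is missing).
.consensus_call <- function(pile, refcodes, s, e) {
    counts <- pile$counts[, s:e, drop = FALSE]
    w <- ncol(counts)
    rc <- refcodes[s:e]
    ref_bonus <- matrix(0L, 5L, w)
    ok <- !is.na(rc)
    ref_bonus[cbind(rc[ok], which(ok))] <- 8L
    score <- counts * 16L + ref_bonus + matrix(c(4L, 3L, 2L, 1L, 0L), 5L, w)
    winner <- max.col(t(score), ties.method = "first")
    chars <- c("A", "C", "G", "T", "")[winner]
    sel <- which(pile$ins_pos >= s & pile$ins_pos <= e)
    if (length(sel)) {
        depth <- colSums(counts)
        by_pos <- split(pile$ins_str[sel], pile$ins_pos[sel])
        for (pn in names(by_pos)) {
            p <- as.integer(pn) - s + 1L
            votes <- by_pos[[pn]]
            if (length(votes) > depth[p] / 2) {
                tab <- sort(table(votes), decreasing = TRUE)
                chars[p] <- paste0(names(tab)[1L], chars[p])
            }
        }
    }
    paste(chars, collapse = "")
}

## realign reads lacking a cigar (TSV-derived mappings) against their
## reference window so they can contribute to the pileup
.ensure_cigars <- function(mappings, reference) {
    mc <- S4Vectors::mcols(mappings)
    todo <- which(is.na(mc$cigar) & !is.na(mc$seq))
    if (length(todo) == 0L) return(mappings)
    refchar <- .as_seq_char(.as_seqset(reference))
    starts <- BiocGenerics::start(mappings)
    ends <- BiocGenerics::end(mappings)
    for (i in todo) {
        window <- substr(refchar, starts[i], ends[i])
        aln <- banded_read_align_cpp(mc$seq[i], window, 30L)
        cig <- aln$cigar
        ## anchor the cigar to the stated interval: pad unaligned window
        ## leading/trailing bases as deletions
        lead <- aln$ref_start - 1L
        trail <- nchar(window) - aln$ref_end
        if (lead > 0L) cig <- paste0(lead, "D", cig)
        if (trail > 0L) cig <- paste0(cig, trail, "D")
        mc$cigar[i] <- cig
    }
    S4Vectors::mcols(mappings) <- mc
    mappings
}

#' Call anchor contigs from a mapping pileup
#'
#' Maximal reference intervals with pileup depth at least `minDepth` become
#' contigs; each contig sequence is the column-wise majority base over the
#' reads aligned there (cigar-projected), with ties broken towards the
#' reference base and then alphabetically.  Columns where a deletion wins
#' are dropped from the consensus.
#'
#' @param mappings a [MappedReads].
#' @param reference the reference (single-sequence `DNAStringSet`).
#' @param minDepth minimum pileup depth.
#' @return A [ContigSet] sorted by `ref_start`, provenance `anchor`.
#' @export
callAnchorContigs <- function(mappings, reference, minDepth = 3L) {
    refset <- .as_seqset(reference)
    refchar <- .as_seq_char(refset)
    L <- nchar(refchar)
    empty <- ContigSet(Biostrings::DNAStringSet(), ids = character(0))
    if (length(mappings) == 0L) return(empty)
    mappings <- .ensure_cigars(mappings, refset)
    cov <- GenomicRanges::coverage(mappings)[[1L]]
    islands <- IRanges::slice(cov, lower = minDepth, rangesOnly = TRUE)
    if (length(islands) == 0L) return(empty)
    mc <- S4Vectors::mcols(mappings)
    pile <- .pileup_data(BiocGenerics::start(mappings), mc$cigar,
                         mc$seq, L)
    refcodes <- .CODE[utf8ToInt(refchar)]
    seqs <- character(length(islands))
    depth <- numeric(length(islands))
    for (i in seq_along(islands)) {
        s <- BiocGenerics::start(islands)[i]
        e <- BiocGenerics::end(islands)[i]
        seqs[i] <- .consensus_call(pile, refcodes, s, e)
        depth[i] <- mean(as.numeric(IRanges::Views(cov, islands[i])[[1L]]))
    }
    keep <- nchar(seqs) > 0L
    ContigSet(seqs[keep],
              ref_id = if (!is.null(names(refset))) names(refset)[1L] else "ref",
              ref_start = BiocGenerics::start(islands)[keep],
              ref_end = BiocGenerics::end(islands)[keep],
              provenance = "anchor", depth_mean = depth[keep],
              ids = paste0("anchor_", seq_len(sum(keep))))
}

#' Split contigs into anchors and repeat regions by gap size
#'
#' Contigs whose reference footprint is at least `gapSize` bases survive as
#' anchors; every maximal reference interval not covered by an anchor (the
#' discarded small-contig footprints plus uncovered gaps, merged when
#' adjacent) becomes one repeat region.  Anchors and repeat regions
#' partition the reference.
#'
#' @param contigs a [ContigSet] with reference coordinates (non-overlapping).
#' @param referenceLength reference length in bases.
#' @param gapSize the gap-size threshold in bases (contigs strictly shorter
#'   are discarded; 0 keeps every contig).
#' @return A list with `anchors` (a [ContigSet]) and `regions`
#'   (a [RepeatRegions], read bins still empty).
#' @export
filterSmallContigs <- function(contigs, referenceLength, gapSize = 500L) {
    referenceLength <- as.integer(referenceLength)
    fw <- contigInfo(contigs)$ref_end - contigInfo(contigs)$ref_start + 1L
    keep <- which(!is.na(fw) & fw >= gapSize)
    anchors <- contigs[keep]
    anchor_ir <- IRanges::reduce(IRanges::IRanges(
        contigInfo(anchors)$ref_start, contigInfo(anchors)$ref_end))
    gap_ir <- IRanges::gaps(anchor_ir, start = 1L, end = referenceLength)
    ref_id <- if (length(contigs)) contigInfo(contigs)$ref_id[1L] else "ref"
    gr <- GenomicRanges::GRanges(
        seqnames = rep(ref_id, length(gap_ir)), ranges = gap_ir,
        region_id = if (length(gap_ir)) paste0("region_", seq_along(gap_ir))
                    else character(0))
    list(anchors = anchors, regions = RepeatRegions(gr))
}

#' Bin mapped reads into repeat regions
#'
#' A read belongs to a region when its mapped interval intersects the
#' region expanded by `flank` bases on each side (clipped to the
#' reference).  A read may fall into several regions.
#'
#' @param mappings a [MappedReads].
#' @param regions a [RepeatRegions].
#' @param flank flank in bases.
#' @param referenceLength reference length for clipping (default: from the
#'   `seqlengths` of `mappings`).
#' @return The regions with the `read_ids` and `flank` metadata filled.
#' @export
binReads <- function(mappings, regions, flank = 400L,
                     referenceLength = NA_integer_) {
    if (is.na(referenceLength))
        referenceLength <- GenomeInfoDb::seqlengths(mappings)[1L]
    win_s <- pmax(1L, BiocGenerics::start(regions) - as.integer(flank))
    win_e <- pmin(as.integer(referenceLength),
                  BiocGenerics::end(regions) + as.integer(flank))
    hits_list <- vector("list", length(regions))
    rs <- BiocGenerics::start(mappings)
    re <- BiocGenerics::end(mappings)
    ids <- S4Vectors::mcols(mappings)$read_id
    for (i in seq_along(regions))
        hits_list[[i]] <- ids[rs <= win_e[i] & re >= win_s[i]]
    mc <- S4Vectors::mcols(regions)
    mc$read_ids <- IRanges::CharacterList(hits_list)
    mc$flank <- as.integer(flank)
    S4Vectors::mcols(regions) <- mc
    regions
}
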