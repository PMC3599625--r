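#' Polish a contig by majority consensus of its supporting reads
#'
#' Maps the reads back onto the draft contig with the built-in mapper and
#' replaces every column by the majority base (ties towards the draft base,
#' then alphabetically; majority deletions drop the column).  One round is
#' usually enough to remove the per-read errors a greedy layout leaves in
#' the draft.
#'
#' @param contig draft sequence (character or `DNAString`).
#' @param reads named `DNAStringSet` of supporting reads.
#' @param params a [MapperParams] used for the re-mapping.
#' @param rounds number of polish rounds.
#' @return The polished sequence (character scalar).
#' @export
polishContig <- function(contig, reads, params = MapperParams(),
                         rounds = 1L) {
    contig <- .as_seq_char(.as_seqset(contig))
    if (length(reads) == 0L) return(contig)
    ## reads only partially inside the draft still vote on the columns
    ## they do cover
    params@minAlignedFraction <- min(params@minAlignedFraction, 0.5)
    for (r in seq_len(rounds)) {
        if (nchar(contig) < params@k) break
        draft <- Biostrings::DNAStringSet(contig)
        names(draft) <- "draft"
        mp <- mapReads(reads, draft, params)
        if (length(mp) == 0L) break
        mc <- S4Vectors::mcols(mp)
        pile <- .pileup_data(BiocGenerics::start(mp), mc$cigar, mc$seq,
                             nchar(contig))
        polished <- .consensus_call(pile, .CODE[utf8ToInt(contig)], 1L,
                                    nchar(contig))
        if (polished == contig) { contig <- polished; break }
        contig <- polished
    }
    contig
}

## left/right flanking anchors of one region (NULL when the region touches
## a reference end or no anchor lies on that side)
.flanking_anchors <- function(region_start, region_end, anchors) {
    if (length(anchors) == 0L) return(list(left = NULL, right = NULL))
    info <- contigInfo(anchors)
    left_i <- which(info$ref_end < region_start)
    right_i <- which(info$ref_start > region_end)
    list(
        left = if (length(left_i)) anchors[left_i[which.max(info$ref_end[left_i])]]
               else NULL,
        right = if (length(right_i))
                    anchors[right_i[which.min(info$ref_start[right_i])]]
                else NULL)
}

## one directed extension walk: grow `contig` rightwards read by read,
## recruiting candidates from the whole mapped read set at every step but
## preferring reads binned to this region; stops on closure against
## `closeSeed`, exhaustion, or the length cap
.extend_right <- function(contig, seqs, rcs, ids, bin_set, used, lookup,
                          closeSeed, cfg, maxLen) {
    minov <- cfg@minOverlap
    frac <- cfg@maxMergeMismatchFrac
    ## edit-tolerant fallbacks compare two error-bearing sequences, whose
    ## pairwise difference rate is about twice the per-read error rate, so
    ## they get twice the budget of clean-sequence overlaps
    frac2 <- min(0.10, 2 * frac)
    max_read <- max(nchar(seqs))
    closed <- FALSE
    repeat {
        if (!is.null(closeSeed)) {
            ov <- overlap_scan_cpp(contig, closeSeed, minov, frac)
            if (ov[1L] > 0L) {
                contig <- .splice(contig, closeSeed, ov[1L])
                closed <- TRUE
                break
            }
            ## noisy walk tails carry indels; retry with edits allowed
            nc0 <- nchar(contig)
            tail0 <- substr(contig, max(1L, nc0 - max_read - 50L), nc0)
            eo <- .edit_overlap(tail0, closeSeed, minov, frac2)
            if (!is.null(eo)) {
                contig <- paste0(contig,
                                 substr(closeSeed, eo$b_prefix_len + 1L,
                                        nchar(closeSeed)))
                closed <- TRUE
                break
            }
        }
        if (nchar(contig) > maxLen) break
        nc <- nchar(contig)
        tail_len <- min(nc, max_read + 10L)
        tailseq <- substr(contig, nc - tail_len + 1L, nc)
        cand <- unique(c(lookupCandidates(lookup, tailseq),
                         lookupCandidates(lookup, revComp(tailseq))))
        cand <- cand[!(ids[cand] %in% used)]
        if (length(cand) == 0L) break
        pick <- NULL
        for (pool in list(cand[ids[cand] %in% bin_set],
                          cand[!(ids[cand] %in% bin_set)])) {
            if (length(pool) == 0L) next
            fw <- overlap_scan_suffix_cpp(tailseq, seqs[pool], minov, frac)
            rv <- overlap_scan_suffix_cpp(tailseq, rcs[pool], minov, frac)
            gain_f <- nchar(seqs[pool]) - fw[, 1L]
            gain_r <- nchar(seqs[pool]) - rv[, 1L]
            ok_f <- fw[, 1L] > 0L & gain_f > 0L
            ok_r <- rv[, 1L] > 0L & gain_r > 0L
            len_best <- pmax(ifelse(ok_f, fw[, 1L], 0L),
                             ifelse(ok_r, rv[, 1L], 0L))
            if (all(len_best == 0L)) next
            ord <- order(-len_best, ids[pool])
            b <- ord[1L]
            use_fwd <- ok_f[b] && (!ok_r[b] || fw[b, 1L] >= rv[b, 1L])
            pick <- list(idx = pool[b],
                         seq = if (use_fwd) seqs[pool[b]] else rcs[pool[b]],
                         cut = if (use_fwd) fw[b, 1L] else rv[b, 1L])
            break
        }
        if (is.null(pick)) {
            ## substitution-only scan found nothing: indel-tolerant retry,
            ## restricted to reads sharing a k-mer with the last few tip
            ## bases so the bounded subset holds actual extension candidates
            tip <- substr(contig, max(1L, nc - 59L), nc)
            tipcand <- unique(c(lookupCandidates(lookup, tip),
                                lookupCandidates(lookup, revComp(tip))))
            tipcand <- tipcand[!(ids[tipcand] %in% used)]
            pool <- tipcand[order(!(ids[tipcand] %in% bin_set),
                                  ids[tipcand])]
            pool <- pool[seq_len(min(length(pool), 20L))]
            best_cols <- 0L
            for (ci in pool) {
                for (sq in c(seqs[ci], rcs[ci])) {
                    eo <- .edit_overlap(tailseq, sq, minov, frac2)
                    if (!is.null(eo) && eo$length > best_cols &&
                        nchar(sq) - eo$b_prefix_len > 0L) {
                        best_cols <- eo$length
                        pick <- list(idx = ci, seq = sq,
                                     cut = eo$b_prefix_len)
                    }
                }
            }
        }
        if (is.null(pick)) break
        contig <- paste0(contig, substr(pick$seq, pick$cut + 1L,
                                        nchar(pick$seq)))
        used <- c(used, ids[pick$idx])
    }
    list(contig = contig, used = used, closed = closed)
}

#' Re-assemble one repeat region from its reads
#'
#' Iterative, locally seeded re-assembly of a repeat region.  The walk
#' starts from the flanking anchors' end windows (so the result is anchored
#' to this locus even when repeat copies elsewhere are identical), extends
#' read by read through the region, and at every step recruits candidate
#' reads from the whole mapped read set — reads binned to this region are
#' preferred, which keeps locus-specific flank reads ahead of reads from
#' other repeat copies.  Iteration stops when the contig set no longer
#' changes or after `maxIters` passes.  When a region has no flanking
#' anchors at all, a plain [greedyAssemble] of the bin with iterative
#' recruitment is used instead.  Resulting contigs are polished by majority
#' consensus of the reads they used.
#'
#' @param region a single-range [RepeatRegions] (binned).
#' @param mappings the full [MappedReads] set.
#' @param reads named `DNAStringSet` of all reads.
#' @param anchors the anchor [ContigSet].
#' @param cfg a [PipelineConfig] (`flank` must be resolved, not `NA`).
#' @param lookup optional precomputed [readKmerLookup] over the mapped
#'   reads (built on the fly when missing).
#' @return A [ContigSet] of region contigs (possibly empty), provenance
#'   `repeat_resolved`, with approximate reference placement.
#' @export
resolveRegion <- function(region, mappings, reads, anchors, cfg,
                          lookup = NULL) {
    stopifnot(length(region) == 1L)
    flank <- cfg@flank
    if (is.na(flank)) stop("cfg@flank must be resolved before resolveRegion")
    mapped_ids <- unique(S4Vectors::mcols(mappings)$read_id)
    pool <- reads[names(reads) %in% mapped_ids]
    empty <- ContigSet(Biostrings::DNAStringSet(), ids = character(0))
    bin_set <- S4Vectors::mcols(region)$read_ids[[1L]]
    if (length(pool) == 0L) return(empty)
    seqs <- as.character(pool)
    ids <- names(pool)
    names(seqs) <- NULL
    rcs <- revComp(seqs)
    if (is.null(lookup)) lookup <- readKmerLookup(seqs)
    fl <- .flanking_anchors(BiocGenerics::start(region),
                            BiocGenerics::end(region), anchors)
    rstart <- BiocGenerics::start(region)
    rend <- BiocGenerics::end(region)
    maxLen <- (rend - rstart + 1L) + 2L * flank + 4L * max(nchar(seqs))

    if (is.null(fl$left) && is.null(fl$right)) {
        if (length(bin_set) == 0L) return(empty)
        out <- .resolve_unanchored(bin_set, seqs, rcs, ids, lookup, cfg)
    } else {
        out <- .resolve_anchored(fl, seqs, rcs, ids, bin_set, lookup, cfg,
                                 rstart, rend, maxLen, flank)
    }
    if (length(out$contigs) == 0L) return(empty)
    support <- unique(c(bin_set, out$used))
    support_reads <- pool[names(pool) %in% support]
    polished <- vapply(out$contigs, polishContig, "",
                       reads = support_reads, params = cfg@mapper,
                       USE.NAMES = FALSE)
    ## unclosed regions leave two polished partials; with the per-read
    ## errors consensus-corrected, a deep middle overlap may now qualify
    if (length(polished) == 2L) {
        ov <- overlap_scan_cpp(polished[1L], polished[2L], cfg@minOverlap,
                               cfg@maxMergeMismatchFrac)
        eo <- NULL
        if (ov[1L] == 0L) {
            cap <- 4500L
            n1 <- nchar(polished[1L])
            ## partial tips are thin-coverage, so residual errors cluster
            ## there; allow the doubled edit budget of the fallbacks
            eo <- .edit_overlap(
                substr(polished[1L], max(1L, n1 - cap + 1L), n1),
                substr(polished[2L], 1L, min(nchar(polished[2L]), cap)),
                cfg@minOverlap, min(0.10, 2 * cfg@maxMergeMismatchFrac))
        }
        merged <- if (ov[1L] > 0L)
            .splice(polished[1L], polished[2L], ov[1L])
        else if (!is.null(eo))
            paste0(polished[1L], substr(polished[2L], eo$b_prefix_len + 1L,
                                        nchar(polished[2L])))
        else NULL
        if (!is.null(merged)) {
            polished <- merged
            out$ref_start <- out$ref_start[1L]
        }
    }
    ContigSet(polished,
              ref_id = as.character(GenomeInfoDb::seqnames(region))[1L],
              ref_start = out$ref_start,
              ref_end = out$ref_start + nchar(polished) - 1L,
              provenance = "repeat_resolved",
              ids = paste0(S4Vectors::mcols(region)$region_id, "_ctg",
                           seq_along(polished)))
}

.resolve_anchored <- function(fl, seqs, rcs, ids, bin_set, lookup, cfg,
                              rstart, rend, maxLen, flank) {
    left_seed <- right_seed <- NULL
    left_ref_start <- NA_integer_
    if (!is.null(fl$left)) {
        aseq <- as.character(contigSeqs(fl$left))[1L]
        w <- min(nchar(aseq), flank)
        left_seed <- substr(aseq, nchar(aseq) - w + 1L, nchar(aseq))
        left_ref_start <- contigInfo(fl$left)$ref_end - w + 1L
    }
    if (!is.null(fl$right)) {
        aseq <- as.character(contigSeqs(fl$right))[1L]
        right_seed <- substr(aseq, 1L, min(nchar(aseq), flank))
    }
    used <- character(0)
    contigs <- character(0)
    ref_start <- integer(0)
    prev <- NULL
    for (iter in seq_len(cfg@maxIters)) {
        used <- character(0)
        contigs <- character(0)
        ref_start <- integer(0)
        closed <- FALSE
        if (!is.null(left_seed)) {
            walk <- .extend_right(left_seed, seqs, rcs, ids, bin_set, used,
                                  lookup, right_seed, cfg, maxLen)
            used <- walk$used
            closed <- walk$closed
            contigs <- walk$contig
            ref_start <- left_ref_start
        }
        if (!closed && !is.null(right_seed)) {
            ## walk leftwards from the right anchor in the rc frame
            walk2 <- .extend_right(revComp(right_seed), seqs, rcs, ids,
                                   bin_set, used, lookup,
                                   if (length(contigs)) revComp(contigs[1L])
                                   else (if (is.null(left_seed)) NULL
                                         else revComp(left_seed)),
                                   cfg, maxLen)
            used <- walk2$used
            back <- revComp(walk2$contig)
            if (walk2$closed) {
                contigs <- back
                ref_start <- if (is.na(left_ref_start))
                    rstart - (nchar(back) -
                              (rend - rstart + 1L) - flank) else left_ref_start
                closed <- TRUE
            } else if (length(contigs)) {
                ## two partials; do they already meet in the middle?
                ## (deep noisy overlaps are retried after polishing)
                ov <- overlap_scan_cpp(contigs[1L], back, cfg@minOverlap,
                                       cfg@maxMergeMismatchFrac)
                if (ov[1L] > 0L) {
                    contigs <- .splice(contigs[1L], back, ov[1L])
                    closed <- TRUE
                } else {
                    right_anchor_start <- contigInfo(fl$right)$ref_start
                    contigs <- c(contigs, back)
                    ref_start <- c(ref_start,
                                   right_anchor_start + flank - nchar(back))
                }
            } else {
                right_anchor_start <- contigInfo(fl$right)$ref_start
                contigs <- back
                ref_start <- right_anchor_start + flank - nchar(back)
            }
        }
        state <- paste(contigs, collapse = "|")
        if (identical(state, prev)) break
        prev <- state
        if (closed) break
    }
    list(contigs = contigs, used = used, ref_start = as.integer(ref_start))
}

## spec-shaped fallback when no anchor flanks the region: greedy-assemble
## the bin, recruit reads overlapping the contig ends, repeat to a fixed
## point (or maxIters)
.resolve_unanchored <- function(bin_set, seqs, rcs, ids, lookup, cfg) {
    cur_ids <- intersect(bin_set, ids)
    if (length(cur_ids) == 0L)
        return(list(contigs = character(0), used = character(0),
                    ref_start = integer(0)))
    prev <- NULL
    contigs <- character(0)
    for (iter in seq_len(cfg@maxIters)) {
        set <- setNames(seqs[match(cur_ids, ids)], cur_ids)
        asm <- greedyAssemble(set, cfg@minOverlap, cfg@maxMergeMismatchFrac)
        contigs <- as.character(contigSeqs(asm))
        state <- paste(sort(contigs), collapse = "|")
        if (identical(state, prev)) break
        prev <- state
        recruits <- character(0)
        for (ctg in contigs) {
            for (w in c(substr(ctg, max(1L, nchar(ctg) - 500L), nchar(ctg)),
                        substr(ctg, 1L, min(nchar(ctg), 500L)))) {
                cand <- unique(c(lookupCandidates(lookup, w),
                                 lookupCandidates(lookup, revComp(w))))
                cand <- cand[!(ids[cand] %in% cur_ids)]
                for (ci in cand) {
                    q <- function(a, b) overlap_scan_cpp(
                        a, b, cfg@minOverlap, cfg@maxMergeMismatchFrac)[1L] > 0L
                    if (q(ctg, seqs[ci]) || q(seqs[ci], ctg) ||
                        q(ctg, rcs[ci]) || q(rcs[ci], ctg))
                        recruits <- c(recruits, ids[ci])
                }
            }
        }
        if (length(recruits) == 0L) break
        cur_ids <- union(cur_ids, recruits)
    }
    list(contigs = contigs, used = cur_ids, ref_start = NA_integer_)
}
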