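## max/min over possibly all-NA coordinate sets without the -Inf warning
.max_na <- function(...) {
    v <- c(...); v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_integer_
}
.min_na <- function(...) {
    v <- c(...); v <- v[!is.na(v)]
    if (length(v)) min(v) else NA_integer_
}

## depth-aware splice: on a qualifying suffix(a)/prefix(b) overlap the side
## with higher mean depth contributes the overlap bases
.splice_depth <- function(a, b, cut_a, cut_b, a_depth, b_depth) {
    if (!is.na(b_depth) && (is.na(a_depth) || b_depth > a_depth))
        paste0(substr(a, 1L, nchar(a) - cut_a), b)
    else paste0(a, substr(b, cut_b + 1L, nchar(b)))
}

## suffix(a)/prefix(b) junction in one orientation: strict scan first,
## edit-tolerant fallback on capped end windows second
.junction_pair <- function(a, b, cfg) {
    ov <- overlap_scan_cpp(a, b, cfg@minOverlap, cfg@maxMergeMismatchFrac)
    if (ov[1L] > 0L)
        return(list(cut_a = ov[1L], cut_b = ov[1L], len = ov[1L]))
    cap <- 800L
    na <- nchar(a)
    eo <- .edit_overlap(substr(a, max(1L, na - cap + 1L), na),
                        substr(b, 1L, min(nchar(b), cap)),
                        cfg@minOverlap, cfg@maxMergeMismatchFrac)
    if (is.null(eo)) NULL
    else list(cut_a = eo$a_suffix_len, cut_b = eo$b_prefix_len,
              len = eo$length)
}

## best qualifying overlap of `cur` 3' end against the 5' start of each of
## `pieces` (or their reverse complements).  A strict substitution-only
## scan is tried first; residual indels near contig tips are caught by an
## edit-tolerant fallback on capped end windows.  Returns the piece index,
## orientation, and how many bases to cut from each side at the splice.
.best_junction <- function(cur, pieces, cfg) {
    if (length(pieces) == 0L) return(NULL)
    fw <- overlap_scan_suffix_cpp(cur, pieces, cfg@minOverlap,
                                  cfg@maxMergeMismatchFrac)
    rv <- overlap_scan_suffix_cpp(cur, revComp(pieces), cfg@minOverlap,
                                  cfg@maxMergeMismatchFrac)
    len <- pmax(fw[, 1L], rv[, 1L])
    if (max(len) > 0L) {
        b <- which.max(len)
        use_fwd <- fw[b, 1L] >= rv[b, 1L]
        l <- if (use_fwd) fw[b, 1L] else rv[b, 1L]
        return(list(i = b, orientation = if (use_fwd) "+" else "-",
                    cut_a = l, cut_b = l, len = l))
    }
    cap <- 800L
    nc <- nchar(cur)
    a_tail <- substr(cur, max(1L, nc - cap + 1L), nc)
    best <- NULL
    for (b in seq_along(pieces)) {
        for (orient in c("+", "-")) {
            p <- if (orient == "+") pieces[b] else revComp(pieces[b])
            eo <- .edit_overlap(a_tail, substr(p, 1L, min(nchar(p), cap)),
                                cfg@minOverlap, cfg@maxMergeMismatchFrac)
            if (!is.null(eo) && (is.null(best) || eo$length > best$len))
                best <- list(i = b, orientation = orient,
                             cut_a = eo$a_suffix_len,
                             cut_b = eo$b_prefix_len, len = eo$length)
        }
    }
    best
}

#' Stitch anchors and repeat-resolved contigs into final contigs
#'
#' Walks the reference left to right.  At each junction the current merged
#' contig's 3' end is joined to the next piece's 5' start (or its reverse
#' complement) when a qualifying end overlap exists, splicing by overlap
#' consensus (the higher-depth side wins inside the overlap).  Repeat-region
#' contigs may chain across a junction; on failure the current contig is
#' closed and a new one starts.  Region contigs that merge nowhere are
#' emitted unchanged.  Output contigs get provenance `merged` and stable
#' ids `final_1, final_2, ...` in decreasing length order.
#'
#' @param anchors anchor [ContigSet] (sorted by `ref_start`).
#' @param regions a [RepeatRegions] (defines junction order).
#' @param regionContigs list of [ContigSet], one per region (same order).
#' @param cfg a [PipelineConfig].
#' @param referenceLength reference length in bases.
#' @return A [ContigSet] of final contigs.
#' @export
stitchContigs <- function(anchors, regions, regionContigs, cfg,
                          referenceLength) {
    ainfo <- contigInfo(anchors)
    aord <- order(ainfo$ref_start)
    rord <- order(BiocGenerics::start(regions))
    ## ordered elements along the reference
    elements <- list()
    ai <- 1L; ri <- 1L
    while (ai <= length(anchors) || ri <= length(regions)) {
        a_pos <- if (ai <= length(anchors))
            ainfo$ref_start[aord[ai]] else Inf
        r_pos <- if (ri <= length(regions))
            BiocGenerics::start(regions)[rord[ri]] else Inf
        if (a_pos <= r_pos) {
            elements[[length(elements) + 1L]] <-
                list(type = "anchor", idx = aord[ai])
            ai <- ai + 1L
        } else {
            elements[[length(elements) + 1L]] <-
                list(type = "region", idx = rord[ri])
            ri <- ri + 1L
        }
    }

    finals <- list()   # list of list(seq, start, end, depth)
    emit <- function(piece) finals[[length(finals) + 1L]] <<- piece
    cur <- NULL
    pending_seq <- character(0)
    pending_start <- integer(0)

    grow_right <- function(cur) {
        repeat {
            j <- .best_junction(cur$seq, pending_seq, cfg)
            if (is.null(j)) return(cur)
            p <- if (j$orientation == "+") pending_seq[j$i]
                 else revComp(pending_seq[j$i])
            cur$seq <- .splice_depth(cur$seq, p, j$cut_a, j$cut_b,
                                     cur$depth, NA_real_)
            cur$end <- .max_na(cur$end,
                               pending_start[j$i] + nchar(p) - 1L)
            pending_seq <<- pending_seq[-j$i]
            pending_start <<- pending_start[-j$i]
        }
    }
    grow_left_of <- function(piece) {
        ## extend an anchor's 5' side with pending region contigs
        repeat {
            if (length(pending_seq) == 0L) return(piece)
            best <- NULL
            for (b in seq_along(pending_seq)) {
                for (orient in c("+", "-")) {
                    p <- if (orient == "+") pending_seq[b]
                         else revComp(pending_seq[b])
                    jp <- .junction_pair(p, piece$seq, cfg)
                    if (!is.null(jp) &&
                        (is.null(best) || jp$len > best$len)) {
                        best <- jp; best$i <- b; best$p <- p
                    }
                }
            }
            if (is.null(best)) return(piece)
            piece$seq <- .splice_depth(best$p, piece$seq, best$cut_a,
                                       best$cut_b, NA_real_, piece$depth)
            piece$start <- .min_na(piece$start, pending_start[best$i])
            pending_seq <<- pending_seq[-best$i]
            pending_start <<- pending_start[-best$i]
        }
    }

    for (el in elements) {
        if (el$type == "region") {
            rc <- regionContigs[[el$idx]]
            if (!is.null(rc) && length(rc)) {
                pending_seq <- as.character(contigSeqs(rc))
                pending_start <- contigInfo(rc)$ref_start
            }
            next
        }
        a <- anchors[el$idx]
        piece <- list(seq = as.character(contigSeqs(a))[1L],
                      start = contigInfo(a)$ref_start,
                      end = contigInfo(a)$ref_end,
                      depth = contigInfo(a)$depth_mean)
        if (is.null(cur)) {
            cur <- grow_left_of(piece)
        } else {
            cur <- grow_right(cur)
            j <- .best_junction(cur$seq, piece$seq, cfg)
            if (is.null(j)) {
                piece <- grow_left_of(piece)
                j <- .best_junction(cur$seq, piece$seq, cfg)
            }
            if (!is.null(j)) {
                p <- if (j$orientation == "+") piece$seq else revComp(piece$seq)
                cur$seq <- .splice_depth(cur$seq, p, j$cut_a, j$cut_b,
                                         cur$depth, piece$depth)
                cur$end <- .max_na(cur$end, piece$end)
                cur$depth <- .max_na(cur$depth, piece$depth)
            } else {
                emit(cur)
                cur <- piece
            }
        }
        ## leftover region contigs that merged nowhere
        for (k in seq_along(pending_seq))
            emit(list(seq = pending_seq[k], start = pending_start[k],
                      end = pending_start[k] + nchar(pending_seq[k]) - 1L,
                      depth = NA_real_))
        pending_seq <- character(0)
        pending_start <- integer(0)
    }
    if (!is.null(cur)) {
        cur <- grow_right(cur)
        emit(cur)
    }
    for (k in seq_along(pending_seq))
        emit(list(seq = pending_seq[k], start = pending_start[k],
                  end = pending_start[k] + nchar(pending_seq[k]) - 1L,
                  depth = NA_real_))

    if (length(finals) == 0L)
        return(ContigSet(Biostrings::DNAStringSet(), ids = character(0)))

    seqsv <- vapply(finals, `[[`, "", "seq")
    starts <- vapply(finals, function(x) as.integer(x$start), integer(1))
    ends <- vapply(finals, function(x) as.integer(x$end), integer(1))

    if (cfg@circular && length(seqsv) >= 1L) {
        if (length(seqsv) == 1L) {
            s <- seqsv[1L]
            w <- min(nchar(s) - 1L, 5000L)
            ov <- overlap_scan_cpp(substr(s, nchar(s) - w + 1L, nchar(s)),
                                   substr(s, 1L, w), cfg@minOverlap,
                                   cfg@maxMergeMismatchFrac)
            if (ov[1L] > 0L)
                seqsv[1L] <- substr(s, 1L, nchar(s) - ov[1L])
        } else {
            last <- length(seqsv)
            ov <- overlap_scan_cpp(seqsv[last], seqsv[1L], cfg@minOverlap,
                                   cfg@maxMergeMismatchFrac)
            if (ov[1L] > 0L) {
                seqsv[1L] <- .splice(seqsv[last], seqsv[1L], ov[1L])
                starts[1L] <- .min_na(starts[1L], starts[last])
                ends[1L] <- .max_na(ends[1L], ends[last])
                seqsv <- seqsv[-last]; starts <- starts[-last]
                ends <- ends[-last]
            }
        }
    }
    ord <- order(-nchar(seqsv), starts)
    ref_id <- if (length(anchors)) contigInfo(anchors)$ref_id[1L] else "ref"
    ContigSet(seqsv[ord], ref_id = ref_id, ref_start = starts[ord],
              ref_end = ends[ord], provenance = "merged",
              ids = paste0("final_", seq_along(ord)))
}

#' Run the full re-assembly pipeline
#'
#' Map (unless a mapping is supplied) → call anchor contigs → filter by gap
#' size into anchors and repeat regions → bin reads → re-assemble every
#' repeat region iteratively → stitch → metrics.  Deterministic for fixed
#' inputs and configuration.
#'
#' @param reads named `DNAStringSet` of reads.
#' @param reference single-sequence reference (`DNAStringSet`).
#' @param cfg a [PipelineConfig].
#' @param mappings optional precomputed [MappedReads] (e.g. from
#'   [readMappings]); when `NULL` the built-in mapper is used.
#' @param verbose log per-stage counts via `message()`.
#' @return A [ReassemblyResult].
#' @examples
#' tr <- makeGenome(5000, seed = 3)
#' rs <- simulateReads(tr, ReadSimConfig(coverage = 12, meanLen = 300,
#'     subRate = 0, insRate = 0, delRate = 0, seed = 4))
#' res <- runPipeline(rs$reads, truthGenome(tr), verbose = FALSE)
#' metrics(res)
#' @export
runPipeline <- function(reads, reference, cfg = PipelineConfig(),
                        mappings = NULL, verbose = TRUE) {
    reference <- .as_seqset(reference)
    if (is.null(names(reference))) names(reference) <- "ref"
    reads <- .as_seqset(reads)
    L <- Biostrings::width(reference)[1L]
    say <- function(...) if (verbose) message(...)
    if (is.na(cfg@flank))
        cfg@flank <- if (length(reads))
            as.integer(round(mean(Biostrings::width(reads)))) else 400L
    if (is.null(mappings)) {
        say("mapping ", length(reads), " reads")
        mappings <- mapReads(reads, reference, cfg@mapper,
                             verbose = verbose)
    } else {
        mappings <- .ensure_cigars(mappings, reference)
    }
    say("  mapped: ", length(mappings), "/", length(reads))
    contigs <- callAnchorContigs(mappings, reference, cfg@minDepth)
    fs <- filterSmallContigs(contigs, L, cfg@gapSize)
    anchors <- fs$anchors
    regions <- binReads(mappings, fs$regions, cfg@flank, L)
    say("  anchors: ", length(anchors), "; repeat regions: ",
        length(regions))
    mapped_ids <- unique(S4Vectors::mcols(mappings)$read_id)
    pool <- reads[names(reads) %in% mapped_ids]
    lookup <- if (length(pool)) readKmerLookup(as.character(pool)) else NULL
    regionContigs <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        regionContigs[[i]] <- resolveRegion(regions[i], mappings, reads,
                                            anchors, cfg, lookup)
    }
    closed_guess <- sum(vapply(regionContigs, function(x)
        length(x) == 1L, logical(1)))
    say("  regions with a single re-assembled contig: ", closed_guess,
        "/", length(regions))
    final <- stitchContigs(anchors, regions, regionContigs, cfg, L)
    say("  final contigs: ", length(final))
    am <- assemblyMetrics(final, anchors, reference)
    new("ReassemblyResult", final = final, anchors = anchors,
        regions = regions, regionContigs = regionContigs,
        mappings = mappings, metrics = am, config = cfg)
}
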