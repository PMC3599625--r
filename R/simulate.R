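#' Generate a genome with planted repeat families
#'
#' Background sequence is i.i.d. uniform over ACGT from the seeded
#' generator.  Each [RepeatSpec] plants a repeat family at non-overlapping
#' positions (pairwise separated by at least `minSpacing` bases so distinct
#' copies are flanked by unique sequence): `dispersed` copies are scattered,
#' `tandem` copies form one adjacent block, and `inverted` places two
#' copies with the second equal to the reverse complement of the first —
#' the structure of the chloroplast large inverted repeat.  Per-copy
#' divergence substitutes that fraction of bases in every copy after the
#' first.  Deterministic for fixed arguments.
#'
#' @param length genome length in bases (>= 1000).
#' @param repeats a list of [RepeatSpec] objects.
#' @param seed RNG seed.
#' @param minSpacing minimum distance in bases between planted intervals
#'   (and from the genome ends).
#' @return A [SimTruth] with the genome and the planted repeat intervals
#'   (read origins empty until [simulateReads] fills them).
#' @examples
#' tr <- makeGenome(20000, list(RepeatSpec("dispersed", 1000, 3)), seed = 1)
#' truthRepeats(tr)
#' @export
makeGenome <- function(length, repeats = list(), seed = 1L,
                       minSpacing = 2000L) {
    length <- as.integer(length)
    if (length < 1000L) stop("genome length must be >= 1000")
    for (r in repeats) stopifnot(is(r, "RepeatSpec"))
    footprint <- sum(vapply(repeats, function(r)
        r@unitLength * r@copies, numeric(1)))
    if (footprint >= length)
        stop("total repeat footprint (", footprint,
             ") must be smaller than the genome length (", length, ")")
    withr::with_seed(as.integer(seed), {
        genome <- sample(BASES, length, replace = TRUE)
        placed <- IRanges::IRanges()
        iv_list <- list()
        for (fi in seq_along(repeats)) {
            r <- repeats[[fi]]
            unit <- sample(BASES, r@unitLength, replace = TRUE)
            ivs <- if (r@kind == "tandem")
                .place_intervals(length, r@unitLength * r@copies, 1L,
                                 placed, minSpacing)
            else
                .place_intervals(length, r@unitLength, r@copies,
                                 placed, minSpacing)
            placed <- c(placed, ivs)
            copies <- switch(r@kind,
                tandem = list(rep.int(unit, r@copies)),
                inverted = list(unit,
                    strsplit(revComp(paste(unit, collapse = "")), "")[[1L]]),
                dispersed = rep(list(unit), r@copies))
            for (ci in seq_along(copies)) {
                cp <- copies[[ci]]
                if (ci > 1L && r@divergence > 0) {
                    nmut <- round(r@divergence * base::length(cp))
                    if (nmut > 0) {
                        at <- sample.int(base::length(cp), nmut)
                        cp[at] <- vapply(cp[at], function(b)
                            sample(setdiff(BASES, b), 1L), "")
                    }
                }
                s <- BiocGenerics::start(ivs)[ci]
                genome[s:(s + base::length(cp) - 1L)] <- cp
            }
            iv_list[[fi]] <- GenomicRanges::GRanges(
                seqnames = "genome", ranges = ivs,
                family = sprintf("fam%d", fi), kind = r@kind,
                copy = seq_along(ivs))
        }
        gseq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
        names(gseq) <- "genome"
        reps <- if (base::length(iv_list)) do.call(c, iv_list)
                else GenomicRanges::GRanges()
        new("SimTruth", genome = gseq, repeats = sort(reps),
            readOrigins = S4Vectors::DataFrame(
                read_id = character(0), start = integer(0),
                strand = character(0), length = integer(0)))
    })
}

## rejection-sample `n` non-overlapping intervals of width `w` keeping
## `spacing` bases from already-placed intervals and the genome ends
.place_intervals <- function(L, w, n, placed, spacing) {
    out <- IRanges::IRanges()
    tries <- 0L
    while (base::length(out) < n) {
        if ((tries <- tries + 1L) > 10000L)
            stop("could not place repeat copies; genome too small for the ",
                 "requested repeat footprint and spacing")
        s <- sample.int(L - w - 2L * spacing, 1L) + spacing
        cand <- IRanges::IRanges(s, width = w)
        pad <- IRanges::IRanges(max(1L, s - spacing),
                                min(L, s + w - 1L + spacing))
        if (!any(IRanges::overlapsAny(pad, placed)) &&
            !any(IRanges::overlapsAny(pad, out)))
            out <- c(out, cand)
    }
    out
}

#' Simulate pyrosequencing-style reads from a genome
#'
#' Read count is `round(coverage * genome_length / meanLen)`; start
#' positions are uniform over valid windows, strand is uniform, and lengths
#' follow a truncated normal (minimum 30 bases).  Errors are applied per
#' base: substitutions at `subRate`, insertions/deletions at
#' `insRate`/`delRate` multiplied by `homopolymerMultiplier` inside
#' homopolymer runs of length >= 3 (the signature error mode of 454 and
#' IonTorrent chemistry).  Deterministic for a fixed `seed`.
#'
#' @param truth a [SimTruth] from [makeGenome] (or any single-sequence
#'   genome wrapped in one).
#' @param cfg a [ReadSimConfig].
#' @return A list with `reads` (named `DNAStringSet`, `read_<i>`) and
#'   `truth` (the input with `readOrigins` filled: true forward-strand
#'   1-based start, strand, and error-free length of each read).
#' @examples
#' tr <- makeGenome(10000, seed = 1)
#' rs <- simulateReads(tr, ReadSimConfig(coverage = 2, seed = 7))
#' length(rs$reads)
#' @export
simulateReads <- function(truth, cfg) {
    stopifnot(is(truth, "SimTruth"), is(cfg, "ReadSimConfig"))
    gchar <- as.character(truth@genome[[1L]])
    L <- nchar(gchar)
    if (grepl("N", gchar, fixed = TRUE))
        stop("simulated reads require an N-free genome")
    template <- if (cfg@circular)
        paste0(gchar, substr(gchar, 1L, cfg@meanLen)) else gchar
    Lt <- nchar(template)
    n <- round(cfg@coverage * L / cfg@meanLen)
    if (n == 0L) {
        origins <- S4Vectors::DataFrame(read_id = character(0),
                                        start = integer(0),
                                        strand = character(0),
                                        length = integer(0))
        truth@readOrigins <- origins
        return(list(reads = Biostrings::DNAStringSet(), truth = truth))
    }
    withr::with_seed(cfg@seed, {
        lens <- pmin(Lt, pmax(30L, as.integer(round(
            rnorm(n, cfg@meanLen, cfg@lenSd)))))
        starts <- vapply(lens, function(l)
            sample.int(Lt - l + 1L, 1L), integer(1))
        strands <- sample(c("+", "-"), n, replace = TRUE)
        ids <- sprintf("read_%0*d", nchar(n), seq_len(n))
        seqs <- character(n)
        for (i in seq_len(n)) {
            s <- substr(template, starts[i], starts[i] + lens[i] - 1L)
            if (strands[i] == "-") s <- revComp(s)
            seqs[i] <- .apply_read_errors(s, cfg)
        }
        reads <- Biostrings::DNAStringSet(seqs)
        names(reads) <- ids
        truth@readOrigins <- S4Vectors::DataFrame(
            read_id = ids,
            start = ifelse(starts > L, starts - L, starts),
            strand = strands, length = lens)
        list(reads = reads, truth = truth)
    })
}

## per-base error process on one read sequence (read space); indel rates
## are boosted inside homopolymer runs of length >= 3
.apply_read_errors <- function(s, cfg) {
    if (cfg@subRate == 0 && cfg@insRate == 0 && cfg@delRate == 0)
        return(s)
    b <- strsplit(s, "")[[1L]]
    n <- base::length(b)
    runs <- rle(b)
    in_hp <- rep.int(runs$lengths >= 3L, runs$lengths)
    mult <- ifelse(in_hp, cfg@homopolymerMultiplier, 1)
    ins_p <- pmin(1, cfg@insRate * mult)
    del_p <- pmin(1, cfg@delRate * mult)
    sub <- runif(n) < cfg@subRate
    if (any(sub)) {
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        b[sub] <- vapply(b[sub], function(x) alt[[x]][sample.int(3L, 1L)],
                         "", USE.NAMES = FALSE)
    }
    del <- runif(n) < del_p
    ins <- runif(n) < ins_p
    ins_base <- ifelse(ins, sample(BASES, n, replace = TRUE), "")
    out <- paste0(ifelse(del, "", b), ins_base, collapse = "")
    if (nchar(out) == 0L) s else out
}
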