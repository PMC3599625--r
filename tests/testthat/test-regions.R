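## build error-free MappedReads tiling given intervals of a reference
tiling_mappings <- function(refchar, from, to, step, read_len,
                            ref_id = "chr") {
    starts <- unlist(lapply(seq_along(from), function(i)
        seq(from[i], to[i] - read_len + 1L, by = step)))
    gr <- GenomicRanges::GRanges(
        seqnames = ref_id,
        ranges = IRanges::IRanges(starts, width = read_len),
        strand = "+",
        read_id = paste0("t", seq_along(starts)),
        identity = 1,
        cigar = paste0(read_len, "M"),
        seq = substring(refchar, starts, starts + read_len - 1L))
    GenomeInfoDb::seqlengths(gr) <- nchar(refchar)
    MappedReads(gr)
}

test_that("anchor calling recovers the covered interval and its sequence", {
    set.seed(51)
    refchar <- rand_seq(5000)
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    mp <- tiling_mappings(refchar, 1L, 1000L, 10L, 100L)
    ctg <- callAnchorContigs(mp, ref, minDepth = 3)
    expect_length(ctg, 1L)
    info <- contigInfo(ctg)
    expect_identical(c(info$ref_start, info$ref_end), c(21L, 980L))
    expect_identical(unname(as.character(contigSeqs(ctg))[1]),
                     substr(refchar, 21, 980))
    expect_identical(provenance(ctg), "anchor")
})

test_that("disjoint coverage yields one contig per covered island", {
    set.seed(52)
    refchar <- rand_seq(5000)
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    mp <- tiling_mappings(refchar, c(1L, 601L), c(400L, 1000L), 10L, 100L)
    ctg <- callAnchorContigs(mp, ref, minDepth = 3)
    expect_length(ctg, 2L)
    info <- contigInfo(ctg)
    expect_identical(info$ref_start, c(21L, 621L))
    expect_identical(info$ref_end, c(380L, 980L))
    expect_length(callAnchorContigs(MappedReads(GenomicRanges::GRanges()),
                                    ref, 3), 0L)
})

test_that("pileup consensus takes the column majority", {
    refchar <- paste0("AAAA", strrep("C", 96))
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    ## three reads over [1,50]; one carries G at column 3
    seqs <- c(substr(refchar, 1, 50), substr(refchar, 1, 50),
              paste0("AAG", substr(refchar, 4, 50)))
    gr <- GenomicRanges::GRanges(seqnames = "chr", IRanges::IRanges(c(1, 1, 1), width = 50),
        strand = "+", read_id = c("a", "b", "c"), identity = 1,
        cigar = "50M", seq = seqs)
    GenomeInfoDb::seqlengths(gr) <- 100L
    ctg <- callAnchorContigs(MappedReads(gr), ref, minDepth = 3)
    expect_identical(unname(substr(as.character(contigSeqs(ctg))[1], 1, 4)),
                     "AAAA")
})

test_that("gap-size filtering splits anchors and repeat regions as a partition", {
    ## contigs 2000/300/1500 with 100-base uncovered gaps in between
    L <- 4000L
    ctg <- ContigSet(c(rand_seq(2000), rand_seq(300), rand_seq(1500)),
                     ref_id = "chr",
                     ref_start = c(1L, 2101L, 2501L),
                     ref_end = c(2000L, 2400L, 4000L),
                     provenance = "anchor")
    fs <- filterSmallContigs(ctg, L, gapSize = 500)
    expect_length(fs$anchors, 2L)
    expect_length(fs$regions, 1L)
    expect_identical(start(fs$regions), 2001L)
    expect_identical(end(fs$regions), 2500L)

    fs0 <- filterSmallContigs(ctg, L, gapSize = 0)
    expect_length(fs0$anchors, 3L)
    expect_identical(start(fs0$regions), c(2001L, 2401L))
    expect_identical(end(fs0$regions), c(2100L, 2500L))

    fs_all <- filterSmallContigs(ctg, L, gapSize = 5000)
    expect_length(fs_all$anchors, 0L)
    expect_identical(start(fs_all$regions), 1L)
    expect_identical(end(fs_all$regions), L)
})

test_that("anchors plus repeat regions always partition the reference (property)", {
    set.seed(53)
    for (rep in 1:25) {
        L <- 10000L
        lay <- random_layout(L, sample(1:8, 1), 100, 2000, by = 50)
        s <- lay$s; e <- lay$e
        ctg <- ContigSet(vapply(e - s + 1L, rand_seq, ""), ref_id = "chr",
                         ref_start = s, ref_end = e, provenance = "anchor")
        g <- sample(c(0L, 300L, 800L, 5000L), 1)
        fs <- filterSmallContigs(ctg, L, g)
        ar <- contigRanges(fs$anchors)
        all_ir <- c(IRanges::ranges(ar), IRanges::ranges(fs$regions))
        expect_identical(IRanges::reduce(all_ir), IRanges::IRanges(1L, L))
        expect_identical(sum(IRanges::width(all_ir)), L)
    }
})

test_that("repeat-region footprint is monotone in the gap size (property)", {
    set.seed(54)
    for (rep in 1:25) {
        L <- 20000L
        lay <- random_layout(L, sample(2:10, 1), 50, 2400)
        s <- lay$s; e <- lay$e
        ctg <- ContigSet(vapply(e - s + 1L, rand_seq, ""), ref_id = "chr",
                         ref_start = s, ref_end = e, provenance = "anchor")
        foot <- vapply(c(0, 100, 500, 1000, 2500, 10000), function(g)
            sum(width(filterSmallContigs(ctg, L, g)$regions)), numeric(1))
        expect_true(all(diff(foot) >= 0))
    }
})

test_that("read binning uses flanked interval intersection", {
    gr <- GenomicRanges::GRanges(seqnames = "chr",
        IRanges::IRanges(c(881, 301, 1001), c(980, 400, 1500)),
        strand = "+",
        read_id = c("near", "far", "inside"), identity = 1,
        cigar = NA_character_, seq = NA_character_)
    GenomeInfoDb::seqlengths(gr) <- 5000L
    mp <- MappedReads(gr)
    region <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(1001, 1500)))
    binned <- binReads(mp, region, flank = 100)
    ids <- S4Vectors::mcols(binned)$read_ids[[1]]
    expect_true("near" %in% ids)     # [881,980] meets [901,1600]
    expect_false("far" %in% ids)
    expect_true("inside" %in% ids)
    b0 <- binReads(mp, region, flank = 0)
    expect_identical(S4Vectors::mcols(b0)$read_ids[[1]], "inside")
})
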