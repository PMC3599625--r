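test_that("a spanning region contig closes the gap between two anchors", {
    set.seed(91)
    truth <- rand_seq(3000)
    anchors <- ContigSet(c(substr(truth, 1, 1000), substr(truth, 2001, 3000)),
                         ref_id = "chr", ref_start = c(1L, 2001L),
                         ref_end = c(1000L, 3000L), provenance = "anchor",
                         depth_mean = 10)
    regions <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(1001, 2000)))
    span <- ContigSet(substr(truth, 961, 2040), ref_id = "chr",
                      ref_start = 961L, ref_end = 2040L,
                      provenance = "repeat_resolved")
    final <- stitchContigs(anchors, regions, list(span), PipelineConfig(),
                           3000L)
    expect_length(final, 1L)
    expect_identical(unname(as.character(contigSeqs(final))[1]), truth)
    expect_identical(provenance(final), "merged")
    expect_identical(names(final), "final_1")
})

test_that("without region contigs the anchors pass through unchanged", {
    set.seed(92)
    truth <- rand_seq(3000)
    anchors <- ContigSet(c(substr(truth, 1, 1000), substr(truth, 2001, 3000)),
                         ref_id = "chr", ref_start = c(1L, 2001L),
                         ref_end = c(1000L, 3000L), provenance = "anchor")
    regions <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(1001, 2000)))
    final <- stitchContigs(anchors, regions, list(NULL), PipelineConfig(),
                           3000L)
    expect_length(final, 2L)
    expect_setequal(unname(as.character(contigSeqs(final))),
                    unname(as.character(contigSeqs(anchors))))
})

test_that("a region contig reaching only one anchor extends that side alone", {
    set.seed(93)
    truth <- rand_seq(3000)
    anchors <- ContigSet(c(substr(truth, 1, 1000), substr(truth, 2001, 3000)),
                         ref_id = "chr", ref_start = c(1L, 2001L),
                         ref_end = c(1000L, 3000L), provenance = "anchor")
    regions <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(1001, 2000)))
    left_only <- ContigSet(substr(truth, 961, 1500), ref_id = "chr",
                           ref_start = 961L, ref_end = 1500L,
                           provenance = "repeat_resolved")
    final <- stitchContigs(anchors, regions, list(left_only),
                           PipelineConfig(), 3000L)
    expect_length(final, 2L)
    expect_identical(sort(width(final), decreasing = TRUE),
                     c(1500L, 1000L))
    expect_true(substr(truth, 1, 1500) %in%
                as.character(contigSeqs(final)))
})

test_that("final contig count never exceeds anchors plus region contigs", {
    set.seed(94)
    truth <- rand_seq(5000)
    anchors <- ContigSet(c(substr(truth, 1, 1200), substr(truth, 2001, 3200),
                           substr(truth, 4001, 5000)),
                         ref_id = "chr", ref_start = c(1L, 2001L, 4001L),
                         ref_end = c(1200L, 3200L, 5000L),
                         provenance = "anchor")
    regions <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(c(1201, 3201), c(2000, 4000))))
    rc1 <- ContigSet(substr(truth, 1151, 2050), ref_id = "chr",
                     ref_start = 1151L, ref_end = 2050L,
                     provenance = "repeat_resolved")
    final <- stitchContigs(anchors, regions, list(rc1, NULL),
                           PipelineConfig(), 5000L)
    expect_lte(length(final), 3L + 1L)
    ## gap filling never shrinks the assembly
    expect_gte(sum(width(final)), sum(width(anchors)))
})

test_that("the full pipeline reconstructs a repeat-free genome from exact reads", {
    tr <- makeGenome(8000, seed = 95)
    rs <- simulateReads(tr, ReadSimConfig(coverage = 15, meanLen = 300,
        lenSd = 30, subRate = 0, insRate = 0, delRate = 0, seed = 96))
    res <- runPipeline(rs$reads, truthGenome(tr), verbose = FALSE)
    expect_length(finalContigs(res), 1L)
    g <- as.character(truthGenome(tr)[[1]])
    ident <- globalIdentity(as.character(contigSeqs(finalContigs(res)))[1],
                            g)$identity
    expect_gte(ident, 0.999)
    m <- metrics(res)
    expect_identical(m@contigNumber, 1L)
    expect_identical(m@ng50, as.numeric(m@totalLength))
})

test_that("zero reads produce an empty assembly with genome-size-only metrics", {
    tr <- makeGenome(5000, seed = 97)
    res <- runPipeline(Biostrings::DNAStringSet(), truthGenome(tr),
                       verbose = FALSE)
    expect_length(finalContigs(res), 0L)
    df <- as.data.frame(metrics(res))
    expect_identical(df$genome_size, 5000)
    expect_identical(df$total_length, 0)
    expect_identical(df$contig_number, 0L)
    expect_true(is.na(df$ng50))
})

test_that("the pipeline is byte-deterministic for fixed inputs", {
    tr <- makeGenome(10000, list(RepeatSpec("dispersed", 800, 2)), seed = 98)
    rs <- simulateReads(tr, ReadSimConfig(coverage = 12, meanLen = 300,
        lenSd = 30, seed = 99))
    r1 <- runPipeline(rs$reads, truthGenome(tr), verbose = FALSE)
    r2 <- runPipeline(rs$reads, truthGenome(tr), verbose = FALSE)
    f1 <- tempfile(); f2 <- tempfile()
    writeFasta(contigSeqs(finalContigs(r1)), f1)
    writeFasta(contigSeqs(finalContigs(r2)), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(as.data.frame(metrics(r1)), as.data.frame(metrics(r2)))
})
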