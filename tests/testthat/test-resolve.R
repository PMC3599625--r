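## a small study system: genome with one dispersed repeat family whose
## extra copies break the pileup, built once per file
local_fixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            tr <- makeGenome(30000, list(RepeatSpec("dispersed", 1500, 2)),
                             seed = 81)
            rs <- simulateReads(tr, ReadSimConfig(coverage = 15,
                meanLen = 300, lenSd = 30, subRate = 0, insRate = 0,
                delRate = 0, seed = 82))
            mp <- mapReads(rs$reads, truthGenome(tr))
            cfg <- PipelineConfig(flank = 300L)
            contigs <- callAnchorContigs(mp, truthGenome(tr), cfg@minDepth)
            fs <- filterSmallContigs(contigs, 30000L, cfg@gapSize)
            regions <- binReads(mp, fs$regions, cfg@flank, 30000L)
            cache <<- list(tr = tr, rs = rs, mp = mp, cfg = cfg,
                           anchors = fs$anchors, regions = regions)
        }
        cache
    }
})

test_that("polishing repairs a corrupted draft by read consensus", {
    set.seed(83)
    tmpl <- rand_seq(1500)
    starts <- seq(1, 1401, by = 25)
    reads <- Biostrings::DNAStringSet(substring(tmpl, starts,
                                                pmin(starts + 199, 1500)))
    names(reads) <- paste0("p", seq_along(reads))
    bad <- strsplit(tmpl, "")[[1]]
    bad[c(700, 900)] <- ""                      # deletions
    bad[300] <- paste0(bad[300], "A")           # insertion
    bad[500] <- setdiff(c("A", "C", "G", "T"), bad[500])[1]  # substitution
    polished <- polishContig(paste(bad, collapse = ""), reads)
    expect_identical(polished, tmpl)
    ## a clean draft stays untouched
    expect_identical(polishContig(tmpl, reads), tmpl)
})

test_that("a repeat-broken region resolves to one contig spanning its flanks", {
    fx <- local_fixture()
    ## pick the region flanked by two anchors (not at a reference end)
    inner <- which(start(fx$regions) > 1 &
                   end(fx$regions) < 30000)
    expect_gte(length(inner), 1L)
    region <- fx$regions[inner[1]]
    out <- resolveRegion(region, fx$mp, fx$rs$reads, fx$anchors, fx$cfg)
    expect_length(out, 1L)
    ## spans the region plus both anchor-side flanks
    expect_gte(width(out)[1], width(region) + 2 * 250)
    g <- as.character(truthGenome(fx$tr)[[1]])
    info <- contigInfo(out)
    tmpl <- substr(g, info$ref_start, info$ref_end)
    expect_identical(unname(as.character(contigSeqs(out))[1]), tmpl)
})

test_that("region resolution is deterministic and empty bins yield no contigs", {
    fx <- local_fixture()
    inner <- which(start(fx$regions) > 1 & end(fx$regions) < 30000)
    region <- fx$regions[inner[1]]
    o1 <- resolveRegion(region, fx$mp, fx$rs$reads, fx$anchors, fx$cfg)
    o2 <- resolveRegion(region, fx$mp, fx$rs$reads, fx$anchors, fx$cfg)
    expect_identical(as.character(contigSeqs(o1)),
                     as.character(contigSeqs(o2)))
    drained <- region
    S4Vectors::mcols(drained)$read_ids <- IRanges::CharacterList(list(character(0)))
    empty_maps <- MappedReads(GenomicRanges::GRanges())
    out <- resolveRegion(drained, empty_maps, Biostrings::DNAStringSet(),
                         fx$anchors, fx$cfg)
    expect_length(out, 0L)
})

test_that("without anchors the bin is assembled by iterative greedy recruitment", {
    set.seed(84)
    tmpl <- rand_seq(900)
    starts <- seq(1, 701, by = 20)
    reads <- Biostrings::DNAStringSet(substring(tmpl, starts, starts + 199))
    names(reads) <- paste0("u", seq_along(reads))
    gr <- GenomicRanges::GRanges(seqnames = "chr",
        IRanges::IRanges(starts, starts + 199), strand = "+",
        read_id = names(reads), identity = 1, cigar = "200M",
        seq = as.character(reads))
    GenomeInfoDb::seqlengths(gr) <- 900L
    mp <- MappedReads(gr)
    ## bin holds only reads from the region core; the rest are recruited
    region <- RepeatRegions(GenomicRanges::GRanges("chr",
        IRanges::IRanges(300, 600)))
    region <- binReads(mp, region, flank = 0)
    no_anchors <- ContigSet(Biostrings::DNAStringSet(), ids = character(0))
    cfg <- PipelineConfig(flank = 200L, minOverlap = 30L)
    out <- resolveRegion(region, mp, reads, no_anchors, cfg)
    expect_gte(length(out), 1L)
    ## recruitment must have pushed the contig beyond the bare bin span
    expect_gt(max(width(out)), 500L)
})
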