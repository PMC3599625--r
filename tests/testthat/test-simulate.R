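test_that("genome generation is deterministic and plants repeats as specified", {
    specs <- list(RepeatSpec("dispersed", 1200, copies = 3),
                  RepeatSpec("inverted", 1000))
    t1 <- makeGenome(30000, specs, seed = 42)
    t2 <- makeGenome(30000, specs, seed = 42)
    expect_identical(as.character(truthGenome(t1)),
                     as.character(truthGenome(t2)))
    g <- as.character(truthGenome(t1)[[1]])
    reps <- truthRepeats(t1)
    disp <- reps[reps$kind == "dispersed"]
    expect_length(disp, 3L)
    segs <- substring(g, start(disp), end(disp))
    expect_identical(segs, rep(segs[1], 3))      # divergence 0 -> identical
    inv <- reps[reps$kind == "inverted"]
    expect_length(inv, 2L)
    segs2 <- substring(g, start(inv), end(inv))
    expect_identical(segs2[order(inv$copy)][2],
                     revComp(segs2[order(inv$copy)][1]))
})

test_that("tandem repeats form one adjacent block and divergence mutates later copies", {
    tr <- makeGenome(20000, list(RepeatSpec("tandem", 500, copies = 4)),
                     seed = 7)
    reps <- truthRepeats(tr)
    expect_identical(width(reps), 2000L)
    td <- makeGenome(20000, list(RepeatSpec("dispersed", 1000, copies = 2,
                                            divergence = 0.05)), seed = 7)
    g <- as.character(truthGenome(td)[[1]])
    r <- truthRepeats(td)
    segs <- substring(g, start(r), end(r))
    mm <- mismatch_count(segs[1], segs[2])
    expect_gt(mm, 0)
    expect_lte(mm, 0.05 * 1000 + 10)
})

test_that("an oversized repeat footprint is rejected", {
    expect_error(makeGenome(5000, list(RepeatSpec("dispersed", 2000, 3)),
                            seed = 1), "footprint")
})

test_that("read count follows n = round(coverage * L / meanLen)", {
    tr <- makeGenome(20000, seed = 3)
    rs <- simulateReads(tr, ReadSimConfig(coverage = 10, meanLen = 400,
        subRate = 0, insRate = 0, delRate = 0, seed = 1))
    expect_length(rs$reads, 500L)
    rs0 <- simulateReads(tr, ReadSimConfig(coverage = 0, seed = 1))
    expect_length(rs0$reads, 0L)
})

test_that("zero-noise reads are exact oriented substrings at their origins", {
    tr <- makeGenome(20000, seed = 3)
    rs <- simulateReads(tr, ReadSimConfig(coverage = 5, meanLen = 300,
        lenSd = 30, subRate = 0, insRate = 0, delRate = 0, seed = 9))
    g <- as.character(truthGenome(tr)[[1]])
    oo <- readOrigins(rs$truth)
    expect_identical(oo$read_id, names(rs$reads))
    for (i in seq_along(rs$reads)) {
        tmpl <- substr(g, oo$start[i], oo$start[i] + oo$length[i] - 1L)
        if (oo$strand[i] == "-") tmpl <- revComp(tmpl)
        expect_identical(as.character(rs$reads[[i]]), tmpl)
    }
})

test_that("the empirical substitution rate matches the configured rate", {
    ## substitution-only model so the per-base binomial oracle applies
    tr <- makeGenome(50000, seed = 5)
    p <- 0.005
    rs <- simulateReads(tr, ReadSimConfig(coverage = 25, meanLen = 450,
        lenSd = 0, subRate = p, insRate = 0, delRate = 0, seed = 6))
    g <- as.character(truthGenome(tr)[[1]])
    oo <- readOrigins(rs$truth)
    total <- 0; mism <- 0
    for (i in seq_along(rs$reads)) {
        tmpl <- substr(g, oo$start[i], oo$start[i] + oo$length[i] - 1L)
        if (oo$strand[i] == "-") tmpl <- revComp(tmpl)
        mism <- mism + mismatch_count(as.character(rs$reads[[i]]), tmpl)
        total <- total + nchar(tmpl)
    }
    expect_gte(total, 1e6)
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(mism / total - p), 3 * se)
})

test_that("mean depth tracks the requested coverage within 10%", {
    tr <- makeGenome(30000, seed = 8)
    for (cov in c(5, 12)) {
        rs <- simulateReads(tr, ReadSimConfig(coverage = cov, meanLen = 350,
            lenSd = 35, subRate = 0, insRate = 0, delRate = 0, seed = cov))
        depth <- sum(readOrigins(rs$truth)$length) / 30000
        expect_lt(abs(depth - cov) / cov, 0.10)
    }
})

test_that("truth intervals and genome round-trip through the io module", {
    tr <- makeGenome(12000, list(RepeatSpec("dispersed", 800, 2)), seed = 2)
    fa <- tempfile(fileext = ".fa")
    writeFasta(truthGenome(tr), fa)
    expect_identical(as.character(readFasta(fa)),
                     as.character(truthGenome(tr)))
    bed <- tempfile(fileext = ".bed")
    writeBed(truthRepeats(tr), bed)
    back <- readBed(bed)
    expect_identical(start(back), start(truthRepeats(tr)))
    expect_identical(end(back), end(truthRepeats(tr)))
})
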