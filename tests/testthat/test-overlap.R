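test_that("bestOverlap finds the longest suffix/prefix match", {
    ## brute force confirms 4 ("GTAA") is maximal for this pair
    expect_identical(oracle_overlap("ACGTACGTAA", "GTAATTTT", 4, 0)$length, 4L)
    ov <- bestOverlap("ACGTACGTAA", "GTAATTTT", minOverlap = 4,
                      maxMismatchFrac = 0)
    expect_identical(ov$length, 4L)
    expect_identical(ov$mismatches, 0L)
    expect_identical(ov$orientation, "+")
})

test_that("identical sequences overlap over their full length", {
    s <- rand_seq(120)
    ov <- bestOverlap(s, s, minOverlap = 10, maxMismatchFrac = 0)
    expect_identical(ov$length, 120L)
})

test_that("reverse-complement overlaps are reported with '-' orientation", {
    set.seed(61)
    a <- rand_seq(100)
    tail50 <- substr(a, 51, 100)
    b_fwd <- paste0(tail50, rand_seq(60))       # b starts with a's tail
    ov <- bestOverlap(a, revComp(b_fwd), minOverlap = 20,
                      maxMismatchFrac = 0)
    expect_identical(ov$length, 50L)
    expect_identical(ov$orientation, "-")
})

test_that("overlap scan matches the brute-force oracle on random pairs", {
    set.seed(62)
    for (i in 1:200) {
        la <- sample(60:300, 1); lb <- sample(60:300, 1)
        a <- rand_seq(la); b <- rand_seq(lb)
        if (i %% 3 == 0) {      # plant a true overlap sometimes
            L <- sample(20:min(la, lb), 1)
            b <- paste0(substr(a, la - L + 1, la),
                        substr(b, L + 1, lb))
        }
        frac <- sample(c(0, 0.02, 0.05), 1)
        got <- regap:::overlap_scan_cpp(a, b, 15L, frac)
        want <- oracle_overlap(a, b, 15, frac)
        if (is.null(want)) {
            expect_identical(got[1], 0L)
        } else {
            expect_identical(got[1], want$length)
            expect_identical(got[2], want$mismatches)
        }
    }
})

test_that("random kilobase pairs share no qualifying overlap", {
    set.seed(63)
    for (i in 1:20) {
        a <- rand_seq(1000); b <- rand_seq(1000)
        expect_null(bestOverlap(a, b, minOverlap = 40, maxMismatchFrac = 0))
        expect_null(oracle_overlap(a, b, 40, 0))
    }
})

test_that("edit mode tolerates an indel inside the overlap", {
    set.seed(64)
    a <- rand_seq(200)
    ov_part <- substr(a, 101, 200)                       # 100-base overlap
    ov_indel <- paste0(substr(ov_part, 1, 50), substr(ov_part, 52, 100))
    b <- paste0(ov_indel, rand_seq(80))
    expect_null(bestOverlap(a, b, minOverlap = 60, maxMismatchFrac = 0.02))
    ov <- bestOverlap(a, b, minOverlap = 60, maxMismatchFrac = 0.02,
                      mode = "edit")
    expect_false(is.null(ov))
    expect_gte(ov$length, 60L)
    expect_lte(ov$mismatches, 2L)
})

test_that("greedy assembly reconstructs a tiled template", {
    set.seed(65)
    template <- rand_seq(60)
    reads <- substring(template, seq(1, 41, 10), seq(20, 60, 10))
    names(reads) <- paste0("r", seq_along(reads))
    asm <- greedyAssemble(reads, minOverlap = 5, maxMismatchFrac = 0)
    expect_length(asm, 1L)
    expect_identical(unname(as.character(contigSeqs(asm))[1]), template)
    expect_identical(provenance(asm), "repeat_resolved")
})

test_that("greedy assembly degenerate cases behave as documented", {
    r <- c(only = rand_seq(80))
    asm1 <- greedyAssemble(r, minOverlap = 20)
    expect_length(asm1, 1L)
    expect_identical(unname(as.character(contigSeqs(asm1))[1]), unname(r))
    expect_error(greedyAssemble(Biostrings::DNAStringSet()), "non-empty")

    set.seed(66)
    t1 <- rand_seq(100); t2 <- rand_seq(100)
    reads <- c(a1 = substr(t1, 1, 60), a2 = substr(t1, 41, 100),
               b1 = substr(t2, 1, 60), b2 = substr(t2, 41, 100))
    asm2 <- greedyAssemble(reads, minOverlap = 15, maxMismatchFrac = 0)
    expect_length(asm2, 2L)
    expect_setequal(as.character(contigSeqs(asm2)), c(t1, t2))
})

test_that("greedy assembly invariants hold on random tilings", {
    set.seed(67)
    for (i in 1:10) {
        template <- rand_seq(sample(150:400, 1))
        L <- nchar(template)
        starts <- sort(unique(c(1L, sample(seq(1, L - 59), 12, replace = TRUE))))
        reads <- substring(template, starts, pmin(starts + 59, L))
        names(reads) <- paste0("r", seq_along(reads))
        asm <- greedyAssemble(reads, minOverlap = 10, maxMismatchFrac = 0)
        w <- width(asm)
        ## no invention: total consensus <= total read bases
        expect_lte(sum(w), sum(nchar(reads)))
        ## nothing shorter than the longest read
        expect_gte(max(w), max(nchar(reads)))
        ## sorted by decreasing length
        expect_true(all(diff(w) <= 0))
        ## deterministic
        asm2 <- greedyAssemble(reads, minOverlap = 10, maxMismatchFrac = 0)
        expect_identical(as.character(contigSeqs(asm)),
                         as.character(contigSeqs(asm2)))
    }
})
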