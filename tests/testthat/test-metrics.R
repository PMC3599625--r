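test_that("ngx and lgx reproduce the worked examples", {
    ## cumulative-sum oracle: 10 >= 20*0.5 at the first contig
    expect_identical(oracle_ngx(c(10, 8, 6), 20, 50), 10)
    expect_identical(ngx(c(10, 8, 6), 20, 50), 10)
    expect_identical(ngx(c(5), 10, 50), 5)
    expect_true(is.na(ngx(c(3, 3), 100, 50)))
    expect_identical(oracle_lgx(c(10, 8, 6), 20, 50), 1L)
    expect_identical(lgx(c(10, 8, 6), 20, 50), 1L)
    expect_identical(lgx(c(4, 4, 4), 20, 50), 3L)
    expect_true(is.na(lgx(c(3, 3), 100, 50)))
    expect_error(ngx(c(-1, 5), 10, 50), "non-negative")
    expect_error(ngx(c(5), 10, 150), "x must")
})

test_that("ngx/lgx agree with the brute-force oracle on random inputs", {
    set.seed(71)
    for (i in 1:1000) {
        lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
        gs <- sample(1000:100000, 1)
        x <- sample(c(10, 25, 50, 75, 90), 1)
        n1 <- ngx(lens, gs, x); n2 <- oracle_ngx(lens, gs, x)
        l1 <- lgx(lens, gs, x); l2 <- oracle_lgx(lens, gs, x)
        expect_true(identical(is.na(n1), is.na(n2)) &&
                    (is.na(n1) || n1 == n2))
        expect_true(identical(is.na(l1), is.na(l2)) &&
                    (is.na(l1) || l1 == l2))
    }
})

test_that("ngx is non-increasing and lgx non-decreasing in x", {
    set.seed(72)
    for (i in 1:50) {
        lens <- sample(1:2000, sample(3:30, 1), replace = TRUE)
        gs <- sum(lens)          # thresholds always reachable
        xs <- c(10, 30, 50, 70, 90)
        nn <- vapply(xs, function(x) ngx(lens, gs, x), numeric(1))
        ll <- vapply(xs, function(x) lgx(lens, gs, x), integer(1))
        expect_true(all(diff(nn) <= 0))
        expect_true(all(diff(ll) >= 0))
    }
})

test_that("gap filling counts gaps completely covered by a final contig", {
    set.seed(73)
    refchar <- rand_seq(3000)
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    anchors <- ContigSet(c(substr(refchar, 1, 1000),
                           substr(refchar, 1501, 3000)),
                         ref_id = "chr", ref_start = c(1L, 1501L),
                         ref_end = c(1000L, 3000L), provenance = "anchor")
    final_full <- ContigSet(refchar, ref_id = "chr", ref_start = 1L,
                            ref_end = 3000L, provenance = "merged")
    gf <- gapFillStats(anchors, final_full, ref)
    expect_identical(gf$number, 1L)
    expect_identical(gf$length, 500L)
    ## final == anchors: nothing filled
    gf0 <- gapFillStats(anchors, anchors, ref)
    expect_identical(gf0$number, 0L)
    expect_identical(gf0$length, 0L)
})

test_that("partially covered gaps are not counted", {
    set.seed(74)
    refchar <- rand_seq(4000)
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    ## two gaps: [1001,1200] (200) and [2501,2800] (300)
    anchors <- ContigSet(c(substr(refchar, 1, 1000),
                           substr(refchar, 1201, 2500),
                           substr(refchar, 2801, 4000)),
                         ref_id = "chr", ref_start = c(1L, 1201L, 2801L),
                         ref_end = c(1000L, 2500L, 4000L),
                         provenance = "anchor")
    final <- ContigSet(c(substr(refchar, 1, 2500),
                         substr(refchar, 2801, 4000)),
                       ref_id = "chr", ref_start = c(1L, 2801L),
                       ref_end = c(2500L, 4000L), provenance = "merged")
    gf <- gapFillStats(anchors, final, ref)
    expect_identical(gf$number, 1L)
    expect_identical(gf$length, 200L)
    expect_lte(gf$length, 500L)   # never exceeds the pre-existing gap total
})

test_that("assembly metrics aggregate consistently", {
    set.seed(75)
    refchar <- rand_seq(2000)
    ref <- Biostrings::DNAStringSet(c(chr = refchar))
    final <- ContigSet(c(substr(refchar, 1, 1200), substr(refchar, 1301, 2000)),
                       ref_id = "chr", ref_start = c(1L, 1301L),
                       ref_end = c(1200L, 2000L), provenance = "merged")
    anchors <- final
    m <- assemblyMetrics(final, anchors, ref)
    df <- as.data.frame(m)
    expect_identical(df$total_length, as.numeric(sum(width(final))))
    expect_identical(df$contig_number, 2L)
    expect_identical(df$ng50, 1200)
    expect_identical(df$lg50, 1L)
    expect_lte(df$lg50, df$contig_number)
})

test_that("globalIdentity measures matches over aligned columns", {
    expect_identical(globalIdentity("ACGTACGTAC", "ACGTACGTAC")$identity, 1)
    g <- globalIdentity("ACGTACGTAC", "ACGTACGAAC")
    expect_equal(g$identity, 0.9)
    set.seed(76)
    s <- rand_seq(5000)
    mut <- strsplit(s, "")[[1]]
    mut[c(100, 2000, 4000)] <- "N"   # three guaranteed mismatches
    g2 <- globalIdentity(s, paste(mut, collapse = ""))
    expect_equal(g2$matches, 4997)
    expect_equal(g2$columns, 5000)
})
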