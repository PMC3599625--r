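## independent brute-force oracles used to pin down expected values

rand_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## all-offsets suffix/prefix overlap scanner (substitutions only)
oracle_overlap <- function(a, b, min_overlap, frac) {
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    best <- 0L; bm <- 0L
    for (L in seq(min_overlap, min(la, lb))) {
        mm <- sum(av[(la - L + 1L):la] != bv[1:L])
        if (mm <= floor(frac * L + 1e-9) && L > best) { best <- L; bm <- mm }
    }
    if (best == 0L) NULL else list(length = best, mismatches = bm)
}

## explicit sort-and-scan NG(X)/LG(X)
oracle_ngx <- function(lens, gs, x) {
    s <- sort(lens, decreasing = TRUE)
    tot <- 0
    for (i in seq_along(s)) {
        tot <- tot + s[i]
        if (tot >= gs * x / 100) return(s[i])
    }
    NA_real_
}

oracle_lgx <- function(lens, gs, x) {
    s <- sort(lens, decreasing = TRUE)
    tot <- 0
    for (i in seq_along(s)) {
        tot <- tot + s[i]
        if (tot >= gs * x / 100) return(i)
    }
    NA_integer_
}

## random non-overlapping contig layout on [1, L]
random_layout <- function(L, n, wmin, wmax, by = 100) {
    s <- sort(sample(seq(1, L - wmax - 10, by = by), n))
    e <- pmin(s + sample(wmin:wmax, n, replace = TRUE), L)
    keep <- logical(length(s))
    last_end <- 0L
    for (i in seq_along(s)) {
        if (s[i] > last_end) { keep[i] <- TRUE; last_end <- e[i] }
    }
    list(s = s[keep], e = e[keep])
}

## per-base comparison of a read against its true template substring
## (valid only for substitution-only simulations)
mismatch_count <- function(read, template) {
    stopifnot(nchar(read) == nchar(template))
    sum(utf8ToInt(read) != utf8ToInt(template))
}
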