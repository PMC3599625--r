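#' @useDynLib regap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head read.table tail write.table
NULL

BASES <- c("A", "C", "G", "T")

## reverse complement on plain character vectors (keeps the rest of the
## code free of DNAString round-trips in hot paths)
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.as_seq_char <- function(x) {
    if (is(x, "XStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x))
        as.character(x[[1L]])
    } else if (is(x, "XString")) as.character(x)
    else if (is.character(x) && length(x) == 1L) x
    else stop("cannot interpret input as a single DNA sequence")
}

.as_seqset <- function(x) {
    if (is(x, "DNAStringSet")) x
    else if (is(x, "XString")) Biostrings::DNAStringSet(as.character(x))
    else if (is.character(x)) Biostrings::DNAStringSet(x)
    else stop("cannot interpret input as a DNAStringSet")
}

## Hashed k-mer index of one sequence: environment mapping k-mer -> start
## positions (1-based).  K-mers containing N are skipped.
kmerPositions <- function(seq, k) {
    L <- nchar(seq)
    if (L < k) return(new.env(hash = TRUE, parent = emptyenv()))
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    idx <- split(starts[keep], kmers[keep])
    list2env(idx, envir = new.env(hash = TRUE, parent = emptyenv()))
}

## k-mer -> read-index lookup over a read set, sampling read k-mers at a
## stride; used for overlap-candidate recruitment.
readKmerLookup <- function(seqs, k = 17L, stride = 10L) {
    chars <- as.character(seqs)
    all_kmers <- character(0)
    all_ids <- integer(0)
    for (i in seq_along(chars)) {
        L <- nchar(chars[i])
        if (L < k) next
        starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
        km <- substring(chars[i], starts, starts + k - 1L)
        all_kmers <- c(all_kmers, km)
        all_ids <- c(all_ids, rep.int(i, length(km)))
    }
    idx <- lapply(split(all_ids, all_kmers), unique)
    env <- list2env(idx, envir = new.env(hash = TRUE, parent = emptyenv()))
    structure(list(env = env, k = k, n = length(chars)), class = "readKmerLookup")
}

## read indices whose sampled k-mers intersect the k-mers of `window`
## (forward orientation of the window; callers pass the reverse complement
## too when strand is unknown)
lookupCandidates <- function(lookup, window) {
    L <- nchar(window)
    k <- lookup$k
    if (L < k) return(integer(0))
    starts <- seq_len(L - k + 1L)
    km <- unique(substring(window, starts, starts + k - 1L))
    hits <- mget(km, envir = lookup$env, ifnotfound = list(NULL))
    unique(unlist(hits, use.names = FALSE))
}
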