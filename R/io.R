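#' Read sequences from FASTA or FASTQ
#'
#' The format is autodetected from the first non-empty character (`>` FASTA,
#' `@` FASTQ).  Sequences are uppercased and `U` is mapped to `T`; FASTQ
#' quality strings are attached as the `quality` metadata column.  Record
#' ids are the first whitespace-separated token of the header.
#'
#' @param path path to a FASTA or FASTQ file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L)
        return(Biostrings::DNAStringSet())
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    raw <- tryCatch(
        Biostrings::readBStringSet(path, format = fmt, with.qualities = FALSE),
        error = function(e) stop("malformed ", fmt, " in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    chars <- chartr("u", "t", toupper(as.character(raw)))
    chars <- chartr("U", "T", chars)
    if (any(nchar(chars) == 0L))
        stop("empty sequence for record '",
             names(raw)[which(nchar(chars) == 0L)[1L]], "' in ", path)
    out <- Biostrings::DNAStringSet(chars)
    names(out) <- vapply(strsplit(names(raw), "[ \t]"), `[`, "", 1L)
    if (fmt == "fastq") {
        q <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
        S4Vectors::mcols(out)$quality <-
            as.character(S4Vectors::mcols(q)$qualities)
    }
    out
}

#' Write sequences as FASTA
#'
#' @param records a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @param width line width for wrapping sequences (>= 1).
#' @return Invisibly, `path`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeFasta(c(r1 = "ACGT"), fa)
#' @export
writeFasta <- function(records, path, width = 60L) {
    if (width < 1L) stop("width must be >= 1")
    records <- .as_seqset(records)
    if (length(records) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    Biostrings::writeXStringSet(records, filepath = path, width = width)
    invisible(path)
}

## cigar helpers -------------------------------------------------------------

.cigar_ref_width <- function(cigar) {
    GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

## alignment columns (M + I + D) and inserted/deleted base counts
.cigar_counts <- function(cigar) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
    t(mapply(function(o, l) {
        c(M = sum(l[o %in% c("M", "=", "X")]),
          I = sum(l[o == "I"]), D = sum(l[o == "D"]),
          S = sum(l[o == "S"]))
    }, ops, lens))
}

#' Read a read-to-reference mapping from SAM or the 6-column TSV dialect
#'
#' Two dialects are accepted and autodetected: SAM (header lines start with
#' `@`), and a plain tab-separated table with comment lines starting `#` and
#' columns `read_id`, `ref_id`, `ref_start`, `ref_end`, `strand`,
#' `identity`, where `ref_start`/`ref_end` are 0-based half-open.  Either
#' way the result uses 1-based closed coordinates (the `GRanges`
#' convention), and minus-strand records carry the read sequence already in
#' reference orientation.
#'
#' For SAM input, identity is computed from the `NM` tag when present
#' (`matches / alignment columns`); for TSV input the identity column is
#' taken as is, and read sequences are attached from `reads` when supplied.
#'
#' @param path path to a SAM file or mapping TSV.
#' @param reference the reference as a single-sequence `DNAStringSet` (used
#'   to validate intervals).
#' @param reads optional named `DNAStringSet` of the raw reads (TSV dialect
#'   only; supplies the read sequences).
#' @return A [MappedReads] object.
#' @export
readMappings <- function(path, reference, reads = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    reference <- .as_seqset(reference)
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    if (identical(first, "@") || grepl("\\.sam$", path, ignore.case = TRUE))
        .read_mappings_sam(path, reference)
    else
        .read_mappings_tsv(path, reference, reads)
}

.read_mappings_sam <- function(path, reference) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    param <- Rsamtools::ScanBamParam(what = c("seq", "qname"), tag = "NM")
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    if (length(ga) == 0L)
        return(MappedReads(GenomicRanges::GRanges(
            seqnames = character(0), ranges = IRanges::IRanges(),
            strand = character(0), read_id = character(0),
            identity = numeric(0), cigar = character(0),
            seq = character(0))))
    L <- Biostrings::width(reference)[1L]
    if (any(GenomicAlignments::end(ga) > L) ||
        any(GenomicAlignments::start(ga) < 1L)) {
        bad <- which(GenomicAlignments::end(ga) > L |
                     GenomicAlignments::start(ga) < 1L)[1L]
        stop("mapping record ", bad, " lies outside the reference")
    }
    cig <- GenomicAlignments::cigar(ga)
    cnt <- .cigar_counts(cig)
    nm <- S4Vectors::mcols(ga)$NM
    cols <- cnt[, "M"] + cnt[, "I"] + cnt[, "D"]
    ident <- ifelse(is.na(nm), NA_real_, (cnt[, "M"] - (nm - cnt[, "I"] -
                    cnt[, "D"])) / cols)
    ident[!is.na(ident) & ident < 0] <- 0
    gr <- GenomicRanges::GRanges(
        seqnames = names(reference)[1L],
        ranges = IRanges::IRanges(GenomicAlignments::start(ga),
                                  GenomicAlignments::end(ga)),
        strand = BiocGenerics::strand(ga),
        read_id = S4Vectors::mcols(ga)$qname,
        identity = as.numeric(ident),
        cigar = cig,
        ## SAM stores SEQ already reference-oriented
        seq = as.character(S4Vectors::mcols(ga)$seq))
    GenomeInfoDb::seqlengths(gr) <- L
    MappedReads(gr)
}

.read_mappings_tsv <- function(path, reference, reads) {
    tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      col.names = c("read_id", "ref_id", "ref_start",
                                    "ref_end", "strand", "identity"),
                      colClasses = c("character", "character", "integer",
                                     "integer", "character", "numeric"))
    L <- Biostrings::width(reference)[1L]
    if (nrow(tab)) {
        bad_strand <- which(!tab$strand %in% c("+", "-"))
        if (length(bad_strand))
            stop("unknown strand symbol '", tab$strand[bad_strand[1L]],
                 "' in mapping record ", bad_strand[1L])
        bad <- which(tab$ref_start < 0L | tab$ref_end > L |
                     tab$ref_start >= tab$ref_end)
        if (length(bad))
            stop("mapping record ", bad[1L], " lies outside the reference ",
                 "or has an empty interval")
    }
    seqs <- rep(NA_character_, nrow(tab))
    if (!is.null(reads) && nrow(tab)) {
        m <- match(tab$read_id, names(reads))
        ok <- !is.na(m)
        seqs[ok] <- as.character(reads[m[ok]])
        neg <- ok & tab$strand == "-"
        if (any(neg)) seqs[neg] <- revComp(seqs[neg])
    }
    gr <- GenomicRanges::GRanges(
        seqnames = rep(names(reference)[1L], nrow(tab)),
        ## TSV is 0-based half-open; GRanges is 1-based closed
        ranges = IRanges::IRanges(start = tab$ref_start + 1L,
                                  end = tab$ref_end),
        strand = tab$strand,
        read_id = tab$read_id, identity = tab$identity,
        cigar = rep(NA_character_, nrow(tab)), seq = seqs)
    GenomeInfoDb::seqlengths(gr) <- L
    MappedReads(gr)
}

#' Write a mapping as the 6-column TSV dialect
#'
#' Coordinates are written 0-based half-open (the on-disk convention of the
#' dialect; in memory `MappedReads` is 1-based closed).
#'
#' @param mappings a [MappedReads] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMappings <- function(mappings, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#read_id\tref_id\tref_start\tref_end\tstrand\tidentity", con)
    if (length(mappings)) {
        df <- data.frame(
            read_id = S4Vectors::mcols(mappings)$read_id,
            ref_id = as.character(GenomeInfoDb::seqnames(mappings)),
            ref_start = BiocGenerics::start(mappings) - 1L,
            ref_end = BiocGenerics::end(mappings),
            strand = as.character(BiocGenerics::strand(mappings)),
            identity = format(S4Vectors::mcols(mappings)$identity,
                              digits = 6))
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(path)
}

#' Export intervals as BED
#'
#' Used for repeat regions and simulation truth intervals.  BED is 0-based
#' half-open on disk; the conversion from the in-memory 1-based
#' representation is handled by rtracklayer.
#'
#' @param gr a `GRanges` (e.g. [RepeatRegions] or [truthRepeats] output).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
    mc <- S4Vectors::mcols(gr)
    nm <- if ("region_id" %in% colnames(mc)) mc$region_id
          else if ("family" %in% colnames(mc)) mc$family
          else names(gr)
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::ranges(gr))
    if (!is.null(nm)) out$name <- nm
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read a BED file as GRanges
#'
#' @param path BED path.
#' @return A `GRanges` (1-based closed in memory).
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
                           name = if (!is.null(gr$name)) gr$name
                                  else rep(".", length(gr)))
}
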