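# core_io: readers/writers for the standard formats the pipeline touches.
# Genomic intervals live in GRanges (1-based inclusive, the Bioconductor
# convention); explicit converters expose the 0-based half-open arithmetic
# used when slicing sequences, and GFF3 output goes through rtracklayer.

#' Read a FASTA file into an XStringSet
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA, upfolds lowercase,
#' and normalizes T/U to the declared alphabet. Records must be non-empty
#' and ids unique within the file.
#'
#' @param path FASTA file path.
#' @param alphabet `"dna"` or `"rna"`.
#' @return a `DNAStringSet` or `RNAStringSet`, in file order.
#' @export
readSeqs <- function(path, alphabet = c("dna", "rna")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                        stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e)))
    if (any(Biostrings::width(raw) == 0L)) {
        bad <- which(Biostrings::width(raw) == 0L)[1]
        stop("record ", bad, " ('", names(raw)[bad], "') has no sequence")
    }
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- if (alphabet == "dna") asDNA(raw) else asRNA(raw)
    pat <- if (alphabet == "dna") "[^ACGTN]" else "[^ACGUN]"
    if (any(grepl(pat, seqs)))
        stop("sequence characters outside declared ", alphabet, " alphabet")
    out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
           else Biostrings::RNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write sequences to FASTA
#'
#' @param seqs an `XStringSet` (or named character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeqs <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Convert 0-based half-open intervals to GRanges (and back)
#'
#' Internal interval arithmetic is simplest 0-based half-open; annotation is
#' emitted 1-based inclusive (the GFF3 / GRanges convention). The conversion
#' is `start + 1, end`, and the two functions are exact inverses.
#'
#' @param chrom character vector of sequence names.
#' @param start0,end0 0-based half-open bounds (`end0 > start0`).
#' @param strand `"+"` or `"-"`.
#' @return `zeroBasedToGRanges`: a `GRanges`; `grangesToZeroBased`: a
#'   `data.frame` with columns `chrom`, `start0`, `end0`, `strand`.
#' @examples
#' gr <- zeroBasedToGRanges("chr1", 0, 10)   # GFF columns 4,5 = 1,10
#' grangesToZeroBased(gr)
#' @export
zeroBasedToGRanges <- function(chrom, start0, end0, strand = "+") {
    if (any(end0 <= start0)) stop("end0 must exceed start0")
    if (any(start0 < 0)) stop("start0 must be >= 0")
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start = start0 + 1, end = end0),
                           strand = strand)
}

#' @rdname zeroBasedToGRanges
#' @param gr a `GRanges`.
#' @export
grangesToZeroBased <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start0 = GenomicRanges::start(gr) - 1L,
               end0 = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
}

#' Write annotation to GFF3
#'
#' Exports a `GRanges` (1-based inclusive) through rtracklayer. If sequence
#' lengths are known (on the object or via `seqlens`), intervals beyond the
#' sequence end are an error.
#'
#' @param features a `GRanges`, possibly with metadata columns.
#' @param path output path.
#' @param seqlens optional named integer vector of sequence lengths.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(features, path, seqlens = NULL) {
    if (!is.null(seqlens)) {
        sn <- as.character(GenomicRanges::seqnames(features))
        known <- sn %in% names(seqlens)
        if (any(known & GenomicRanges::end(features) > seqlens[sn]))
            stop("interval end beyond sequence length")
        if (any(!known))
            stop("unknown sequence name(s): ",
                 paste(unique(sn[!known]), collapse = ", "))
    }
    rtracklayer::export.gff3(features, path)
    invisible(path)
}

#' Write a feature / audit table as TSV
#'
#' Plain TSV with header, no quoting, full float precision.
#'
#' @param df a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(df, path) {
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write an SSR signature table
#'
#' Two-column TSV (`family`, `motif`) mapping miRNA family names to their
#' trinucleotide signature motifs.
#'
#' @param path TSV path.
#' @return `readSignatureTable`: named list, one character vector of motifs
#'   per family.
#' @export
readSignatureTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("family", "motif") %in% names(df)))
        stop("signature table needs columns 'family' and 'motif'")
    split(asRNA(df$motif), df$family)
}

#' @rdname readSignatureTable
#' @param table named list of motif vectors (as from
#'   [tabulateFamilySignatures()]).
#' @export
writeSignatureTable <- function(table, path) {
    df <- data.frame(family = rep(names(table), lengths(table)),
                     motif = unlist(table, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
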