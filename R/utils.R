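# Internal sequence helpers shared across modules. Sequences cross module
# boundaries as plain uppercase character strings; genomes are DNA (T),
# anything entering the folding engine is RNA (U).

.upper <- function(x) toupper(as.character(x))

#' Convert between DNA and RNA alphabets
#'
#' `asRNA` upfolds and maps T to U; `asDNA` maps U to T. Both accept
#' character vectors or `XStringSet` input and return character vectors.
#'
#' @param x character vector (or `XStringSet`) of sequences.
#' @return character vector in the requested alphabet (names preserved).
#' @export
asRNA <- function(x) {
    nm <- if (is.character(x)) names(x) else names(as.character(x))
    out <- chartr("Tt", "UU", .upper(x))
    names(out) <- nm %||% names(x)
    out
}

#' @rdname asRNA
#' @export
asDNA <- function(x) {
    nm <- if (is.character(x)) names(x) else names(as.character(x))
    out <- chartr("Uu", "TT", .upper(x))
    names(out) <- nm %||% names(x)
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.RNA_CODES <- c(A = 0L, C = 1L, G = 2L, U = 3L)

.encodeRNA <- function(seq) {
    ch <- strsplit(asRNA(seq), "", fixed = TRUE)[[1]]
    codes <- .RNA_CODES[ch]
    if (anyNA(codes))
        stop("ambiguous or non-RNA base in sequence: ",
             paste(unique(ch[is.na(codes)]), collapse = ", "))
    unname(codes)
}

.hasAmbiguous <- function(seq) {
    grepl("[^ACGTU]", .upper(seq))
}

#' Reverse complement of a DNA sequence
#'
#' Character-level convenience wrapper around
#' [Biostrings::reverseComplement()]; N maps to N. An involution:
#' `revComp(revComp(s)) == s`.
#'
#' @param seq character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revComp <- function(seq) {
    seq <- .upper(seq)
    bad <- grepl("[^ACGTN]", seq)
    if (any(bad))
        stop("non-DNA character in sequence(s): ",
             paste(which(bad), collapse = ", "))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Complementary RNA base lookup (Watson-Crick), used by duplex code.
.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.rnaComplement <- function(chars) unname(.RNA_COMP[chars])

# coerce to character while preserving (or inventing) names
.namedChar <- function(x, stem) {
    nm <- names(x)
    x <- as.character(x)
    if (is.null(nm)) nm <- if (length(x)) paste0(stem, seq_along(x))
                           else character(0)
    names(x) <- nm
    x
}

# seeded-derived sub-seeds kept below 2^31
.subSeed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k
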