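#' Find open reading frames in six frames
#'
#' Scans all three frames of a transcript and of its reverse complement.
#' The default ORF definition is start-to-stop: within each stop-delimited
#' segment of a frame, the first in-frame ATG opens an ORF that runs to the
#' next stop codon (included) or, when the frame ends without a stop, to the
#' last complete codon (open-ended). With `requireStart = FALSE` every
#' stop-to-stop stretch counts (the getorf-style convention).
#'
#' @param seq transcript sequence (DNA or RNA, character scalar).
#' @param minAA report only ORFs of at least this many amino acids.
#' @param requireStart require an ATG start codon (default) or accept
#'   stop-to-stop stretches.
#' @return `data.frame` with columns `frame` (+1..+3, -1..-3), `start`,
#'   `end` (0-based half-open on the frame's own strand; minus-frame
#'   coordinates refer to the reverse complement), `lengthAA` (amino acids,
#'   excluding the stop), `hasStop`; sorted by `lengthAA` descending.
#' @examples
#' findORFs("ATGAAATAA")  # one ORF of 2 aa (MK)
#' @export
findORFs <- function(seq, minAA = 0L, requireStart = TRUE) {
    dna <- asDNA(seq)
    strands <- list(`1` = dna, `-1` = revComp(gsub("U", "T", dna)))
    stops <- c("TAA", "TAG", "TGA")
    rows <- list()
    for (sgn in names(strands)) {
        s <- strands[[sgn]]
        n <- nchar(s)
        for (off in 0:2) {
            ncod <- (n - off) %/% 3L
            if (ncod < 1L) next
            codStart <- off + 3L * (seq_len(ncod) - 1L)
            codons <- substring(s, codStart + 1L, codStart + 3L)
            isStop <- codons %in% stops
            isStart <- codons == "ATG"
            segFrom <- 1L
            stopIdx <- c(which(isStop), if (!isStop[ncod]) NA_integer_)
            for (sp in stopIdx) {
                segTo <- if (is.na(sp)) ncod else sp
                lastCoding <- if (is.na(sp)) segTo else sp - 1L
                from <- if (requireStart) {
                    w <- which(isStart[seq.int(segFrom, length.out = max(0L, lastCoding - segFrom + 1L))])
                    if (length(w)) segFrom + w[1L] - 1L else NA_integer_
                } else if (lastCoding >= segFrom) segFrom else NA_integer_
                if (!is.na(from)) {
                    aa <- lastCoding - from + 1L
                    if (aa >= minAA && aa > 0L) {
                        rows[[length(rows) + 1L]] <- data.frame(
                            frame = as.integer(sgn) * (off + 1L),
                            start = off + 3L * (from - 1L),
                            end = off + 3L * segTo,
                            lengthAA = aa,
                            hasStop = !is.na(sp),
                            stringsAsFactors = FALSE)
                    }
                }
                segFrom <- segTo + 1L
            }
        }
    }
    if (!length(rows))
        return(data.frame(frame = integer(), start = integer(),
                          end = integer(), lengthAA = integer(),
                          hasStop = logical(), stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res[order(-res$lengthAA, res$frame, res$start), , drop = FALSE]
}

# Longest ORF length (aa) of a transcript; 0 when there is none.
.longestOrfAA <- function(seq, requireStart = TRUE) {
    orfs <- findORFs(seq, requireStart = requireStart)
    if (nrow(orfs)) orfs$lengthAA[1L] else 0L
}
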