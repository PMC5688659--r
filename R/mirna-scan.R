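# mirna_discovery (part 1): exhaustive homology scan, precursor window
# extraction and protein-coding exclusion. The scan is a complete ungapped
# Hamming-distance search on both strands (Biostrings matchPattern), not a
# heuristic: at <= 3 mismatches over ~21-mers nothing is lost at desk scale.

.familyFromId <- function(id) {
    m <- regexpr("miR[0-9]+", id, ignore.case = TRUE)
    out <- rep(NA_character_, length(id))
    out[m > 0] <- sub("^mir", "miR", regmatches(id, m), ignore.case = TRUE)
    out
}

#' Exhaustive homology scan of mature miRNAs against a genome
#'
#' Finds every ungapped occurrence of each mature miRNA on both genome
#' strands with at most `maxMismatch` substitutions (0-3 by default).
#' Matures containing N are skipped with a warning. Multiple matures hitting
#' identical coordinates collapse to one locus, keeping the lowest-mismatch
#' query.
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param matures `RNAStringSet`/`DNAStringSet` (or named character) of
#'   mature miRNAs, 15-30 nt, miRBase-style ids (family parsed from the
#'   `miRNNN` token).
#' @param maxMismatch maximum Hamming distance (inclusive).
#' @return a `GRanges` (1-based inclusive) with metadata columns
#'   `matureID`, `family`, `mismatches`, `matureSeq`.
#' @export
scanHomology <- function(genome, matures, maxMismatch = 3L) {
    if (!methods::is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(asDNA(genome))
    mats <- asDNA(matures)
    ids <- names(mats)
    if (is.null(ids)) ids <- paste0("mat", seq_along(mats))
    out <- list()
    for (k in seq_along(mats)) {
        pat <- mats[[k]]
        if (grepl("N", pat, fixed = TRUE)) {
            warning("mature '", ids[k], "' contains N; skipped")
            next
        }
        if (nchar(pat) < 15L || nchar(pat) > 30L)
            stop("mature '", ids[k], "' outside the 15-30 nt range")
        for (ci in seq_along(genome)) {
            chrom <- genome[[ci]]
            for (str in c("+", "-")) {
                p <- if (str == "+") pat else revComp(pat)
                hits <- Biostrings::matchPattern(p, chrom,
                                                 max.mismatch = maxMismatch)
                if (!length(hits)) next
                mm <- Biostrings::neditStartingAt(
                    Biostrings::DNAString(p), chrom,
                    starting.at = BiocGenerics::start(hits),
                    with.indels = FALSE)
                out[[length(out) + 1L]] <- data.frame(
                    chrom = names(genome)[ci],
                    start = BiocGenerics::start(hits),
                    end = BiocGenerics::end(hits),
                    strand = str, matureID = ids[k],
                    family = .familyFromId(ids[k]),
                    mismatches = mm, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(GenomicRanges::GRanges(matureID = character(),
                                      family = character(),
                                      mismatches = integer(),
                                      matureSeq = character()))
    df <- do.call(rbind, out)
    # collapse identical loci, keep lowest-mismatch query
    key <- paste(df$chrom, df$start, df$end, df$strand)
    df <- df[order(key, df$mismatches), ]
    df <- df[!duplicated(paste(df$chrom, df$start, df$end, df$strand)), ]
    df <- df[order(df$chrom, df$start), ]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    seqs <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        s <- as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                             df$start[i], df$end[i]))
        seqs[i] <- if (df$strand[i] == "-") revComp(s) else s
    }
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        matureID = df$matureID, family = df$family,
        mismatches = df$mismatches, matureSeq = seqs)
    gr
}

#' Window extraction policy
#'
#' @param lengths candidate window total lengths (nt); the default ladder
#'   60-300 in steps of 20 spans the plant pre-miRNA length range.
#' @param placements mature arm placements: `"5p"` (mature at the window's
#'   5' end) and/or `"3p"`.
#' @return a policy list for [extractWindows()].
#' @export
windowPolicy <- function(lengths = seq(60L, 300L, by = 20L),
                         placements = c("5p", "3p")) {
    list(lengths = as.integer(lengths), placements = placements)
}

#' Extract candidate precursor windows around homology hits
#'
#' For each hit, builds a ladder of windows of the policy's lengths with the
#' mature placed on the 5' or 3' arm (asymmetric flanks), clipped at
#' chromosome ends. Minus-strand hits are reverse-complemented so the mature
#' always appears in sense. Windows containing N are discarded (folding
#' statistics are undefined for ambiguous bases), as are windows that no
#' longer contain the full mature after clipping.
#'
#' @param hits `GRanges` from [scanHomology()].
#' @param genome `DNAStringSet` of chromosomes.
#' @param policy from [windowPolicy()].
#' @return `data.frame` with one row per candidate window: `hitIndex`,
#'   `chrom`, `winStart`, `winEnd`, `strand`, `length`, `matureStart`,
#'   `matureEnd` (1-based within the window, sense orientation), `seq`
#'   (RNA), plus the hit's `matureID`, `family`, `mismatches`.
#' @export
extractWindows <- function(hits, genome, policy = windowPolicy()) {
    if (!methods::is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(asDNA(genome))
    rows <- list()
    mc <- S4Vectors::mcols(hits)
    for (h in seq_along(hits)) {
        chrom <- as.character(GenomicRanges::seqnames(hits))[h]
        hs <- GenomicRanges::start(hits)[h]
        he <- GenomicRanges::end(hits)[h]
        str <- as.character(GenomicRanges::strand(hits))[h]
        clen <- Biostrings::width(genome)[match(chrom, names(genome))]
        mlen <- he - hs + 1L
        for (L in policy$lengths) {
            if (L < mlen) next
            for (pl in policy$placements) {
                anchor5 <- (pl == "5p") == (str == "+")
                ws <- if (anchor5) hs else he - L + 1L
                we <- if (anchor5) hs + L - 1L else he
                ws <- max(1L, ws); we <- min(clen, we)
                if (ws > hs || we < he) next    # mature clipped off
                s <- as.character(Biostrings::subseq(genome[[chrom]], ws, we))
                if (grepl("N", s, fixed = TRUE)) next
                if (str == "-") s <- revComp(s)
                mstart <- if (str == "+") hs - ws + 1L else we - he + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    hitIndex = h, chrom = chrom, winStart = ws, winEnd = we,
                    strand = str, length = we - ws + 1L,
                    matureStart = mstart, matureEnd = mstart + mlen - 1L,
                    seq = asRNA(s), matureID = mc$matureID[h],
                    family = mc$family[h], mismatches = mc$mismatches[h],
                    placement = pl, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(hitIndex = integer(), chrom = character(),
                          winStart = integer(), winEnd = integer(),
                          strand = character(), length = integer(),
                          matureStart = integer(), matureEnd = integer(),
                          seq = character(), matureID = character(),
                          family = character(), mismatches = integer(),
                          placement = character(), stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    df[!duplicated(df[c("hitIndex", "winStart", "winEnd")]), , drop = FALSE]
}

#' Remove protein-coding candidate windows
#'
#' With a protein database, a window is removed when any of its six frame
#' translations aligns locally to a database protein above the significance
#' and identity cutoffs (same alignment route as
#' [proteinSimilarityFilter()]). Without a database, a configurable ORF
#' heuristic removes windows containing an ORF of at least `minOrfAA` amino
#' acids; disabling both is a configuration error.
#'
#' @param candidates window `data.frame` from [extractWindows()].
#' @param proteins optional protein database (`AAStringSet` or character).
#' @param minOrfAA ORF-length heuristic threshold (aa); `NULL` disables it.
#' @param maxIdentity,eCutoff alignment cutoffs for the database route.
#' @return list with `kept` and `removed` candidate `data.frame`s.
#' @export
excludeCoding <- function(candidates, proteins = NULL, minOrfAA = 80L,
                          maxIdentity = 40, eCutoff = 1e-3) {
    if (!nrow(candidates))
        return(list(kept = candidates, removed = candidates))
    if (!is.null(proteins)) {
        if (!length(proteins)) {
            warning("empty protein database; all candidates retained")
            return(list(kept = candidates, removed = candidates[0, ]))
        }
        seqs <- stats::setNames(asDNA(candidates$seq),
                                paste0("w", seq_len(nrow(candidates))))
        res <- proteinSimilarityFilter(seqs, proteins,
                                       maxIdentity = maxIdentity,
                                       eCutoff = eCutoff)
        rm <- res$details$removed
        return(list(kept = candidates[!rm, , drop = FALSE],
                    removed = candidates[rm, , drop = FALSE]))
    }
    if (is.null(minOrfAA))
        stop("no protein database and ORF heuristic disabled: ",
             "configure one coding-exclusion route")
    longest <- vapply(candidates$seq, .longestOrfAA, 0L)
    rm <- longest >= minOrfAA
    list(kept = candidates[!rm, , drop = FALSE],
         removed = candidates[rm, , drop = FALSE])
}
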