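# lncrna_discovery: length filter, ORF filter, two-stage coding-potential
# classification, and protein-similarity removal. All literature thresholds are
# honored with strict/non-strict boundaries as documented on each function.

#' Transcript length filter
#'
#' Retains transcripts strictly longer than `minLen` nucleotides (a 200-nt
#' transcript is removed; 201 nt is retained).
#'
#' @param transcripts named character vector or `XStringSet`.
#' @param minLen minimum length bound (exclusive), nucleotides.
#' @return the retained subset, same container type.
#' @export
lengthFilter <- function(transcripts, minLen = 200L) {
    w <- if (methods::is(transcripts, "XStringSet"))
        Biostrings::width(transcripts) else nchar(transcripts)
    transcripts[w > minLen]
}

#' Maximum-ORF filter
#'
#' Retains transcripts whose longest ORF (any of the six frames, see
#' [findORFs()]) is strictly shorter than `maxAA` amino acids; a transcript
#' with no ORF at all is vacuously retained.
#'
#' @inheritParams lengthFilter
#' @param maxAA upper ORF length bound (exclusive), amino acids.
#' @return the retained subset.
#' @export
orfFilter <- function(transcripts, maxAA = 120L) {
    longest <- vapply(as.character(transcripts), .longestOrfAA, 0L)
    transcripts[longest < maxAA]
}

#' Two-stage coding-potential classification
#'
#' Applies the primary score S with class boundaries: non-coding when
#' S <= -0.5, coding when S >= 1.0, neutral otherwise. Neutral transcripts
#' are re-examined with the secondary score and classified as ncRNA when it
#' is < 0.2; neutral transcripts at or above 0.2 stay discarded as
#' potentially coding.
#'
#' @param transcripts named character vector or `XStringSet`.
#' @param scorer a [CodingScorer-class], or an external-score adapter: a
#'   list with named numeric vectors `primary` and `secondary` (id -> score)
#'   as produced by external coding-potential programs.
#' @return `data.frame` with columns `id`, `S`, `secondary` (NA unless the
#'   neutral branch was evaluated), `label` in
#'   `c("noncoding", "coding", "neutral", "ncRNA-by-secondary",
#'   "unresolved")`, and `isNcRNA` (`TRUE` for noncoding or
#'   ncRNA-by-secondary).
#' @export
classifyCodingPotential <- function(transcripts, scorer) {
    seqs <- .namedChar(transcripts, "tx")
    ids <- names(seqs)
    S <- tryCatch({
        if (methods::is(scorer, "CodingScorer")) primaryScore(scorer, seqs)
        else unname(scorer$primary[ids])
    }, error = function(e) rep(NA_real_, length(seqs)))
    label <- rep("unresolved", length(seqs))
    label[!is.na(S) & S <= -0.5] <- "noncoding"
    label[!is.na(S) & S >= 1.0] <- "coding"
    neutral <- !is.na(S) & S > -0.5 & S < 1.0
    sec <- rep(NA_real_, length(seqs))
    if (any(neutral)) {
        sec[neutral] <- tryCatch({
            if (methods::is(scorer, "CodingScorer"))
                secondaryScore(scorer, seqs[neutral])
            else unname(scorer$secondary[ids[neutral]])
        }, error = function(e) rep(NA_real_, sum(neutral)))
        label[neutral & !is.na(sec) & sec < 0.2] <- "ncRNA-by-secondary"
        label[neutral & !is.na(sec) & sec >= 0.2] <- "neutral"
    }
    data.frame(id = ids, S = S, secondary = sec, label = label,
               isNcRNA = label %in% c("noncoding", "ncRNA-by-secondary"),
               stringsAsFactors = FALSE)
}

# Karlin-Altschul gapped BLOSUM62 parameters (gap open 11 / extend 1),
# used to turn local alignment raw scores into approximate E-values.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Protein-similarity removal
#'
#' Removes candidate non-coding transcripts that still align to a protein
#' database: a transcript is removed iff its best local alignment of any of
#' the six frame translations passes the significance cutoff AND exceeds
#' 40 percent identity (strictly; exactly 40 percent is retained). The
#' built-in route aligns with BLOSUM62 (gap open 11 / extend 1) and converts
#' raw scores to approximate Karlin-Altschul E-values; alternatively a
#' precomputed 12-column tabular alignment (`hits`) from an external aligner
#' can be supplied.
#'
#' @param transcripts named character vector or `XStringSet`.
#' @param proteins protein database (`AAStringSet` or named character), or
#'   `NULL`.
#' @param hits optional external tabular alignments, a `data.frame` with at
#'   least `qseqid`, `pident`, `evalue` (BLAST outfmt-6 style).
#' @param maxIdentity identity removal bound in percent (exclusive).
#' @param eCutoff significance cutoff on the E-value.
#' @return list with `kept` (the lncRNA catalog), `removed`, `details`
#'   per-transcript `data.frame`, and `filtered` (FALSE when no database was
#'   available and the stage was skipped with a warning).
#' @export
proteinSimilarityFilter <- function(transcripts, proteins = NULL, hits = NULL,
                                    maxIdentity = 40, eCutoff = 1e-3) {
    seqs <- .namedChar(transcripts, "tx")
    ids <- names(seqs)
    if (is.null(proteins) && is.null(hits)) {
        warning("no protein database or external hits supplied; ",
                "similarity stage SKIPPED - catalog is unfiltered")
        return(list(kept = transcripts, removed = transcripts[0],
                    details = NULL, filtered = FALSE))
    }
    if (!is.null(hits)) {
        sig <- hits$evalue <= eCutoff & hits$pident > maxIdentity
        rm_ids <- unique(hits$qseqid[sig])
        removed <- ids %in% rm_ids
        det <- data.frame(id = ids, removed = removed,
                          stringsAsFactors = FALSE)
        return(list(kept = transcripts[!removed],
                    removed = transcripts[removed],
                    details = det, filtered = TRUE))
    }
    prot <- if (methods::is(proteins, "AAStringSet")) proteins
            else Biostrings::AAStringSet(as.character(proteins))
    if (!length(prot)) {
        warning("empty protein database; all transcripts retained")
        return(list(kept = transcripts, removed = transcripts[0],
                    details = NULL, filtered = TRUE))
    }
    nDB <- sum(Biostrings::width(prot))
    bestId <- bestE <- numeric(length(seqs))
    for (t in seq_along(seqs)) {
        frames <- .sixFrameTranslations(seqs[[t]])
        bI <- 0; bE <- Inf
        for (fr in frames) {
            if (nchar(fr) < 5L) next
            aln <- Biostrings::pairwiseAlignment(
                prot, Biostrings::AAString(fr), type = "local",
                substitutionMatrix = "BLOSUM62",
                gapOpening = 11, gapExtension = 1)
            sc <- Biostrings::score(aln)
            ev <- .KA_K * nchar(fr) * nDB * exp(-.KA_LAMBDA * sc)
            idp <- Biostrings::pid(aln)
            if (any(ev < bE)) bE <- min(ev)
            cand <- which(ev <= eCutoff)
            if (length(cand) && max(idp[cand]) > bI) bI <- max(idp[cand])
        }
        bestId[t] <- bI; bestE[t] <- bE
    }
    removed <- bestId > maxIdentity
    det <- data.frame(id = ids, bestIdentity = bestId, bestE = bestE,
                      removed = removed, stringsAsFactors = FALSE)
    list(kept = transcripts[!removed], removed = transcripts[removed],
         details = det, filtered = TRUE)
}

# All six frame translations of a nucleotide sequence (character, with *).
.sixFrameTranslations <- function(seq) {
    dna <- asDNA(seq)
    strands <- c(dna, revComp(dna))
    out <- character()
    for (s in strands) {
        for (off in 0:2) {
            n <- nchar(s) - off
            n <- n - n %% 3L
            if (n < 3L) next
            sub <- substr(s, off + 1L, off + n)
            out <- c(out, suppressWarnings(as.character(
                Biostrings::translate(Biostrings::DNAString(sub),
                                      if.fuzzy.codon = "solve"))))
        }
    }
    out
}
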