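# ssr_signatures: maximal primitive tandem repeats (periods 1-6), per-family
# trinucleotide signature tables, and the normalized signature density R
# (signature SSR count per 100 nt).

.DEFAULT_MIN_REPEATS <- c(`1` = 5L, `2` = 3L, `3` = 2L, `4` = 2L,
                          `5` = 2L, `6` = 2L)

.isPrimitive <- function(motif) {
    p <- nchar(motif)
    if (p == 1L) return(TRUE)
    for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            strrep(substr(motif, 1L, d), p / d) == motif)
            return(FALSE)
    }
    TRUE
}

#' Canonical rotation of a repeat motif
#'
#' The lexicographically smallest rotation on the forward strand, used to
#' identify the same tandem tract regardless of the reading frame in which
#' it was first encountered (e.g. "AUA"- and "UAA"-phased renderings of one
#' tract reduce to the same canonical motif).
#'
#' @param motif character vector of motifs.
#' @return character vector of canonical rotations.
#' @export
canonicalRotation <- function(motif) {
    vapply(motif, function(m) {
        p <- nchar(m)
        if (p <= 1L) return(m)
        rot <- vapply(seq_len(p), function(i)
            paste0(substr(m, i, p), substr(m, 1L, i - 1L)), "")
        min(rot)
    }, "", USE.NAMES = FALSE)
}

#' Find simple sequence repeats
#'
#' Scans for all maximal primitive tandem repeats with motif period 1-6 nt
#' that meet the per-period minimum repeat counts. A tract is maximal when
#' it cannot be extended left or right by a full motif copy, and its motif
#' is primitive (not itself a repeat of a shorter motif; "AAAAAA" is an
#' A-run, never an "AA" repeat). The default minima (5 copies for
#' mononucleotide, 3 for dinucleotide, 2 for periods 3-6) are conventional
#' microsatellite-survey settings and are configurable.
#'
#' @param seq unambiguous sequence (character scalar, DNA or RNA; reported
#'   motifs use the input alphabet after RNA normalization).
#' @param minRepeats named integer vector, minimum repeat count per period
#'   ("1" through "6").
#' @return `data.frame` with columns `motif`, `period`, `start` (1-based),
#'   `repeatCount`, `span` (= period x repeatCount), sorted by `start`.
#' @examples
#' findSSRs("AUAUAUGC")  # AU x 3 at position 1
#' @export
findSSRs <- function(seq, minRepeats = .DEFAULT_MIN_REPEATS) {
    seq <- asRNA(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(ch)
    out <- list()
    for (p in 1:6) {
        need <- minRepeats[[as.character(p)]]
        if (is.null(need) || L < p * need) next
        m <- ch[seq_len(L - p)] == ch[seq_len(L - p) + p]
        r <- rle(m)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            stretch <- r$lengths[k] + p          # periodic stretch length
            count <- stretch %/% p
            if (count < need) next
            a <- starts[k]
            motif <- substr(seq, a, a + p - 1L)
            if (!.isPrimitive(motif)) next
            out[[length(out) + 1L]] <-
                data.frame(motif = motif, period = p, start = a,
                           repeatCount = count, span = p * count,
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(motif = character(), period = integer(),
                          start = integer(), repeatCount = integer(),
                          span = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[order(res$start, res$period), , drop = FALSE]
}

#' Normalized SSR signature density R
#'
#' Counts the SSR occurrences in `seq` whose motif, reduced to its canonical
#' rotation, belongs to the family's signature set, normalized per 100
#' nucleotides: R = 100 x count / L.
#'
#' @param seq candidate precursor sequence.
#' @param family miRNA family name, must be present in `table`.
#' @param table named list mapping family to signature motifs (see
#'   [tabulateFamilySignatures()] / [readSignatureTable()]).
#' @param minRepeats per-period minimum repeat counts, as in [findSSRs()].
#' @return R >= 0, in signature occurrences per 100 nt.
#' @export
signatureDensityR <- function(seq, family, table,
                              minRepeats = .DEFAULT_MIN_REPEATS) {
    if (!family %in% names(table))
        stop("family '", family, "' absent from the signature table ",
             "(an empty signature set would be listed with zero motifs)")
    sigs <- canonicalRotation(asRNA(table[[family]]))
    occ <- findSSRs(seq, minRepeats)
    hits <- sum(canonicalRotation(occ$motif) %in% sigs)
    100 * hits / nchar(seq)
}

#' Derive per-family SSR signature tables
#'
#' A trinucleotide motif is a signature of a family when it occurs as an SSR
#' in at least `minPremirs` of that family's precursors. Motifs are keyed as
#' first encountered at the leftmost maximal tract (rotation-distinct
#' triplets stay distinct in the tabulation, mirroring published signature
#' tables; canonicalization is applied only at matching time). Also reports,
#' per motif, the percentage of families carrying it.
#'
#' @param families named list: family name to character vector of precursor
#'   sequences. Empty families are dropped with a warning.
#' @param minRepeats per-period minimum repeat counts.
#' @param minPremirs minimum number of a family's precursors that must carry
#'   a motif for it to count as a signature.
#' @return list with `table` (named list family -> motifs) and `summary`
#'   (`data.frame` with `motif` and `percentFamilies`).
#' @export
tabulateFamilySignatures <- function(families,
                                     minRepeats = .DEFAULT_MIN_REPEATS,
                                     minPremirs = 1L) {
    if (!length(families)) stop("need at least one family")
    empty <- lengths(families) == 0L
    if (any(empty)) {
        warning("dropping empty families: ",
                paste(names(families)[empty], collapse = ", "))
        families <- families[!empty]
    }
    tab <- lapply(families, function(seqs) {
        mot <- unlist(lapply(seqs, function(s) {
            occ <- findSSRs(s, minRepeats)
            unique(occ$motif[occ$period == 3L])
        }))
        if (!length(mot)) return(character())
        cnt <- table(mot)
        sort(names(cnt)[cnt >= minPremirs])
    })
    allMotifs <- sort(unique(unlist(tab)))
    pct <- vapply(allMotifs, function(m)
        100 * mean(vapply(tab, function(x) m %in% x, NA)), 0)
    list(table = tab,
         summary = data.frame(motif = allMotifs,
                              percentFamilies = unname(pct),
                              stringsAsFactors = FALSE))
}
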