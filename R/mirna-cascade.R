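# mirna_discovery (part 2): feature threshold cascade, per-hit best-candidate
# retention ("maximum MFEI and maximum R"), and catalog naming.

#' Default filter thresholds for the pre-miRNA cascade
#'
#' CALIBRATED DEFAULTS, NOT PUBLISHED CUTOFFS: the cutoff values behind the
#' published pipeline live in an inaccessible supplement and are in any case
#' tied to a specific folding engine; absolute values of MFEI, NQ, ND and
#' Npb are energy-model dependent. These defaults were calibrated once on
#' the packaged synthetic corpus under [defaultEnergyModel()] (see the
#' package vignette for the calibration) and are all configurable.
#'
#' @param minMFEI minimum minimal folding energy index.
#' @param maxNQ maximum normalized Shannon entropy (bits/nt).
#' @param maxND maximum normalized base-pair distance (per nt).
#' @param npbRange inclusive range for base-pairing propensity.
#' @param minR minimum SSR signature density (per 100 nt); the default 0
#'   keeps R as a ranking criterion only, since signature tables are
#'   corpus-derived.
#' @param composition per-base inclusive fraction ranges.
#' @param requireHairpinPlacement demand the mature arm not pair with itself
#'   (i.e. lie on one helical arm of the MFE hairpin).
#' @return a thresholds list for [applyFilterCascade()].
#' @export
defaultFilterThresholds <- function(minMFEI = 1.5,
                                    maxNQ = 0.5,
                                    maxND = 0.16,
                                    npbRange = c(0.30, 0.50),
                                    minR = 0,
                                    composition = list(A = c(0, 0.6),
                                                       C = c(0, 0.6),
                                                       G = c(0.05, 0.7),
                                                       U = c(0, 0.6)),
                                    requireHairpinPlacement = TRUE) {
    list(minMFEI = minMFEI, maxNQ = maxNQ, maxND = maxND,
         npbRange = npbRange, minR = minR, composition = composition,
         requireHairpinPlacement = requireHairpinPlacement)
}

#' Mature-arm placement check
#'
#' TRUE when no base of the mature interval pairs with another base inside
#' the mature itself in the given (MFE) structure, i.e. the mature lies
#' entirely within one helical arm and does not straddle the hairpin loop.
#'
#' @param structure a [SecondaryStructure-class] of the candidate window.
#' @param matureStart,matureEnd 1-based inclusive mature bounds in the
#'   window.
#' @return logical scalar.
#' @export
maturePlacementOK <- function(structure, matureStart, matureEnd) {
    p <- structure@pairs
    if (!nrow(p)) return(TRUE)
    inside <- p[, 1] >= matureStart & p[, 1] <= matureEnd &
              p[, 2] >= matureStart & p[, 2] <= matureEnd
    !any(inside)
}

#' Apply the pre-miRNA filter cascade to one candidate
#'
#' Evaluates every filter and records a per-filter verdict for audit;
#' the candidate passes overall iff all verdicts pass.
#'
#' @param features one-row `data.frame` from [hairpinFeatures()] (R filled
#'   in where a signature table is in force).
#' @param thresholds from [defaultFilterThresholds()].
#' @param structure the window's MFE [SecondaryStructure-class] (required
#'   when placement is enforced).
#' @param matureStart,matureEnd mature bounds within the window.
#' @return list with `pass` (logical) and `verdicts` (named logical vector
#'   over composition, MFEI, NQ, ND, Npb, R, hairpinPlacement).
#' @export
applyFilterCascade <- function(features, thresholds = defaultFilterThresholds(),
                               structure = NULL, matureStart = NA,
                               matureEnd = NA) {
    th <- thresholds
    compOK <- all(vapply(names(th$composition), function(b) {
        f <- features[[paste0("frac", b)]]
        f >= th$composition[[b]][1] && f <= th$composition[[b]][2]
    }, NA))
    placeOK <- if (!th$requireHairpinPlacement) TRUE
               else if (is.null(structure) || is.na(matureStart)) NA
               else maturePlacementOK(structure, matureStart, matureEnd)
    v <- c(composition = compOK,
           MFEI = is.finite(features$MFEI) && features$MFEI >= th$minMFEI,
           NQ = features$NQ <= th$maxNQ,
           ND = features$ND <= th$maxND,
           Npb = features$Npb >= th$npbRange[1] &&
                 features$Npb <= th$npbRange[2],
           R = features$R >= th$minR,
           hairpinPlacement = isTRUE(placeOK))
    list(pass = all(v), verdicts = v)
}

#' Retain the best candidate window of one hit
#'
#' Among the passing windows of a single homology hit, retains the one with
#' the maximum MFEI; ties are broken by maximum R, then by shortest window,
#' then by leftmost start (deterministic).
#'
#' @param candidates `data.frame` of passing candidates for one hit, with
#'   columns `MFEI`, `R`, `length`, `winStart`.
#' @return the selected single-row `data.frame`.
#' @export
selectBestCandidate <- function(candidates) {
    if (!nrow(candidates)) stop("no passing candidates: hit is rejected")
    o <- order(-candidates$MFEI, -candidates$R, candidates$length,
               candidates$winStart)
    candidates[o[1L], , drop = FALSE]
}

#' Assign family names and catalog identifiers
#'
#' Accepted loci inherit the family of their best-matching known mature;
#' within a family, letter suffixes run in genomic order (a, b, ..., z, aa,
#' ab, ...). A locus is flagged novel when it has no 0-mismatch match to the
#' known mature library.
#'
#' @param accepted `data.frame` of accepted loci with columns `family`,
#'   `chrom`, `winStart`, `mismatches`.
#' @param prefix species-style catalog prefix (e.g. "cca" in cca-miR171b).
#' @return `accepted` with added `name` and `novel` columns, in genomic
#'   order.
#' @export
assignFamilyAndName <- function(accepted, prefix = "syn") {
    if (!nrow(accepted)) {
        accepted$name <- character(0)
        accepted$novel <- logical(0)
        return(accepted)
    }
    accepted <- accepted[order(accepted$chrom, accepted$winStart), ,
                         drop = FALSE]
    suffixes <- function(n) {
        if (n <= 26L) return(letters[seq_len(n)])
        c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
    }
    accepted$name <- NA_character_
    for (fam in unique(accepted$family)) {
        idx <- which(accepted$family == fam)
        accepted$name[idx] <- paste0(prefix, "-", fam,
                                     suffixes(length(idx)))
    }
    accepted$novel <- accepted$mismatches > 0L
    accepted
}

#' Mature-length distribution statistics
#'
#' Summary of a catalog's mature lengths: mean, standard deviation, and the
#' percentage falling in a reference range (18-22 nt by default, the band
#' in which plant mature miRNAs concentrate).
#'
#' @param lengths integer vector of mature lengths (nt).
#' @param range inclusive reference range.
#' @return named list: `meanLength`, `sdLength`, `percentInRange`, `n`.
#' @export
matureLengthStats <- function(lengths, range = c(18L, 22L)) {
    lengths <- as.integer(lengths)
    list(meanLength = mean(lengths), sdLength = stats::sd(lengths),
         percentInRange = 100 * mean(lengths >= range[1] &
                                     lengths <= range[2]),
         n = length(lengths))
}
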