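#' @import methods
NULL

#' Additive pair-energy model for RNA secondary structure
#'
#' Holds the stacking-free additive energy model behind all folding
#' statistics: one energy per permitted pair type (G:C, A:U, G:U, symmetric,
#' kcal/mol, negative), the minimum hairpin loop size (unpaired bases that
#' must separate the two ends of a pair), and the thermal energy RT used in
#' Boltzmann weighting. The model is deliberately transparent so that an
#' exhaustive enumeration oracle can certify the dynamic programming exactly;
#' every downstream statistic (MFE, MFEI, NQ, ND, Npb, UPE) is model-agnostic.
#'
#' @slot pairEnergies named numeric, energies (kcal/mol) for "GC", "AU", "GU".
#' @slot minLoop integer, minimum unpaired bases enclosed by a pair.
#' @slot RT numeric, thermal energy in kcal/mol.
#' @seealso [defaultEnergyModel()]
#' @exportClass EnergyModel
setClass("EnergyModel",
         representation(pairEnergies = "numeric", minLoop = "integer",
                        RT = "numeric"))

setValidity("EnergyModel", function(object) {
    msg <- character()
    if (!all(c("GC", "AU", "GU") %in% names(object@pairEnergies)))
        msg <- c(msg, "pairEnergies must name GC, AU and GU")
    if (any(object@pairEnergies >= 0))
        msg <- c(msg, "pair energies must be negative (stabilizing)")
    if (object@minLoop < 3L)
        msg <- c(msg, "minLoop must be >= 3")
    if (object@RT <= 0)
        msg <- c(msg, "RT must be positive")
    if (length(msg)) msg else TRUE
})

#' RNA secondary structure (set of base pairs)
#'
#' A pseudoknot-free set of base pairs on a sequence of length `length`,
#' stored as a two-column matrix of 1-based (i, j) positions with i < j,
#' together with its additive energy. Rendered as a dot-bracket string by
#' [dotBracket()].
#'
#' @slot pairs integer matrix, two columns (i, j), i < j, each index used at
#'   most once, no crossing pairs.
#' @slot length integer, sequence length the structure lives on.
#' @slot energy numeric, total additive energy (kcal/mol).
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
         representation(pairs = "matrix", length = "integer",
                        energy = "numeric"))

setValidity("SecondaryStructure", function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must have two columns")
    if (nrow(p) == 0L) return(TRUE)
    if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
    if (any(p < 1L) || any(p > object@length))
        return("pair indices out of sequence range")
    if (anyDuplicated(c(p[, 1], p[, 2])))
        return("each base may occur in at most one pair")
    # no pseudoknots: no i < k < j < l with (i,j) and (k,l) both pairs
    if (nrow(p) > 1L) {
        o <- order(p[, 1])
        p <- p[o, , drop = FALSE]
        for (a in seq_len(nrow(p) - 1L)) {
            b <- (a + 1L):nrow(p)
            cross <- p[b, 1] < p[a, 2] & p[b, 2] > p[a, 2]
            if (any(cross)) return("crossing pairs (pseudoknot) not allowed")
        }
    }
    TRUE
})

#' Result of folding one RNA in the Boltzmann ensemble
#'
#' Bundles the minimum-free-energy structure with the McCaskill-style
#' ensemble quantities: the log partition function over all pseudoknot-free
#' structures (the open chain contributes weight 1 at E = 0, so `logZ >= 0`)
#' and the symmetric base-pair probability matrix \eqn{p_{ij}}.
#'
#' @slot sequence character, the folded RNA (A/C/G/U).
#' @slot mfe numeric, minimum free energy (kcal/mol, <= 0).
#' @slot mfeStructure the [SecondaryStructure-class] attaining `mfe`.
#' @slot logZ numeric, natural log of the partition function.
#' @slot bpp numeric matrix, \eqn{p_{ij}}; zero unless (i, j) is a permitted
#'   pair separated by more than the minimum loop.
#' @exportClass FoldingResult
setClass("FoldingResult",
         representation(sequence = "character", mfe = "numeric",
                        mfeStructure = "SecondaryStructure",
                        logZ = "numeric", bpp = "matrix"))

setValidity("FoldingResult", function(object) {
    msg <- character()
    n <- nchar(object@sequence)
    if (object@mfe > 1e-9) msg <- c(msg, "MFE must be <= 0")
    if (!is.finite(object@logZ) || object@logZ < -1e-9)
        msg <- c(msg, "logZ must be finite and >= 0 (open chain has weight 1)")
    if (nrow(object@bpp) != n || ncol(object@bpp) != n)
        msg <- c(msg, "bpp must be an L x L matrix")
    else {
        if (any(object@bpp < 0) || any(object@bpp > 1 + 1e-12))
            msg <- c(msg, "base-pair probabilities must lie in [0, 1]")
        if (n > 0 && max(abs(object@bpp - t(object@bpp))) > 1e-9)
            msg <- c(msg, "bpp must be symmetric")
        if (n > 0 && any(rowSums(object@bpp) > 1 + 1e-6))
            msg <- c(msg, "row sums of bpp must not exceed 1")
    }
    if (length(msg)) msg else TRUE
})

#' Coding-potential scorer trained on labelled transcripts
#'
#' A calibrated stand-in for external coding-potential programs. It extracts
#' ORF-coverage, Fickett-style positional-bias and in-frame hexamer
#' log-likelihood features, fits two logistic models, and maps the primary
#' model's log-odds onto an open-ended score scale calibrated so that
#' training coding transcripts score >= 1.0 and training non-coding ones
#' <= -0.5 at high rate; the secondary model reports a probability in [0, 1].
#'
#' @slot primary fitted `glm` for the primary (open-scale) score.
#' @slot secondary fitted `glm` for the secondary (probability) score.
#' @slot alpha,beta numeric, affine calibration of the primary log-odds.
#' @slot hexamerLLR numeric, per-hexamer log2 likelihood ratios.
#' @slot trainingRate numeric, calibration rates achieved on training data.
#' @seealso [buildCodingScorer()]
#' @exportClass CodingScorer
setClass("CodingScorer",
         representation(primary = "ANY", secondary = "ANY", alpha = "numeric",
                        beta = "numeric", hexamerLLR = "numeric",
                        trainingRate = "numeric"))
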