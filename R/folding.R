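#' Minimum-free-energy secondary structure
#'
#' Folds an RNA under the additive pair-energy model by Nussinov-style
#' dynamic programming. Among equal-energy structures the one with fewer
#' pairs is preferred, remaining ties resolved toward the lexicographically
#' smallest pair list, so results are deterministic.
#'
#' @param seq RNA sequence (character scalar; T is accepted and read as U).
#' @param model an [EnergyModel-class]; default [defaultEnergyModel()].
#' @param constraint optional integer vector of 1-based positions forced to
#'   stay unpaired.
#' @return a [SecondaryStructure-class] minimizing total energy.
#' @examples
#' foldMFE("GAAAC")          # single G:C pair, E = -3
#' dotBracket(foldMFE("GGGAAAACCC"))
#' @export
foldMFE <- function(seq, model = defaultEnergyModel(), constraint = NULL) {
    codes <- .encodeRNA(seq)
    n <- length(codes)
    canPair <- rep(TRUE, n)
    if (!is.null(constraint)) {
        constraint <- as.integer(constraint)
        if (length(constraint) && (min(constraint) < 1L || max(constraint) > n))
            stop("constraint positions out of sequence bounds")
        canPair[constraint] <- FALSE
    }
    res <- .c_fold_mfe(codes, as.numeric(.pairEnergyMatrix(model)),
                       model@minLoop, canPair)
    p <- res$pairs
    if (nrow(p) > 1L) p <- p[order(p[, 1]), , drop = FALSE]
    storage.mode(p) <- "integer"
    new("SecondaryStructure", pairs = p, length = n, energy = res$energy)
}

#' Constrained refolding with a region forced unpaired
#'
#' Minimum-energy structure among all structures that leave every base of
#' `region` unpaired; used to compute the energy of opening a target site
#' (UPE). The constrained optimum can never be more stable than the
#' unconstrained one.
#'
#' @param seq RNA sequence.
#' @param model an [EnergyModel-class].
#' @param region integer vector `c(start, end)`, 1-based inclusive bounds of
#'   the region kept unpaired; `NULL` for no constraint.
#' @return a [SecondaryStructure-class].
#' @seealso [computeUPE()]
#' @export
constrainedMFE <- function(seq, model = defaultEnergyModel(), region = NULL) {
    if (is.null(region)) return(foldMFE(seq, model))
    region <- as.integer(region)
    n <- nchar(seq)
    if (length(region) != 2L || region[1] < 1L || region[2] > n ||
        region[1] > region[2])
        stop("region must be c(start, end) within the sequence")
    foldMFE(seq, model, constraint = seq.int(region[1], region[2]))
}

#' Partition function and base-pair probabilities
#'
#' Computes the Boltzmann ensemble over all pseudoknot-free structures
#' \eqn{S(s)}: each structure has probability
#' \eqn{P(S_\alpha) = e^{-E_\alpha/RT} / \sum_\alpha e^{-E_\alpha/RT}}, and
#' the pairing probability of bases (i, j) is
#' \eqn{p_{ij} = \sum_\alpha P(S_\alpha)\,\delta_{ij}}, evaluated by
#' inside-outside recursions with per-nucleotide rescaling (finite up to
#' several hundred nucleotides at default energies).
#'
#' @inheritParams foldMFE
#' @param withBpp compute the full \eqn{p_{ij}} matrix (`TRUE`) or only the
#'   partition function.
#' @return a [FoldingResult-class].
#' @examples
#' fr <- partitionFunction("GAAAC")
#' exp(logZ(fr))                      # 1 + exp(3/0.6163)
#' bppMatrix(fr)[1, 5]
#' @export
partitionFunction <- function(seq, model = defaultEnergyModel(),
                              withBpp = TRUE, constraint = NULL) {
    codes <- .encodeRNA(seq)
    n <- length(codes)
    canPair <- rep(TRUE, n)
    if (!is.null(constraint)) canPair[as.integer(constraint)] <- FALSE
    st <- foldMFE(seq, model, constraint = constraint)
    res <- .c_partition(codes, as.numeric(.pairEnergyMatrix(model)),
                        model@RT, model@minLoop, canPair, st@energy, withBpp)
    bpp <- if (withBpp) res$bpp else matrix(0, n, n)
    new("FoldingResult", sequence = asRNA(seq), mfe = st@energy,
        mfeStructure = st, logZ = res$logZ, bpp = bpp)
}

#' Exhaustive enumeration of secondary structures
#'
#' Lists every valid pseudoknot-free structure (including the empty one)
#' exactly once. This is the independent oracle used to certify the dynamic
#' programming: for small sequences, MFE, partition function and every
#' \eqn{p_{ij}} can be recomputed by direct summation over this list.
#'
#' @inheritParams foldMFE
#' @param maxLen guard against combinatorial blow-up; sequences longer than
#'   this are refused.
#' @return list of [SecondaryStructure-class] objects.
#' @examples
#' length(enumerateStructures("GAAAC"))  # open chain + one pair = 2
#' @export
enumerateStructures <- function(seq, model = defaultEnergyModel(),
                                maxLen = 25L) {
    codes <- .encodeRNA(seq)
    n <- length(codes)
    if (n > maxLen)
        stop("refusing to enumerate structures for length ", n, " > ", maxLen)
    E <- .pairEnergyMatrix(model)
    ml <- model@minLoop
    rec <- function(i, j) {
        # list of pair matrices on [i, j]
        if (j - i < ml + 1L)
            return(list(matrix(integer(), 0, 2)))
        out <- rec(i + 1L, j)  # i unpaired
        for (k in seq.int(i + ml + 1L, j)) {
            if (E[codes[i] + 1L, codes[k] + 1L] < 1e8) {
                left <- rec(i + 1L, k - 1L)
                right <- rec(k + 1L, j)
                for (L in left) for (R in right)
                    out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
            }
        }
        out
    }
    pairsList <- if (n == 0L) list(matrix(integer(), 0, 2)) else rec(1L, n)
    lapply(pairsList, function(p) {
        storage.mode(p) <- "integer"
        if (nrow(p) > 1L) p <- p[order(p[, 1]), , drop = FALSE]
        e <- if (nrow(p)) sum(E[cbind(codes[p[, 1]] + 1L, codes[p[, 2]] + 1L)]) else 0
        new("SecondaryStructure", pairs = p, length = n, energy = e)
    })
}

#' @rdname dotBracket
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x, ...) {
    db <- rep(".", x@length)
    if (nrow(x@pairs)) {
        db[x@pairs[, 1]] <- "("
        db[x@pairs[, 2]] <- ")"
    }
    paste(db, collapse = "")
})

#' @rdname dotBracket
#' @export
setMethod("dotBracket", "FoldingResult",
          function(x, ...) dotBracket(x@mfeStructure))

#' @rdname basePairs
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @rdname basePairs
#' @export
setMethod("basePairs", "FoldingResult", function(x) x@mfeStructure@pairs)

#' @rdname structureEnergy
#' @export
setMethod("structureEnergy", "SecondaryStructure", function(x) x@energy)

#' @rdname structureEnergy
#' @export
setMethod("mfe", "FoldingResult", function(x) x@mfe)

#' @rdname structureEnergy
#' @export
setMethod("logZ", "FoldingResult", function(x) x@logZ)

#' @rdname structureEnergy
#' @export
setMethod("bppMatrix", "FoldingResult", function(x) x@bpp)

setMethod("show", "SecondaryStructure", function(object) {
    cat("SecondaryStructure:", nrow(object@pairs), "pair(s), E =",
        object@energy, "kcal/mol\n ", dotBracket(object), "\n")
})

setMethod("show", "FoldingResult", function(object) {
    cat("FoldingResult: L =", nchar(object@sequence),
        "| MFE =", object@mfe, "kcal/mol | logZ =",
        format(object@logZ, digits = 6), "\n ",
        dotBracket(object@mfeStructure), "\n")
})
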