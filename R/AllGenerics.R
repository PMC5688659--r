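#' Dot-bracket rendering of a secondary structure
#'
#' @param x a [SecondaryStructure-class] or [FoldingResult-class].
#' @param ... unused.
#' @return a character scalar of "(", ")" and ".".
#' @export
setGeneric("dotBracket", function(x, ...) standardGeneric("dotBracket"))

#' Base pairs of a structure
#'
#' @param x a [SecondaryStructure-class] or [FoldingResult-class].
#' @return integer matrix with columns i, j (1-based, i < j).
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' Structure / ensemble energy accessors
#'
#' `structureEnergy` returns the additive energy of a structure; `mfe` the
#' minimum free energy of a folding result; `logZ` the log partition
#' function; `bppMatrix` the base-pair probability matrix.
#'
#' @param x a [SecondaryStructure-class] or [FoldingResult-class].
#' @return numeric scalar (energies) or matrix (`bppMatrix`).
#' @export
setGeneric("structureEnergy", function(x) standardGeneric("structureEnergy"))

#' @rdname structureEnergy
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))

#' @rdname structureEnergy
#' @export
setGeneric("logZ", function(x) standardGeneric("logZ"))

#' @rdname structureEnergy
#' @export
setGeneric("bppMatrix", function(x) standardGeneric("bppMatrix"))

#' Coding-potential scores
#'
#' `primaryScore` returns the open-ended coding score (non-coding <= -0.5,
#' coding >= 1.0 by calibration); `secondaryScore` a probability in [0, 1].
#'
#' @param object a [CodingScorer-class].
#' @param seqs character vector or `DNAStringSet` of transcripts.
#' @return numeric vector, one score per transcript.
#' @export
setGeneric("primaryScore",
           function(object, seqs) standardGeneric("primaryScore"))

#' @rdname primaryScore
#' @export
setGeneric("secondaryScore",
           function(object, seqs) standardGeneric("secondaryScore"))
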