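# hairpin_features: the per-candidate statistics consumed by the pre-miRNA
# filter cascade. Formulas follow the field's defining equations exactly:
#   AMFE = -MFE/L * 100
#   MFEI = AMFE / (G+C)%          (GC on the 0-100 scale)
#   NQ   = -(1/L) sum_{i<j} p_ij log2 p_ij
#   ND   =  (1/L) sum_{i<j} p_ij (1 - p_ij)
#   Npb  = |pairs in the MFE structure| / L, in [0, 0.5]

#' Adjusted minimum free energy
#'
#' AMFE = -MFE/L x 100: the magnitude of the folding energy per 100
#' nucleotides, positive when MFE < 0.
#'
#' @param MFE minimum free energy (kcal/mol, <= 0).
#' @param L sequence length in nucleotides (>= 1).
#' @return AMFE in kcal/mol per 100 nt.
#' @examples
#' amfe(-40, 100)  # 40
#' @export
amfe <- function(MFE, L) {
    if (any(L < 1)) stop("L must be >= 1")
    -MFE / L * 100
}

#' Minimal folding energy index
#'
#' MFEI = AMFE / (G+C)%, with GC expressed as a percentage on the 0-100
#' scale (so a typical plant pre-miRNA lands near the literature's
#' 0.67-1.0 range under nearest-neighbor energies). A GC content of zero
#' makes the index undefined; such candidates are rejected upstream.
#'
#' @param AMFE adjusted MFE, from [amfe()].
#' @param gcPercent GC content in percent (0-100 scale, > 0).
#' @return the dimensionless index.
#' @examples
#' mfei(40, 50)  # 0.8
#' @export
mfei <- function(AMFE, gcPercent) {
    if (any(gcPercent <= 0))
        stop("MFEI undefined for GC% = 0; reject the candidate instead")
    AMFE / gcPercent
}

#' Normalized Shannon entropy of the base-pairing ensemble
#'
#' NQ = -(1/L) sum over i < j of p_ij log2 p_ij, in bits per nucleotide.
#' Terms with p_ij = 0 (and p_ij = 1) contribute zero; a deterministic
#' ensemble therefore has NQ = 0.
#'
#' @param P base-pair probability matrix (from [bppMatrix()]).
#' @param L sequence length; defaults to `nrow(P)`.
#' @return NQ >= 0.
#' @export
nq <- function(P, L = nrow(P)) {
    p <- P[upper.tri(P)]
    p <- p[p > 0]
    if (!length(p)) return(0)
    -sum(p * log2(p)) / L
}

#' Normalized base-pair distance of the ensemble
#'
#' ND = (1/L) sum over i < j of p_ij (1 - p_ij): the ensemble's expected
#' base-pair distance per nucleotide, zero exactly when every p_ij is 0 or 1.
#'
#' @inheritParams nq
#' @return ND >= 0.
#' @export
nd <- function(P, L = nrow(P)) {
    p <- P[upper.tri(P)]
    sum(p * (1 - p)) / L
}

#' Normalized base-pairing propensity
#'
#' Npb = number of base pairs in the secondary structure divided by the
#' sequence length; ranges from 0.0 (no pairs) to 0.5 (L/2 pairs). Computed
#' on the MFE structure, the single structure the pipeline produces.
#'
#' @param structure a [SecondaryStructure-class].
#' @param L sequence length; defaults to the structure's length.
#' @return Npb in [0, 0.5].
#' @export
npb <- function(structure, L = structure@length) {
    nrow(structure@pairs) / L
}

#' Nucleotide composition
#'
#' Per-base fractions and GC percentage of an unambiguous sequence.
#'
#' @param seq RNA or DNA sequence (character scalar).
#' @return named list: `fractions` (A/C/G/U summing to 1) and `gcPercent`
#'   on the 0-100 scale.
#' @export
composition <- function(seq) {
    ch <- strsplit(asRNA(seq), "", fixed = TRUE)[[1]]
    if (any(!ch %in% names(.RNA_CODES)))
        stop("ambiguous base in sequence")
    L <- length(ch)
    frac <- vapply(names(.RNA_CODES), function(b) sum(ch == b) / L, 0)
    list(fractions = frac, gcPercent = 100 * (frac[["G"]] + frac[["C"]]))
}

#' Full hairpin feature vector for one candidate
#'
#' Folds the candidate (MFE structure and Boltzmann ensemble) and assembles
#' every statistic the filter cascade consumes. The SSR signature density R
#' is filled in by the caller when a signature table is in force (default 0).
#'
#' @param seq candidate RNA sequence.
#' @param model an [EnergyModel-class].
#' @param R SSR signature density per 100 nt (see [signatureDensityR()]).
#' @return one-row `data.frame` with columns `L`, `fracA`..`fracU`,
#'   `gcPercent`, `MFE`, `AMFE`, `MFEI` (NA when GC = 0), `NQ`, `ND`,
#'   `Npb`, `R`.
#' @examples
#' hp <- makeHairpin("UGGAGCUCCCUUCAUUCCAAU", seed = 1)
#' hairpinFeatures(hp$sequence)
#' @export
hairpinFeatures <- function(seq, model = defaultEnergyModel(), R = 0) {
    fr <- partitionFunction(seq, model)
    comp <- composition(seq)
    L <- nchar(seq)
    a <- amfe(fr@mfe, L)
    data.frame(L = L,
               fracA = comp$fractions[["A"]], fracC = comp$fractions[["C"]],
               fracG = comp$fractions[["G"]], fracU = comp$fractions[["U"]],
               gcPercent = comp$gcPercent,
               MFE = fr@mfe, AMFE = a,
               MFEI = if (comp$gcPercent > 0) mfei(a, comp$gcPercent) else NA_real_,
               NQ = nq(fr@bpp, L), ND = nd(fr@bpp, L),
               Npb = npb(fr@mfeStructure, L), R = R)
}
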