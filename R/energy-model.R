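#' Default additive energy model
#'
#' Constructs the package's default [EnergyModel-class]: per-pair energies
#' G:C = -3.0, A:U = -2.0, G:U = -1.0 kcal/mol, minimum hairpin loop of 3
#' unpaired bases, and RT = 0.6163 kcal/mol (310.15 K). The ordering
#' G:C < A:U < G:U mirrors relative pair stabilities; absolute folding
#' statistics are model-dependent, which is why all filter thresholds
#' downstream are calibrated against this model (see the package vignette).
#'
#' @param gc,au,gu pair energies in kcal/mol (negative).
#' @param minLoop minimum number of unpaired bases enclosed by a pair.
#' @param RT thermal energy in kcal/mol.
#' @return an [EnergyModel-class] object.
#' @examples
#' em <- defaultEnergyModel()
#' foldMFE("GGGAAAACCC", em)
#' @export
defaultEnergyModel <- function(gc = -3.0, au = -2.0, gu = -1.0,
                               minLoop = 3L, RT = 0.6163) {
    new("EnergyModel", pairEnergies = c(GC = gc, AU = au, GU = gu),
        minLoop = as.integer(minLoop), RT = RT)
}

# 4x4 energy lookup (A,C,G,U order); forbidden pairs get a huge energy.
.pairEnergyMatrix <- function(model) {
    E <- matrix(1e9, 4, 4)
    pe <- model@pairEnergies
    E[3, 2] <- E[2, 3] <- pe[["GC"]]  # G:C
    E[1, 4] <- E[4, 1] <- pe[["AU"]]  # A:U
    E[3, 4] <- E[4, 3] <- pe[["GU"]]  # G:U
    E
}

#' @describeIn defaultEnergyModel compact display.
#' @param object an [EnergyModel-class].
#' @export
setMethod("show", "EnergyModel", function(object) {
    pe <- object@pairEnergies
    cat("EnergyModel: GC", pe[["GC"]], "AU", pe[["AU"]], "GU", pe[["GU"]],
        "kcal/mol; min loop", object@minLoop, "; RT", object@RT, "kcal/mol\n")
})
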