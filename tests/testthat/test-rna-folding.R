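em <- defaultEnergyModel()

test_that("trivial folds behave as dictated by the pairing rules", {
    expect_equal(nrow(basePairs(foldMFE("AAAAA"))), 0)
    expect_equal(structureEnergy(foldMFE("AAAAA")), 0)
    st <- foldMFE("GAAAC")
    expect_equal(basePairs(st), cbind(1L, 5L), ignore_attr = TRUE)
    expect_equal(structureEnergy(st), -3)
    expect_identical(dotBracket(st), "(...)")
    expect_error(foldMFE("GANAC"), "ambiguous")
})

test_that("enumeration lists every structure exactly once", {
    expect_length(enumerateStructures("AAAA"), 1)  # open chain only
    expect_length(enumerateStructures("GAAAC"), 2)
    # counts match an independent memoized counter on random sequences
    set.seed(21)
    for (i in 1:25) {
        s <- randomRNA(sample(6:14, 1))
        en <- enumerateStructures(s)
        expect_equal(length(en), oracleCountStructures(s))
        # uniqueness of the listing
        keys <- vapply(en, dotBracket, "")
        expect_false(anyDuplicated(keys) > 0)
    }
    expect_error(enumerateStructures(randomRNA(30)), "refusing")
})

test_that("closed-form two-structure ensemble is reproduced exactly", {
    fr <- partitionFunction("GAAAC")
    w <- exp(3 / em@RT)
    expect_equal(exp(logZ(fr)), 1 + w, tolerance = 1e-12)
    expect_equal(bppMatrix(fr)[1, 5], w / (1 + w), tolerance = 1e-12)
    # pair-free sequence: Z = 1, empty probability matrix
    fr0 <- partitionFunction("AAAAA")
    expect_equal(logZ(fr0), 0)
    expect_true(all(bppMatrix(fr0) == 0))
})

test_that("DP matches exhaustive enumeration for MFE, Z and every p_ij", {
    set.seed(7)
    for (i in 1:40) {
        s <- randomRNA(sample(8:15, 1))
        fr <- partitionFunction(s)
        or <- oracleEnsemble(s)
        expect_equal(mfe(fr), or$mfe, tolerance = 1e-9)
        expect_equal(exp(logZ(fr)), or$Z, tolerance = 1e-9)
        expect_equal(bppMatrix(fr), or$P, tolerance = 1e-9,
                     ignore_attr = TRUE)
    }
})

test_that("probability matrix satisfies its marginal invariants", {
    set.seed(8)
    for (i in 1:10) {
        s <- randomRNA(60)
        P <- bppMatrix(partitionFunction(s))
        expect_true(all(P >= 0 & P <= 1))
        expect_equal(P, t(P))
        expect_true(all(rowSums(P) <= 1 + 1e-9))
    }
})

test_that("constraints never stabilize and reduce to known cases", {
    s <- "GGGAAAACCC"
    free <- structureEnergy(foldMFE(s))
    expect_equal(structureEnergy(constrainedMFE(s, region = c(1, 10))), 0)
    expect_equal(structureEnergy(constrainedMFE("GAAAC", region = c(1, 1))), 0)
    set.seed(9)
    for (i in 1:15) {
        sq <- randomRNA(30)
        a <- sample(1:20, 1)
        con <- structureEnergy(constrainedMFE(sq, region = c(a, a + 8)))
        expect_gte(con, structureEnergy(foldMFE(sq)) - 1e-9)
    }
    # constrained optimum agrees with filtered enumeration
    for (i in 1:10) {
        sq <- randomRNA(12)
        reg <- c(3, 6)
        en <- enumerateStructures(sq)
        okE <- vapply(en, function(st) {
            p <- basePairs(st)
            if (!nrow(p)) return(0)
            if (any(p >= reg[1] & p <= reg[2])) NA_real_
            else structureEnergy(st)
        }, 0)
        expect_equal(structureEnergy(constrainedMFE(sq, region = reg)),
                     min(okE, na.rm = TRUE), tolerance = 1e-9)
    }
    expect_error(constrainedMFE("GAAAC", region = c(0, 3)), "region")
})

test_that("low temperature concentrates the ensemble on a strict optimum", {
    # GGAAACC has a unique 2-pair optimum {(1,7),(2,6)}
    cold <- defaultEnergyModel(RT = 0.05)
    P <- bppMatrix(partitionFunction("GGAAACC", cold))
    expect_equal(P[1, 7], 1, tolerance = 1e-6)
    expect_equal(P[2, 6], 1, tolerance = 1e-6)
    expect_lt(max(P[1, 6], P[2, 7]), 1e-6)
})

test_that("partition function stays finite for long sequences", {
    set.seed(10)
    s <- randomRNA(400)
    fr <- partitionFunction(s)
    expect_true(is.finite(logZ(fr)))
    expect_gte(logZ(fr), -mfe(fr) / em@RT)   # MFE structure is in the sum
    expect_true(all(is.finite(bppMatrix(fr))))
})

test_that("MFE tie-breaking is deterministic across repeated calls", {
    set.seed(12)
    for (i in 1:10) {
        s <- randomRNA(25)
        expect_identical(dotBracket(foldMFE(s)), dotBracket(foldMFE(s)))
    }
})
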