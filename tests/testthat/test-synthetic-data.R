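test_that("hairpin construction is deterministic and folds as a hairpin", {
    m <- "UGGAGCUCCCUUCAUUCCAAU"
    hp1 <- makeHairpin(m, loopLen = 8, seed = 81)
    hp2 <- makeHairpin(m, loopLen = 8, seed = 81)
    expect_identical(hp1$sequence, hp2$sequence)
    expect_equal(hp1$length, 2 * nchar(m) + 8)
    # perfect-stem precursor: Npb >= 0.4 under the built-in model
    st <- foldMFE(hp1$sequence)
    expect_gte(npb(st, hp1$length), 0.4)
    expect_error(makeHairpin(m, loopLen = 2), "geometry")
    expect_error(makeHairpin("ACGU"), "15-24")
    # a heavily mismatched stem no longer passes the cascade
    bad <- makeHairpin(m, loopLen = 8, stemMismatches = 10, seed = 82)
    cv <- applyFilterCascade(hairpinFeatures(bad$sequence),
                             defaultFilterThresholds(),
                             foldMFE(bad$sequence), 1, nchar(m))
    expect_false(cv$pass)
})

test_that("mature library lengths follow the plant-typical distribution", {
    lib <- randomMatureLibrary(400, seed = 83)
    lens <- nchar(lib)
    expect_true(all(lens >= 18 & lens <= 24))
    st <- matureLengthStats(lens)
    expect_gt(st$percentInRange, 85)
    expect_lt(abs(st$meanLength - 20), 1)
    expect_true(all(grepl("^syn-miR[0-9]+a$", names(lib))))
})

test_that("synthetic genomes honor GC request and ledger soundness", {
    mats <- randomMatureLibrary(5, seed = 84)
    g <- makeGenome(mats, nChroms = 2, chromLen = 5000, gc = 0.5,
                    nPlanted = 5, nDecoys = 4, seed = 84)
    gcObs <- sum(Biostrings::letterFrequency(g$genome, c("G", "C"))) /
        sum(Biostrings::width(g$genome))
    expect_lt(abs(gcObs - 0.5), 0.02)
    # every truth entry matches its re-extracted sequence content
    planted <- g$truth[g$truth$type == "planted", ]
    for (i in seq_len(nrow(planted))) {
        sub <- as.character(Biostrings::subseq(
            g$genome[[planted$chrom[i]]],
            planted$matureGenomicStart[i], planted$matureGenomicEnd[i]))
        if (planted$strand[i] == "-") sub <- revComp(sub)
        expect_identical(asRNA(sub), asRNA(g$matures[[planted$matureID[i]]]))
    }
    # determinism: same seed reproduces byte-identical chromosomes
    g2 <- makeGenome(mats, nChroms = 2, chromLen = 5000, gc = 0.5,
                     nPlanted = 5, nDecoys = 4, seed = 84)
    expect_identical(as.character(g$genome), as.character(g2$genome))
    # mutated decoys straddle the scan boundary from the wrong side
    dec <- g$truth[g$truth$type == "decoy_mutated", ]
    for (i in seq_len(nrow(dec))) {
        sub <- as.character(Biostrings::subseq(g$genome[[dec$chrom[i]]],
                                               dec$start[i], dec$end[i]))
        mm <- sum(strsplit(sub, "")[[1]] !=
                  strsplit(asDNA(g$matures[[dec$matureID[i]]]), "")[[1]])
        expect_gte(mm, 4)
        expect_lte(mm, 6)
    }
})

test_that("dinucleotide shuffling preserves dinucleotide counts exactly", {
    set.seed(85)
    for (i in 1:15) {
        s <- randomDNA(sample(50:400, 1))
        sh <- dinucleotideShuffle(s)
        expect_equal(nchar(sh), nchar(s))
        expect_identical(dinucCounts(sh), dinucCounts(s))
    }
    # shuffles are not the identity for long sequences
    s <- randomDNA(300)
    expect_false(identical(dinucleotideShuffle(s), dinucleotideShuffle(s)) &&
                 identical(dinucleotideShuffle(s), s))
})

test_that("synthetic transcriptomes carry the designed ORF structure", {
    tr <- makeTranscriptome(10, 10, seed = 86)
    lab <- tr$labels
    # every coding transcript contains an ORF >= 150 aa by construction
    longest <- vapply(as.character(tr$transcripts), function(s)
        findORFs(s)$lengthAA[1], 0L)
    expect_true(all(longest[lab == "coding"] >= 150))
    # shuffled negatives keep composition but lose the long ORF
    expect_true(all(longest[lab == "noncoding"] < 150))
    expect_equal(length(tr$proteins), 10)
    # proteins are the translated ORFs
    expect_true(all(substr(as.character(tr$proteins), 1, 1) == "M"))
})

test_that("planted target sites realize their designed penalties", {
    mats <- randomMatureLibrary(4, seed = 87)
    txs <- stats::setNames(vapply(1:4, function(i) randomDNA(300), ""),
                           paste0("t", 1:4))
    design <- data.frame(mature = names(mats),
                         transcript = names(txs),
                         penalty = c(0, 1, 2, 4))
    pt <- plantTargetSites(mats, txs, design, seed = 88)
    for (i in seq_len(nrow(pt$truth))) {
        tr <- pt$truth[i, ]
        site <- substr(as.character(pt$transcripts[[tr$transcript]]),
                       tr$start, tr$end)
        expect_equal(scoreExpectation(asRNA(mats[[tr$mature]]), asRNA(site)),
                     tr$designedPenalty)
    }
    # byte-identical reproduction under the same seed
    pt2 <- plantTargetSites(mats, txs, design, seed = 88)
    expect_identical(as.character(pt$transcripts),
                     as.character(pt2$transcripts))
})
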