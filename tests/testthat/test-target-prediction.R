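mkMature <- function() {
    # 21-nt mature with a G at position 5 and non-G/U at position 20
    "AUCAGUUCAAGCUAGAUCCAA"
}

test_that("expectation scoring reproduces hand-applied penalty cases", {
    m <- mkMature()
    L <- nchar(m)
    perfect <- asRNA(revComp(asDNA(m)))
    expect_equal(scoreExpectation(m, perfect), 0)
    # G:U wobble at mature position 5 (core): 0.5 x 2 = 1.0
    s <- strsplit(perfect, "")[[1]]
    expect_equal(substr(m, 5, 5), "G")
    j <- L - 5 + 1
    expect_equal(s[j], "C")
    s[j] <- "U"
    expect_equal(scoreExpectation(m, paste(s, collapse = "")), 1.0)
    # mismatch at mature position 20 (outside core): 1 x 1 = 1.0
    s <- strsplit(perfect, "")[[1]]
    p20 <- substr(m, 20, 20)
    j <- L - 20 + 1
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", p20),
                     if (p20 == "G") "U" else if (p20 == "U") "G"))[1]
    s[j] <- bad
    expect_equal(scoreExpectation(m, paste(s, collapse = "")), 1.0)
    expect_error(scoreExpectation("", "ACG"), "empty")
})

test_that("gapped duplexes take the best single interior bulge", {
    m <- mkMature()
    L <- nchar(m)
    perfect <- strsplit(asRNA(revComp(asDNA(m))), "")[[1]]
    # insert one extra target base between non-core-facing positions:
    # bulge after mature position 15 -> gap penalty at weight 1 = 2.0
    tIns <- append(perfect, "A", after = L - 15)
    expect_equal(scoreExpectation(m, paste(tIns, collapse = "")), 2.0)
    # deleting one target base forces a bulged miRNA base
    tDel <- perfect[-(L - 16 + 1)]
    expect_lte(scoreExpectation(m, paste(tDel, collapse = "")), 4.0)
})

test_that("site search equals the exhaustive window-scoring oracle", {
    set.seed(71)
    m <- mkMature()
    for (rep in 1:4) {
        tx <- randomRNA(180)
        # plant a near-perfect site to guarantee reportable windows
        site <- asRNA(revComp(asDNA(m)))
        substr(tx, 60, 59 + nchar(site)) <- site
        found <- findTargetSites(m, tx,
                                 targetScheme(maxExpectation = 3.0))
        orc <- oracleBestWindowScore(m, tx)
        for (i in seq_len(nrow(found))) {
            # reported expectation equals the oracle minimum at that locus
            expect_equal(found$expectation[i],
                         oracleMinScoreAt(m, tx, found$start[i],
                                          found$end[i]),
                         tolerance = 1e-9)
        }
        # completeness: every oracle window at or below cutoff overlaps a
        # reported site
        good <- orc[orc$score <= 3.0, , drop = FALSE]
        for (i in seq_len(nrow(good)))
            expect_true(any(found$start <= good$end[i] &
                            found$end >= good$start[i]))
    }
})

test_that("the expectation cutoff is honored at its boundary", {
    m <- mkMature()
    L <- nchar(m)
    mkSite <- function(nCore) {
        s <- strsplit(asRNA(revComp(asDNA(m))), "")[[1]]
        mch <- strsplit(m, "")[[1]]
        for (p in seq_len(nCore) + 4L) {       # core positions 5,6,...
            j <- L - p + 1
            s[j] <- setdiff(c("A", "C", "G", "U"),
                            c(chartr("ACGU", "UGCA", mch[p]),
                              if (mch[p] == "G") "U"
                              else if (mch[p] == "U") "G"))[1]
        }
        paste(s, collapse = "")
    }
    tx1 <- paste0(randomRNA(30), mkSite(1), randomRNA(30))  # penalty 2.0
    expect_equal(nrow(findTargetSites(m, tx1)), 1)
    tx3 <- paste0(randomRNA(30), mkSite(3), randomRNA(30))  # penalty 6.0
    expect_equal(nrow(findTargetSites(m, tx3)), 0)
})

test_that("site sets are monotone in the expectation cutoff", {
    set.seed(72)
    m <- mkMature()
    tx <- paste0(randomRNA(40), asRNA(revComp(asDNA(m))), randomRNA(40))
    s1 <- findTargetSites(m, tx, targetScheme(maxExpectation = 0.5))
    s2 <- findTargetSites(m, tx, targetScheme(maxExpectation = 2.0))
    s3 <- findTargetSites(m, tx, targetScheme(maxExpectation = 4.0))
    key <- function(d) paste(d$start, d$end)
    expect_true(all(key(s1) %in% key(s2)))
    expect_true(all(key(s2) %in% key(s3)))
})

test_that("inhibition mode flags central perfection as cleavage", {
    m <- mkMature()
    L <- nchar(m)
    tx <- paste0(randomRNA(25), asRNA(revComp(asDNA(m))), randomRNA(25))
    s <- findTargetSites(m, tx)
    expect_equal(s$mode, "cleavage")
    # break a central position (9-11 for a 21-mer)
    mch <- strsplit(m, "")[[1]]
    site <- strsplit(asRNA(revComp(asDNA(m))), "")[[1]]
    j <- L - 10 + 1
    site[j] <- setdiff(c("A", "C", "G", "U"),
                       c(chartr("ACGU", "UGCA", mch[10]),
                         if (mch[10] == "G") "U"
                         else if (mch[10] == "U") "G"))[1]
    tx2 <- paste0(randomRNA(25), paste(site, collapse = ""), randomRNA(25))
    s2 <- findTargetSites(m, tx2)
    expect_equal(s2$mode, "translation")
})

test_that("UPE is zero in unstructured context and equals stem energy", {
    # all-U mature -> all-A site in an all-A transcript: nothing to unpair
    mU <- strrep("U", 21)
    txA <- strrep("A", 120)
    expect_equal(computeUPE(50, 70, txA), 0)
    # site buried under a G:C stem of known additive energy
    mC <- strrep("C", 21)
    tx8 <- paste0(strrep("C", 8), strrep("A", 4), strrep("G", 21),
                  strrep("A", 13))
    expect_equal(computeUPE(13, 33, tx8), 8 * 3)   # 8 G:C pairs opened
    expect_gte(computeUPE(13, 33, tx8), 0)
})

test_that("the UPE cutoff excludes sites above 25 kcal", {
    mC <- stats::setNames(strrep("C", 21), "syn-miR990a")
    mkTx <- function(nC) paste0(strrep("C", nC), strrep("A", 4),
                                strrep("G", 21), strrep("A", 13))
    keep <- predictTargets(mC, c(ok = mkTx(8)))     # UPE 24 <= 25
    expect_equal(nrow(keep$coding), 1)
    drop <- predictTargets(mC, c(no = mkTx(9)))     # UPE 27 > 25
    expect_equal(nrow(drop$coding), 0)
})

test_that("target tables and network recover planted edges", {
    set.seed(73)
    mats <- randomMatureLibrary(3, seed = 73)
    txs <- stats::setNames(vapply(1:3, function(i) randomDNA(400), ""),
                           paste0("t", 1:3))
    design <- data.frame(mature = names(mats), transcript = names(txs),
                         penalty = c(0, 1, 4))
    pt <- plantTargetSites(mats, txs, design, seed = 74)
    res <- predictTargets(mats, as.character(pt$transcripts))
    tr <- pt$truth
    for (i in 1:2) {   # designed positives recovered at planted positions
        hit <- res$coding[res$coding$miRNA == tr$mature[i] &
                          res$coding$transcript == tr$transcript[i], ]
        expect_gte(nrow(hit), 1)
        expect_true(any(hit$start <= tr$end[i] & hit$end >= tr$start[i]))
        expect_lte(min(hit$expectation), tr$designedPenalty[i] + 1e-9)
    }
    # designed negative absent
    expect_false(any(res$coding$miRNA == tr$mature[3] &
                     res$coding$transcript == tr$transcript[3]))
    # degrees and network export
    expect_equal(sum(res$degrees), nrow(res$coding))
    sif <- withr::local_tempfile(fileext = ".sif")
    gml <- withr::local_tempfile(fileext = ".graphml")
    exportNetwork(res, sif, gml)
    expect_equal(length(readLines(sif)), nrow(res$coding))
    expect_true(file.size(gml) > 0)
})

test_that("empty catalogs yield empty outputs with a warning", {
    expect_warning(res <- predictTargets(character(), character()), "empty")
    expect_equal(nrow(res$coding), 0)
    expect_equal(nrow(res$lncrna), 0)
})
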