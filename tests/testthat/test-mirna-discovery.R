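test_that("homology scan recovers planted matures and obeys the mismatch bound", {
    mat <- randomMatureLibrary(1, seed = 51)
    set.seed(151)          # genome stream independent of the mature's
    g <- randomDNA(1000)
    L <- nchar(mat)
    substr(g, 200, 199 + L) <- asDNA(mat)
    # a 4-substitution decoy must not be hit
    decoy <- strsplit(asDNA(mat), "")[[1]]
    for (j in c(2, 6, 11, 15))
        decoy[j] <- setdiff(c("A", "C", "G", "T"), decoy[j])[1]
    substr(g, 600, 599 + L) <- paste(decoy, collapse = "")
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
    hits <- scanHomology(genome, mat)
    expect_equal(length(hits), 1)
    expect_equal(GenomicRanges::start(hits), 200)
    expect_equal(S4Vectors::mcols(hits)$mismatches, 0)
    # 3 substitutions is still a hit (boundary of "zero to three")
    three <- strsplit(asDNA(mat), "")[[1]]
    for (j in c(3, 9, 17))
        three[j] <- setdiff(c("A", "C", "G", "T"), three[j])[1]
    substr(g, 800, 799 + L) <- paste(three, collapse = "")
    hits3 <- scanHomology(Biostrings::DNAStringSet(c(chr1 = g)), mat)
    expect_equal(sort(GenomicRanges::start(hits3)), c(200, 800))
    expect_warning(
        scanHomology(genome, c(bad = paste0("ACGTN", strrep("A", 15)))),
        "skipped")
})

test_that("homology scan equals the naive all-positions Hamming oracle", {
    set.seed(52)
    for (rep in 1:3) {
        g <- randomDNA(600)
        mat <- stats::setNames(randomRNA(16), "syn-miR901a")
        # plant a couple of imperfect copies to make hits likely
        m <- strsplit(asDNA(mat), "")[[1]]
        m[4] <- setdiff(c("A", "C", "G", "T"), m[4])[1]
        substr(g, 100, 115) <- paste(m, collapse = "")
        substr(g, 350, 365) <- revComp(asDNA(mat))
        hits <- scanHomology(Biostrings::DNAStringSet(c(c1 = g)), mat)
        orc <- oracleHammingScan(g, asDNA(mat), 3L)
        got <- data.frame(start = GenomicRanges::start(hits),
                          strand = as.character(GenomicRanges::strand(hits)),
                          mismatches = S4Vectors::mcols(hits)$mismatches)
        got <- got[order(got$start, got$strand), ]
        orc <- orc[order(orc$start, orc$strand),
                   c("start", "strand", "mismatches")]
        expect_equal(got, orc, ignore_attr = TRUE)
    }
})

test_that("window extraction follows the placement policy and clips at ends", {
    set.seed(58)
    gs <- randomDNA(500)
    mat <- stats::setNames(randomRNA(21), "syn-miR900a")
    substr(gs, 3, 23) <- asDNA(mat)                 # near chromosome start
    g <- Biostrings::DNAStringSet(c(chr1 = gs))
    hits <- scanHomology(g, mat)
    w <- extractWindows(hits, g, windowPolicy(lengths = 100L))
    # 5'-arm placement: 0 upstream / 79 downstream
    w5 <- w[w$placement == "5p", ]
    expect_equal(w5$matureStart, 1)
    expect_equal(w5$winStart, 3)
    expect_equal(w5$length, 100)
    # 3'-arm placement would extend past the chromosome start: clipped off
    expect_false(any(w$placement == "3p" & w$length == 100))
    # mature subsequence inside every window equals the mature
    for (i in seq_len(nrow(w)))
        expect_identical(substr(w$seq[i], w$matureStart[i], w$matureEnd[i]),
                         unname(asRNA(mat)))
})

test_that("minus-strand windows come out as the planted sense sequence", {
    set.seed(53)
    mat <- randomMatureLibrary(1, seed = 53)
    hp <- makeHairpin(mat[[1]], loopLen = 8)
    g <- randomDNA(400)
    ins <- revComp(asDNA(hp$sequence))
    substr(g, 150, 149 + nchar(ins)) <- ins
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
    hits <- scanHomology(genome, mat)
    minus <- hits[as.character(GenomicRanges::strand(hits)) == "-"]
    expect_gte(length(minus), 1)
    w <- extractWindows(minus, genome,
                        windowPolicy(lengths = nchar(hp$sequence),
                                     placements = "5p"))
    expect_true(asRNA(hp$sequence) %in% w$seq)
})

test_that("coding exclusion removes ORF-bearing windows, keeps noise", {
    set.seed(54)
    orf <- paste0("ATG", strrep("GAA", 70), "TAA")
    cand <- data.frame(hitIndex = 1:2,
                       seq = c(asRNA(paste0(randomDNA(20), orf)),
                               asRNA(randomDNA(150))),
                       stringsAsFactors = FALSE)
    res <- excludeCoding(cand, minOrfAA = 60L)
    expect_equal(res$removed$hitIndex, 1)
    expect_equal(res$kept$hitIndex, 2)
    expect_error(excludeCoding(cand, proteins = NULL, minOrfAA = NULL),
                 "configure")
    expect_warning(excludeCoding(cand, proteins = character()), "empty")
})

test_that("coding-exclusion heuristic false-positive rate is low", {
    set.seed(55)
    cand <- data.frame(hitIndex = 1:40,
                       seq = vapply(1:40, function(i) randomRNA(250), ""),
                       stringsAsFactors = FALSE)
    res <- excludeCoding(cand, minOrfAA = 80L)
    expect_lt(nrow(res$removed) / nrow(cand), 0.05)
})

test_that("the filter cascade records per-filter verdicts", {
    hp <- makeHairpin("UGGAGCUCCCUUCAUUCCAAU", seed = 56)
    ft <- hairpinFeatures(hp$sequence)
    st <- foldMFE(hp$sequence)
    # everything passes at infinitely permissive thresholds
    loose <- defaultFilterThresholds(minMFEI = -Inf, maxNQ = Inf,
                                     maxND = Inf, npbRange = c(0, 0.5),
                                     minR = 0,
                                     requireHairpinPlacement = FALSE)
    expect_true(applyFilterCascade(ft, loose)$pass)
    # failing only the MFEI filter flags exactly that verdict
    tight <- loose; tight$minMFEI <- ft$MFEI + 1
    cv <- applyFilterCascade(ft, tight, st, 1, 21)
    expect_false(cv$pass)
    expect_false(cv$verdicts[["MFEI"]])
    expect_true(all(cv$verdicts[setdiff(names(cv$verdicts), "MFEI")]))
})

test_that("cascade separates planted hairpins from shuffled decoys", {
    set.seed(57)
    mats <- randomMatureLibrary(20, seed = 57)
    pass <- matrix(NA, 20, 2, dimnames = list(NULL, c("hairpin", "decoy")))
    for (i in 1:20) {
        hp <- makeHairpin(mats[[i]], loopLen = 8,
                          stemMismatches = sample(0:1, 1))
        bg <- randomRNA(20)
        for (cls in colnames(pass)) {
            w <- if (cls == "hairpin") paste0(hp$sequence, bg)
                 else dinucleotideShuffle(paste0(hp$sequence, bg))
            cv <- applyFilterCascade(hairpinFeatures(w),
                                     defaultFilterThresholds(),
                                     foldMFE(w), 1, nchar(mats[[i]]))
            pass[i, cls] <- cv$pass
        }
    }
    expect_gte(mean(pass[, "hairpin"]), 0.9)   # sensitivity
    expect_gte(mean(!pass[, "decoy"]), 0.9)    # specificity
})

test_that("best-candidate retention maximizes MFEI then R", {
    cand <- data.frame(MFEI = c(0.9, 1.1), R = c(5, 0),
                       length = c(100, 100), winStart = c(1, 1))
    expect_equal(selectBestCandidate(cand)$MFEI, 1.1)
    tie <- data.frame(MFEI = c(1, 1), R = c(0, 2.5),
                      length = c(100, 100), winStart = c(1, 1))
    expect_equal(selectBestCandidate(tie)$R, 2.5)
    single <- data.frame(MFEI = 1, R = 0, length = 80, winStart = 5)
    expect_equal(selectBestCandidate(single), single)
    expect_error(selectBestCandidate(single[0, ]), "rejected")
})

test_that("catalog naming runs in genomic order with novelty flags", {
    acc <- data.frame(family = c("miR171", "miR171", "miR9"),
                      chrom = c("chr1", "chr1", "chr2"),
                      winStart = c(500, 100, 50),
                      mismatches = c(0L, 2L, 1L), stringsAsFactors = FALSE)
    out <- assignFamilyAndName(acc, prefix = "syn")
    m171 <- out[out$family == "miR171", ]
    expect_equal(m171$name[order(m171$winStart)],
                 c("syn-miR171a", "syn-miR171b"))
    expect_identical(out$novel, out$mismatches > 0L)
})

test_that("mature placement check rejects loop-straddling matures", {
    st <- foldMFE("GGGGGAAAACCCCC")   # 5-pair stem, loop 5..10
    expect_true(maturePlacementOK(st, 1, 5))     # 5' arm
    expect_false(maturePlacementOK(st, 3, 12))   # straddles the loop
})
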