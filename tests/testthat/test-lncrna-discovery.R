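test_that("ORF finding matches hand-translated and degenerate cases", {
    o <- findORFs("ATGAAATAA")
    expect_equal(nrow(o), 1)
    expect_equal(o$lengthAA, 2)            # MK
    expect_equal(o$start, 0)
    expect_equal(o$end, 9)
    expect_true(o$hasStop)
    # no start codon under the start-to-stop definition
    expect_equal(nrow(findORFs("CCCCCCTAACCC")), 0)
})

test_that("ORF finding equals the naive six-frame oracle", {
    set.seed(61)
    for (i in 1:25) {
        s <- randomDNA(sample(200:500, 1))
        a <- findORFs(s)
        a <- a[order(a$frame, a$start), c("frame", "start", "end",
                                          "lengthAA", "hasStop")]
        b <- oracleORFs(s)
        b <- b[order(b$frame, b$start), ]
        expect_equal(a, b, ignore_attr = TRUE)
    }
})

test_that("length filter boundary is strict at 200 nt", {
    txs <- stats::setNames(c(randomDNA(200), randomDNA(201)),
                           c("at", "above"))
    kept <- lengthFilter(txs)
    expect_identical(names(kept), "above")
    expect_length(lengthFilter(character()), 0)
})

test_that("ORF filter boundary is strict at 120 aa", {
    mk <- function(nCodons) paste0("ATG", strrep("GAA", nCodons), "TAA")
    txs <- stats::setNames(c(mk(118), mk(119)), c("aa119", "aa120"))
    longest <- vapply(txs, function(s) findORFs(s)$lengthAA[1], 0L)
    expect_equal(longest, c(aa119 = 119L, aa120 = 120L))
    kept <- orfFilter(txs)
    expect_identical(names(kept), "aa119")
    # no ORF at all: vacuously retained
    expect_length(orfFilter(c(none = strrep("CCG", 50))), 1)
})

test_that("coding-potential class boundaries follow the score rules", {
    ids <- paste0("t", 1:5)
    txs <- stats::setNames(rep(strrep("ACGT", 60), 5), ids)
    adapter <- list(
        primary = stats::setNames(c(-0.6, -0.5, -0.49, 0.99, 1.0), ids),
        secondary = stats::setNames(c(0.5, 0.5, 0.19, 0.2, 0.5), ids))
    out <- classifyCodingPotential(txs, adapter)
    expect_identical(out$label,
                     c("noncoding", "noncoding", "ncRNA-by-secondary",
                       "neutral", "coding"))
    expect_identical(out$isNcRNA, c(TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_true(all(is.na(out$secondary[!(out$S > -0.5 & out$S < 1.0)])))
})

test_that("protein similarity removal is strict above 40% identity", {
    txs <- stats::setNames(rep(randomDNA(300), 3), c("a", "b", "c"))
    hits <- data.frame(qseqid = c("a", "b", "c"),
                       pident = c(40.0, 40.1, 95.0),
                       evalue = c(1e-6, 1e-6, 2e-3))
    res <- proteinSimilarityFilter(txs, hits = hits)
    # a: exactly 40% retained; b: >40% removed; c: insignificant e-value
    expect_identical(sort(names(res$kept)), c("a", "c"))
    # e-value boundary: 0.001 itself is significant
    hits$evalue[3] <- 1e-3; hits$pident[3] <- 80
    res2 <- proteinSimilarityFilter(txs, hits = hits)
    expect_identical(names(res2$kept), "a")
})

test_that("built-in aligner removes a transcript embedding a DB protein", {
    set.seed(62)
    tr <- makeTranscriptome(5, 5, seed = 62)
    coding1 <- as.character(tr$transcripts[["cds_1"]])
    shuffled <- dinucleotideShuffle(coding1)
    res <- proteinSimilarityFilter(
        stats::setNames(c(coding1, shuffled), c("planted", "shuffle")),
        proteins = tr$proteins)
    expect_false("planted" %in% names(res$kept))
    expect_true("shuffle" %in% names(res$kept))
    expect_warning(proteinSimilarityFilter(c(x = "ACGTACGT")), "SKIPPED")
})

test_that("the built-in scorer separates codon-biased ORFs from shuffles", {
    tr <- makeTranscriptome(60, 60, seed = 63)
    sc <- buildCodingScorer(
        as.character(tr$transcripts[tr$labels == "coding"]),
        as.character(tr$transcripts[tr$labels == "noncoding"]))
    expect_gte(sc@trainingRate[["coding"]], 0.9)
    expect_gte(sc@trainingRate[["noncoding"]], 0.9)
    # held-out set: the two-stage decision rule separates the classes
    heldout <- makeTranscriptome(25, 25, seed = 64)
    cls <- classifyCodingPotential(heldout$transcripts, sc)
    lab <- heldout$labels[cls$id]
    expect_gte(mean(cls$isNcRNA == (lab == "noncoding")), 0.9)
    expect_gt(mean(cls$S[lab == "coding"]), mean(cls$S[lab == "noncoding"]))
    expect_true(all(secondaryScore(sc, as.character(
        heldout$transcripts[1:4])) >= 0))
    expect_error(buildCodingScorer(rep("ATGAAA", 10), rep("CCCCCC", 10)),
                 ">= 50")
})

test_that("pipeline stage counts are monotonically non-increasing", {
    tr <- makeTranscriptome(30, 30, seed = 65)
    train <- makeTranscriptome(60, 60, seed = 66)
    sc <- buildCodingScorer(
        as.character(train$transcripts[train$labels == "coding"]),
        as.character(train$transcripts[train$labels == "noncoding"]))
    out <- runLncrnaPipeline(tr$transcripts, sc, proteins = tr$proteins)
    expect_true(all(out$audit$output <= out$audit$input))
    expect_true(all(out$audit$input[-1] == out$audit$output[-nrow(out$audit)]))
    # audit conservation: every transcript has exactly one fate
    expect_equal(nrow(out$perTranscript), length(tr$transcripts))
    expect_equal(sum(out$perTranscript$fate == "lncRNA"),
                 length(out$lncRNA))
})
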