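# cli_workflow: the end-to-end pipelines with per-stage audit records, and
# the packaged synthetic benchmarks that score them against planted truth.

.auditRow <- function(stage, nIn, nOut, note = "") {
    data.frame(stage = stage, input = nIn, output = nOut, note = note,
               stringsAsFactors = FALSE)
}

# features from an already-computed fold (avoids folding twice per window)
.featuresFromFold <- function(seq, fr, R = 0) {
    comp <- composition(seq)
    L <- nchar(seq)
    a <- amfe(fr@mfe, L)
    data.frame(L = L,
               fracA = comp$fractions[["A"]], fracC = comp$fractions[["C"]],
               fracG = comp$fractions[["G"]], fracU = comp$fractions[["U"]],
               gcPercent = comp$gcPercent, MFE = fr@mfe, AMFE = a,
               MFEI = if (comp$gcPercent > 0) mfei(a, comp$gcPercent)
                      else NA_real_,
               NQ = nq(fr@bpp, L), ND = nd(fr@bpp, L),
               Npb = npb(fr@mfeStructure, L), R = R)
}

#' Run the pre-miRNA discovery pipeline
#'
#' Executes the full cascade: homology scan, window-ladder extraction,
#' protein-coding exclusion, feature computation (folding statistics + SSR
#' signature density), threshold cascade, per-hit best-candidate retention
#' (maximum MFEI, then maximum R), and catalog naming. Every hit leaves the
#' pipeline exactly once, as an accepted locus or as a rejection with a
#' recorded reason; audit rows count every stage.
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param matures named mature miRNA library.
#' @param proteins optional protein database for coding exclusion (without
#'   it, the ORF heuristic with `minOrfAA` applies).
#' @param signatureTable optional named list (family -> signature motifs)
#'   used for the R feature.
#' @param thresholds from [defaultFilterThresholds()].
#' @param policy from [windowPolicy()].
#' @param model an [EnergyModel-class].
#' @param minOrfAA ORF heuristic threshold for coding exclusion.
#' @param maxMismatch homology scan mismatch bound.
#' @param prefix catalog name prefix.
#' @return list with `catalog` (accepted loci with names, coordinates,
#'   features, novelty flags), `rejected` (per-hit reasons), `hits`,
#'   `audit`.
#' @export
runMirnaPipeline <- function(genome, matures, proteins = NULL,
                             signatureTable = NULL,
                             thresholds = defaultFilterThresholds(),
                             policy = windowPolicy(),
                             model = defaultEnergyModel(),
                             minOrfAA = 80L, maxMismatch = 3L,
                             prefix = "syn") {
    if (!length(matures))
        return(list(catalog = NULL, rejected = NULL,
                    hits = GenomicRanges::GRanges(),
                    audit = .auditRow("homology_scan", 0L, 0L,
                                      "empty mature library")))
    audit <- list()
    hits <- scanHomology(genome, matures, maxMismatch)
    audit[[1]] <- .auditRow("homology_scan", length(matures), length(hits))
    cand <- extractWindows(hits, genome, policy)
    audit[[2]] <- .auditRow("window_extraction", length(hits), nrow(cand))
    ec <- excludeCoding(cand, proteins, minOrfAA = minOrfAA)
    cand <- ec$kept
    audit[[3]] <- .auditRow("coding_exclusion",
                            nrow(cand) + nrow(ec$removed), nrow(cand))
    accepted <- list(); rejected <- list()
    nPass <- 0L
    for (h in seq_along(hits)) {
        rows <- cand[cand$hitIndex == h, , drop = FALSE]
        if (!nrow(rows)) {
            rejected[[length(rejected) + 1L]] <- data.frame(
                hitIndex = h, reason = "no_window_survived_extraction",
                stringsAsFactors = FALSE)
            next
        }
        feats <- vector("list", nrow(rows))
        pass <- logical(nrow(rows))
        failCounts <- integer(0)
        for (i in seq_len(nrow(rows))) {
            fr <- partitionFunction(rows$seq[i], model)
            R <- if (!is.null(signatureTable) &&
                     rows$family[i] %in% names(signatureTable))
                signatureDensityR(rows$seq[i], rows$family[i],
                                  signatureTable) else 0
            ft <- .featuresFromFold(rows$seq[i], fr, R)
            cv <- applyFilterCascade(ft, thresholds, fr@mfeStructure,
                                     rows$matureStart[i], rows$matureEnd[i])
            pass[i] <- cv$pass
            if (!cv$pass) {
                fails <- names(cv$verdicts)[!cv$verdicts]
                failCounts[fails] <- (failCounts[fails] %-na% 0L) + 1L
            }
            feats[[i]] <- ft
        }
        rows <- cbind(rows, do.call(rbind, feats))
        if (!any(pass)) {
            top <- if (length(failCounts))
                paste0("failed_", paste(names(sort(failCounts,
                                                   decreasing = TRUE)),
                                        collapse = "+")) else "no_candidate"
            rejected[[length(rejected) + 1L]] <- data.frame(
                hitIndex = h, reason = top, stringsAsFactors = FALSE)
            next
        }
        nPass <- nPass + sum(pass)
        accepted[[length(accepted) + 1L]] <-
            selectBestCandidate(rows[pass, , drop = FALSE])
    }
    audit[[4]] <- .auditRow("filter_cascade", nrow(cand), nPass)
    audit[[5]] <- .auditRow("best_candidate", length(hits),
                            length(accepted))
    catalog <- if (length(accepted)) do.call(rbind, accepted) else NULL
    if (!is.null(catalog)) {
        catalog$matureGenomicStart <- ifelse(
            catalog$strand == "+",
            catalog$winStart + catalog$matureStart - 1L,
            catalog$winEnd - catalog$matureEnd + 1L)
        catalog$matureGenomicEnd <- catalog$matureGenomicStart +
            (catalog$matureEnd - catalog$matureStart)
        catalog <- assignFamilyAndName(catalog, prefix = prefix)
    }
    list(catalog = catalog,
         rejected = if (length(rejected)) do.call(rbind, rejected) else NULL,
         hits = hits, audit = do.call(rbind, audit))
}

#' Run the lncRNA discovery pipeline
#'
#' Stage order: length filter (> 200 nt), maximum-ORF filter (< 120 aa),
#' two-stage coding-potential classification (S <= -0.5 non-coding;
#' neutral re-checked with the secondary score < 0.2), protein-similarity
#' removal (> 40 percent identity at e <= 0.001). Per-stage counts are
#' audited and monotonically non-increasing.
#'
#' @param transcripts named character vector or `XStringSet`.
#' @param scorer a [CodingScorer-class] or external score adapter (see
#'   [classifyCodingPotential()]).
#' @param proteins optional protein database for the similarity stage.
#' @param hits optional external tabular alignments (see
#'   [proteinSimilarityFilter()]).
#' @param minLen,maxAA,maxIdentity,eCutoff stage thresholds.
#' @return list with `lncRNA` (the final catalog, same container as the
#'   input), `perTranscript` (`data.frame` of ids with the stage at which
#'   each was removed, or "lncRNA"), `audit`.
#' @export
runLncrnaPipeline <- function(transcripts, scorer, proteins = NULL,
                              hits = NULL, minLen = 200L, maxAA = 120L,
                              maxIdentity = 40, eCutoff = 1e-3) {
    ids <- names(transcripts)
    fate <- stats::setNames(rep("lncRNA", length(transcripts)), ids)
    audit <- list()
    s1 <- lengthFilter(transcripts, minLen)
    fate[setdiff(ids, names(s1))] <- "removed_length"
    audit[[1]] <- .auditRow("length_filter", length(transcripts), length(s1))
    s2 <- orfFilter(s1, maxAA)
    fate[setdiff(names(s1), names(s2))] <- "removed_orf"
    audit[[2]] <- .auditRow("orf_filter", length(s1), length(s2))
    cp <- classifyCodingPotential(s2, scorer)
    s3 <- s2[cp$isNcRNA]
    fate[cp$id[!cp$isNcRNA]] <- paste0("removed_coding_potential_",
                                       cp$label[!cp$isNcRNA])
    audit[[3]] <- .auditRow("coding_potential", length(s2), length(s3))
    ps <- proteinSimilarityFilter(s3, proteins, hits,
                                  maxIdentity = maxIdentity,
                                  eCutoff = eCutoff)
    fate[setdiff(names(s3), names(ps$kept))] <- "removed_protein_similarity"
    audit[[4]] <- .auditRow("protein_similarity", length(s3),
                            length(ps$kept),
                            if (ps$filtered) "" else "SKIPPED (no database)")
    list(lncRNA = ps$kept, classification = cp,
         perTranscript = data.frame(id = ids, fate = unname(fate[ids]),
                                    stringsAsFactors = FALSE),
         audit = do.call(rbind, audit))
}

#' Run the target-prediction pipeline
#'
#' Predicts miRNA targets on the coding transcripts and, with identical
#' scoring configuration, on the lncRNA catalog, with audit rows.
#'
#' @inheritParams predictTargets
#' @return list with the [predictTargets()] outputs plus `audit`.
#' @export
runTargetPipeline <- function(matures, transcripts, lncRNAs = NULL,
                              scheme = targetScheme(),
                              model = defaultEnergyModel()) {
    res <- predictTargets(matures, transcripts, lncRNAs, scheme, model)
    res$audit <- rbind(
        .auditRow("coding_targets", length(matures) * length(transcripts),
                  nrow(res$coding)),
        .auditRow("lncrna_targets",
                  length(matures) * length(if (is.null(lncRNAs)) character()
                                           else lncRNAs),
                  nrow(res$lncrna)))
    res
}

#' Packaged synthetic benchmark: pre-miRNA recovery
#'
#' Builds the packaged synthetic genome (planted hairpins, shuffled and
#' mutated decoys), derives the family signature table from the planted
#' precursors, runs [runMirnaPipeline()] at defaults, and scores recovery
#' against the truth ledger: a planted precursor is recovered when an
#' accepted locus places its mature within 5 nt of the planted mature
#' interval; accepted loci matching no planted element are false
#' discoveries.
#'
#' @param seed RNG seed for the corpus.
#' @param nMatures,nPlanted,nDecoys corpus dimensions.
#' @param ... passed to [makeGenome()].
#' @return list with `sensitivity`, `fdr`, `nPlanted`, `nAccepted`,
#'   `result` (the full pipeline output), `corpus`.
#' @export
benchmarkMirna <- function(seed = 42L, nMatures = 10L, nPlanted = 10L,
                           nDecoys = 10L, ...) {
    mats <- randomMatureLibrary(nMatures, seed = .subSeed(seed, 1L))
    corpus <- makeGenome(mats, nPlanted = nPlanted, nDecoys = nDecoys,
                         seed = .subSeed(seed, 2L), ...)
    planted <- corpus$truth[corpus$truth$type == "planted", ]
    fams <- split(vapply(seq_len(nrow(planted)), function(i) {
        s <- as.character(Biostrings::subseq(
            corpus$genome[[planted$chrom[i]]],
            planted$start[i], planted$end[i]))
        asRNA(if (planted$strand[i] == "-") revComp(s) else s)
    }, ""), planted$family)
    sig <- tabulateFamilySignatures(fams)$table
    res <- runMirnaPipeline(corpus$genome, corpus$matures,
                            signatureTable = sig)
    cat <- res$catalog
    # an accepted locus is true when its mature interval falls inside a
    # planted precursor footprint (+/- 5 nt); note a planted hairpin exposes
    # two genuine loci, one per arm (the 3' arm matches the mature on the
    # minus strand), and either counts as recovering that precursor
    inFootprint <- function(j, i) {
        cat$chrom[j] == planted$chrom[i] &&
            cat$matureGenomicStart[j] >= planted$start[i] - 5L &&
            cat$matureGenomicEnd[j] <= planted$end[i] + 5L
    }
    recovered <- vapply(seq_len(nrow(planted)), function(i) {
        if (is.null(cat)) return(FALSE)
        any(vapply(seq_len(nrow(cat)), inFootprint, NA, i = i))
    }, NA)
    falsePos <- if (is.null(cat)) 0L else
        sum(!vapply(seq_len(nrow(cat)), function(j)
            any(vapply(seq_len(nrow(planted)),
                       function(i) inFootprint(j, i), NA)), NA))
    nAcc <- if (is.null(cat)) 0L else nrow(cat)
    list(sensitivity = mean(recovered),
         fdr = if (nAcc) falsePos / nAcc else 0,
         nPlanted = nrow(planted), nAccepted = nAcc,
         result = res, corpus = corpus)
}

#' Packaged synthetic benchmark: lncRNA classification accuracy
#'
#' Trains the built-in coding scorer on one synthetic transcriptome and
#' runs the lncRNA pipeline on an independent held-out one (its own protein
#' database backing the similarity stage). Accuracy counts non-coding
#' transcripts retained as lncRNAs plus coding transcripts removed.
#'
#' @param seed RNG seed.
#' @param nTrain,nTest per-class transcript counts.
#' @return list with `accuracy`, `n`, `pipeline` (full output), `labels`.
#' @export
benchmarkLncrna <- function(seed = 42L, nTrain = 60L, nTest = 40L) {
    train <- makeTranscriptome(nTrain, nTrain, seed = .subSeed(seed, 3L))
    test <- makeTranscriptome(nTest, nTest, seed = .subSeed(seed, 4L))
    scorer <- buildCodingScorer(
        as.character(train$transcripts[train$labels == "coding"]),
        as.character(train$transcripts[train$labels == "noncoding"]))
    pipe <- runLncrnaPipeline(test$transcripts, scorer,
                              proteins = test$proteins)
    predNc <- names(test$transcripts) %in% names(pipe$lncRNA)
    truthNc <- test$labels == "noncoding"
    list(accuracy = mean(predNc == truthNc), n = length(test$transcripts),
         pipeline = pipe, labels = test$labels)
}

#' Packaged synthetic benchmark: target-site recovery
#'
#' Plants target sites with designed expectation penalties (0 and 1 as
#' positives, 4 as designed negatives beyond the 2.0 cutoff) into random
#' transcripts and lncRNA-like sequences, runs the target pipeline, and
#' scores planted-edge recovery and negative exclusion.
#'
#' @param seed RNG seed.
#' @param nMatures,nTranscripts corpus dimensions.
#' @param txLen transcript length (nt).
#' @return list with `recovery` (fraction of designed-positive edges found
#'   at their planted site), `negativesExcluded` (fraction of designed
#'   negatives absent), `result`, `truth`.
#' @export
benchmarkTargets <- function(seed = 42L, nMatures = 6L, nTranscripts = 6L,
                             txLen = 800L) {
    set.seed(.subSeed(seed, 5L))
    mats <- randomMatureLibrary(nMatures, seed = .subSeed(seed, 6L))
    txs <- stats::setNames(vapply(seq_len(nTranscripts), function(i)
        .randomDNA(txLen), ""), paste0("tx_", seq_len(nTranscripts)))
    lncs <- stats::setNames(vapply(seq_len(nTranscripts), function(i)
        .randomDNA(txLen), ""), paste0("lnc_", seq_len(nTranscripts)))
    design <- data.frame(
        mature = rep(names(mats), 2L),
        transcript = c(rep(names(txs), length.out = nMatures),
                       rep(names(lncs), length.out = nMatures)),
        penalty = rep(c(0, 1, 4), length.out = 2L * nMatures),
        stringsAsFactors = FALSE)
    pt <- plantTargetSites(mats, c(txs, lncs), design,
                           seed = .subSeed(seed, 7L))
    planted <- as.character(pt$transcripts)
    res <- runTargetPipeline(mats, planted[names(txs)], planted[names(lncs)])
    edges <- rbind(res$coding, res$lncrna)
    found <- vapply(seq_len(nrow(pt$truth)), function(i) {
        tr <- pt$truth[i, ]
        any(edges$miRNA == tr$mature & edges$transcript == tr$transcript &
            edges$start <= tr$end & edges$end >= tr$start)
    }, NA)
    pos <- pt$truth$designedPenalty <= 2
    list(recovery = mean(found[pos]),
         negativesExcluded = mean(!found[!pos]),
         nPositive = sum(pos), nNegative = sum(!pos),
         result = res, truth = pt$truth)
}
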