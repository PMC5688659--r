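# synthetic_data: seeded generators for genomes with planted pre-miRNA
# hairpins, transcriptomes mixing codon-biased ORFs with dinucleotide-
# shuffled non-coding sequences, and planted miRNA target sites - each with
# a ground-truth ledger so recovery metrics can be scored without downloads.

.BASES_DNA <- c("A", "C", "G", "T")

.randomDNA <- function(n, gc = 0.5) {
    paste(sample(.BASES_DNA, n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# bases that neither Watson-Crick- nor wobble-pair a given miRNA base
.nonPairingBases <- function(mBase) {
    setdiff(c("A", "C", "G", "U"),
            c(.RNA_COMP[[mBase]],
              if (mBase == "G") "U" else if (mBase == "U") "G"))
}

#' Construct a synthetic pre-miRNA hairpin
#'
#' Builds mature + loop + near-reverse-complement of the mature, with a
#' requested number of stem mismatches. With zero to two mismatches the
#' construct folds into a clean hairpin under the built-in energy model;
#' heavily mismatched constructs serve as negative controls. A trinucleotide
#' SSR motif can be tiled into the loop so the precursor carries a family
#' signature.
#'
#' @param mature mature miRNA sequence (RNA, 15-24 nt).
#' @param loopLen loop length (>= the model's minimum loop).
#' @param stemMismatches number of 3'-arm positions mutated to non-pairing
#'   bases.
#' @param ssrMotif optional trinucleotide motif tiled across the loop.
#' @param model an [EnergyModel-class] (for the geometry check).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `sequence` (RNA), `matureStart`, `matureEnd` (1-based,
#'   the 5' arm), `length`.
#' @export
makeHairpin <- function(mature, loopLen = 8L, stemMismatches = 0L,
                        ssrMotif = NULL, model = defaultEnergyModel(),
                        seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    mature <- asRNA(mature)
    L <- nchar(mature)
    if (L < 15L || L > 24L) stop("mature must be 15-24 nt")
    if (loopLen < model@minLoop)
        stop("impossible geometry: loop shorter than the minimum loop")
    loop <- if (!is.null(ssrMotif)) {
        substr(strrep(asRNA(ssrMotif), ceiling(loopLen / nchar(ssrMotif))),
               1L, loopLen)
    } else {
        paste(sample(c("A", "C"), loopLen, replace = TRUE,
                     prob = c(0.85, 0.15)), collapse = "")
    }
    arm3 <- strsplit(asRNA(revComp(asDNA(mature))), "")[[1]]
    if (stemMismatches > 0L) {
        if (stemMismatches > L) stop("more mismatches than stem positions")
        pos <- sample.int(L, stemMismatches)
        mch <- strsplit(mature, "")[[1]]
        for (j in pos) {
            # arm3 index pairing mature position p is L - p + 1
            p <- L - j + 1L
            arm3[j] <- sample(.nonPairingBases(mch[p]), 1L)
        }
    }
    seqs <- paste0(mature, loop, paste(arm3, collapse = ""))
    list(sequence = seqs, matureStart = 1L, matureEnd = L,
         length = nchar(seqs))
}

#' Random mature miRNA library
#'
#' Draws matures with the length distribution observed for plant mature
#' miRNAs (concentrated in 18-22 nt, mean close to 20 nt), one per family,
#' with miRBase-style identifiers.
#'
#' @param n number of matures/families.
#' @param seed RNG seed.
#' @param prefix identifier prefix.
#' @return named character vector of RNA matures
#'   (`<prefix>-miR<family><letter>`).
#' @export
randomMatureLibrary <- function(n, seed = NULL, prefix = "syn") {
    if (!is.null(seed)) set.seed(seed)
    lens <- sample(18:24, n, replace = TRUE,
                   prob = c(0.06, 0.15, 0.42, 0.25, 0.05, 0.04, 0.03))
    seqs <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
              collapse = ""), "")
    names(seqs) <- paste0(prefix, "-miR", 100L + seq_len(n), "a")
    seqs
}

#' Synthetic genome with planted precursors and decoys
#'
#' Generates i.i.d. background chromosomes at a requested GC content,
#' inserts hairpin precursors (random strand, non-overlapping) built from a
#' mature library, and adds two decoy classes: dinucleotide-shuffled
#' precursors (hairpin destroyed, composition kept) and matures mutated to
#' 4-6 mismatches (straddling the homology scan's 3-mismatch boundary from
#' the wrong side). Emits a complete ground-truth ledger.
#'
#' @param matures named character vector of matures (one per family), e.g.
#'   from [randomMatureLibrary()].
#' @param nChroms,chromLen chromosome count and length (nt).
#' @param gc background GC fraction.
#' @param nPlanted,nDecoys planted precursor and decoy counts.
#' @param loopLen hairpin loop length.
#' @param stemMismatches vector sampled per planted hairpin.
#' @param ssrMotifs trinucleotide signature motifs cycled over families and
#'   tiled into the loops.
#' @param seed RNG seed (determinism: same seed, same bytes).
#' @return list with `genome` (`DNAStringSet`), `truth` (`data.frame`:
#'   `type`, `chrom`, `start`, `end` 1-based inclusive, `strand`,
#'   `matureID`, `family`, `matureGenomicStart`, `matureGenomicEnd`,
#'   `ssrMotif`), and `matures`.
#' @export
makeGenome <- function(matures, nChroms = 2L, chromLen = 10000L, gc = 0.5,
                       nPlanted = 10L, nDecoys = 10L, loopLen = 8L,
                       stemMismatches = 0:1,
                       ssrMotifs = c("AAU", "AGU", "UUC", "GAU"),
                       seed = 42L) {
    set.seed(seed)
    chroms <- vapply(seq_len(nChroms), function(i) .randomDNA(chromLen, gc),
                     "")
    names(chroms) <- paste0("chr", seq_len(nChroms))
    used <- lapply(chroms, function(x) integer(0))  # occupied positions
    place <- function(len) {
        for (try in 1:200) {
            ci <- sample.int(nChroms, 1L)
            st <- sample.int(chromLen - len - 1L, 1L)
            if (!any(seq.int(st, st + len - 1L) %in% used[[ci]]))
                return(list(ci = ci, start = st))
        }
        stop("overcrowded: could not place element without overlap")
    }
    insert <- function(ci, start, dna) {
        substr(chroms[[ci]], start, start + nchar(dna) - 1L) <<- dna
        used[[ci]] <<- c(used[[ci]], seq.int(start, start + nchar(dna) - 1L))
    }
    truth <- list()
    famMotif <- stats::setNames(
        rep(ssrMotifs, length.out = length(matures)),
        .familyFromId(names(matures)))
    for (i in seq_len(nPlanted)) {
        k <- ((i - 1L) %% length(matures)) + 1L
        fam <- .familyFromId(names(matures)[k])
        hp <- makeHairpin(matures[[k]], loopLen = loopLen,
                          stemMismatches = sample(stemMismatches, 1L),
                          ssrMotif = famMotif[[fam]])
        dna <- asDNA(hp$sequence)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "-") revComp(dna) else dna
        loc <- place(nchar(ins))
        insert(loc$ci, loc$start, ins)
        gEnd <- loc$start + nchar(ins) - 1L
        mLen <- hp$matureEnd - hp$matureStart + 1L
        truth[[length(truth) + 1L]] <- data.frame(
            type = "planted", chrom = names(chroms)[loc$ci],
            start = loc$start, end = gEnd, strand = strand,
            matureID = names(matures)[k], family = fam,
            matureGenomicStart = if (strand == "+") loc$start
                                 else gEnd - mLen + 1L,
            matureGenomicEnd = if (strand == "+") loc$start + mLen - 1L
                               else gEnd,
            ssrMotif = famMotif[[fam]], stringsAsFactors = FALSE)
    }
    for (i in seq_len(nDecoys)) {
        k <- ((i - 1L) %% length(matures)) + 1L
        if (i %% 2L == 1L) {   # shuffled precursor
            hp <- makeHairpin(matures[[k]], loopLen = loopLen)
            dna <- dinucleotideShuffle(asDNA(hp$sequence))
            type <- "decoy_shuffled"
        } else {               # mature mutated to 4-6 mismatches
            mch <- strsplit(asDNA(matures[[k]]), "")[[1]]
            nm <- sample(4:6, 1L)
            pos <- sample.int(length(mch), min(nm, length(mch)))
            for (j in pos)
                mch[j] <- sample(setdiff(.BASES_DNA, mch[j]), 1L)
            dna <- paste(mch, collapse = "")
            type <- "decoy_mutated"
        }
        loc <- place(nchar(dna))
        insert(loc$ci, loc$start, dna)
        truth[[length(truth) + 1L]] <- data.frame(
            type = type, chrom = names(chroms)[loc$ci], start = loc$start,
            end = loc$start + nchar(dna) - 1L, strand = "+",
            matureID = names(matures)[k],
            family = .familyFromId(names(matures)[k]),
            matureGenomicStart = NA_integer_,
            matureGenomicEnd = NA_integer_,
            ssrMotif = NA_character_, stringsAsFactors = FALSE)
    }
    list(genome = Biostrings::DNAStringSet(chroms),
         truth = do.call(rbind, truth), matures = matures)
}

#' Exact-count dinucleotide shuffle
#'
#' Permutes a sequence while preserving its dinucleotide counts exactly
#' (and hence first and last base), by drawing a random Eulerian path
#' through the dinucleotide transition multigraph: for every base a random
#' "last" outgoing edge is drawn until the last-edge graph leads every base
#' to the final one, remaining edges are permuted, and the path is walked.
#' This destroys reading frames and hairpin complementarity while keeping
#' composition, which makes shuffles the honest negative class.
#'
#' @param seq character scalar (any alphabet).
#' @return shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotideShuffle <- function(seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 3L) return(seq)
    verts <- unique(ch)
    edges <- split(ch[-1L], factor(ch[-n], levels = verts))
    last <- ch[n]
    for (attempt in 1:500) {
        lastEdge <- vapply(verts, function(v) {
            if (v == last || !length(edges[[v]])) NA_character_
            else sample(edges[[v]], 1L)
        }, "")
        reaches <- function(v) {
            seen <- character()
            while (!is.na(v) && v != last && !(v %in% seen)) {
                seen <- c(seen, v)
                v <- lastEdge[[v]]
            }
            identical(v, last)
        }
        ok <- all(vapply(verts, function(v)
            v == last || !length(edges[[v]]) || reaches(v), NA))
        if (ok) break
        if (attempt == 500L) stop("could not draw a valid shuffle")
    }
    pools <- lapply(verts, function(v) {
        e <- edges[[v]]
        if (!length(e)) return(character())
        if (v == last || is.na(lastEdge[[v]])) return(sample(e, length(e)))
        e <- e[-match(lastEdge[[v]], e)]
        c(if (length(e)) sample(e, length(e)) else character(),
          lastEdge[[v]])
    })
    names(pools) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in 2:n) {
        nxt <- pools[[cur]][ptr[[cur]]]
        ptr[[cur]] <- ptr[[cur]] + 1L
        out[i] <- nxt
        cur <- nxt
    }
    paste(out, collapse = "")
}

# biased codon table: for each amino acid one preferred codon at weight 0.7
.CODONS <- {
    b <- c("T", "C", "A", "G")
    all <- as.vector(outer(outer(b, b, paste0), b, paste0))
    all[!all %in% c("TAA", "TAG", "TGA")]
}

#' Synthetic transcriptome with labelled coding and non-coding classes
#'
#' Coding transcripts are a codon-biased ORF (ATG ... stop, >= `minOrfAA`
#' amino acids) flanked by random UTRs; non-coding transcripts are
#' dinucleotide shuffles of coding ones (ORFs destroyed, composition kept).
#' Translated ORFs are emitted as the companion protein database.
#'
#' @param nCoding,nNoncoding class sizes.
#' @param lenRange total transcript length range (nt).
#' @param minOrfAA,maxOrfAA ORF length range (amino acids).
#' @param codonBias weight concentrated on each amino acid's preferred
#'   codon (0 = uniform use, 1 = single codon per amino acid).
#' @param seed RNG seed.
#' @return list with `transcripts` (named `DNAStringSet`), `labels` (named
#'   character, "coding"/"noncoding"), `proteins` (`AAStringSet`).
#' @export
makeTranscriptome <- function(nCoding = 60L, nNoncoding = 60L,
                              lenRange = c(500L, 1200L), minOrfAA = 150L,
                              maxOrfAA = 250L, codonBias = 0.7, seed = 1L) {
    set.seed(seed)
    stopifnot(nCoding >= 1L, nNoncoding >= 1L)
    aaCodons <- split(.CODONS, vapply(.CODONS, function(cd)
        as.character(Biostrings::translate(Biostrings::DNAString(cd))), ""))
    sampleCodon <- function(aa) {
        cds <- aaCodons[[aa]]
        if (length(cds) == 1L) return(cds)
        p <- rep((1 - codonBias) / (length(cds) - 1L), length(cds))
        p[1L] <- codonBias
        sample(cds, 1L, prob = p)
    }
    aas <- setdiff(names(aaCodons), "M")
    coding <- character(nCoding); prot <- character(nCoding)
    for (i in seq_len(nCoding)) {
        nAA <- sample(minOrfAA:maxOrfAA, 1L)
        aaSeq <- sample(aas, nAA - 1L, replace = TRUE)
        orf <- paste0("ATG",
                      paste(vapply(aaSeq, sampleCodon, ""), collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
        total <- max(sample(lenRange[1]:lenRange[2], 1L), nchar(orf) + 60L)
        utr5 <- .randomDNA(sample(20:(total - nchar(orf) - 20L), 1L))
        utr3 <- .randomDNA(total - nchar(orf) - nchar(utr5))
        coding[i] <- paste0(utr5, orf, utr3)
        prot[i] <- paste0("M", paste(aaSeq, collapse = ""))
    }
    noncoding <- vapply(seq_len(nNoncoding), function(i)
        dinucleotideShuffle(coding[((i - 1L) %% nCoding) + 1L]), "")
    txs <- Biostrings::DNAStringSet(c(coding, noncoding))
    names(txs) <- c(paste0("cds_", seq_len(nCoding)),
                    paste0("shuf_", seq_len(nNoncoding)))
    labels <- stats::setNames(rep(c("coding", "noncoding"),
                                  c(nCoding, nNoncoding)), names(txs))
    proteins <- Biostrings::AAStringSet(prot)
    names(proteins) <- paste0("prot_", seq_len(nCoding))
    list(transcripts = txs, labels = labels, proteins = proteins)
}

#' Plant miRNA target sites with designed expectation penalties
#'
#' Inserts reverse-complement target sites into transcripts, mutated to a
#' designed penalty: 0 (perfect), small positive values via non-core/core
#' mismatches, or > 2 for designed negatives that the expectation cutoff
#' must exclude. Site placement avoids collisions with previously planted
#' sites (bounded retries). The truth ledger records every planted edge.
#'
#' @param matures named character vector of matures (RNA).
#' @param transcripts named character vector / `DNAStringSet`.
#' @param design `data.frame` with columns `mature`, `transcript`,
#'   `penalty` (multiples of 0.5); or `NULL` to plant one edge per mature
#'   with penalties cycling 0, 1, 4.
#' @param scheme from [targetScheme()] (for core weighting).
#' @param seed RNG seed.
#' @return list with `transcripts` (modified, `DNAStringSet`) and `truth`
#'   (`data.frame`: `mature`, `transcript`, `start`, `end`,
#'   `designedPenalty`).
#' @export
plantTargetSites <- function(matures, transcripts, design = NULL,
                             scheme = targetScheme(), seed = 7L) {
    set.seed(seed)
    nm <- names(transcripts)
    txs <- asDNA(as.character(transcripts))
    names(txs) <- if (is.null(nm)) paste0("tx", seq_along(txs)) else nm
    if (is.null(design))
        design <- data.frame(
            mature = names(matures),
            transcript = rep(names(txs), length.out = length(matures)),
            penalty = rep(c(0, 1, 4), length.out = length(matures)),
            stringsAsFactors = FALSE)
    occupied <- lapply(txs, function(x) integer(0))
    truth <- list()
    for (r in seq_len(nrow(design))) {
        mat <- asRNA(matures[[design$mature[r]]])
        L <- nchar(mat)
        w <- .coreWeights(L, scheme)
        site <- strsplit(asRNA(revComp(asDNA(mat))), "")[[1]]
        mch <- strsplit(mat, "")[[1]]
        remaining <- design$penalty[r]
        corePos <- which(w > 1); nonCore <- which(w == 1)
        usedPos <- integer(0)
        mutateAt <- function(p) {
            j <- L - p + 1L
            site[j] <<- sample(.nonPairingBases(mch[p]), 1L)
            usedPos <<- c(usedPos, p)
        }
        while (remaining >= 2 - 1e-9 && length(setdiff(corePos, usedPos))) {
            mutateAt(sample(setdiff(corePos, usedPos), 1L))
            remaining <- remaining - 2
        }
        while (remaining >= 1 - 1e-9 && length(setdiff(nonCore, usedPos))) {
            mutateAt(sample(setdiff(nonCore, usedPos), 1L))
            remaining <- remaining - 1
        }
        if (remaining > 1e-9) {
            gu <- setdiff(intersect(nonCore, which(mch %in% c("G", "U"))),
                          usedPos)
            if (!length(gu)) stop("cannot realize designed penalty ",
                                  design$penalty[r])
            p <- sample(gu, 1L)
            site[L - p + 1L] <- if (mch[p] == "G") "U" else "G"
            remaining <- remaining - 0.5
        }
        siteDNA <- asDNA(paste(site, collapse = ""))
        tx <- design$transcript[r]
        n <- nchar(txs[[tx]])
        placed <- FALSE
        for (try in 1:100) {
            st <- sample.int(n - L - 1L, 1L)
            span <- seq.int(st, st + L - 1L)
            if (!any(span %in% occupied[[tx]])) {
                substr(txs[[tx]], st, st + L - 1L) <- siteDNA
                occupied[[tx]] <- c(occupied[[tx]], span)
                truth[[length(truth) + 1L]] <- data.frame(
                    mature = design$mature[r], transcript = tx,
                    start = st, end = st + L - 1L,
                    designedPenalty = design$penalty[r],
                    stringsAsFactors = FALSE)
                placed <- TRUE
                break
            }
        }
        if (!placed) stop("could not place target site without collision")
    }
    list(transcripts = Biostrings::DNAStringSet(txs),
         truth = do.call(rbind, truth))
}
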