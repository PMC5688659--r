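# target_prediction: expectation-penalty complementarity scoring of
# miRNA:transcript duplexes (mismatch 1.0, G:U wobble 0.5, gap 2.0, doubled
# in the 5' core), site search with at most one interior bulge, target-site
# unpairing energy (UPE) via constrained refolding, and network export.

#' Target scoring scheme
#'
#' Penalty constants of the expectation score and the site-level cutoffs.
#' Penalties are doubled within the core region (mature positions 2-13 from
#' the 5' end, rescaled proportionally for matures shorter than 15 nt); the
#' central region used for the cleavage/translation call is positions 9-11,
#' rescaled the same way for variable mature lengths.
#'
#' @param mismatch,wobble,gap penalty units per mismatch, G:U pair and
#'   bulged base.
#' @param coreMultiplier weighting applied inside the core region.
#' @param maxExpectation maximum reported expectation (penalty units).
#' @param maxUPE maximum energy of unpairing the site (kcal/mol).
#' @param flankUp,flankDown flanking nucleotides folded around the site for
#'   the UPE computation (17 upstream / 13 downstream).
#' @return a scheme list consumed by the scoring functions.
#' @export
targetScheme <- function(mismatch = 1.0, wobble = 0.5, gap = 2.0,
                         coreMultiplier = 2.0, maxExpectation = 2.0,
                         maxUPE = 25, flankUp = 17L, flankDown = 13L) {
    list(mismatch = mismatch, wobble = wobble, gap = gap,
         coreMultiplier = coreMultiplier, maxExpectation = maxExpectation,
         maxUPE = maxUPE, flankUp = flankUp, flankDown = flankDown)
}

# position weights over mature positions 1..L (core doubled)
.coreWeights <- function(L, scheme) {
    lo <- if (L >= 15L) 2L else max(1L, round(2 * L / 21))
    hi <- if (L >= 15L) min(13L, L) else min(L, round(13 * L / 21))
    w <- rep(1, L)
    w[lo:hi] <- scheme$coreMultiplier
    w
}

.centralRegion <- function(L) {
    c(max(1L, round(9 * L / 21)), min(L, round(11 * L / 21)))
}

# 4x4 penalty lookup: rows = miRNA base, cols = target base (A,C,G,U)
.duplexPenalty <- function(scheme) {
    P <- matrix(scheme$mismatch, 4, 4,
                dimnames = list(names(.RNA_CODES), names(.RNA_CODES)))
    P["A", "U"] <- P["U", "A"] <- P["G", "C"] <- P["C", "G"] <- 0
    P["G", "U"] <- P["U", "G"] <- scheme$wobble
    P
}

#' Expectation penalty of one miRNA:site duplex
#'
#' Scores the antiparallel duplex of a mature miRNA (5'->3') against a
#' target site (transcript sense, 5'->3'): each aligned position adds 0 for
#' a Watson-Crick pair, the wobble penalty for G:U, or the mismatch penalty,
#' all doubled in the core; a bulged base adds the gap penalty at that
#' position's weight. A site one nucleotide longer (or shorter) than the
#' mature is aligned with the best single interior target (or miRNA) bulge.
#' A perfect complement scores 0.
#'
#' @param mature mature miRNA sequence (RNA, 5'->3').
#' @param site target site sequence (RNA, transcript sense), length within
#'   1 of the mature length.
#' @param scheme from [targetScheme()].
#' @return the expectation penalty (>= 0).
#' @examples
#' m <- "UGGAGCUCCCUUCAUUCCAAU"
#' scoreExpectation(m, revComp(gsub("U", "T", m)))  # 0
#' @export
scoreExpectation <- function(mature, site, scheme = targetScheme()) {
    m <- strsplit(asRNA(mature), "")[[1]]
    t <- strsplit(asRNA(site), "")[[1]]
    if (!length(m) || !length(t)) stop("empty mature or site sequence")
    L <- length(m); n <- length(t)
    if (abs(n - L) > 1L)
        stop("site length must be within one gap of the mature length")
    P <- .duplexPenalty(scheme)
    w <- .coreWeights(L, scheme)
    pen <- function(p, tIdx) P[m[p], t[tIdx]] * w[p]
    if (n == L) {
        return(sum(vapply(seq_len(L), function(p) pen(p, n - p + 1), 0)))
    }
    if (n == L + 1L) {   # one bulged target base after mature position g
        best <- Inf
        for (g in seq_len(L - 1L)) {
            s <- sum(vapply(seq_len(g), function(p) pen(p, n - p + 1), 0)) +
                 sum(vapply((g + 1L):L, function(p) pen(p, n - p), 0)) +
                 scheme$gap * w[min(g + 1L, L)]
            best <- min(best, s)
        }
        return(best)
    }
    # n == L - 1: one bulged (unpaired) miRNA base at interior position g
    best <- Inf
    for (g in 2:(L - 1L)) {
        s <- scheme$gap * w[g]
        if (g > 1L)
            s <- s + sum(vapply(seq_len(g - 1L),
                                function(p) pen(p, n - p + 1), 0))
        if (g < L)
            s <- s + sum(vapply((g + 1L):L,
                                function(p) pen(p, n - p + 2), 0))
        best <- min(best, s)
    }
    best
}

# Vectorized scan of all windows of a transcript for one mature.
# Returns every window variant with its expectation; gap variants carry the
# bulge description. Internal; findTargetSites applies cutoff + collapse.
.scanWindows <- function(mature, transcript, scheme) {
    m <- strsplit(asRNA(mature), "")[[1]]
    t <- strsplit(asRNA(transcript), "")[[1]]
    L <- length(m); n <- length(t)
    if (n < L) return(NULL)
    P <- .duplexPenalty(scheme)
    w <- .coreWeights(L, scheme)
    ti <- .RNA_CODES[t] + 1L
    mi <- .RNA_CODES[m] + 1L
    at <- function(idx) ifelse(idx >= 1L & idx <= n, idx, NA_integer_)
    # penalty matrices rows p = 1..L, cols e = 1..n (NA-padded -> 0)
    mk <- function(shift) {
        M <- matrix(0, L, n)
        for (p in seq_len(L)) {
            idx <- at(seq_len(n) - p + shift)
            v <- P[cbind(mi[p], ti[idx])] * w[p]
            v[is.na(v)] <- 0
            M[p, ] <- v
        }
        M
    }
    P0 <- mk(1L)                       # pairs e - p + 1
    cum0 <- apply(P0, 2, cumsum)
    if (L == 1L) cum0 <- matrix(cum0, nrow = 1L)
    res <- list()
    eG <- L:n
    res$none <- data.frame(start = eG - L + 1L, end = eG,
                           expectation = colSums(P0)[eG],
                           gapType = "none", gapPos = NA_integer_)
    if (n >= L + 1L && L >= 2L) {
        P1 <- mk(0L)                   # pairs e - p
        cum1 <- apply(P1, 2, cumsum)
        tot1 <- cum1[L, ]
        eT <- (L + 1L):n
        best <- rep(Inf, length(eT)); bestG <- rep(NA_integer_, length(eT))
        for (g in seq_len(L - 1L)) {
            sc <- cum0[g, eT] + (tot1[eT] - cum1[g, eT]) +
                  scheme$gap * w[min(g + 1L, L)]
            upd <- sc < best
            best[upd] <- sc[upd]; bestG[upd] <- g
        }
        res$target <- data.frame(start = eT - L, end = eT,
                                 expectation = best, gapType = "target",
                                 gapPos = bestG)
    }
    if (L >= 3L && n >= L - 1L) {
        Pm1 <- mk(2L)                  # pairs e - p + 2
        cumm1 <- apply(Pm1, 2, cumsum)
        totm1 <- cumm1[L, ]
        eM <- (L - 1L):n
        best <- rep(Inf, length(eM)); bestG <- rep(NA_integer_, length(eM))
        for (g in 2:(L - 1L)) {
            sc <- scheme$gap * w[g] + (totm1[eM] - cumm1[g, eM])
            if (g > 1L) sc <- sc + cum0[g - 1L, eM]
            upd <- sc < best
            best[upd] <- sc[upd]; bestG[upd] <- g
        }
        res$mature <- data.frame(start = eM - L + 2L, end = eM,
                                 expectation = best, gapType = "mature",
                                 gapPos = bestG)
    }
    out <- do.call(rbind, res)
    out[out$start >= 1L, , drop = FALSE]
}

#' Find miRNA target sites on a transcript
#'
#' Scores every window of the transcript (gapless, or with one interior
#' bulge on either strand of the duplex) and reports sites whose best
#' alignment has expectation at or below the cutoff. Overlapping candidate
#' windows are collapsed to local minima of the expectation (leftmost on
#' ties). The inhibition mode is `"cleavage"` when every central mature
#' position (9-11, length-rescaled) is a perfect Watson-Crick pair with no
#' adjacent bulge, `"translation"` otherwise.
#'
#' @param mature mature miRNA (RNA, 5'->3').
#' @param transcript target transcript sequence.
#' @param scheme from [targetScheme()]; `maxExpectation` defaults to the
#'   stringent 2.0.
#' @return `data.frame` with `start`, `end` (1-based inclusive on the
#'   transcript), `expectation`, `gapType`, `gapPos`, `mode`.
#' @export
findTargetSites <- function(mature, transcript, scheme = targetScheme()) {
    sc <- .scanWindows(mature, transcript, scheme)
    if (is.null(sc)) return(.emptySites())
    sc <- sc[sc$expectation <= scheme$maxExpectation + 1e-9, , drop = FALSE]
    if (!nrow(sc)) return(.emptySites())
    # collapse overlapping windows to local minima of expectation
    sc <- sc[order(sc$start, sc$expectation), , drop = FALSE]
    keep <- logical(nrow(sc))
    clusterEnd <- -1L; bestIdx <- NA_integer_; bestVal <- Inf
    for (i in seq_len(nrow(sc))) {
        if (sc$start[i] > clusterEnd) {      # new cluster
            if (!is.na(bestIdx)) keep[bestIdx] <- TRUE
            bestIdx <- i; bestVal <- sc$expectation[i]
            clusterEnd <- sc$end[i]
        } else {
            clusterEnd <- max(clusterEnd, sc$end[i])
            if (sc$expectation[i] < bestVal - 1e-12) {
                bestVal <- sc$expectation[i]; bestIdx <- i
            }
        }
    }
    if (!is.na(bestIdx)) keep[bestIdx] <- TRUE
    sc <- sc[keep, , drop = FALSE]
    L <- nchar(mature)
    cr <- .centralRegion(L)
    sc$mode <- vapply(seq_len(nrow(sc)), function(i) {
        site <- substr(asRNA(transcript), sc$start[i], sc$end[i])
        .inhibitionMode(mature, site, sc$gapType[i], sc$gapPos[i], cr)
    }, "")
    rownames(sc) <- NULL
    sc
}

.emptySites <- function() {
    data.frame(start = integer(), end = integer(), expectation = numeric(),
               gapType = character(), gapPos = integer(), mode = character(),
               stringsAsFactors = FALSE)
}

# cleavage iff central mature positions are perfect WC pairs, no bulge there
.inhibitionMode <- function(mature, site, gapType, gapPos, central) {
    m <- strsplit(asRNA(mature), "")[[1]]
    t <- strsplit(asRNA(site), "")[[1]]
    L <- length(m); n <- length(t)
    targetOf <- function(p) {
        if (gapType == "none") n - p + 1
        else if (gapType == "target") { if (p <= gapPos) n - p + 1 else n - p }
        else { if (p < gapPos) n - p + 1 else if (p > gapPos) n - p + 2 else NA }
    }
    for (p in central[1]:central[2]) {
        tp <- targetOf(p)
        if (is.na(tp)) return("translation")
        if (.RNA_COMP[[m[p]]] != t[tp]) return("translation")
    }
    if (gapType != "none" && !is.na(gapPos) &&
        gapPos >= central[1] - 1L && gapPos <= central[2])
        return("translation")
    "cleavage"
}

#' Target-site unpairing energy (UPE)
#'
#' The energetic cost of opening the local secondary structure around a
#' target site so the miRNA can bind: the site plus flanking context (17 nt
#' upstream, 13 nt downstream, clipped at transcript ends) is folded twice,
#' once unconstrained and once with every site base forced unpaired;
#' UPE = E(constrained) - E(unconstrained) >= 0.
#'
#' @param siteStart,siteEnd 1-based inclusive site bounds on the transcript.
#' @param transcript transcript sequence.
#' @param model an [EnergyModel-class].
#' @param flankUp,flankDown flank lengths (nt).
#' @return UPE in kcal/mol.
#' @export
computeUPE <- function(siteStart, siteEnd, transcript,
                       model = defaultEnergyModel(),
                       flankUp = 17L, flankDown = 13L) {
    n <- nchar(transcript)
    if (siteStart < 1L || siteEnd > n || siteStart > siteEnd)
        stop("site out of transcript bounds")
    a <- max(1L, siteStart - flankUp)
    b <- min(n, siteEnd + flankDown)
    sub <- asRNA(substr(transcript, a, b))
    rel <- c(siteStart - a + 1L, siteEnd - a + 1L)
    eu <- foldMFE(sub, model)@energy
    ec <- constrainedMFE(sub, model, region = rel)@energy
    ec - eu
}

#' Predict targets of a miRNA catalog on transcripts and lncRNAs
#'
#' Runs the site search for every mature against every coding transcript
#' and (with identical scoring configuration) against every lncRNA, filters
#' sites by expectation and UPE, and assembles the bipartite
#' miRNA-target interaction network.
#'
#' @param matures named character vector / `RNAStringSet` of matures.
#' @param transcripts named coding transcript set (may be empty).
#' @param lncRNAs named lncRNA set (may be `NULL` or empty).
#' @param scheme from [targetScheme()].
#' @param model energy model for the UPE computation.
#' @return list with `coding` and `lncrna` site tables (miRNA, transcript,
#'   site coordinates, expectation, UPE, mode), `degrees` (targets per
#'   miRNA) and `network` (an igraph bipartite graph).
#' @export
predictTargets <- function(matures, transcripts, lncRNAs = NULL,
                           scheme = targetScheme(),
                           model = defaultEnergyModel()) {
    matures <- .namedChar(matures, "mir")
    if (!length(matures) || (!length(transcripts) && !length(lncRNAs)))
        warning("empty catalog(s): target tables will be empty")
    scanSet <- function(txs, class) {
        txs <- .namedChar(txs, "tx")
        rows <- list()
        for (mi in seq_along(matures)) for (ti in seq_along(txs)) {
            sites <- findTargetSites(matures[[mi]], txs[[ti]], scheme)
            if (!nrow(sites)) next
            sites$UPE <- vapply(seq_len(nrow(sites)), function(i)
                computeUPE(sites$start[i], sites$end[i], txs[[ti]], model,
                           scheme$flankUp, scheme$flankDown), 0)
            sites <- sites[sites$UPE <= scheme$maxUPE + 1e-9, , drop = FALSE]
            if (!nrow(sites)) next
            sites$miRNA <- names(matures)[mi]
            sites$transcript <- names(txs)[ti]
            sites$targetClass <- class
            rows[[length(rows) + 1L]] <- sites
        }
        if (!length(rows)) {
            e <- .emptySites()
            e$UPE <- numeric(); e$miRNA <- character()
            e$transcript <- character(); e$targetClass <- character()
            return(e)
        }
        do.call(rbind, rows)
    }
    coding <- scanSet(transcripts, "coding")
    lnc <- scanSet(if (is.null(lncRNAs)) character() else lncRNAs, "lncRNA")
    edges <- rbind(coding, lnc)
    degrees <- if (nrow(edges)) table(edges$miRNA) else table(character())
    g <- igraph::make_empty_graph(directed = FALSE)
    if (nrow(edges)) {
        verts <- data.frame(
            name = c(unique(edges$miRNA), unique(edges$transcript)),
            type = rep(c(TRUE, FALSE), c(length(unique(edges$miRNA)),
                                         length(unique(edges$transcript)))))
        g <- igraph::graph_from_data_frame(
            edges[, c("miRNA", "transcript", "expectation")],
            directed = FALSE, vertices = verts)
    }
    list(coding = coding, lncrna = lnc, degrees = degrees, network = g)
}

#' Export an interaction network
#'
#' Writes the miRNA-target network as SIF (`miRNA targets transcript`) and,
#' optionally, GraphML with the expectation as an edge attribute.
#'
#' @param targets result of [predictTargets()].
#' @param sifPath output SIF path.
#' @param graphmlPath optional GraphML path.
#' @return `sifPath`, invisibly.
#' @export
exportNetwork <- function(targets, sifPath, graphmlPath = NULL) {
    edges <- rbind(targets$coding, targets$lncrna)
    lines <- if (nrow(edges))
        paste(edges$miRNA, "targets", edges$transcript) else character()
    writeLines(lines, sifPath)
    if (!is.null(graphmlPath))
        igraph::write_graph(targets$network, graphmlPath, format = "graphml")
    invisible(sifPath)
}
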