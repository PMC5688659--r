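# Independent brute-force oracles used to certify the package's optimized
# implementations. These are deliberately naive reformulations: no code is
# shared with the package internals beyond the public enumeration API.

# --- structure counting (independent of enumerateStructures) --------------
oracleCountStructures <- function(seq, minloop = 3L) {
    ch <- strsplit(toupper(seq), "")[[1]]
    ok <- function(a, b) {
        p <- paste0(ch[a], ch[b])
        p %in% c("GC", "CG", "AU", "UA", "GU", "UG")
    }
    memo <- new.env()
    cnt <- function(i, j) {
        if (j - i < minloop + 1L) return(1)
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        total <- cnt(i + 1L, j)
        for (k in (i + minloop + 1L):j)
            if (ok(i, k)) total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
        memo[[key]] <- total
        total
    }
    cnt(1L, length(ch))
}

# --- ensemble statistics by direct summation over the enumeration ---------
oracleEnsemble <- function(seq, model = defaultEnergyModel()) {
    structs <- enumerateStructures(seq, model)
    E <- vapply(structs, structureEnergy, 0)
    w <- exp(-E / model@RT)
    Z <- sum(w)
    L <- nchar(seq)
    P <- matrix(0, L, L)
    for (k in seq_along(structs)) {
        p <- basePairs(structs[[k]])
        if (nrow(p))
            for (r in seq_len(nrow(p)))
                P[p[r, 1], p[r, 2]] <- P[p[r, 1], p[r, 2]] + w[k] / Z
    }
    list(Z = Z, mfe = min(E), P = P + t(P), n = length(structs))
}

# --- all-positions Hamming scan -------------------------------------------
oracleHammingScan <- function(genomeSeq, pattern, maxMismatch = 3L) {
    hits <- list()
    for (strand in c("+", "-")) {
        pat <- if (strand == "+") pattern else revComp(pattern)
        pch <- strsplit(pat, "")[[1]]
        gch <- strsplit(genomeSeq, "")[[1]]
        L <- length(pch)
        for (s in seq_len(length(gch) - L + 1L)) {
            mm <- sum(gch[s:(s + L - 1L)] != pch)
            if (mm <= maxMismatch)
                hits[[length(hits) + 1L]] <- data.frame(
                    start = s, end = s + L - 1L, strand = strand,
                    mismatches = mm)
        }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
}

# --- quadratic tandem-repeat scan -----------------------------------------
oracleSSR <- function(seq, minRepeats = c(`1` = 5L, `2` = 3L, `3` = 2L,
                                          `4` = 2L, `5` = 2L, `6` = 2L)) {
    seq <- asRNA(seq)
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    isPrim <- function(m) {
        p <- nchar(m)
        for (d in seq_len(max(0L, p - 1L)))
            if (p %% d == 0L && strrep(substr(m, 1, d), p / d) == m)
                return(FALSE)
        TRUE
    }
    out <- list()
    for (p in 1:6) {
        for (i in seq_len(max(0L, n - 2L * p + 1L))) {
            # tract phase start: position i-1 must break the periodicity
            if (i > 1L && i - 1L + p <= n && ch[i - 1L] == ch[i - 1L + p])
                next
            k <- 1L
            while (i + (k + 1L) * p - 1L <= n &&
                   all(ch[i:(i + p - 1L)] ==
                       ch[(i + k * p):(i + (k + 1L) * p - 1L)]))
                k <- k + 1L
            motif <- paste(ch[i:(i + p - 1L)], collapse = "")
            if (k >= minRepeats[[as.character(p)]] && isPrim(motif))
                out[[length(out) + 1L]] <- data.frame(
                    motif = motif, period = p, start = i, repeatCount = k,
                    span = p * k, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(motif = character(), period = integer(),
                          start = integer(), repeatCount = integer(),
                          span = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$period), , drop = FALSE]
    rownames(res) <- NULL
    res
}

# --- naive six-frame ORF scan ---------------------------------------------
oracleORFs <- function(seq) {
    dna <- asDNA(seq)
    res <- list()
    for (sgn in c(1L, -1L)) {
        s <- if (sgn == 1L) dna else revComp(dna)
        ch <- strsplit(s, "")[[1]]
        n <- length(ch)
        for (off in 0:2) {
            i <- off + 1L
            inOrf <- FALSE; orfStart <- NA
            while (i + 2L <= n) {
                cod <- paste(ch[i:(i + 2L)], collapse = "")
                if (!inOrf && cod == "ATG") { inOrf <- TRUE; orfStart <- i }
                if (inOrf && cod %in% c("TAA", "TAG", "TGA")) {
                    res[[length(res) + 1L]] <- data.frame(
                        frame = sgn * (off + 1L), start = orfStart - 1L,
                        end = i + 2L, lengthAA = (i - orfStart) %/% 3L,
                        hasStop = TRUE)
                    inOrf <- FALSE
                }
                i <- i + 3L
            }
            if (inOrf)
                res[[length(res) + 1L]] <- data.frame(
                    frame = sgn * (off + 1L), start = orfStart - 1L,
                    end = i - 1L, lengthAA = (i - orfStart) %/% 3L,
                    hasStop = FALSE)
        }
    }
    if (!length(res)) return(NULL)
    do.call(rbind, res)
}

# --- exhaustive duplex window scoring -------------------------------------
# Direct per-window, per-gap-position evaluation of the expectation scheme.
oracleBestWindowScore <- function(mature, transcript,
                                  scheme = targetScheme()) {
    m <- strsplit(asRNA(mature), "")[[1]]
    t <- strsplit(asRNA(transcript), "")[[1]]
    L <- length(m); n <- length(t)
    wob <- function(a, b) (a == "G" && b == "U") || (a == "U" && b == "G")
    wc <- c(A = "U", C = "G", G = "C", U = "A")
    core <- if (L >= 15L) 2:min(13L, L)
            else max(1L, round(2 * L / 21)):min(L, round(13 * L / 21))
    wgt <- rep(1, L); wgt[core] <- scheme$coreMultiplier
    pairPen <- function(p, tb) {
        if (wc[[m[p]]] == tb) 0
        else if (wob(m[p], tb)) scheme$wobble * wgt[p]
        else scheme$mismatch * wgt[p]
    }
    best <- data.frame(start = integer(), end = integer(),
                       score = numeric())
    addWin <- function(s, e, sc)
        best <<- rbind(best, data.frame(start = s, end = e, score = sc))
    for (s in seq_len(max(0L, n - L + 1L))) {     # gapless
        e <- s + L - 1L
        sc <- sum(vapply(1:L, function(p) pairPen(p, t[e - p + 1L]), 0))
        addWin(s, e, sc)
    }
    if (n >= L + 1L)                               # one bulged target base
        for (s in seq_len(n - L)) {
            e <- s + L
            for (g in 1:(L - 1L)) {
                sc <- scheme$gap * wgt[min(g + 1L, L)]
                for (p in 1:L) {
                    ti <- if (p <= g) e - p + 1L else e - p
                    sc <- sc + pairPen(p, t[ti])
                }
                addWin(s, e, sc)
            }
        }
    if (L >= 3L && n >= L - 1L)                    # one bulged miRNA base
        for (s in seq_len(n - L + 2L)) {
            e <- s + L - 2L
            for (g in 2:(L - 1L)) {
                sc <- scheme$gap * wgt[g]
                for (p in setdiff(1:L, g)) {
                    ti <- if (p < g) e - p + 1L else e - p + 2L
                    sc <- sc + pairPen(p, t[ti])
                }
                addWin(s, e, sc)
            }
        }
    best
}

# minimal expectation over all windows overlapping a given interval
oracleMinScoreAt <- function(mature, transcript, from, to,
                             scheme = targetScheme()) {
    w <- oracleBestWindowScore(mature, transcript, scheme)
    w <- w[w$start <= to & w$end >= from, , drop = FALSE]
    if (!nrow(w)) Inf else min(w$score)
}

randomRNA <- function(L) paste(sample(c("A", "C", "G", "U"), L, TRUE),
                               collapse = "")
randomDNA <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = "")

dinucCounts <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
}
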