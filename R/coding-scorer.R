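# Built-in coding-potential scorer: a calibrated stand-in for external
# coding-potential classifiers, not a reimplementation of any of them.
# External programs' tabular outputs can be supplied instead wherever a
# scorer is accepted (see classifyCodingPotential).

.fickettAsymmetry <- function(seq) {
    ch <- strsplit(asDNA(seq), "", fixed = TRUE)[[1]]
    pos <- (seq_along(ch) - 1L) %% 3L
    vapply(c("A", "C", "G", "T"), function(b) {
        cnt <- vapply(0:2, function(p) sum(ch == b & pos == p), 0)
        max(cnt) / (min(cnt) + 1)
    }, 0)
}

.orfHexamers <- function(seq) {
    orfs <- findORFs(seq)
    if (!nrow(orfs)) return(character())
    o <- orfs[1L, ]
    s <- if (o$frame > 0) asDNA(seq) else revComp(asDNA(seq))
    orfSeq <- substr(s, o$start + 1L, o$end)
    n <- nchar(orfSeq)
    if (n < 6L) return(character())
    at <- seq.int(1L, n - 5L, by = 3L)
    substring(orfSeq, at, at + 5L)
}

.allHexamers <- function(seq) {
    s <- asDNA(seq)
    n <- nchar(s)
    if (n < 6L) return(character())
    substring(s, seq_len(n - 5L), seq_len(n - 5L) + 5L)
}

.scorerFeatures <- function(seqs, hexLLR) {
    feats <- t(vapply(seqs, function(s) {
        L <- nchar(s)
        orfs <- findORFs(s)
        orfNt <- if (nrow(orfs)) orfs$end[1L] - orfs$start[1L] else 0L
        orfAA <- if (nrow(orfs)) orfs$lengthAA[1L] else 0L
        hx <- .orfHexamers(s)
        hexScore <- if (length(hx)) {
            v <- hexLLR[hx]
            mean(v[!is.na(v)], na.rm = TRUE)
        } else 0
        if (!is.finite(hexScore)) hexScore <- 0
        asym <- .fickettAsymmetry(s)
        gc <- composition(s)$gcPercent / 100
        c(orfCoverage = orfNt / L, logOrfAA = log1p(orfAA),
          hexScore = hexScore, asym, gc = gc)
    }, numeric(8)))
    as.data.frame(feats)
}

#' Train the built-in coding-potential scorer
#'
#' Extracts ORF-coverage, in-frame hexamer log-likelihood and Fickett-style
#' positional-asymmetry features from labelled training transcripts, fits a
#' primary logistic model whose log-odds are affinely calibrated onto an
#' open-ended score scale (training coding >= 1.0 and non-coding <= -0.5 at
#' >= 90 percent rate, by construction from the 10th/90th training
#' quantiles), and a secondary alignment-free logistic model reporting a
#' probability in [0, 1].
#'
#' @param coding,noncoding character vectors (or `XStringSet`) of training
#'   transcripts, at least 50 per class.
#' @return a [CodingScorer-class].
#' @seealso [classifyCodingPotential()], [primaryScore()]
#' @export
buildCodingScorer <- function(coding, noncoding) {
    coding <- as.character(coding); noncoding <- as.character(noncoding)
    if (length(coding) < 50L || length(noncoding) < 50L)
        stop("need >= 50 training sequences per class; for smaller sets ",
             "supply external coding-potential scores as a score table")
    pc <- table(unlist(lapply(coding, .orfHexamers)))
    pn <- table(unlist(lapply(noncoding, .allHexamers)))
    hexes <- sort(unique(c(names(pc), names(pn))))
    fc <- (as.numeric(pc[hexes]) %-na% 0 + 1) ; fc <- fc / sum(fc)
    fn <- (as.numeric(pn[hexes]) %-na% 0 + 1) ; fn <- fn / sum(fn)
    hexLLR <- stats::setNames(log2(fc / fn), hexes)

    seqs <- c(coding, noncoding)
    y <- rep(c(1L, 0L), c(length(coding), length(noncoding)))
    X <- .scorerFeatures(seqs, hexLLR)
    primary <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()))
    secondary <- suppressWarnings(
        stats::glm(y ~ hexScore + A + C + G + T + gc,
                   data = cbind(y = y, X), family = stats::binomial()))
    lp <- stats::predict(primary, X)
    qc <- stats::quantile(lp[y == 1L], 0.10, names = FALSE)
    qn <- stats::quantile(lp[y == 0L], 0.90, names = FALSE)
    if (qc <= qn)
        stop("training classes do not separate; supply external scores ",
             "from a dedicated coding-potential program instead")
    beta <- 1.5 / (qc - qn)
    alpha <- 1 - beta * qc
    S <- alpha + beta * lp
    new("CodingScorer", primary = primary, secondary = secondary,
        alpha = alpha, beta = beta, hexamerLLR = hexLLR,
        trainingRate = c(coding = mean(S[y == 1L] >= 1.0),
                         noncoding = mean(S[y == 0L] <= -0.5)))
}

`%-na%` <- function(x, repl) { x[is.na(x)] <- repl; x }

#' @rdname primaryScore
#' @export
setMethod("primaryScore", "CodingScorer", function(object, seqs) {
    X <- .scorerFeatures(as.character(seqs), object@hexamerLLR)
    unname(object@alpha + object@beta * stats::predict(object@primary, X))
})

#' @rdname primaryScore
#' @export
setMethod("secondaryScore", "CodingScorer", function(object, seqs) {
    X <- .scorerFeatures(as.character(seqs), object@hexamerLLR)
    unname(stats::predict(object@secondary, X, type = "response"))
})

setMethod("show", "CodingScorer", function(object) {
    cat("CodingScorer:", length(object@hexamerLLR), "hexamers;",
        "training calibration rates: coding",
        round(object@trainingRate[["coding"]], 3), "/ noncoding",
        round(object@trainingRate[["noncoding"]], 3), "\n")
})
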