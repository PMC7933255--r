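# Independent oracles used to validate the package's computations.

# Exact copy-number distribution after nPeriods periods from one copy,
# by explicit multinomial transition sums over {delete, keep, duplicate}
# outcomes (independent of the pgf-composition implementation).
oraclePMF <- function(alpha, beta, gamma, nPeriods, wgdTime = NA) {
    trans <- function(v) {
        K <- length(v) - 1L
        out <- numeric(2L * K + 1L)
        for (k in 0:K) {
            if (v[k + 1L] == 0) next
            if (k == 0L) { out[1L] <- out[1L] + v[1L]; next }
            for (d in 0:k) for (u in 0:(k - d)) {
                s <- k - d - u
                w <- exp(lgamma(k + 1) - lgamma(d + 1) - lgamma(s + 1) -
                         lgamma(u + 1)) *
                    alpha^d * beta^s * gamma^u
                j <- s + 2L * u
                out[j + 1L] <- out[j + 1L] + v[k + 1L] * w
            }
        }
        out
    }
    dbl <- function(v) {
        out <- numeric(2L * (length(v) - 1L) + 1L)
        out[2L * (seq_along(v) - 1L) + 1L] <- v
        out
    }
    v <- c(0, 1)
    if (nPeriods >= 1L) for (t in seq_len(nPeriods)) {
        if (!is.na(wgdTime) && t == wgdTime + 1L) v <- dbl(v)
        v <- trans(v)
    }
    if (!is.na(wgdTime) && wgdTime == nPeriods) v <- dbl(v)
    v
}

# Brute-force Barnard p-value: explicit loops over all tables with the
# observed column margins and over the nuisance grid.
oracleBarnard <- function(a, b, c, d, piGrid = seq(0.001, 0.999, 0.001)) {
    m1 <- a + c; m2 <- b + d
    wald <- function(x1, x2) {
        p1 <- if (m1 > 0) x1 / m1 else 0
        p2 <- if (m2 > 0) x2 / m2 else 0
        pp <- (x1 + x2) / (m1 + m2)
        se <- sqrt(pp * (1 - pp) * (1 / max(m1, 1) + 1 / max(m2, 1)))
        if (!is.finite(se) || se == 0) 0 else (p1 - p2) / se
    }
    tObs <- abs(wald(a, b))
    best <- 0
    for (p in piGrid) {
        tot <- 0
        for (x1 in 0:m1) for (x2 in 0:m2) {
            if (abs(wald(x1, x2)) >= tObs - 1e-7)
                tot <- tot + dbinom(x1, m1, p) * dbinom(x2, m2, p)
        }
        if (tot > best) best <- tot
    }
    min(best, 1)
}

# in-memory segment table builder (1-based closed coordinates)
makeSegTable <- function(sampleId, chrom, start, end, major, minor) {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start, end),
        majorCN = as.integer(major), minorCN = as.integer(minor),
        totalCN = as.integer(major) + as.integer(minor))
    new("SegmentTable", sampleId = sampleId, segments = gr)
}

# in-memory mutation table builder
makeMutations <- function(chrom, pos, ids, consequence, presentIn,
                          ccf = NA_real_) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                 mutationId = ids, gene = "G",
                                 consequence = consequence,
                                 ccf = rep_len(ccf, length(pos)))
    S4Vectors::mcols(gr)$presentIn <- IRanges::CharacterList(presentIn)
    gr
}

writeTempTSV <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}
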