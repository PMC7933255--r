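## LOH "sculpting" statistics: expected non-synonymous counts from codon
## usage, per-segment excess flags, the one-sided binomial aggregate
## test, the large-segment filter, and the 2x2 exclusivity classification.

## per-codon count of non-synonymous single-nucleotide neighbours (of 9),
## computed once at load; stop-gain changes count as non-synonymous
.codonNonsynCounts <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        gc <- Biostrings::GENETIC_CODE
        sense <- names(gc)[gc != "*"]
        bases <- c("A", "C", "G", "T")
        cnt <- vapply(sense, function(cd) {
            aa <- gc[[cd]]
            n <- 0L
            for (p in 1:3) {
                for (b in setdiff(bases, substr(cd, p, p))) {
                    mut <- cd
                    substr(mut, p, p) <- b
                    if (gc[[mut]] != aa) n <- n + 1L
                }
            }
            n
        }, 0L)
        cache <<- cnt
        cache
    }
})

#' Codon-usage-weighted mutability profile
#'
#' For each sense codon of the standard genetic code, enumerates its 9
#' single-nucleotide neighbours and classifies each change as synonymous
#' or non-synonymous (changes to a stop codon count as non-synonymous).
#' \code{pNonsyn} is the usage-weighted probability that a random coding
#' single-nucleotide change is non-synonymous, under a uniform
#' substitution model over the 9 neighbours.
#'
#' @param usage named numeric codon-usage vector as returned by
#'   [readCodonUsage()] (codons absent from the table get weight 0).
#' @return list with \code{pNonsyn}, \code{pSyn} (their sum is 1) and
#'   the \code{ratio = pNonsyn / pSyn} used to convert synonymous counts
#'   into expected non-synonymous counts.
#' @examples
#' codonMutability(c(TGG = 1))$pNonsyn  # 1: every change alters Trp
#' codonMutability(c(GCT = 1))$pNonsyn  # 6/9: third position is 4-fold
#' @export
codonMutability <- function(usage) {
    if (!length(usage)) .stopf("empty codon usage table")
    nsCnt <- .codonNonsynCounts()
    usage <- usage[names(usage) %in% names(nsCnt)]
    if (!length(usage) || sum(usage) <= 0)
        .stopf("codon usage table has no sense codons with positive weight")
    w <- usage / sum(usage)
    pNs <- sum(w * nsCnt[names(w)] / 9)
    list(pNonsyn = pNs, pSyn = 1 - pNs, ratio = pNs / (1 - pNs))
}

#' Per-segment non-synonymous excess
#'
#' Counts synonymous and non-synonymous mutations falling in each
#' segment and compares the non-synonymous count with its expectation
#' \code{nSyn * pNonsyn / pSyn} derived from the synonymous count and
#' codon usage. With no synonymous mutations the expectation is 0 and
#' any non-synonymous mutation is an excess.
#'
#' @param segs \code{GRanges} of segments (e.g. acquired-LOH segments).
#' @param mutations mutation \code{GRanges} restricted to the mutations
#'   relevant to the comparison (e.g. those lost with the segments).
#' @param profile a mutability profile from [codonMutability()].
#' @return \code{data.frame} with one row per segment: coordinates,
#'   \code{nSyn}, \code{nNonsyn}, \code{expectedNonsyn}, \code{exceeds}.
#' @export
segmentExcess <- function(segs, mutations, profile) {
    stopifnot(is(segs, "GRanges"))
    cons <- mcols(mutations)$consequence
    nS <- GenomicRanges::countOverlaps(segs,
                                       mutations[cons == "synonymous"])
    nN <- GenomicRanges::countOverlaps(segs,
                                       mutations[cons == "nonsynonymous"])
    expN <- nS * profile$ratio
    data.frame(chromosome = as.character(seqnames(segs)),
               start = start(segs), end = end(segs),
               nSyn = nS, nNonsyn = nN, expectedNonsyn = expN,
               exceeds = nN > expN, stringsAsFactors = FALSE)
}

#' Keep segments longer than a minimum length
#'
#' Strict filter \code{length > minLength}; the default 10 Mb drops the
#' small acquired-LOH segments that tend to arise from over-segmentation
#' in copy-number estimation.
#'
#' @param segs \code{GRanges}.
#' @param minLength minimum length in bp (default 1e7).
#' @return the retained \code{GRanges}.
#' @export
filterLargeSegments <- function(segs, minLength = 1e7) {
    stopifnot(is(segs, "GRanges"))
    segs[width(segs) > minLength]
}

#' One-sided binomial test for aggregate non-synonymous excess
#'
#' Given per-segment excess flags (see [segmentExcess()]), tests whether
#' segments exceeding their expected non-synonymous count are more
#' frequent than chance. A segment with \code{sz = nSyn + nNonsyn}
#' mutations exceeds its expectation exactly when
#' \code{nNonsyn > sz * pNonsyn}, so with \code{null = "per_segment"}
#' (default) the null probability is the mean over segments of the exact
#' per-segment exceedance probability
#' \code{P(Binomial(sz, pNonsyn) > sz * pNonsyn)}, which depends only on
#' the segment's mutation count; with \code{null = "half"} it is 0.5.
#' The p-value is the exact binomial upper tail
#' \code{P(Binomial(n, nullP) >= k)}.
#'
#' @param summaries \code{data.frame} from [segmentExcess()].
#' @param null \code{"per_segment"} or \code{"half"}.
#' @param profile mutability profile (required for
#'   \code{null = "per_segment"}).
#' @return list with \code{k}, \code{n}, \code{nullP}, \code{pValue}.
#' @export
binomialExcessTest <- function(summaries, null = c("per_segment", "half"),
                               profile = NULL) {
    null <- match.arg(null)
    n <- nrow(summaries)
    if (is.null(n) || n < 1L) .stopf("need at least one segment summary")
    k <- sum(summaries$exceeds)
    if (null == "half") {
        nullP <- 0.5
    } else {
        if (is.null(profile))
            .stopf("null = 'per_segment' requires the mutability profile")
        sz <- summaries$nSyn + summaries$nNonsyn
        ## P(X > sz * pNonsyn) = P(X >= floor(sz * pNonsyn) + 1)
        nullP <- mean(ifelse(sz > 0,
                             stats::pbinom(floor(sz * profile$pNonsyn),
                                           sz, profile$pNonsyn,
                                           lower.tail = FALSE),
                             0))
    }
    p <- stats::pbinom(k - 1, n, nullP, lower.tail = FALSE)
    list(k = k, n = n, nullP = nullP, pValue = p)
}

#' Classify LOH events into a 2x2 neo-antigenicity / mutation-load table
#'
#' Median split on each measure (values strictly above the median are
#' "high"; ties go to "low"). Cell \code{a} counts (high-neo, low-nonsyn)
#' events, \code{b} (high-neo, high-nonsyn), \code{c} (low-neo,
#' low-nonsyn), \code{d} (low-neo, high-nonsyn): mutual exclusivity
#' loads \code{a} and \code{d}.
#'
#' @param neoScore numeric per-event neo-antigenicity measure.
#' @param nonsynCount numeric per-event non-synonymous mutation count.
#' @return list with counts \code{a, b, c, d} and the 2x2 \code{table}
#'   (rows neo high/low, columns nonsyn low/high).
#' @export
classifyEvents2x2 <- function(neoScore, nonsynCount) {
    if (length(neoScore) != length(nonsynCount))
        .stopf("neoScore and nonsynCount must have equal length")
    if (length(neoScore) < 4L)
        .stopf("need at least 4 events with both measures, got %d",
               length(neoScore))
    hiNeo <- neoScore > stats::median(neoScore)
    hiNs <- nonsynCount > stats::median(nonsynCount)
    a <- sum(hiNeo & !hiNs); b <- sum(hiNeo & hiNs)
    c_ <- sum(!hiNeo & !hiNs); d <- sum(!hiNeo & hiNs)
    tab <- matrix(c(a, c_, b, d), 2, 2,
                  dimnames = list(neo = c("high", "low"),
                                  nonsyn = c("low", "high")))
    list(a = a, b = b, c = c_, d = d, table = tab)
}
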