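#' Summarise segments to arm-level copy numbers
#'
#' For each included arm, takes the length-weighted modal (major, minor)
#' pair among overlapping determined segments. An arm is undetermined
#' when determined segments cover less than half of its length. Weight
#' ties break deterministically towards the smaller (major, minor) pair.
#'
#' @param segTable a [SegmentTable-class].
#' @param armDefs an [ArmDefinitions-class].
#' @param minCoverage minimum determined fraction of the arm (default 0.5).
#' @return An [ArmCNProfile-class] over the included arms.
#' @examples
#' ad <- hg19Arms()
#' gr <- arms(ad, includedOnly = TRUE)[1:2]
#' st <- new("SegmentTable", sampleId = "s",
#'           segments = GenomicRanges::GRanges(
#'               GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
#'               majorCN = c(1L, 2L), minorCN = c(1L, 1L),
#'               totalCN = c(2L, 3L)))
#' armProfileTable(summarizeArms(st, ad))[1:2, ]
#' @export
summarizeArms <- function(segTable, armDefs, minCoverage = 0.5) {
    stopifnot(is(segTable, "SegmentTable"), is(armDefs, "ArmDefinitions"))
    armGr <- arms(armDefs, includedOnly = TRUE)
    seg <- segments(segTable)
    mc <- mcols(seg)
    det <- !is.na(mc$majorCN) & !is.na(mc$minorCN)
    hits <- findOverlaps(armGr, seg)
    if (!length(hits))
        .stopf("no segments of sample '%s' overlap any included arm",
               sampleId(segTable))
    ov <- pintersect(armGr[queryHits(hits)], seg[subjectHits(hits)])
    w <- width(ov)
    armIdx <- queryHits(hits)
    segIdx <- subjectHits(hits)
    n <- length(armGr)
    maj <- rep(NA_integer_, n); mnr <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        sel <- armIdx == i & det[segIdx]
        if (!any(sel)) next
        cov <- sum(w[sel]) / width(armGr)[i]
        if (cov < minCoverage) next
        key <- paste(mc$majorCN[segIdx[sel]], mc$minorCN[segIdx[sel]])
        wt <- tapply(w[sel], key, sum)
        pair <- strsplit(names(wt), " ", fixed = TRUE)
        pm <- as.integer(vapply(pair, `[`, "", 1L))
        pn <- as.integer(vapply(pair, `[`, "", 2L))
        pick <- order(-as.numeric(wt), pm, pn)[1L]
        maj[i] <- pm[pick]; mnr[i] <- pn[pick]
    }
    armCNProfile(sampleId(segTable), mcols(armGr)$armId, maj, mnr)
}
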