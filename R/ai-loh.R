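## Allelic imbalance / LOH genome summarisation and acquired-LOH calling.

#' Classify the allelic state of a (major, minor) copy-number pair
#'
#' Regions of allelic balance have equal maternal and paternal copy
#' number; allelic imbalance (AI) has unequal copy numbers; an AI with
#' minor copy number zero is loss of heterozygosity (LOH) — homozygous
#' deletion (0, 0) is counted as LOH. Missing copy numbers are
#' undetermined.
#'
#' @param majorCN,minorCN integer vectors (NA = missing).
#' @return factor with levels \code{balanced, ai_no_loh, ai_loh,
#'   undetermined}.
#' @examples
#' classifyAllelicState(c(1L, 2L, 2L, NA), c(1L, 0L, 1L, NA))
#' @export
classifyAllelicState <- function(majorCN, minorCN) {
    majorCN <- as.integer(majorCN); minorCN <- as.integer(minorCN)
    if (length(majorCN) != length(minorCN))
        .stopf("majorCN and minorCN must have equal length")
    both <- !is.na(majorCN) & !is.na(minorCN)
    if (any(minorCN[both] > majorCN[both]))
        .stopf("minorCN > majorCN at position %d",
               which(both & minorCN > majorCN)[1L])
    out <- rep("undetermined", length(majorCN))
    out[both & minorCN == 0L] <- "ai_loh"
    out[both & minorCN > 0L & majorCN == minorCN] <- "balanced"
    out[both & minorCN > 0L & majorCN > minorCN] <- "ai_no_loh"
    factor(out, levels = .AI_STATES)
}

## segment GRanges annotated with its allelic state
.segmentStates <- function(segTable) {
    gr <- segments(segTable)
    mcols(gr)$state <- classifyAllelicState(mcols(gr)$majorCN,
                                            mcols(gr)$minorCN)
    gr
}

#' Genome-wide allelic-state summary
#'
#' Fractions of \code{genomeLength} occupied by each allelic state, with
#' genome not covered by any segment counted as undetermined, and the
#' length-weighted mean total copy number (mean ploidy) over determined
#' segments.
#'
#' @param segTable a [SegmentTable-class].
#' @param genomeLength assayed genome length in bp; must be at least the
#'   total segment length. Defaults to the summed length of the bundled
#'   hg19 autosomal arms.
#' @return A [GenomeStateSummary-class].
#' @export
genomeStateSummary <- function(segTable,
                               genomeLength = sum(width(arms(hg19Arms(),
                                   includedOnly = TRUE)))) {
    stopifnot(is(segTable, "SegmentTable"))
    gr <- .segmentStates(segTable)
    w <- width(gr)
    if (sum(w) > genomeLength)
        .stopf("genomeLength %.0f smaller than total segment length %.0f",
               genomeLength, sum(w))
    fr <- vapply(.AI_STATES, function(s)
        sum(w[mcols(gr)$state == s]) / genomeLength, 0)
    fr["undetermined"] <- fr["undetermined"] +
        (genomeLength - sum(w)) / genomeLength
    det <- mcols(gr)$state != "undetermined"
    if (!any(det))
        .stopf("no determined segments: mean ploidy is undefined")
    tot <- mcols(gr)$majorCN[det] + mcols(gr)$minorCN[det]
    new("GenomeStateSummary", fractions = fr,
        meanPloidy = sum(tot * w[det]) / sum(w[det]))
}

#' Acquired-LOH segments between an early and a late sample
#'
#' Intersects the LOH regions of the late sample with the regions where
#' the early sample is determined and not already LOH (balanced or AI
#' without LOH). Early-undetermined regions are excluded, so every
#' reported interval is one where heterozygosity was demonstrably
#' present early and lost late.
#'
#' @param early,late [SegmentTable-class] objects from the same patient.
#' @return \code{GRanges} with metadata columns \code{earlySample},
#'   \code{lateSample}, \code{earlyState} and \code{lengthBp}.
#' @export
acquiredLOH <- function(early, late) {
    stopifnot(is(early, "SegmentTable"), is(late, "SegmentTable"))
    eg <- .segmentStates(early)
    lg <- .segmentStates(late)
    lateLoh <- lg[mcols(lg)$state == "ai_loh"]
    earlyHet <- eg[mcols(eg)$state %in% c("balanced", "ai_no_loh")]
    hits <- findOverlaps(lateLoh, earlyHet)
    out <- pintersect(lateLoh[queryHits(hits)], earlyHet[subjectHits(hits)])
    mcols(out) <- DataFrame(
        earlySample = rep(sampleId(early), length(out)),
        lateSample = rep(sampleId(late), length(out)),
        earlyState = as.character(mcols(earlyHet)$state[subjectHits(hits)]),
        lengthBp = width(out))
    sort(out)
}

#' Fraction of lost mutations explained by acquired LOH
#'
#' A mutation is lost when it is present in the early sample and absent
#' from the late sample. Returns the proportion of lost mutations whose
#' position lies inside acquired-LOH intervals, together with the
#' early-disease cancer-cell fractions of the two groups (inside vs
#' outside LOH) for descriptive comparison.
#'
#' @param mutations mutation \code{GRanges} (see [readMutationTable()]).
#' @param earlySample,lateSample sample identifiers.
#' @param acquired acquired-LOH \code{GRanges} from [acquiredLOH()].
#' @return list with \code{fraction} (NA with a warning when no mutation
#'   was lost), \code{nLost}, \code{nInLOH}, \code{ccfInLOH},
#'   \code{ccfElsewhere} and the two group medians.
#' @export
lostMutationLOHFraction <- function(mutations, earlySample, lateSample,
                                    acquired) {
    pres <- mcols(mutations)$presentIn
    inE <- vapply(pres, function(x) earlySample %in% x, TRUE)
    inL <- vapply(pres, function(x) lateSample %in% x, TRUE)
    lost <- inE & !inL
    if (!any(lost)) {
        .warnf("no mutations lost between '%s' and '%s'; fraction undefined",
               earlySample, lateSample)
        return(list(fraction = NA_real_, nLost = 0L, nInLOH = 0L,
                    ccfInLOH = numeric(0), ccfElsewhere = numeric(0),
                    medianCcfInLOH = NA_real_,
                    medianCcfElsewhere = NA_real_))
    }
    lm <- mutations[lost]
    inLoh <- if (length(acquired)) overlapsAny(lm, acquired)
             else rep(FALSE, length(lm))
    ccf <- mcols(lm)$ccf
    list(fraction = mean(inLoh), nLost = length(lm), nInLOH = sum(inLoh),
         ccfInLOH = ccf[inLoh & !is.na(ccf)],
         ccfElsewhere = ccf[!inLoh & !is.na(ccf)],
         medianCcfInLOH = stats::median(ccf[inLoh], na.rm = TRUE),
         medianCcfElsewhere = stats::median(ccf[!inLoh], na.rm = TRUE))
}

#' Merge acquired-LOH segments across late samples into events
#'
#' Single-linkage merge of overlapping (>= 1 bp) acquired-LOH intervals
#' from one patient's late samples; abutting but non-overlapping
#' intervals remain separate events.
#'
#' @param acquiredList a list of acquired-LOH \code{GRanges} (one per
#'   late sample, as from [acquiredLOH()]), or a single such
#'   \code{GRanges}.
#' @return \code{GRanges} of events with metadata columns
#'   \code{memberSamples} (\code{CharacterList}), \code{nSegments} and
#'   \code{members} (\code{GRangesList} of the member segments).
#' @export
mergeLOHEvents <- function(acquiredList) {
    if (is(acquiredList, "GRanges")) acquiredList <- list(acquiredList)
    all <- suppressWarnings(do.call(c, unname(lapply(acquiredList,
                                                     identity))))
    if (!length(all)) {
        ev <- GRanges()
        mcols(ev) <- DataFrame(memberSamples = IRanges::CharacterList(),
                               nSegments = integer(0))
        return(ev)
    }
    ev <- reduce(all, min.gapwidth = 0L)
    hits <- findOverlaps(ev, all)
    samp <- split(mcols(all)$lateSample[subjectHits(hits)],
                  factor(queryHits(hits), levels = seq_along(ev)))
    mcols(ev)$memberSamples <- IRanges::CharacterList(
        lapply(samp, function(x) sort(unique(x))))
    mcols(ev)$nSegments <- as.integer(table(factor(queryHits(hits),
                                            levels = seq_along(ev))))
    mcols(ev)$members <- GRangesList(
        lapply(seq_along(ev), function(i)
            all[subjectHits(hits)[queryHits(hits) == i]]))
    ev
}
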