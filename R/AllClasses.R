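#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps pintersect
#'   reduce width start end isDisjoint
#' @importFrom GenomeInfoDb seqnames
NULL

## ---------------------------------------------------------------------------
## BranchingParams
## ---------------------------------------------------------------------------

#' Parameters of the arm-level branching-process model
#'
#' Each copy of each chromosome arm independently, per time period, is
#' deleted with probability \code{alpha}, retained with probability
#' \code{beta}, or duplicated with probability \code{gamma}
#' (\code{alpha + beta + gamma = 1}). Evolution runs for \code{nPeriods}
#' periods from a single copy per allele; the WGD variant doubles every
#' extant copy after \code{wgdTime} periods.
#'
#' @slot alpha per-copy deletion probability per period.
#' @slot beta per-copy no-change probability per period.
#' @slot gamma per-copy duplication probability per period.
#' @slot nPeriods number of time periods \code{N >= 0}.
#' @slot wgdTime integer WGD time \code{M} with \code{1 <= M <= N}, or
#'   \code{NA} for the model without WGD.
#' @slot constrained logical; \code{TRUE} when the symmetric-rate
#'   constraint \code{alpha == gamma} is imposed.
#'
#' @seealso [branchingParams()], [copyNumberPMF()], [fitBranchingModel()]
#' @export
setClass("BranchingParams",
    representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                   nPeriods = "integer", wgdTime = "integer",
                   constrained = "logical"))

setValidity("BranchingParams", function(object) {
    p <- c(object@alpha, object@beta, object@gamma)
    if (length(p) != 3L || anyNA(p))
        return("alpha, beta, gamma must be single non-missing numbers")
    if (any(p < 0))
        return("alpha, beta, gamma must be non-negative")
    if (abs(sum(p) - 1) > 1e-12)
        return(sprintf("alpha + beta + gamma = %.15g, must equal 1", sum(p)))
    if (length(object@nPeriods) != 1L || is.na(object@nPeriods) ||
        object@nPeriods < 0L)
        return("nPeriods must be a single integer >= 0")
    if (length(object@wgdTime) != 1L)
        return("wgdTime must be length 1 (NA for the model without WGD)")
    if (!is.na(object@wgdTime) &&
        (object@wgdTime < 1L || object@wgdTime > object@nPeriods))
        return(sprintf("wgdTime = %d out of range [1, %d]",
                       object@wgdTime, object@nPeriods))
    if (isTRUE(object@constrained) &&
        abs(object@alpha - object@gamma) > 1e-12)
        return("constrained = TRUE requires alpha == gamma")
    TRUE
})

#' Construct branching-process parameters
#'
#' @param alpha,beta,gamma per-copy per-period probabilities of deletion,
#'   no change and duplication; must sum to 1.
#' @param nPeriods number of time periods \code{N}.
#' @param wgdTime WGD time \code{M} in \code{1..N}, or \code{NA} (default)
#'   for the model without a WGD event.
#' @param constrained impose \code{alpha == gamma}.
#' @return A [BranchingParams-class] object.
#' @examples
#' branchingParams(0.1, 0.8, 0.1, nPeriods = 6)
#' @export
branchingParams <- function(alpha, beta, gamma, nPeriods = 6L,
                            wgdTime = NA_integer_,
                            constrained = isTRUE(all.equal(alpha, gamma))) {
    new("BranchingParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
        gamma = as.numeric(gamma), nPeriods = as.integer(nPeriods),
        wgdTime = as.integer(wgdTime), constrained = isTRUE(constrained))
}

#' Symmetric-rate parameters
#'
#' Convenience constructor under the constraint \code{alpha == gamma == rate},
#' \code{beta = 1 - 2 * rate}.
#'
#' @param rate common deletion/duplication rate in \code{[0, 0.5]}.
#' @inheritParams branchingParams
#' @return A [BranchingParams-class] object with \code{constrained = TRUE}.
#' @export
symmetricParams <- function(rate, nPeriods = 6L, wgdTime = NA_integer_) {
    branchingParams(rate, 1 - 2 * rate, rate, nPeriods = nPeriods,
                    wgdTime = wgdTime, constrained = TRUE)
}

setMethod("show", "BranchingParams", function(object) {
    cat(sprintf(
        "BranchingParams: alpha=%.5g beta=%.5g gamma=%.5g N=%d%s%s\n",
        object@alpha, object@beta, object@gamma, object@nPeriods,
        if (is.na(object@wgdTime)) " (no WGD)"
        else sprintf(" WGD at M=%d", object@wgdTime),
        if (object@constrained) " [alpha=gamma]" else ""))
})

## ---------------------------------------------------------------------------
## CopyNumberPMF
## ---------------------------------------------------------------------------

#' Exact per-allele copy-number distribution
#'
#' Probability vector over per-allele arm copy numbers \code{0..cMax},
#' obtained as the coefficient list of the branching-process probability
#' generating function. \code{cMax = 2^N} without WGD and \code{2^(N+1)}
#' with WGD.
#'
#' @slot probs numeric probability vector, element \code{i} giving
#'   \code{P(copy number = i - 1)}.
#' @slot nPeriods number of periods the pgf was composed over.
#' @slot wgdTime WGD time, or \code{NA}.
#' @seealso [copyNumberPMF()]
#' @export
setClass("CopyNumberPMF",
    representation(probs = "numeric", nPeriods = "integer",
                   wgdTime = "integer"))

setValidity("CopyNumberPMF", function(object) {
    p <- object@probs
    if (any(p < -1e-12)) return("negative probabilities")
    if (abs(sum(p) - 1) > 1e-9)
        return(sprintf("probabilities sum to %.12g, not 1", sum(p)))
    cmax <- 2^(object@nPeriods + !is.na(object@wgdTime))
    if (length(p) != cmax + 1L)
        return(sprintf("expected support 0..%d (length %d), got length %d",
                       cmax, cmax + 1L, length(p)))
    TRUE
})

#' @describeIn CopyNumberPMF-class probability vector accessor (named by
#'   copy number).
#' @param object a \code{CopyNumberPMF}.
#' @export
setGeneric("pmfProbs", function(object) standardGeneric("pmfProbs"))

#' @rdname CopyNumberPMF-class
#' @export
setMethod("pmfProbs", "CopyNumberPMF", function(object) {
    p <- object@probs
    names(p) <- seq_along(p) - 1L
    p
})

setMethod("show", "CopyNumberPMF", function(object) {
    cat(sprintf("CopyNumberPMF over copy numbers 0..%d (N=%d%s)\n",
                length(object@probs) - 1L, object@nPeriods,
                if (is.na(object@wgdTime)) ""
                else sprintf(", WGD at M=%d", object@wgdTime)))
    p <- pmfProbs(object)
    show(head(round(p[p > 1e-6], 5), 10))
})

## ---------------------------------------------------------------------------
## SegmentTable
## ---------------------------------------------------------------------------

#' Allele-specific copy-number segments of one sample
#'
#' Wraps a \code{GRanges} (1-based, closed intervals) with integer
#' metadata columns \code{majorCN}, \code{minorCN}, \code{totalCN}
#' (\code{NA} = undetermined). Row order is the file order; rows of a
#' chromosome must not overlap.
#'
#' @slot sampleId sample identifier.
#' @slot segments \code{GRanges} with the copy-number metadata columns.
#' @seealso [readSegmentTable()], [segments()], [genomeStateSummary()]
#' @export
setClass("SegmentTable",
    representation(sampleId = "character", segments = "GRanges"))

setValidity("SegmentTable", function(object) {
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        return("sampleId must be a single string")
    gr <- object@segments
    mc <- mcols(gr)
    need <- c("majorCN", "minorCN", "totalCN")
    if (!all(need %in% names(mc)))
        return("segments must carry majorCN, minorCN, totalCN columns")
    maj <- mc$majorCN; mnr <- mc$minorCN; tot <- mc$totalCN
    both <- !is.na(maj) & !is.na(mnr)
    if (any(mnr[both] > maj[both]))
        return("minorCN greater than majorCN")
    all3 <- both & !is.na(tot)
    if (any(tot[all3] != maj[all3] + mnr[all3]))
        return("totalCN != majorCN + minorCN")
    if (length(gr) && !isDisjoint(gr))
        return("segments overlap within a chromosome")
    TRUE
})

#' @describeIn SegmentTable-class sample identifier accessor.
#' @param object,x a \code{SegmentTable}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname SegmentTable-class
#' @export
setMethod("sampleId", "SegmentTable", function(object) object@sampleId)

#' @describeIn SegmentTable-class underlying \code{GRanges} accessor.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname SegmentTable-class
#' @export
setMethod("segments", "SegmentTable", function(x) x@segments)

setMethod("show", "SegmentTable", function(object) {
    cat(sprintf("SegmentTable '%s': %d segments on %d chromosomes\n",
                object@sampleId, length(object@segments),
                length(unique(as.character(seqnames(object@segments))))))
})

## ---------------------------------------------------------------------------
## ArmDefinitions
## ---------------------------------------------------------------------------

#' Chromosome-arm definitions
#'
#' One interval per arm (1-based, closed), derived from a cytogenetic band
#' file by splitting each chromosome at its centromere. Arms carry an
#' \code{included} flag; acrocentric short arms (13p, 14p, 15p, 21p, 22p)
#' and the sex chromosomes are excluded from arm-level model fitting by
#' default, leaving 39 modelled autosomal arms.
#'
#' @slot arms \code{GRanges} with metadata columns \code{armId} and
#'   \code{included}.
#' @seealso [readArmDefinitions()], [hg19Arms()]
#' @export
setClass("ArmDefinitions", representation(arms = "GRanges"))

setValidity("ArmDefinitions", function(object) {
    gr <- object@arms
    mc <- mcols(gr)
    if (!all(c("armId", "included") %in% names(mc)))
        return("arms must carry armId and included columns")
    if (anyDuplicated(mc$armId)) return("duplicate armId")
    if (length(gr) && !isDisjoint(gr))
        return("arms of a chromosome overlap")
    TRUE
})

#' @describeIn ArmDefinitions-class arm \code{GRanges} accessor.
#' @param x an \code{ArmDefinitions} object.
#' @param includedOnly return only arms flagged included.
#' @export
setGeneric("arms", function(x, includedOnly = FALSE) standardGeneric("arms"))

#' @rdname ArmDefinitions-class
#' @export
setMethod("arms", "ArmDefinitions", function(x, includedOnly = FALSE) {
    gr <- x@arms
    if (includedOnly) gr <- gr[mcols(gr)$included]
    gr
})

setMethod("show", "ArmDefinitions", function(object) {
    inc <- sum(mcols(object@arms)$included)
    cat(sprintf("ArmDefinitions: %d arms (%d included in modelling)\n",
                length(object@arms), inc))
})

## ---------------------------------------------------------------------------
## ArmCNProfile
## ---------------------------------------------------------------------------

#' Arm-level allele-specific copy-number profile of one sample
#'
#' Parallel vectors of arm identifiers and (major, minor) integer copy
#' numbers; \code{NA} pairs mark undetermined arms.
#'
#' @slot sampleId sample identifier.
#' @slot armId character arm identifiers (e.g. \code{"8q"}).
#' @slot majorCN,minorCN integer copy numbers per arm.
#' @seealso [summarizeArms()], [simulateArmProfile()],
#'   [fitBranchingModel()]
#' @export
setClass("ArmCNProfile",
    representation(sampleId = "character", armId = "character",
                   majorCN = "integer", minorCN = "integer"))

setValidity("ArmCNProfile", function(object) {
    n <- length(object@armId)
    if (length(object@majorCN) != n || length(object@minorCN) != n)
        return("armId, majorCN, minorCN must have equal length")
    if (anyDuplicated(object@armId)) return("duplicate armId")
    both <- !is.na(object@majorCN) & !is.na(object@minorCN)
    if (any(object@minorCN[both] > object@majorCN[both]))
        return("minorCN greater than majorCN")
    if (any(object@majorCN[both] < 0L) || any(object@minorCN[both] < 0L))
        return("negative copy number")
    TRUE
})

#' Construct an arm-level copy-number profile
#'
#' @param sampleId sample identifier.
#' @param armId character vector of arm ids.
#' @param majorCN,minorCN integer copy numbers (NA = undetermined).
#' @return An [ArmCNProfile-class] object.
#' @export
armCNProfile <- function(sampleId, armId, majorCN, minorCN) {
    new("ArmCNProfile", sampleId = as.character(sampleId),
        armId = as.character(armId), majorCN = as.integer(majorCN),
        minorCN = as.integer(minorCN))
}

#' @rdname ArmCNProfile-class
#' @param object an \code{ArmCNProfile}.
#' @export
setMethod("sampleId", "ArmCNProfile", function(object) object@sampleId)

#' @describeIn ArmCNProfile-class profile as a \code{data.frame} with
#'   columns \code{armId}, \code{majorCN}, \code{minorCN}.
#' @export
setGeneric("armProfileTable", function(object)
    standardGeneric("armProfileTable"))

#' @rdname ArmCNProfile-class
#' @export
setMethod("armProfileTable", "ArmCNProfile", function(object) {
    data.frame(armId = object@armId, majorCN = object@majorCN,
               minorCN = object@minorCN, stringsAsFactors = FALSE)
})

setMethod("show", "ArmCNProfile", function(object) {
    det <- !is.na(object@majorCN) & !is.na(object@minorCN)
    cat(sprintf("ArmCNProfile '%s': %d arms (%d determined)\n",
                object@sampleId, length(object@armId), sum(det)))
})

## ---------------------------------------------------------------------------
## FitResult
## ---------------------------------------------------------------------------

#' Maximum-likelihood fit of one branching-process model
#'
#' Carries the MLE parameters, the log-likelihood in nats, the free
#' parameter count \code{k} of the fitted model, and
#' \code{aic = 2k - 2 logL}. After [selectModel()] the comparison fields
#' \code{deltaAIC = AIC_non-WGD - AIC_WGD} and \code{selected} are
#' populated; \code{deltaAIC > 0} supports genome doubling.
#'
#' @slot model \code{"wgd"} or \code{"non_wgd"}.
#' @slot params [BranchingParams-class] at the MLE.
#' @slot logLik log-likelihood (nats).
#' @slot k free-parameter count of this model as fitted.
#' @slot aic \code{2k - 2 logL}.
#' @slot nObs number of determined arms the fit used.
#' @slot obsUnit \code{"allele"} (default) or \code{"total"}.
#' @slot deltaAIC \code{AIC_non-WGD - AIC_WGD}, \code{NA} until compared.
#' @slot selected selected model label, \code{NA} until compared.
#' @seealso [fitBranchingModel()], [selectModel()], [generalAIC()]
#' @export
setClass("FitResult",
    representation(model = "character", params = "BranchingParams",
                   logLik = "numeric", k = "integer", aic = "numeric",
                   nObs = "integer", obsUnit = "character",
                   deltaAIC = "numeric", selected = "character"))

setValidity("FitResult", function(object) {
    if (!object@model %in% c("wgd", "non_wgd"))
        return("model must be 'wgd' or 'non_wgd'")
    if (!object@k %in% 1:3) return("k must be 1, 2 or 3")
    if (is.finite(object@logLik) &&
        abs(object@aic - (2 * object@k - 2 * object@logLik)) > 1e-8)
        return("aic != 2k - 2 logL")
    if (!is.na(object@selected) &&
        !object@selected %in% c("wgd", "non_wgd"))
        return("selected must be 'wgd' or 'non_wgd'")
    if (!is.na(object@deltaAIC) && !is.na(object@selected)) {
        if ((object@deltaAIC > 0) != (object@selected == "wgd"))
            return("deltaAIC > 0 must coincide with selected == 'wgd'")
    }
    TRUE
})

#' @describeIn FitResult-class MLE parameters.
#' @param object a \code{FitResult}.
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname FitResult-class
#' @export
setMethod("fitParams", "FitResult", function(object) object@params)

#' @describeIn FitResult-class \code{AIC = 2k - 2 logL} with the model's
#'   own parameter count.
#' @export
setGeneric("modelAIC", function(object) standardGeneric("modelAIC"))

#' @rdname FitResult-class
#' @export
setMethod("modelAIC", "FitResult", function(object) object@aic)

#' @describeIn FitResult-class log-likelihood in nats.
#' @export
setGeneric("fitLogLik", function(object) standardGeneric("fitLogLik"))

#' @rdname FitResult-class
#' @export
setMethod("fitLogLik", "FitResult", function(object) object@logLik)

#' @describeIn FitResult-class comparison accessors.
#' @export
setGeneric("deltaAIC", function(object) standardGeneric("deltaAIC"))

#' @rdname FitResult-class
#' @export
setMethod("deltaAIC", "FitResult", function(object) object@deltaAIC)

#' @describeIn FitResult-class selected model after [selectModel()].
#' @export
setGeneric("selectedModel", function(object) standardGeneric("selectedModel"))

#' @rdname FitResult-class
#' @export
setMethod("selectedModel", "FitResult", function(object) object@selected)

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s]: logL=%.4f k=%d AIC=%.4f (n=%d %s obs)\n",
                object@model, object@logLik, object@k, object@aic,
                object@nObs, object@obsUnit))
    show(object@params)
    if (!is.na(object@selected))
        cat(sprintf("  deltaAIC = %.4f -> selected: %s\n",
                    object@deltaAIC, object@selected))
})

## ---------------------------------------------------------------------------
## GenomeStateSummary
## ---------------------------------------------------------------------------

#' Genome-wide allelic-state summary of one sample
#'
#' Fractions of assayed genome length in each allelic state (balanced,
#' allelic imbalance without LOH, allelic imbalance with LOH,
#' undetermined; summing to 1) plus the length-weighted mean ploidy over
#' determined segments.
#'
#' @slot fractions named numeric of length 4 over the allelic states.
#' @slot meanPloidy length-weighted mean total copy number.
#' @seealso [genomeStateSummary()], [classifyAllelicState()]
#' @export
setClass("GenomeStateSummary",
    representation(fractions = "numeric", meanPloidy = "numeric"))

setValidity("GenomeStateSummary", function(object) {
    f <- object@fractions
    if (!identical(names(f), .AI_STATES))
        return("fractions must be named balanced, ai_no_loh, ai_loh, undetermined")
    if (any(f < -1e-12)) return("negative fraction")
    if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1")
    if (object@meanPloidy < 0) return("meanPloidy must be >= 0")
    TRUE
})

#' @describeIn GenomeStateSummary-class state-fraction accessor.
#' @param object a \code{GenomeStateSummary}.
#' @export
setGeneric("stateFractions", function(object)
    standardGeneric("stateFractions"))

#' @rdname GenomeStateSummary-class
#' @export
setMethod("stateFractions", "GenomeStateSummary",
          function(object) object@fractions)

#' @describeIn GenomeStateSummary-class mean-ploidy accessor.
#' @export
setGeneric("meanPloidy", function(object) standardGeneric("meanPloidy"))

#' @rdname GenomeStateSummary-class
#' @export
setMethod("meanPloidy", "GenomeStateSummary",
          function(object) object@meanPloidy)

setMethod("show", "GenomeStateSummary", function(object) {
    cat("GenomeStateSummary:\n")
    print(round(object@fractions, 4))
    cat(sprintf("  mean ploidy: %.3f\n", object@meanPloidy))
})
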