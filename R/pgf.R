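## Probability generating function machinery.
##
## The per-copy single-period offspring pgf is f(s) = alpha + beta s +
## gamma s^2. N periods of evolution from one copy give the N-fold
## composition F_N = f o ... o f; a WGD event after M periods gives
## G(s) = F_M([F_{N-M}(s)]^2): every copy extant at time M doubles, and
## each of the two daughters evolves independently for the remaining
## N - M periods. All pgfs are represented as coefficient vectors
## (element i = P(copy number i - 1)) and composed by exact polynomial
## arithmetic; for N = 6 degrees stay <= 128 so double precision is
## accurate to ~1e-12.

## polynomial product of coefficient vectors
.polyMul <- function(a, b) {
    la <- length(a); lb <- length(b)
    out <- numeric(la + lb - 1L)
    for (i in seq_len(la)) {
        if (a[i] != 0)
            out[i:(i + lb - 1L)] <- out[i:(i + lb - 1L)] + a[i] * b
    }
    out
}

## p(q(s)) by Horner's scheme on coefficient vectors
.polyCompose <- function(p, q) {
    n <- length(p)
    r <- p[n]
    if (n == 1L) return(r)
    for (i in (n - 1L):1L) {
        r <- .polyMul(r, q)
        r[1L] <- r[1L] + p[i]
    }
    r
}

## ladder of iterates: element k+1 holds the coefficients of F_k,
## F_0(s) = s, F_{k+1} = f(F_k) = alpha + beta F_k + gamma F_k^2
.pgfLadder <- function(alpha, beta, gamma, nPeriods) {
    lad <- vector("list", nPeriods + 1L)
    lad[[1L]] <- c(0, 1)
    if (nPeriods >= 1L) for (k in seq_len(nPeriods)) {
        Fk <- lad[[k]]
        out <- gamma * .polyMul(Fk, Fk)
        out[seq_along(Fk)] <- out[seq_along(Fk)] + beta * Fk
        out[1L] <- out[1L] + alpha
        lad[[k + 1L]] <- out
    }
    lad
}

## per-allele pmf coefficients for one model, given a precomputed ladder;
## wgdTime NA selects the model without WGD
.pmfFromLadder <- function(lad, nPeriods, wgdTime = NA_integer_) {
    if (is.na(wgdTime)) {
        p <- lad[[nPeriods + 1L]]
        cmax <- 2^nPeriods
    } else {
        inner <- lad[[nPeriods - wgdTime + 1L]]
        p <- .polyCompose(lad[[wgdTime + 1L]], .polyMul(inner, inner))
        cmax <- 2^(nPeriods + 1L)
    }
    ## pad to the full support; coefficients are sums of products of
    ## non-negative terms, so no sign dust can arise
    out <- numeric(cmax + 1L)
    out[seq_along(p)] <- p
    out
}

#' Single-period offspring distribution
#'
#' Coefficients of the per-copy offspring pgf
#' \code{f(s) = alpha + beta s + gamma s^2}: the probabilities that one
#' arm copy leaves 0, 1 or 2 copies after one time period.
#'
#' @param params a [BranchingParams-class] object.
#' @return numeric of length 3: \code{c(P(0), P(1), P(2))}.
#' @examples
#' offspringPgf(branchingParams(0.1, 0.8, 0.1))
#' @export
offspringPgf <- function(params) {
    stopifnot(is(params, "BranchingParams"))
    validObject(params)
    c(params@alpha, params@beta, params@gamma)
}

#' Exact copy-number distribution of one allele lineage
#'
#' Composes the offspring pgf over \code{nPeriods} periods, inserting a
#' whole-genome doubling after \code{wgdTime} periods when the parameters
#' specify one, and returns the resulting per-allele copy-number
#' distribution starting from a single copy.
#'
#' @param params a [BranchingParams-class] object.
#' @return A [CopyNumberPMF-class] over copy numbers
#'   \code{0..2^N} (no WGD) or \code{0..2^(N+1)} (WGD).
#' @examples
#' pmf <- copyNumberPMF(symmetricParams(0.1, nPeriods = 2))
#' round(pmfProbs(pmf), 4)
#' @export
copyNumberPMF <- function(params) {
    stopifnot(is(params, "BranchingParams"))
    validObject(params)
    lad <- .pgfLadder(params@alpha, params@beta, params@gamma,
                      params@nPeriods)
    new("CopyNumberPMF",
        probs = .pmfFromLadder(lad, params@nPeriods, params@wgdTime),
        nPeriods = params@nPeriods, wgdTime = params@wgdTime)
}

#' Maximum representable total arm copy number
#'
#' The largest total (two-allele) arm copy number the model can assign
#' non-zero probability: each allele lineage can at most double every
#' period, and a WGD event doubles once more, giving
#' \code{2 * 2^nPeriods * (2 if WGD else 1)}. With the default
#' \code{nPeriods = 6} and a WGD event this is 256.
#'
#' @param nPeriods number of time periods, \code{>= 0}.
#' @param withWGD does the model include a WGD event?
#' @return integer maximum total copy number.
#' @examples
#' maxTotalCopyNumber(6, TRUE)   # 256
#' maxTotalCopyNumber(0, FALSE)  # 2
#' @export
maxTotalCopyNumber <- function(nPeriods, withWGD = FALSE) {
    if (!.isCount(nPeriods))
        .stopf("nPeriods must be a single non-negative integer")
    as.integer(2 * 2^nPeriods * (if (isTRUE(withWGD)) 2 else 1))
}
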