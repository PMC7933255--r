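## Likelihood and model fitting for the arm-level branching process.

## tabulate determined per-allele (or total) observations of a profile
.observedCounts <- function(profile, obsUnit = c("allele", "total")) {
    obsUnit <- match.arg(obsUnit)
    det <- !is.na(profile@majorCN) & !is.na(profile@minorCN)
    maj <- profile@majorCN[det]; mnr <- profile@minorCN[det]
    obs <- if (obsUnit == "allele") c(maj, mnr) else maj + mnr
    if (!length(obs)) .stopf("profile '%s' has no determined arms",
                             profile@sampleId)
    tab <- table(obs)
    list(values = as.integer(names(tab)), counts = as.integer(tab),
         nArms = sum(det))
}

## log-likelihood from a per-allele pmf vector and tabulated observations;
## -Inf when any observed state has zero probability
.logLikFromPMF <- function(probs, obsTab, obsUnit) {
    if (obsUnit == "total") probs <- .polyMul(probs, probs)
    if (any(obsTab$values + 1L > length(probs))) return(NA_real_)
    p <- probs[obsTab$values + 1L]
    if (any(p <= 0)) return(-Inf)
    sum(obsTab$counts * log(p))
}

#' Log-likelihood of an arm profile under the branching process
#'
#' By default each determined arm contributes two independent single-copy
#' lineages (the major and the minor allele), so the log-likelihood is the
#' sum over arms and alleles of \code{log P(observed allele copy number)}
#' under [copyNumberPMF()]. \code{obsUnit = "total"} instead scores the
#' total arm copy number against the two-allele convolution of the pmf.
#' Undetermined arms are skipped. Returns \code{-Inf} when any observed
#' state has probability zero under the parameters.
#'
#' @param profile an [ArmCNProfile-class].
#' @param params a [BranchingParams-class].
#' @param obsUnit observation unit, \code{"allele"} or \code{"total"}.
#' @return log-likelihood in nats.
#' @examples
#' prof <- armCNProfile("s", c("1p", "1q"), c(1L, 1L), c(1L, 1L))
#' armLogLikelihood(prof, branchingParams(0, 1, 0, nPeriods = 6))  # 0
#' @export
armLogLikelihood <- function(profile, params,
                             obsUnit = c("allele", "total")) {
    stopifnot(is(profile, "ArmCNProfile"), is(params, "BranchingParams"))
    obsUnit <- match.arg(obsUnit)
    obsTab <- .observedCounts(profile, obsUnit)
    probs <- copyNumberPMF(params)@probs
    ll <- .logLikFromPMF(probs, obsTab, obsUnit)
    if (is.na(ll)) {
        cap <- maxTotalCopyNumber(params@nPeriods, !is.na(params@wgdTime))
        per <- if (obsUnit == "allele") cap %/% 2L else cap
        bad <- obsTab$values[obsTab$values > per][1L]
        det <- which(!is.na(profile@majorCN))
        hit <- det[profile@majorCN[det] == bad | profile@minorCN[det] == bad]
        .stopf(paste0("unrepresentable state: observed copy number %d ",
                      "(arm %s) exceeds the model support %d; increase ",
                      "nPeriods"),
               bad, if (length(hit)) profile@armId[hit[1L]] else "?", per)
    }
    ll
}

## deterministic golden-section maximisation of f on [lo, hi]
.goldenMax <- function(f, lo, hi, tol = 1e-5) {
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- f(x1); f2 <- f(x2)
    while (hi - lo > tol) {
        if (f1 < f2) {
            lo <- x1; x1 <- x2; f1 <- f2
            x2 <- lo + gr * (hi - lo); f2 <- f(x2)
        } else {
            hi <- x2; x2 <- x1; f2 <- f1
            x1 <- hi - gr * (hi - lo); f1 <- f(x1)
        }
    }
    x <- if (f1 >= f2) x1 else x2
    list(x = x, value = max(f1, f2))
}

.NEG_SENTINEL <- -1e18

## cache of gridded per-allele pmfs, keyed by (nPeriods, gridStep): the
## grid likelihood surface depends on the profile only through the
## observation table, so the pmf grid is shared across fits
.pmfGridEnv <- new.env(parent = emptyenv())

.pmfGrid <- function(nPeriods, gridStep) {
    key <- sprintf("N%d_s%.6g", nPeriods, gridStep)
    hit <- .pmfGridEnv[[key]]
    if (!is.null(hit)) return(hit)
    rGrid <- seq(0, 0.5, by = gridStep)
    Ms <- c(NA_integer_, seq_len(nPeriods))
    pmfs <- lapply(Ms, function(M)
        matrix(0, length(rGrid), 2^(nPeriods + !is.na(M)) + 1L))
    for (i in seq_along(rGrid)) {
        lad <- .pgfLadder(rGrid[i], 1 - 2 * rGrid[i], rGrid[i], nPeriods)
        for (j in seq_along(Ms))
            pmfs[[j]][i, ] <- .pmfFromLadder(lad, nPeriods, Ms[j])
    }
    out <- list(rGrid = rGrid, Ms = Ms, pmfs = pmfs)
    .pmfGridEnv[[key]] <- out
    out
}

#' Maximum-likelihood fit of the branching-process model
#'
#' Fits the arm-level copy-number evolution model to one sample's
#' [ArmCNProfile-class], with or without a single WGD event. Under the
#' default symmetric constraint \code{alpha == gamma == r} the search is
#' a deterministic grid over \code{r} in \code{[0, 0.5]} (step
#' \code{gridStep}) followed by golden-section refinement to \code{tol};
#' the WGD model additionally maximises over the doubling time
#' \code{M in 1..nPeriods}. The unconstrained mode searches
#' \code{(alpha, gamma)} on a 2-D grid with Nelder-Mead refinement.
#' All searches are deterministic, so fits are reproducible bit-for-bit.
#'
#' @param profile an [ArmCNProfile-class] with at least one determined arm.
#' @param withWGD fit the model that includes a WGD event?
#' @param nPeriods number of time periods \code{N} (default 6; a warning
#'   is issued above 8 because the pgf degree grows as \code{2^(N+1)}).
#' @param constrained impose \code{alpha == gamma} (default TRUE).
#' @param obsUnit \code{"allele"} (default) or \code{"total"}; see
#'   [armLogLikelihood()].
#' @param gridStep grid resolution for the rate search.
#' @param tol refinement tolerance on the rate.
#' @return A [FitResult-class]. Free-parameter counts are 1 (constrained,
#'   no WGD), 2 (constrained WGD, or unconstrained no WGD) or 3
#'   (unconstrained WGD).
#' @examples
#' prof <- armCNProfile("s", paste0("a", 1:5), rep(2L, 5), rep(2L, 5))
#' fit <- fitBranchingModel(prof, withWGD = TRUE)
#' fitLogLik(fit)  # 0: deterministic doubling explains (2,2) everywhere
#' @export
fitBranchingModel <- function(profile, withWGD = FALSE, nPeriods = 6L,
                              constrained = TRUE,
                              obsUnit = c("allele", "total"),
                              gridStep = 0.005, tol = 1e-5) {
    stopifnot(is(profile, "ArmCNProfile"))
    obsUnit <- match.arg(obsUnit)
    nPeriods <- as.integer(nPeriods)
    if (nPeriods < 1L) .stopf("nPeriods must be >= 1 to fit")
    if (nPeriods > 8L)
        .warnf("nPeriods = %d: pgf degree grows as 2^(N+1); fits will be slow",
               nPeriods)
    obsTab <- .observedCounts(profile, obsUnit)
    cap <- maxTotalCopyNumber(nPeriods, withWGD)
    per <- if (obsUnit == "allele") cap %/% 2L else cap
    if (any(obsTab$values > per))
        .stopf(paste0("observed copy number %d exceeds the support %d of ",
                      "the %s model with nPeriods = %d; increase nPeriods"),
               max(obsTab$values), per,
               if (withWGD) "WGD" else "non-WGD", nPeriods)
    Ms <- if (withWGD) seq_len(nPeriods) else NA_integer_

    llEval <- function(alpha, gamma, M) {
        lad <- .pgfLadder(alpha, 1 - alpha - gamma, gamma, nPeriods)
        .logLikFromPMF(.pmfFromLadder(lad, nPeriods, M), obsTab, obsUnit)
    }

    if (constrained) {
        cacheOK <- obsUnit == "allele"
        grid <- .pmfGrid(nPeriods, gridStep)
        rGrid <- grid$rGrid
        gridLL <- matrix(NA_real_, length(rGrid), length(Ms))
        for (j in seq_along(Ms)) {
            jj <- if (is.na(Ms[j])) 1L else Ms[j] + 1L
            P <- grid$pmfs[[jj]]
            if (cacheOK) {
                sub <- P[, obsTab$values + 1L, drop = FALSE]
                gridLL[, j] <- as.vector(log(sub) %*% obsTab$counts)
            } else {
                for (i in seq_along(rGrid))
                    gridLL[i, j] <- .logLikFromPMF(P[i, ], obsTab, obsUnit)
            }
        }
        gridLL[!is.finite(gridLL)] <- .NEG_SENTINEL
        best <- list(r = NA_real_, M = NA_integer_, ll = .NEG_SENTINEL)
        top <- max(gridLL)
        if (top <= .NEG_SENTINEL)
            .stopf(paste0("no parameter value gives the observations ",
                          "positive probability; increase nPeriods"))
        for (j in seq_along(Ms)) {
            i0 <- which.max(gridLL[, j])
            if (gridLL[i0, j] < top - 10) next  # cannot overtake after refine
            f <- function(r) {
                ll <- llEval(r, r, Ms[j])
                if (!is.finite(ll)) .NEG_SENTINEL else ll
            }
            ref <- .goldenMax(f, max(0, rGrid[i0] - gridStep),
                              min(0.5, rGrid[i0] + gridStep), tol = tol)
            ## the grid point itself may beat the interior refinement
            cand <- if (ref$value >= gridLL[i0, j])
                list(r = ref$x, ll = ref$value)
            else list(r = rGrid[i0], ll = gridLL[i0, j])
            if (cand$ll > best$ll)
                best <- list(r = cand$r, M = Ms[j], ll = cand$ll)
        }
        pars <- symmetricParams(best$r, nPeriods = nPeriods,
                                wgdTime = best$M)
        k <- 1L + as.integer(withWGD)
        ll <- best$ll
    } else {
        ag <- expand.grid(alpha = seq(0, 0.5, by = 0.02),
                          gamma = seq(0, 0.5, by = 0.02))
        best <- list(alpha = NA, gamma = NA, M = NA_integer_,
                     ll = .NEG_SENTINEL)
        for (j in seq_along(Ms)) {
            lls <- mapply(function(a, g) {
                v <- llEval(a, g, Ms[j])
                if (!is.finite(v)) .NEG_SENTINEL else v
            }, ag$alpha, ag$gamma)
            i0 <- which.max(lls)
            obj <- function(x) {
                a <- x[1]; g <- x[2]
                if (a < 0 || g < 0 || a + g > 1) return(.NEG_SENTINEL)
                v <- llEval(a, g, Ms[j])
                if (!is.finite(v)) .NEG_SENTINEL else v
            }
            opt <- stats::optim(c(ag$alpha[i0], ag$gamma[i0]), obj,
                                method = "Nelder-Mead",
                                control = list(fnscale = -1,
                                               reltol = 1e-10,
                                               maxit = 500))
            cand <- if (opt$value >= lls[i0])
                list(a = opt$par[1], g = opt$par[2], ll = opt$value)
            else list(a = ag$alpha[i0], g = ag$gamma[i0], ll = lls[i0])
            if (cand$ll > best$ll)
                best <- list(alpha = cand$a, gamma = cand$g, M = Ms[j],
                             ll = cand$ll)
        }
        if (best$ll <= .NEG_SENTINEL)
            .stopf(paste0("no parameter value gives the observations ",
                          "positive probability; increase nPeriods"))
        pars <- branchingParams(best$alpha,
                                1 - best$alpha - best$gamma, best$gamma,
                                nPeriods = nPeriods, wgdTime = best$M,
                                constrained = FALSE)
        k <- 2L + as.integer(withWGD)
        ll <- best$ll
    }
    new("FitResult", model = if (withWGD) "wgd" else "non_wgd",
        params = pars, logLik = ll, k = k, aic = 2 * k - 2 * ll,
        nObs = obsTab$nArms, obsUnit = obsUnit,
        deltaAIC = NA_real_, selected = NA_character_)
}

#' AIC under the general parameter counting
#'
#' The general model counting assigns 3 free parameters to the WGD model
#' (\code{alpha}, \code{gamma}, \code{M}) and 2 to the non-WGD model,
#' regardless of the symmetric constraint. Applying it to constrained
#' fits offsets both AIC values by a constant +2, which does not change
#' their difference or the selected model.
#'
#' @param fit a [FitResult-class].
#' @return numeric AIC, \code{2 k_general - 2 logL}.
#' @export
generalAIC <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    kGen <- if (fit@model == "wgd") 3L else 2L
    2 * kGen - 2 * fit@logLik
}

#' Compare the WGD and non-WGD fits by AIC
#'
#' Computes \code{deltaAIC = AIC_non-WGD - AIC_WGD}; positive values
#' support genome doubling. Ties (\code{deltaAIC == 0}) resolve to the
#' more parsimonious non-WGD model. The comparison is invariant to
#' whether each model's own parameter count or the general counting
#' (see [generalAIC()]) is used, since the two differ by the same
#' constant for both models.
#'
#' @param fitWGD a [FitResult-class] with \code{model == "wgd"}.
#' @param fitNonWGD a [FitResult-class] with \code{model == "non_wgd"}.
#' @return The selected model's [FitResult-class] with \code{deltaAIC}
#'   and \code{selected} populated.
#' @export
selectModel <- function(fitWGD, fitNonWGD) {
    stopifnot(is(fitWGD, "FitResult"), is(fitNonWGD, "FitResult"))
    if (fitWGD@model != "wgd" || fitNonWGD@model != "non_wgd")
        .stopf("arguments must be the WGD fit then the non-WGD fit")
    if (fitWGD@params@nPeriods != fitNonWGD@params@nPeriods ||
        fitWGD@nObs != fitNonWGD@nObs ||
        fitWGD@obsUnit != fitNonWGD@obsUnit ||
        fitWGD@params@constrained != fitNonWGD@params@constrained)
        .stopf("fits were not produced from the same profile and settings")
    dAIC <- generalAIC(fitNonWGD) - generalAIC(fitWGD)
    sel <- if (dAIC > 0) fitWGD else fitNonWGD
    sel@deltaAIC <- dAIC
    sel@selected <- if (dAIC > 0) "wgd" else "non_wgd"
    validObject(sel)
    sel
}
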