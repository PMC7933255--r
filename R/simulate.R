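## Synthetic-cohort generator: complete multi-sample patients (segment
## tables, mutations, neoantigens, BAF tracks) with a ground-truth
## ledger, so every pipeline stage is testable without external data.

## vectorised forward simulation of n independent single-copy allele
## lineages under the branching process (the independent counterpart of
## the pgf computation in copyNumberPMF)
.simulateAlleleCounts <- function(n, params) {
    a <- params@alpha; g <- params@gamma
    N <- params@nPeriods; M <- params@wgdTime
    cnt <- rep(1L, n)
    pDup <- if (a < 1) g / (1 - a) else 0
    for (t in seq_len(max(N, 0L))) {
        if (!is.na(M) && t == M + 1L) cnt <- 2L * cnt
        pos <- which(cnt > 0L)
        if (length(pos)) {
            k <- cnt[pos]
            del <- stats::rbinom(length(k), k, a)
            dup <- stats::rbinom(length(k), k - del, pDup)
            cnt[pos] <- k - del + dup
        }
    }
    if (!is.na(M) && N == M) cnt <- 2L * cnt
    cnt
}

#' Forward-simulate an arm-level copy-number profile
#'
#' Realises the same branching process that [copyNumberPMF()] solves
#' exactly: for each arm and each of two alleles, a single starting copy
#' undergoes \code{nPeriods} periods of per-copy
#' delete / keep / duplicate draws, with all extant copies doubling
#' after period \code{wgdTime} when the parameters include a WGD event.
#'
#' @param params a [BranchingParams-class].
#' @param nArms number of arms (default 39); ignored when \code{armIds}
#'   is given.
#' @param armIds arm identifiers (default \code{arm01..}).
#' @param sampleId sample identifier for the profile.
#' @param seed optional integer seed for reproducibility.
#' @return An [ArmCNProfile-class].
#' @export
simulateArmProfile <- function(params, nArms = 39L, armIds = NULL,
                               sampleId = "sim", seed = NULL) {
    stopifnot(is(params, "BranchingParams"))
    if (!is.null(seed)) set.seed(seed)
    if (is.null(armIds))
        armIds <- sprintf("arm%02d", seq_len(nArms))
    n <- length(armIds)
    a1 <- .simulateAlleleCounts(n, params)
    a2 <- .simulateAlleleCounts(n, params)
    armCNProfile(sampleId, armIds, pmax(a1, a2), pmin(a1, a2))
}

#' Synthetic-cohort configuration
#'
#' Assembles and validates the generator settings. Defaults describe a
#' patient whose early lesions are near-diploid (few elapsed periods, no
#' WGD) and whose late lesions have evolved for the full
#' \code{nPeriods} with a WGD event, with arm-level rates matching the
#' regime the model-selection experiments operate in.
#'
#' @param seed master seed; each patient derives its own stream.
#' @param nPatients number of patients.
#' @param rate symmetric per-copy deletion/duplication rate
#'   \code{alpha = gamma}.
#' @param nPeriods periods \code{N} for late samples.
#' @param wgd do late samples carry a WGD event?
#' @param wgdTime doubling time \code{M}.
#' @param nEarly,nLate sample counts per patient.
#' @param earlyNPeriods elapsed periods for early samples.
#' @param lohTargetFraction target fraction of the genome planted as
#'   acquired LOH in late samples.
#' @param nMutations mutations per patient.
#' @param pNonsyn planted probability a mutation is non-synonymous.
#' @param lostFraction fraction of mutations lost in late disease.
#' @param lostInLOHFraction fraction of lost mutations planted inside
#'   acquired-LOH regions.
#' @param neoPerEvent integer vector (recycled over planted LOH events)
#'   of expressed neoantigens planted as lost per event.
#' @param bafSnpsPerArm heterozygous SNPs simulated per arm.
#' @param bafNoiseSd Gaussian BAF noise sd (truncated to [0, 1]).
#' @param mirroredArm arm id on which the first two late samples mirror
#'   their allelic imbalance, or \code{NULL}.
#' @param boundaryJitter segment boundaries are jittered inward by up to
#'   this many bp to exercise interval logic (0 = noise-free).
#' @return validated config list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(seed = 1L, nPatients = 1L, rate = 0.05,
                         nPeriods = 6L, wgd = TRUE, wgdTime = 3L,
                         nEarly = 2L, nLate = 3L, earlyNPeriods = 2L,
                         lohTargetFraction = 0.25, nMutations = 1000L,
                         pNonsyn = 0.75, lostFraction = 0.2,
                         lostInLOHFraction = 0.8,
                         neoPerEvent = c(2L, 5L, 1L),
                         bafSnpsPerArm = 30L, bafNoiseSd = 0.03,
                         mirroredArm = NULL, boundaryJitter = 1e6) {
    cfg <- list(seed = as.integer(seed), nPatients = as.integer(nPatients),
                rate = rate, nPeriods = as.integer(nPeriods),
                wgd = isTRUE(wgd), wgdTime = as.integer(wgdTime),
                nEarly = as.integer(nEarly), nLate = as.integer(nLate),
                earlyNPeriods = as.integer(earlyNPeriods),
                lohTargetFraction = lohTargetFraction,
                nMutations = as.integer(nMutations), pNonsyn = pNonsyn,
                lostFraction = lostFraction,
                lostInLOHFraction = lostInLOHFraction,
                neoPerEvent = as.integer(neoPerEvent),
                bafSnpsPerArm = as.integer(bafSnpsPerArm),
                bafNoiseSd = bafNoiseSd, mirroredArm = mirroredArm,
                boundaryJitter = boundaryJitter)
    probs <- c(rate = cfg$rate, lohTargetFraction = cfg$lohTargetFraction,
               pNonsyn = cfg$pNonsyn, lostFraction = cfg$lostFraction,
               lostInLOHFraction = cfg$lostInLOHFraction)
    bad <- probs < 0 | probs > 1
    if (any(bad)) .stopf("config value %s = %g outside [0, 1]",
                         names(probs)[bad][1L], probs[bad][1L])
    if (cfg$rate > 0.5) .stopf("rate must be <= 0.5")
    if (cfg$wgd && (cfg$wgdTime < 1L || cfg$wgdTime > cfg$nPeriods))
        .stopf("wgdTime out of range [1, nPeriods]")
    if (cfg$bafNoiseSd < 0 || cfg$boundaryJitter < 0)
        .stopf("noise settings must be non-negative")
    structure(cfg, class = "cohortConfig")
}

## segment table from an arm profile over arm coordinates, with inward
## boundary jitter (jitter 0 reproduces the arm intervals exactly)
.profileToSegments <- function(profile, armGr, jitter) {
    n <- length(armGr)
    js <- if (jitter > 0) floor(stats::runif(n, 0, jitter)) else rep(0, n)
    je <- if (jitter > 0) floor(stats::runif(n, 0, jitter)) else rep(0, n)
    s <- start(armGr) + js
    e <- end(armGr) - je
    maj <- profile@majorCN; mnr <- profile@minorCN
    gr <- GRanges(seqnames(armGr), IRanges(s, e),
                  majorCN = maj, minorCN = mnr, totalCN = maj + mnr)
    new("SegmentTable", sampleId = profile@sampleId, segments = gr)
}

## deterministic per-patient stream derived from the master seed; stable
## under adding patients (kept below 2^31)
.patientSeed <- function(masterSeed, idx)
    as.integer((as.numeric(masterSeed) * 7919 + idx * 104729) %% 2147483647)

#' Simulate one synthetic patient
#'
#' Generates a complete input bundle: early near-diploid and late
#' (optionally post-WGD) segment tables over the bundled hg19 arms,
#' planted acquired-LOH intervals (minor allele forced to zero on chosen
#' arms of every late sample), mutations with the planted
#' synonymous/non-synonymous split and presence flags, neoantigen
#' records with planted per-event losses, BAF tracks (mirrored on the
#' configured arm), and a ground-truth ledger of every planted quantity.
#'
#' @param config a [cohortConfig()] list.
#' @param patientIndex index of the patient within the cohort (drives
#'   the per-patient RNG stream).
#' @return list with \code{patientId}, \code{earlySamples},
#'   \code{lateSamples} (lists of [SegmentTable-class]), \code{mutations}
#'   (\code{GRanges}), \code{neoantigens} (\code{data.frame}), \code{baf}
#'   (list of \code{data.frame}s), and \code{groundTruth}.
#' @export
simulatePatient <- function(config, patientIndex = 1L) {
    stopifnot(inherits(config, "cohortConfig"))
    set.seed(.patientSeed(config$seed, patientIndex))
    ad <- hg19Arms()
    armGr <- arms(ad, includedOnly = TRUE)
    armIds <- mcols(armGr)$armId
    genomeLength <- sum(width(armGr))
    patientId <- sprintf("P%02d", patientIndex)
    earlyIds <- sprintf("%s_early%d", patientId, seq_len(config$nEarly))
    lateIds <- sprintf("%s_late%d", patientId, seq_len(config$nLate))

    earlyPar <- symmetricParams(config$rate,
                                nPeriods = config$earlyNPeriods)
    latePar <- symmetricParams(config$rate, nPeriods = config$nPeriods,
                               wgdTime = if (config$wgd) config$wgdTime
                                         else NA_integer_)
    earlyProf <- lapply(earlyIds, function(id)
        simulateArmProfile(earlyPar, armIds = armIds, sampleId = id))
    lateProf <- lapply(lateIds, function(id)
        simulateArmProfile(latePar, armIds = armIds, sampleId = id))

    ## choose LOH arms: heterozygous in every early sample, not LOH-prone
    eMinor <- do.call(cbind, lapply(earlyProf, function(p) p@minorCN))
    candidate <- which(apply(eMinor > 0L, 1L, all))
    candidate <- candidate[sample.int(length(candidate))]
    lohArms <- integer(0); planted <- 0
    for (i in candidate) {
        if (planted / genomeLength >= config$lohTargetFraction) break
        lohArms <- c(lohArms, i)
        planted <- planted + width(armGr)[i]
    }
    ## force LOH on the chosen arms of every late sample
    for (j in seq_along(lateProf)) {
        p <- lateProf[[j]]
        p@majorCN[lohArms] <- pmax(p@majorCN[lohArms], 1L)
        p@minorCN[lohArms] <- 0L
        lateProf[[j]] <- p
    }
    ## the mirrored arm must be imbalanced in the two mirrored samples
    mirrorIdx <- if (!is.null(config$mirroredArm))
        match(config$mirroredArm, armIds) else NA_integer_
    if (!is.na(mirrorIdx)) {
        for (j in seq_len(min(2L, length(lateProf)))) {
            p <- lateProf[[j]]
            if (!is.na(p@majorCN[mirrorIdx]) &&
                p@majorCN[mirrorIdx] == p@minorCN[mirrorIdx]) {
                p@majorCN[mirrorIdx] <- p@majorCN[mirrorIdx] + 1L
                lateProf[[j]] <- p
            }
        }
    }
    earlySeg <- lapply(earlyProf, .profileToSegments, armGr = armGr,
                       jitter = config$boundaryJitter)
    lateSeg <- lapply(lateProf, .profileToSegments, armGr = armGr,
                      jitter = config$boundaryJitter)

    ## planted acquired-LOH truth for the reference early sample vs each
    ## late sample: simple max-of-starts / min-of-ends interval arithmetic
    refSeg <- segments(earlySeg[[1L]])
    truthAcq <- lapply(seq_along(lateSeg), function(j) {
        ls <- segments(lateSeg[[j]])
        s <- pmax(start(refSeg)[lohArms], start(ls)[lohArms])
        e <- pmin(end(refSeg)[lohArms], end(ls)[lohArms])
        GRanges(seqnames(refSeg)[lohArms], IRanges(s, e))
    })
    names(truthAcq) <- lateIds
    ## intervals planted as lost-in-LOH carriers: intersection across the
    ## reference early sample and all late samples
    lossRegion <- if (length(lohArms)) {
        s <- start(refSeg)[lohArms]; e <- end(refSeg)[lohArms]
        for (j in seq_along(lateSeg)) {
            ls <- segments(lateSeg[[j]])
            s <- pmax(s, start(ls)[lohArms]); e <- pmin(e, end(ls)[lohArms])
        }
        GRanges(seqnames(refSeg)[lohArms], IRanges(s, e))
    } else GRanges()

    ## mutations -------------------------------------------------------
    nMut <- config$nMutations
    nLost <- round(config$lostFraction * nMut)
    nLostLoh <- if (length(lossRegion)) round(config$lostInLOHFraction *
                                              nLost) else 0L
    nLostOther <- nLost - nLostLoh
    outsideGr <- if (length(lohArms)) armGr[-lohArms] else armGr
    if (!length(outsideGr) && nMut > nLostLoh)
        .stopf("infeasible config: no genome left outside planted LOH")

    sampleWithin <- function(gr, n, events = FALSE) {
        if (n == 0L) return(GRanges())
        if (!events) {
            idx <- sample.int(length(gr), n, replace = TRUE,
                              prob = width(gr))
        } else {
            ## round-robin so every event interval receives mutations
            idx <- rep(seq_along(gr), length.out = n)
        }
        pos <- start(gr)[idx] +
            floor(stats::runif(n, 0, width(gr)[idx] - 1))
        GRanges(seqnames(gr)[idx], IRanges(pos, width = 1))
    }
    grLostLoh <- sampleWithin(lossRegion, nLostLoh, events = TRUE)
    grLostOther <- sampleWithin(outsideGr, nLostOther)
    grKept <- sampleWithin(outsideGr, nMut - nLost)
    mut <- c(grLostLoh, grLostOther, grKept)
    n <- length(mut)
    lostFlag <- c(rep(TRUE, nLostLoh + nLostOther),
                  rep(FALSE, n - nLost))
    inLohFlag <- c(rep(TRUE, nLostLoh), rep(FALSE, n - nLostLoh))
    cons <- ifelse(stats::runif(n) < config$pNonsyn,
                   "nonsynonymous", "synonymous")
    ## lost mutations in LOH were clonal early; other losses subclonal
    ccf <- ifelse(lostFlag & inLohFlag, stats::runif(n, 0.7, 1),
           ifelse(lostFlag, stats::runif(n, 0.1, 0.5),
                  stats::runif(n, 0.6, 1)))
    presAll <- c(earlyIds, lateIds)
    mcols(mut)$mutationId <- sprintf("%s_mut%05d", patientId, seq_len(n))
    mcols(mut)$gene <- sprintf("GENE%04d", sample.int(5000L, n,
                                                      replace = TRUE))
    mcols(mut)$consequence <- cons
    mcols(mut)$ccf <- round(ccf, 4)
    mcols(mut)$presentIn <- IRanges::CharacterList(
        lapply(lostFlag, function(l) if (l) earlyIds else presAll))

    ## neoantigens ------------------------------------------------------
    nEvents <- length(lohArms)
    neoPlan <- if (nEvents) rep(config$neoPerEvent,
                                length.out = nEvents) else integer(0)
    neoRows <- list(); truthPerEvent <- integer(nEvents)
    for (i in seq_len(nEvents)) {
        ## lost mutations planted inside this event's interval
        inEv <- which(lostFlag & overlapsAny(mut, lossRegion[i]))
        if (length(inEv) < neoPlan[i])
            .stopf(paste0("infeasible config: event %d holds %d lost ",
                          "mutations but %d planted neoantigen losses"),
                   i, length(inEv), neoPlan[i])
        pick <- inEv[seq_len(neoPlan[i])]
        mcols(mut)$consequence[pick] <- "nonsynonymous"
        truthPerEvent[i] <- neoPlan[i]
        if (length(pick))
            neoRows[[length(neoRows) + 1L]] <- data.frame(
                mutationId = mcols(mut)$mutationId[pick],
                hlaAllele = "HLA-A*02:01",
                bindingRank = round(stats::runif(length(pick), 0.05, 2), 3),
                expressed = TRUE, stringsAsFactors = FALSE)
    }
    ## background neoantigens on retained non-synonymous mutations (not
    ## lost, so they never count), half of them unexpressed
    keptNs <- which(!lostFlag & mcols(mut)$consequence == "nonsynonymous")
    nBg <- min(length(keptNs), 20L)
    if (nBg) {
        pick <- keptNs[seq_len(nBg)]
        neoRows[[length(neoRows) + 1L]] <- data.frame(
            mutationId = mcols(mut)$mutationId[pick],
            hlaAllele = "HLA-B*07:02",
            bindingRank = round(stats::runif(nBg, 0.05, 2), 3),
            expressed = rep(c(TRUE, FALSE), length.out = nBg),
            stringsAsFactors = FALSE)
    }
    neo <- if (length(neoRows)) do.call(rbind, neoRows)
           else data.frame(mutationId = character(0),
                           hlaAllele = character(0),
                           bindingRank = numeric(0),
                           expressed = logical(0))

    ## BAF tracks -------------------------------------------------------
    ## SNP phase (which parental haplotype carries the B allele) is a
    ## germline property shared by all samples of the patient; samples
    ## favouring the same haplotype show the same BAF pattern, a sample
    ## favouring the other haplotype shows the reflected pattern
    allProf <- c(earlyProf, lateProf)
    snpPhase <- lapply(seq_along(armIds), function(ai)
        stats::rbinom(config$bafSnpsPerArm, 1L, 0.5))
    baf <- lapply(seq_along(allProf), function(si) {
        p <- allProf[[si]]
        rows <- lapply(seq_along(armIds), function(ai) {
            k <- config$bafSnpsPerArm
            if (k == 0L) return(NULL)
            pos <- round(seq(start(armGr)[ai] + 1e5, end(armGr)[ai] - 1e5,
                             length.out = k))
            maj <- p@majorCN[ai]; mnr <- p@minorCN[ai]
            mu <- if (is.na(maj) || is.na(mnr) || maj + mnr == 0L) 0.5
                  else maj / (maj + mnr)
            ## the second mirrored late sample favours the other haplotype
            flip <- !is.na(mirrorIdx) && ai == mirrorIdx &&
                si == length(earlyProf) + 2L
            hapB <- if (flip) 1L - snpPhase[[ai]] else snpPhase[[ai]]
            mean <- ifelse(hapB == 1L, mu, 1 - mu)
            b <- mean + stats::rnorm(k, 0, config$bafNoiseSd)
            data.frame(chromosome = as.character(seqnames(armGr))[ai],
                       position = pos, baf = pmin(pmax(b, 0), 1),
                       stringsAsFactors = FALSE)
        })
        df <- do.call(rbind, rows)
        cbind(sampleId = p@sampleId, df, stringsAsFactors = FALSE)
    })
    names(baf) <- vapply(allProf, function(p) p@sampleId, "")

    groundTruth <- list(
        patientId = patientId, seed = .patientSeed(config$seed,
                                                   patientIndex),
        lohArmIds = armIds[lohArms],
        lohFraction = planted / genomeLength,
        acquiredLOH = truthAcq,
        acquiredLOHFraction = vapply(truthAcq, function(g)
            sum(width(g)) / genomeLength, 0),
        nLost = nLost, nLostInLOH = nLostLoh,
        lostInLOHFraction = if (nLost) nLostLoh / nLost else NA_real_,
        lostMutationIds = mcols(mut)$mutationId[lostFlag],
        perEventNeoLosses = truthPerEvent,
        patientNeoLossTotal = sum(truthPerEvent),
        wgd = config$wgd, rate = config$rate,
        wgdTime = if (config$wgd) config$wgdTime else NA_integer_)

    list(patientId = patientId, earlySamples = earlySeg,
         lateSamples = lateSeg, mutations = mut, neoantigens = neo,
         baf = baf, groundTruth = groundTruth, config = config)
}

#' Simulate a synthetic cohort
#'
#' @param config a [cohortConfig()].
#' @return list of patient bundles from [simulatePatient()].
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "cohortConfig"))
    lapply(seq_len(config$nPatients), function(i)
        simulatePatient(config, i))
}

#' Write a patient bundle to disk
#'
#' Serialises every table of a [simulatePatient()] bundle as the TSV
#' dialects the package readers consume, plus a
#' \code{ground_truth.json} ledger (with the seed) of all planted
#' quantities.
#'
#' @param bundle a patient bundle.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writePatientBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (st in c(bundle$earlySamples, bundle$lateSamples)) {
        f <- file.path(dir, paste0("segments_", sampleId(st), ".tsv"))
        writeSegmentTable(st, f); paths <- c(paths, f)
    }
    f <- file.path(dir, "mutations.tsv")
    writeMutationTable(bundle$mutations, f); paths <- c(paths, f)
    f <- file.path(dir, "neoantigens.tsv")
    writeNeoantigenTable(bundle$neoantigens, f); paths <- c(paths, f)
    for (nm in names(bundle$baf)) {
        f <- file.path(dir, paste0("baf_", nm, ".tsv"))
        writeBafTable(bundle$baf[[nm]], f); paths <- c(paths, f)
    }
    gt <- bundle$groundTruth
    gt$acquiredLOH <- lapply(gt$acquiredLOH, function(g)
        data.frame(chromosome = as.character(seqnames(g)),
                   start = start(g), end = end(g)))
    f <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, f, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, f)
    invisible(paths)
}
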