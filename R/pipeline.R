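## Single entry point wiring simulate -> WGD fitting -> AI/LOH -> sculpting,
## with pre-flight input checks and a run manifest.

.md5OrNA <- function(paths) {
    if (!length(paths)) return(character(0))
    unname(tools::md5sum(paths))
}

## hash of the canonical JSON serialisation of the config
.configHash <- function(config) {
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f))
    jsonlite::write_json(config[order(names(config))], f,
                         auto_unbox = TRUE, digits = NA, null = "null")
    unname(tools::md5sum(f))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in dependency order: (1) cohort simulation, writing each
#' patient's input bundle; (2) WGD inference on every sample
#' (arm summarisation, both model fits, AIC selection); (3) allelic
#' imbalance / LOH analysis per patient (genome state summaries,
#' acquired LOH of each late sample against the first early sample,
#' event merging, lost-mutation attribution), writing acquired-LOH
#' intervals as a BED-like TSV (0-based half-open); (4) sculpting
#' statistics (codon mutability, per-segment excess, binomial excess
#' test on segments > 10 Mb, neoantigen losses per event, and the 2x2
#' exclusivity classification with Barnard's test when at least four
#' events exist). A failing stage aborts with the stage named; the run
#' manifest (tool version, config hash, file digests, seed, per-stage
#' status and outputs) is written last.
#'
#' @param config a [cohortConfig()], or the path of a YAML/JSON file of
#'   its fields.
#' @param outDir output directory.
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) {
        if (!file.exists(config))
            .stopf("pre-flight: config file '%s' does not exist", config)
        raw <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
               else jsonlite::read_json(config, simplifyVector = TRUE)
        config <- do.call(cohortConfig, raw)
    }
    stopifnot(inherits(config, "cohortConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(tool = "WGDinfer",
                     version = as.character(utils::packageVersion("WGDinfer")),
                     configHash = .configHash(unclass(config)),
                     seed = config$seed, stages = list())
    addStage <- function(name, status, outputs) {
        manifest$stages[[name]] <<- list(
            status = status, outputs = outputs,
            digests = .md5OrNA(outputs))
    }
    runStage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e) {
            addStage(name, "failed", character(0))
            .stopf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e))
        })
        addStage(name, "ok", res$outputs)
        res$value
    }

    ## stage 1: simulate ------------------------------------------------
    cohort <- runStage("simulate", function() {
        bundles <- simulateCohort(config)
        outs <- unlist(lapply(bundles, function(b)
            writePatientBundle(b, file.path(outDir, b$patientId))))
        list(value = bundles, outputs = outs)
    })

    ## stage 2: fit-wgd -------------------------------------------------
    armDefs <- hg19Arms()
    runStage("fit_wgd", function() {
        rows <- list()
        for (b in cohort) {
            for (st in c(b$earlySamples, b$lateSamples)) {
                prof <- summarizeArms(st, armDefs)
                fW <- fitBranchingModel(prof, withWGD = TRUE,
                                        nPeriods = config$nPeriods)
                fN <- fitBranchingModel(prof, withWGD = FALSE,
                                        nPeriods = config$nPeriods)
                sel <- selectModel(fW, fN)
                rows[[length(rows) + 1L]] <- list(
                    patient = b$patientId, sample = sampleId(st),
                    rateHat = fitParams(sel)@alpha,
                    wgdTimeHat = fitParams(fW)@wgdTime,
                    logLikWGD = fitLogLik(fW),
                    logLikNonWGD = fitLogLik(fN),
                    aicWGD = generalAIC(fW), aicNonWGD = generalAIC(fN),
                    deltaAIC = deltaAIC(sel),
                    selected = selectedModel(sel))
            }
        }
        f <- file.path(outDir, "fit_wgd.json")
        jsonlite::write_json(rows, f, auto_unbox = TRUE, digits = NA)
        list(value = rows, outputs = f)
    })

    ## stage 3: ai-loh --------------------------------------------------
    lohResults <- runStage("ai_loh", function() {
        outs <- character(0); res <- list()
        for (b in cohort) {
            early <- b$earlySamples[[1L]]
            acq <- lapply(b$lateSamples, function(lt)
                acquiredLOH(early, lt))
            events <- mergeLOHEvents(acq)
            summaries <- lapply(c(b$earlySamples, b$lateSamples),
                                genomeStateSummary)
            lost <- lapply(seq_along(b$lateSamples), function(j)
                lostMutationLOHFraction(
                    b$mutations, sampleId(early),
                    sampleId(b$lateSamples[[j]]), acq[[j]]))
            ## BED-like: 0-based half-open
            bed <- do.call(rbind, lapply(acq, function(g)
                if (length(g)) data.frame(
                    chrom = as.character(seqnames(g)),
                    start = start(g) - 1L, end = end(g),
                    earlySample = mcols(g)$earlySample,
                    lateSample = mcols(g)$lateSample,
                    earlyState = mcols(g)$earlyState) else NULL))
            f <- file.path(outDir, b$patientId, "acquired_loh.tsv")
            utils::write.table(bed, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outs <- c(outs, f)
            res[[b$patientId]] <- list(acquired = acq, events = events,
                                       summaries = summaries,
                                       lost = lost)
        }
        f <- file.path(outDir, "ai_loh.json")
        jsonlite::write_json(lapply(res, function(r) list(
            nEvents = length(r$events),
            stateFractions = lapply(r$summaries, function(s)
                as.list(stateFractions(s))),
            lostFractions = lapply(r$lost, function(l) l$fraction))),
            f, auto_unbox = TRUE, digits = NA)
        list(value = res, outputs = c(outs, f))
    })

    ## stage 4: sculpt --------------------------------------------------
    runStage("sculpt", function() {
        prof <- codonMutability(humanCodonUsage())
        res <- list()
        for (b in cohort) {
            r <- lohResults[[b$patientId]]
            acqAll <- unlist(GRangesList(r$acquired))
            lostIds <- b$groundTruth$lostMutationIds
            lostMut <- b$mutations[
                mcols(b$mutations)$mutationId %in% lostIds]
            big <- filterLargeSegments(acqAll)
            binom <- if (length(big)) {
                se <- segmentExcess(big, lostMut, prof)
                binomialExcessTest(se, "per_segment", prof)
            } else NULL
            neoLoss <- neoantigenLosses(r$events, b$neoantigens,
                                        b$mutations)
            twoByTwo <- NULL; barnard <- NULL
            if (length(r$events) >= 4L) {
                evNs <- segmentExcess(r$events, lostMut, prof)$nNonsyn
                twoByTwo <- classifyEvents2x2(neoLoss$perEvent, evNs)
                barnard <- barnardTest(twoByTwo$a, twoByTwo$b,
                                       twoByTwo$c, twoByTwo$d)
            }
            res[[b$patientId]] <- list(
                pNonsyn = prof$pNonsyn, binomial = binom,
                perEventNeoLosses = neoLoss$perEvent,
                patientNeoLossTotal = neoLoss$patientTotal,
                twoByTwo = if (is.null(twoByTwo)) NULL
                           else twoByTwo[c("a", "b", "c", "d")],
                barnardP = if (is.null(barnard)) NULL else barnard$pValue)
        }
        f <- file.path(outDir, "sculpt.json")
        jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
        list(value = res, outputs = f)
    })

    f <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
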