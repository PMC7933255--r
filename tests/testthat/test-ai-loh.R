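# Allelic-state classification, genome summaries, acquired LOH,
# event merging and mirrored allelic imbalance.

test_that("allelic states follow the (major, minor) rules", {
    expect_identical(
        as.character(classifyAllelicState(c(1L, 2L, 2L, 2L, 0L, NA),
                                          c(1L, 2L, 0L, 1L, 0L, NA))),
        c("balanced", "balanced", "ai_loh", "ai_no_loh", "ai_loh",
          "undetermined"))
    expect_error(classifyAllelicState(1L, 2L), "minorCN > majorCN")
})

test_that("genome summaries weight states by length and report mean
           ploidy over determined segments", {
    # whole genome balanced diploid
    st <- makeSegTable("s", "1", 1, 1000, 1, 1)
    gs <- genomeStateSummary(st, genomeLength = 1000)
    expect_equal(unname(stateFractions(gs)["balanced"]), 1)
    expect_equal(meanPloidy(gs), 2)
    # half LOH (single remaining copy), half balanced
    st2 <- makeSegTable("s", c("1", "1"), c(1, 501), c(500, 1000),
                        c(1, 1), c(0, 1))
    gs2 <- genomeStateSummary(st2, genomeLength = 1000)
    expect_equal(unname(stateFractions(gs2)["ai_loh"]), 0.5)
    expect_equal(unname(stateFractions(gs2)["balanced"]), 0.5)
    expect_equal(meanPloidy(gs2), 1.5)
    # doubled genome
    st3 <- makeSegTable("s", "1", 1, 1000, 2, 2)
    gs3 <- genomeStateSummary(st3, genomeLength = 1000)
    expect_equal(meanPloidy(gs3), 4)
    # uncovered genome counts as undetermined
    gs4 <- genomeStateSummary(st, genomeLength = 4000)
    expect_equal(unname(stateFractions(gs4)["undetermined"]), 0.75)
    expect_equal(meanPloidy(gs4), 2)  # over determined segments only
    # all-undetermined table: ploidy undefined
    stNA <- makeSegTable("s", "1", 1, 1000, NA, NA)
    expect_error(genomeStateSummary(stNA, genomeLength = 1000),
                 "undefined")
})

test_that("state fractions always sum to one", {
    set.seed(5)
    for (rep in 1:20) {
        n <- sample(1:8, 1)
        start <- cumsum(sample(600:1600, n))
        end <- start + sample(50:500, n)
        maj <- sample(c(NA, 0:3), n, replace = TRUE)
        mnr <- ifelse(is.na(maj), NA, pmin(maj, sample(0:2, n, TRUE)))
        st <- makeSegTable("s", "1", start, end, maj, mnr)
        gs <- tryCatch(genomeStateSummary(st, genomeLength = sum(
            GenomicRanges::width(segments(st))) + 1000),
            error = function(e) NULL)  # all-undetermined draws
        if (!is.null(gs))
            expect_lt(abs(sum(stateFractions(gs)) - 1), 1e-9)
    }
})

test_that("acquired LOH is the late LOH intersected with early
           demonstrated heterozygosity", {
    # early all balanced, late chr9 fully LOH
    early <- makeSegTable("e", "9", 1, 1e6, 1, 1)
    late <- makeSegTable("l", "9", 1, 1e6, 1, 0)
    acq <- acquiredLOH(early, late)
    expect_length(acq, 1L)
    expect_identical(GenomicRanges::start(acq), 1L)
    expect_identical(GenomicRanges::end(acq), 1000000L)
    expect_identical(S4Vectors::mcols(acq)$earlyState, "balanced")
    # pre-existing LOH is not acquired
    early2 <- makeSegTable("e", "9", 1, 1e6, 1, 0)
    late2 <- makeSegTable("l", "9", 1, 1e6, 2, 0)
    expect_length(acquiredLOH(early2, late2), 0L)
    # early-undetermined half is excluded
    early3 <- makeSegTable("e", c("9", "9"), c(1, 500001),
                           c(500000, 1e6), c(1, NA), c(1, NA))
    acq3 <- acquiredLOH(early3, late)
    expect_length(acq3, 1L)
    expect_identical(GenomicRanges::end(acq3), 500000L)
})

test_that("acquired intervals are contained in the late LOH regions", {
    set.seed(9)
    for (rep in 1:10) {
        n <- 6
        start <- seq(1, by = 2000, length.out = n)
        end <- start + 1500
        mkcn <- function() {
            maj <- sample(0:3, n, TRUE)
            mnr <- pmin(maj, sample(0:2, n, TRUE))
            list(maj = maj, mnr = mnr)
        }
        e <- mkcn(); l <- mkcn()
        early <- makeSegTable("e", "1", start, end, e$maj, e$mnr)
        late <- makeSegTable("l", "1", start, end, l$maj, l$mnr)
        acq <- acquiredLOH(early, late)
        lg <- segments(late)
        lateLoh <- lg[!is.na(S4Vectors::mcols(lg)$minorCN) &
                      S4Vectors::mcols(lg)$minorCN == 0L]
        if (length(acq))
            expect_true(all(IRanges::overlapsAny(acq, lateLoh,
                                                 type = "within")))
    }
})

test_that("LOH events merge overlapping segments by single linkage", {
    g <- function(s, e, sample) GenomicRanges::GRanges(
        "9", IRanges::IRanges(s, e), lateSample = sample)
    # two samples over the same region: one event, both members
    ev <- mergeLOHEvents(list(g(1, 1e7, "l1"), g(1, 1e7, "l2")))
    expect_length(ev, 1L)
    expect_identical(S4Vectors::mcols(ev)$memberSamples[[1]],
                     c("l1", "l2"))
    expect_identical(S4Vectors::mcols(ev)$nSegments, 2L)
    # disjoint intervals stay separate (abutting, zero overlap)
    ev2 <- mergeLOHEvents(list(g(1, 5e6, "l1"), g(5000001, 1e7, "l2")))
    expect_length(ev2, 2L)
    # single-linkage closure: A-B overlap, B-C overlap, A-C disjoint
    ev3 <- mergeLOHEvents(list(g(1, 100, "l1"), g(90, 200, "l2"),
                               g(190, 300, "l3")))
    expect_length(ev3, 1L)
    expect_identical(S4Vectors::mcols(ev3)$memberSamples[[1]],
                     c("l1", "l2", "l3"))
    # events are disjoint and cover exactly the union of the input
    inp <- list(g(1, 100, "l1"), g(50, 120, "l2"), g(500, 600, "l1"))
    ev4 <- mergeLOHEvents(inp)
    expect_true(GenomicRanges::isDisjoint(ev4))
    un <- GenomicRanges::reduce(do.call(c, inp), min.gapwidth = 0L)
    expect_identical(as.data.frame(GenomicRanges::granges(ev4)),
                     as.data.frame(un))
})

test_that("lost-mutation LOH fractions count positions inside acquired
           intervals", {
    pos <- seq(100, by = 100, length.out = 10)
    pres <- rep(list("e1"), 10)          # all lost (absent late)
    mut <- makeMutations("9", pos, sprintf("m%d", 1:10),
                         rep("nonsynonymous", 10), pres, ccf = 0.5)
    acq <- GenomicRanges::GRanges("9", IRanges::IRanges(1, 750))
    res <- lostMutationLOHFraction(mut, "e1", "l1", acq)
    expect_equal(res$fraction, 0.7)
    expect_identical(res$nLost, 10L)
    expect_identical(res$nInLOH, 7L)
    # no acquired LOH at all
    res0 <- lostMutationLOHFraction(mut, "e1", "l1", GenomicRanges::GRanges())
    expect_equal(res0$fraction, 0)
    # nothing lost: undefined, flagged
    mutAll <- makeMutations("9", pos, sprintf("m%d", 1:10),
                            rep("synonymous", 10),
                            rep(list(c("e1", "l1")), 10))
    expect_warning(resNA <- lostMutationLOHFraction(mutAll, "e1", "l1",
                                                    acq),
                   "undefined")
    expect_true(is.na(resNA$fraction))
})

test_that("mirrored allelic imbalance is called from reflected BAFs and
           gated on imbalance", {
    mkBaf <- function(baf, sample) data.frame(
        sampleId = sample, chromosome = "10",
        position = seq_along(baf) * 1000, baf = baf,
        stringsAsFactors = FALSE)
    set.seed(3)
    dev <- runif(40, 0.25, 0.35) * sample(c(-1, 1), 40, TRUE)
    a <- 0.5 + dev
    # perfect mirror
    res <- detectMirroredAI(mkBaf(a, "A"), mkBaf(1 - a, "B"))
    expect_gt(res$mirrorScore, 0.99)
    expect_true(res$isMirrored)
    # same allele lost in both
    res2 <- detectMirroredAI(mkBaf(a, "A"), mkBaf(a, "B"))
    expect_lt(res2$mirrorScore, -0.99)
    expect_false(res2$isMirrored)
    # balanced noise never mirrors, whatever the score
    noise <- 0.5 + rnorm(40, 0, 0.02)
    res3 <- detectMirroredAI(mkBaf(noise, "A"), mkBaf(1 - noise, "B"))
    expect_false(res3$isMirrored)
    # antisymmetry: flipping one sample negates the score
    res4 <- detectMirroredAI(mkBaf(a, "A"), mkBaf(a, "B"))
    res5 <- detectMirroredAI(mkBaf(a, "A"), mkBaf(1 - a, "B"))
    expect_equal(res4$mirrorScore, -res5$mirrorScore)
    # insufficient shared SNPs
    expect_error(detectMirroredAI(mkBaf(a[1:5], "A"), mkBaf(a[1:5], "B")),
                 "shared")
    # region restriction by chromosome label
    resR <- detectMirroredAI(mkBaf(a, "A"), mkBaf(1 - a, "B"),
                             region = "chr10")
    expect_identical(resR$nSnps, 40L)
    expect_error(detectMirroredAI(mkBaf(a, "A"), mkBaf(1 - a, "B"),
                                  region = "chr7"), "shared")
})
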