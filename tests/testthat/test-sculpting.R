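# Codon mutability, non-synonymous excess statistics, neoantigen-loss
# accounting, 2x2 classification and Barnard's unconditional test.

test_that("codon mutability matches per-codon enumeration", {
    # Trp: every single-nucleotide change is non-synonymous or stop-gain
    expect_equal(codonMutability(c(TGG = 1))$pNonsyn, 1)
    # Ala (GCT): the three third-position changes are synonymous
    expect_equal(codonMutability(c(GCT = 1))$pNonsyn, 6 / 9)
    # complement identity
    p <- codonMutability(humanCodonUsage())
    expect_equal(p$pNonsyn + p$pSyn, 1)
    expect_error(codonMutability(numeric(0)), "empty")
})

test_that("uniform-usage mutability equals the unweighted fraction over
           all 549 sense-codon changes", {
    # independent enumeration against the genetic code table
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    bases <- c("A", "C", "G", "T")
    tot <- 0L; ns <- 0L
    for (cd in sense) for (p in 1:3) for (b in bases) {
        if (b == substr(cd, p, p)) next
        mut <- cd; substr(mut, p, p) <- b
        tot <- tot + 1L
        if (gc[[mut]] != gc[[cd]]) ns <- ns + 1L
    }
    expect_identical(tot, 549L)
    uni <- rep(1, 61); names(uni) <- sense
    expect_equal(codonMutability(uni)$pNonsyn, ns / tot)
})

test_that("segment excess compares observed with expected
           non-synonymous counts", {
    prof <- list(pNonsyn = 0.75, pSyn = 0.25, ratio = 3)
    segs <- GenomicRanges::GRanges("1", IRanges::IRanges(
        c(1, 1000, 2000), c(500, 1500, 2500)))
    # segment 1: 4 syn + 10 nonsyn -> expected 12, no excess
    # segment 2: 2 syn + 9 nonsyn  -> expected 6, excess
    # segment 3: empty             -> expected 0, no excess
    mut <- makeMutations(
        "1",
        c(seq(10, 100, length.out = 4), seq(110, 400, length.out = 10),
          seq(1010, 1040, length.out = 2), seq(1050, 1400, length.out = 9)),
        sprintf("m%02d", 1:25),
        c(rep("synonymous", 4), rep("nonsynonymous", 10),
          rep("synonymous", 2), rep("nonsynonymous", 9)),
        rep(list("e1"), 25))
    se <- segmentExcess(segs, mut, prof)
    expect_equal(se$nSyn, c(4, 2, 0))
    expect_equal(se$nNonsyn, c(10, 9, 0))
    expect_equal(se$expectedNonsyn, c(12, 6, 0))
    expect_identical(se$exceeds, c(FALSE, TRUE, FALSE))
})

test_that("the large-segment filter is strict at 10 Mb", {
    segs <- GenomicRanges::GRanges("1", IRanges::IRanges(
        c(1, 1), c(10000001, 10000000)))  # widths 10000001 and 10000000
    kept <- filterLargeSegments(segs)
    expect_length(kept, 1L)
    expect_identical(GenomicRanges::width(kept), 10000001L)
})

test_that("binomial excess p-values match closed-form binomial tails", {
    prof <- codonMutability(humanCodonUsage())
    # every segment exceeds under the half null: p = 0.5^n
    df <- data.frame(nSyn = rep(1, 8), nNonsyn = rep(20, 8),
                     expectedNonsyn = rep(1 * prof$ratio, 8),
                     exceeds = rep(TRUE, 8))
    res <- binomialExcessTest(df, "half")
    expect_equal(res$pValue, 0.5^8)
    expect_identical(res$k, 8L)
    # k = 0: upper tail is 1
    df0 <- transform(df, nNonsyn = 0, exceeds = FALSE)
    expect_equal(binomialExcessTest(df0, "half")$pValue, 1)
    # per-segment null equals the closed-form tail at the same k
    set.seed(21)
    sz <- 5L + rpois(50, 12)
    nN <- rbinom(50, sz, prof$pNonsyn); nS <- sz - nN
    df2 <- data.frame(nSyn = nS, nNonsyn = nN,
                      expectedNonsyn = nS * prof$ratio,
                      exceeds = nN > nS * prof$ratio)
    res2 <- binomialExcessTest(df2, "per_segment", prof)
    nullP <- mean(pbinom(floor(sz * prof$pNonsyn), sz, prof$pNonsyn,
                         lower.tail = FALSE))
    expect_equal(res2$nullP, nullP)
    expect_equal(res2$pValue,
                 sum(dbinom(res2$k:50, 50, nullP)), tolerance = 1e-12)
    expect_error(binomialExcessTest(df2[0, ], "half"), "at least one")
})

test_that("neoantigen losses count event-resident mutations absent from
           all member samples", {
    ev <- GenomicRanges::GRanges("9", IRanges::IRanges(1, 1e6))
    S4Vectors::mcols(ev)$memberSamples <- IRanges::CharacterList(
        list(c("l1", "l2")))
    mut <- makeMutations("9", c(100, 200, 300, 400, 2e6),
                         sprintf("m%d", 1:5),
                         rep("nonsynonymous", 5),
                         list("e1", "e1", "e1", c("e1", "l1"), "e1"))
    neo <- data.frame(mutationId = sprintf("m%d", 1:5),
                      hlaAllele = "HLA-A*02:01", bindingRank = 0.4,
                      expressed = c(TRUE, TRUE, FALSE, TRUE, TRUE))
    res <- neoantigenLosses(ev, neo, mut, expressedOnly = TRUE)
    # m1, m2 lost inside the event; m3 unexpressed; m4 still present in
    # l1; m5 outside the event
    expect_identical(res$perEvent, 2L)
    expect_identical(res$patientTotal, 2L)
    expect_setequal(res$lostIds[[1]], c("m1", "m2"))
    resAll <- neoantigenLosses(ev, neo, mut, expressedOnly = FALSE)
    expect_identical(resAll$perEvent, 3L)
    # dangling mutation id
    neoBad <- rbind(neo, data.frame(mutationId = "mX", hlaAllele = "H",
                                    bindingRank = 1, expressed = TRUE))
    expect_error(neoantigenLosses(ev, neoBad, mut), "mX")
})

test_that("2x2 classification median-splits with ties to low", {
    res <- classifyEvents2x2(c(10, 9, 1, 2), c(1, 2, 9, 10))
    expect_identical(c(res$a, res$b, res$c, res$d), c(2L, 0L, 0L, 2L))
    # all identical: everything is low/low
    res2 <- classifyEvents2x2(rep(3, 5), rep(7, 5))
    expect_identical(c(res2$a, res2$b, res2$d), c(0L, 0L, 0L))
    expect_identical(res2$c, 5L)
    expect_error(classifyEvents2x2(1:3, 1:3), "at least 4")
})

test_that("Barnard's test matches brute-force enumeration and is
           symmetric", {
    # perfectly homogeneous table
    expect_equal(barnardTest(5, 5, 5, 5)$pValue, 1)
    # strong exclusivity: small p, equal to the enumeration oracle
    res <- barnardTest(10, 0, 0, 10)
    expect_lt(res$pValue, 0.01)
    expect_equal(res$pValue, oracleBarnard(10, 0, 0, 10),
                 tolerance = 1e-12)
    # oracle equality on assorted small tables
    for (tb in list(c(3, 1, 1, 4), c(0, 4, 3, 1), c(2, 2, 5, 0),
                    c(6, 2, 1, 5))) {
        expect_equal(barnardTest(tb[1], tb[2], tb[3], tb[4])$pValue,
                     oracleBarnard(tb[1], tb[2], tb[3], tb[4]),
                     tolerance = 1e-12)
    }
    # swapping the two columns flips the statistic's sign, not the p
    res1 <- barnardTest(7, 1, 2, 6)
    res2 <- barnardTest(1, 7, 6, 2)
    expect_equal(res1$pValue, res2$pValue, tolerance = 1e-12)
    expect_equal(res1$statistic, -res2$statistic)
    # matrix interface
    expect_equal(barnardTest(matrix(c(7, 2, 1, 6), 2, 2))$pValue,
                 res1$pValue)
    expect_error(barnardTest(0, 0, 0, 0), "empty")
})

test_that("Barnard's test is exact: its size never exceeds the nominal
           level over the nuisance grid", {
    m1 <- 5L; m2 <- 5L
    piGrid <- seq(0.01, 0.99, by = 0.01)
    pAll <- outer(0:m1, 0:m2, Vectorize(function(x1, x2)
        barnardTest(x1, x2, m1 - x1, m2 - x2, piGrid = piGrid)$pValue))
    for (alpha in c(0.05, 0.1)) {
        reject <- pAll <= alpha
        size <- vapply(piGrid, function(p)
            sum(outer(dbinom(0:m1, m1, p), dbinom(0:m2, m2, p))[reject]),
            0)
        expect_lte(max(size), alpha + 1e-9)
    }
})

test_that("Barnard's test dominates Fisher's in aggregate on small
           tables", {
    set.seed(13)
    pB <- pF <- numeric(12)
    for (rep in 1:12) {
        m1 <- sample(3:8, 1); m2 <- sample(3:8, 1)
        a <- sample(0:m1, 1); b <- sample(0:m2, 1)
        tb <- matrix(c(a, m1 - a, b, m2 - b), 2, 2)
        pB[rep] <- barnardTest(tb)$pValue
        pF[rep] <- fisher.test(tb)$p.value
    }
    expect_lt(mean(pB), mean(pF))
    # strictly smaller on a strong-exclusivity table
    expect_lt(barnardTest(8, 0, 0, 8)$pValue,
              fisher.test(matrix(c(8, 0, 0, 8), 2, 2))$p.value)
})
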