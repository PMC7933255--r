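# Arm-level likelihood, model fitting and AIC selection.

test_that("log-likelihood of perfectly explained profiles is zero", {
    prof <- armCNProfile("s", c("1p", "1q"), c(1L, 1L), c(1L, 1L))
    expect_equal(armLogLikelihood(prof, branchingParams(0, 1, 0,
                                                        nPeriods = 6)), 0)
    prof2 <- armCNProfile("s", "1p", 2L, 2L)
    expect_equal(armLogLikelihood(prof2,
        branchingParams(0, 1, 0, nPeriods = 6, wgdTime = 1L)), 0)
})

test_that("log-likelihood matches the enumerated pmf and handles
           zero-probability and unrepresentable states", {
    # one arm (2,1) under N = 2, r = 0.1: log P(2) + log P(1)
    prof <- armCNProfile("s", "8q", 2L, 1L)
    p <- oraclePMF(0.1, 0.8, 0.1, 2)
    expect_equal(armLogLikelihood(prof, symmetricParams(0.1, nPeriods = 2)),
                 log(p[3]) + log(p[2]))
    # beta = 1 cannot produce two copies without WGD
    expect_identical(armLogLikelihood(prof, branchingParams(0, 1, 0,
                                                            nPeriods = 2)),
                     -Inf)
    # copy number above the support names the arm
    prof3 <- armCNProfile("s", "8q", 3L, 1L)
    expect_error(armLogLikelihood(prof3, symmetricParams(0.1,
                                                         nPeriods = 1)),
                 "unrepresentable.*8q")
    # undetermined arms are skipped
    prof4 <- armCNProfile("s", c("1p", "1q"), c(1L, NA), c(1L, NA))
    expect_equal(armLogLikelihood(prof4, branchingParams(0, 1, 0,
                                                         nPeriods = 6)), 0)
})

test_that("total-CN observation unit scores the two-allele convolution", {
    prof <- armCNProfile("s", "8q", 2L, 1L)
    p <- oraclePMF(0.1, 0.8, 0.1, 2)
    tot <- convolve(p, rev(p), type = "open")  # P(total = 3)
    expect_equal(armLogLikelihood(prof, symmetricParams(0.1, nPeriods = 2),
                                  obsUnit = "total"),
                 log(tot[4]), tolerance = 1e-9)
})

test_that("event-free profiles fit with zero rate and zero log-likelihood", {
    prof <- armCNProfile("s", sprintf("a%02d", 1:10), rep(1L, 10),
                         rep(1L, 10))
    fit <- fitBranchingModel(prof, withWGD = FALSE)
    expect_equal(fitParams(fit)@alpha, 0)
    expect_equal(fitLogLik(fit), 0)
    expect_identical(fit@k, 1L)
    # pure doubling under the WGD model
    prof2 <- armCNProfile("s", sprintf("a%02d", 1:10), rep(2L, 10),
                          rep(2L, 10))
    fit2 <- fitBranchingModel(prof2, withWGD = TRUE)
    expect_equal(fitParams(fit2)@alpha, 0)
    expect_equal(fitLogLik(fit2), 0)
    expect_identical(fit2@k, 2L)
    expect_false(is.na(fitParams(fit2)@wgdTime))
})

test_that("free-parameter counts follow the constrained and general
           counting, and the +2 offset cancels in deltaAIC", {
    prof <- armCNProfile("s", sprintf("a%02d", 1:8),
                         c(2L, 2L, 2L, 2L, 2L, 1L, 2L, 2L),
                         c(2L, 2L, 1L, 2L, 2L, 1L, 2L, 2L))
    fW <- fitBranchingModel(prof, withWGD = TRUE, constrained = TRUE)
    fN <- fitBranchingModel(prof, withWGD = FALSE, constrained = TRUE)
    expect_identical(fW@k, 2L)
    expect_identical(fN@k, 1L)
    uW <- fitBranchingModel(prof, withWGD = TRUE, constrained = FALSE)
    uN <- fitBranchingModel(prof, withWGD = FALSE, constrained = FALSE)
    expect_identical(uW@k, 3L)
    expect_identical(uN@k, 2L)
    # general counting offsets both constrained AICs by exactly +2
    expect_equal(generalAIC(fW) - modelAIC(fW), 2)
    expect_equal(generalAIC(fN) - modelAIC(fN), 2)
    expect_equal(generalAIC(fN) - generalAIC(fW),
                 modelAIC(fN) - modelAIC(fW))
    # AIC identity holds exactly as computed
    for (f in list(fW, fN, uW, uN))
        expect_identical(modelAIC(f) - 2 * f@k + 2 * fitLogLik(f), 0)
})

test_that("equal log-likelihoods select the parsimonious non-WGD model
           with deltaAIC = -2", {
    par <- symmetricParams(0.1, nPeriods = 6)
    parW <- symmetricParams(0.1, nPeriods = 6, wgdTime = 3L)
    fN <- new("FitResult", model = "non_wgd", params = par,
              logLik = -5, k = 1L, aic = 2 * 1 - 2 * (-5), nObs = 10L,
              obsUnit = "allele", deltaAIC = NA_real_,
              selected = NA_character_)
    fW <- new("FitResult", model = "wgd", params = parW,
              logLik = -5, k = 2L, aic = 2 * 2 - 2 * (-5), nObs = 10L,
              obsUnit = "allele", deltaAIC = NA_real_,
              selected = NA_character_)
    sel <- selectModel(fW, fN)
    expect_equal(deltaAIC(sel), -2)
    expect_identical(selectedModel(sel), "non_wgd")
})

test_that("tetraploid-like profiles select WGD and near-diploid ones do
           not", {
    tetra <- armCNProfile("s", sprintf("a%02d", 1:20), rep(2L, 20),
                          rep(2L, 20))
    selT <- selectModel(fitBranchingModel(tetra, TRUE),
                        fitBranchingModel(tetra, FALSE))
    expect_identical(selectedModel(selT), "wgd")
    expect_gt(deltaAIC(selT), 0)
    dip <- armCNProfile("s", sprintf("a%02d", 1:20),
                        c(rep(1L, 19), 2L), rep(1L, 20))
    selD <- selectModel(fitBranchingModel(dip, TRUE),
                        fitBranchingModel(dip, FALSE))
    expect_identical(selectedModel(selD), "non_wgd")
    expect_lte(deltaAIC(selD), 0)
})

test_that("fits refuse profiles outside the model support and mismatched
           comparisons", {
    big <- armCNProfile("s", "1p", 200L, 0L)
    expect_error(fitBranchingModel(big, withWGD = FALSE, nPeriods = 6),
                 "increase nPeriods")
    prof <- armCNProfile("s", c("1p", "1q"), c(1L, 1L), c(1L, 1L))
    other <- armCNProfile("s", c("1p", "1q", "2p"), rep(1L, 3), rep(1L, 3))
    fW <- fitBranchingModel(prof, TRUE)
    fN <- fitBranchingModel(other, FALSE)
    expect_error(selectModel(fW, fN), "same profile")
    expect_error(selectModel(fN, fW), "WGD fit then the non-WGD fit")
})
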