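test_that("streak histogram counts maximal runs, pooling turn directions", {
    h <- streakHistogram(c("F", "F", "L", "L", "L", "F"))
    expect_equal(h$forward, c(`1` = 1L, `2` = 1L))
    expect_equal(h$turn, c(`1` = 0L, `2` = 0L, `3` = 1L))
    # a direction change breaks the run
    h2 <- streakHistogram(c("L", "R"))
    expect_equal(h2$turn, c(`1` = 2L))
    # truncated runs can be excluded
    h3 <- streakHistogram(c("F", "L", "L", "F", "F"), dropTruncated = TRUE)
    expect_equal(h3$turn, c(`1` = 0L, `2` = 1L))
    expect_length(h3$forward, 0)
})

test_that("run lengths from a Markov chain are geometric with mean 1/(1-p)", {
    set.seed(91)
    p <- 0.7
    P <- symmetricTransitionMatrix(p, p, (1 - p) / 2)
    s <- c("F", "L", "R")[sampleMarkovChain(P, stationaryDistribution(P),
                                            2e5)]
    h <- streakHistogram(s)
    meanF <- sum(as.numeric(names(h$forward)) * h$forward) / sum(h$forward)
    expect_lt(abs(meanF - 1 / (1 - p)), 0.1)
})

test_that("streak-length fit inverts exact geometric counts", {
    l1 <- 1.4
    counts <- round(1e6 * exp(-(1:8) / l1))
    names(counts) <- 1:8
    expect_equal(fitStreakLength(counts), l1, tolerance = 1e-3)
    # exact real-valued counts reach full precision
    counts2 <- setNames(1e6 * exp(-(1:8) / l1), 1:8)
    expect_equal(fitStreakLength(counts2), l1, tolerance = 1e-9)
    expect_error(fitStreakLength(c(`1` = 10, `2` = 5)), "3")
})

test_that("fitted streak length matches -1/log P(turn->same) on chain data", {
    set.seed(92)
    p <- 0.49
    P <- symmetricTransitionMatrix(0.5, p, 0.17)
    s <- c("F", "L", "R")[sampleMarkovChain(P, stationaryDistribution(P),
                                            3e5)]
    h <- streakHistogram(s)
    # pooled same-direction turn runs continue with prob P(T->T)
    l1 <- -1 / log(p)
    expect_lt(abs(fitStreakLength(h$turn) - l1) / l1, 0.05)
})

test_that("theoretical persistence lengths follow the closed forms", {
    P <- matrix(1 / 3, 3, 3, dimnames = list(c("F", "L", "R"),
                                             c("F", "L", "R")))
    tl <- theoreticalLengths(P)
    expect_equal(tl$l1, rep(1 / log(3), 3), tolerance = 1e-12)
    expect_equal(tl$l0, rep(1 / log(3), 3), tolerance = 1e-12)
    expect_equal(tl$ratio, rep(1, 3), tolerance = 1e-12)
    # inverse construction: P(s->s) = exp(-1/2)  =>  l1 = 2
    p <- exp(-0.5)
    P2 <- symmetricTransitionMatrix(p, p, (1 - p) / 2)
    expect_equal(theoreticalLengths(P2)$l1, rep(2, 3), tolerance = 1e-12)
    # memoryless null P(s->s') = P(s') gives ratio 1 for every state
    pi <- c(0.5, 0.25, 0.25)
    P3 <- matrix(pi, 3, 3, byrow = TRUE,
                 dimnames = list(c("F", "L", "R"), c("F", "L", "R")))
    expect_equal(theoreticalLengths(P3)$ratio, rep(1, 3), tolerance = 1e-12)
    expect_error(theoreticalLengths(diag(3)))
})

test_that("empirical stubbornness counts q-plets by hand-checkable rules", {
    r <- stubbornnessEmpirical(c("L", "F", "L", "F", "R"), q = 1)
    expect_equal(r$nSame, 1)   # L -> F -> L
    expect_equal(r$nDiff, 1)   # L -> F -> R
    expect_equal(r$fq, 1)
    # q = 0: adjacent turns; overlapping plets all counted
    r0 <- stubbornnessEmpirical(c("L", "L", "L"), q = 0)
    expect_equal(r0$nSame, 2)
    expect_false(r0$defined)
    expect_true(is.na(r0$fq))
})

test_that("stubbornness uncertainty: reported form and bootstrap scale", {
    # internal consistency of the reported ratio and uncertainty
    s <- rep(c("L", "F", "L", "F", "R", "F"), 50)
    r <- stubbornnessEmpirical(s, q = 1)
    expect_equal(r$fq, r$nSame / r$nDiff)
    expect_equal(r$deltaFq,
                 r$fq * sqrt((1 / (r$nSame + r$nDiff)) *
                             (r$nSame / r$nDiff + r$nDiff / r$nSame)))
    # at N_same = N_diff = 50 the reported form gives sqrt(2/100)
    dfq <- 1 * sqrt((1 / 100) * (50 / 50 + 50 / 50))
    expect_equal(dfq, sqrt(0.02))
    # bootstrap oracle over resampled q-plets: the resampling sd equals the
    # exact binomial propagation f * sqrt(1/N_same + 1/N_diff); the
    # reported form is within a factor sqrt(2) of it (equal when one count
    # dominates)
    set.seed(17)
    boots <- replicate(4000, {
        same <- sum(sample(c(TRUE, FALSE), 100, replace = TRUE))
        if (same %in% c(0, 100)) NA_real_ else same / (100 - same)
    })
    exact <- 1 * sqrt(1 / 50 + 1 / 50)
    expect_lt(abs(sd(boots, na.rm = TRUE) - exact) / exact, 0.1)
    expect_lt(abs(log(dfq / exact)), log(sqrt(2)) + 1e-9)
})

test_that("theoretical stubbornness: symmetry gives exactly 1 for q >= 1", {
    set.seed(5)
    for (rep in 1:20) {
        pTT <- runif(1, 0.1, 0.7); pSw <- runif(1, 0.01, (1 - pTT) / 2)
        P <- symmetricTransitionMatrix(runif(1, 0.1, 0.9), pTT, pSw)
        for (q in 1:5)
            expect_equal(stubbornnessTheoretical(P, q), 1,
                         tolerance = 1e-12)
    }
    # q = 0 arithmetic
    P <- symmetricTransitionMatrix(0.5, 0.4, 0.1)
    expect_equal(stubbornnessTheoretical(P, 0), 0.8 / 0.2)
})

test_that("empirical and theoretical stubbornness agree on simulated data", {
    set.seed(29)
    # asymmetric chain
    P <- rbind(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2), c(0.25, 0.15, 0.6))
    dimnames(P) <- list(c("F", "L", "R"), c("F", "L", "R"))
    s <- c("F", "L", "R")[sampleMarkovChain(P, stationaryDistribution(P),
                                            1e6)]
    for (q in c(0, 1)) {
        emp <- stubbornnessEmpirical(s, q)
        theo <- stubbornnessTheoretical(P, q)
        expect_lt(abs(emp$fq - theo), 3 * emp$deltaFq)
    }
})

test_that("symmetric-chain empirical f_1 is 1 within its uncertainty", {
    set.seed(31)
    P <- symmetricTransitionMatrix(0.5, 0.5, 0.25)
    s <- c("F", "L", "R")[sampleMarkovChain(P, stationaryDistribution(P),
                                            1e5)]
    r <- stubbornnessEmpirical(s, 1)
    expect_lt(abs(r$fq - 1), 2 * r$deltaFq)
})

test_that("persistence report assembles lengths and stubbornness", {
    set.seed(37)
    P <- symmetricTransitionMatrix(0.6, 0.5, 0.2)
    s <- c("F", "L", "R")[sampleMarkovChain(P, stationaryDistribution(P),
                                            5e4)]
    rep <- persistenceReport(s, qMax = 2)
    expect_named(rep, c("lengths", "stubbornness"))
    expect_equal(nrow(rep$stubbornness), 3)
    expect_true(all(rep$lengths$l1 > 0))
})
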