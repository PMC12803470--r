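test_that("emission log-densities match closed forms and support rules", {
    m <- BehaviorHMM(symmetricTransitionMatrix(), sigmaF = 15,
                     alpha = 2, theta = 10)
    expect_equal(emissionLogpdf(0, "F", m), log(1 / (15 * sqrt(2 * pi))))
    # outside the Gamma half-line support: finite floor, not -Inf
    expect_equal(emissionLogpdf(-5, "L", m), -1e6)
    expect_equal(emissionLogpdf(5, "R", m), -1e6)
    expect_equal(emissionLogpdf(20, "L", m),
                 dgamma(20, shape = 2, scale = 10, log = TRUE))
    expect_equal(emissionLogpdf(-20, "R", m),
                 dgamma(20, shape = 2, scale = 10, log = TRUE))
})

test_that("forward log-likelihood equals exhaustive enumeration (T <= 8)", {
    set.seed(42)
    for (rep in 1:25) {
        m <- randomBehaviorHMM()
        Tn <- sample(1:8, 1)
        angles <- sampleStatesAndAngles(m, Tn)$angles
        oracle <- bruteForceLoglik(behaviorLogB(angles, m),
                                   log(initialDistribution(m)),
                                   log(transitionMatrix(m)))
        expect_equal(sequenceLoglik(angles, m), oracle$loglik,
                     tolerance = 1e-10)
    }
})

test_that("length-1 sequence log-likelihood is logsumexp(initial*emission)", {
    m <- wellSeparatedBehaviorHMM()
    a <- 3.7
    manual <- log(sum(initialDistribution(m) *
        exp(c(emissionLogpdf(a, "F", m), emissionLogpdf(a, "L", m),
              emissionLogpdf(a, "R", m)))))
    expect_equal(sequenceLoglik(a, m), manual, tolerance = 1e-12)
})

test_that("Viterbi path score equals exhaustive maximum (T <= 8)", {
    set.seed(43)
    for (rep in 1:25) {
        m <- randomBehaviorHMM()
        Tn <- sample(1:8, 1)
        angles <- sampleStatesAndAngles(m, Tn)$angles
        oracle <- bruteForceLoglik(behaviorLogB(angles, m),
                                   log(initialDistribution(m)),
                                   log(transitionMatrix(m)))
        v <- viterbiDecode(angles, m, withScore = TRUE)
        expect_equal(v$score, oracle$best, tolerance = 1e-10)
    }
})

test_that("Viterbi recovers states of a near-deterministic model", {
    off <- 0.0005
    P <- matrix(off, 3, 3); diag(P) <- 0.999
    dimnames(P) <- list(c("F", "L", "R"), c("F", "L", "R"))
    m <- BehaviorHMM(P, sigmaF = 5, alpha = 8, theta = 8)
    sim <- sampleStatesAndAngles(m, 5000, seed = 5)
    dec <- viterbiDecode(sim$angles, m)
    expect_gt(mean(states(dec) == states(sim$states)), 0.99)
})

test_that("large positive angles decode to L", {
    m <- wellSeparatedBehaviorHMM()
    expect_true(all(states(viterbiDecode(rep(60, 10), m)) == "L"))
})

test_that("ancestral sampling matches the generating law", {
    m <- BehaviorHMM(symmetricTransitionMatrix(0.6, 0.5, 0.2))
    sim <- sampleStatesAndAngles(m, 1e5, seed = 7)
    Phat <- estimateTransitions(states(sim$states))
    expect_lt(max(abs(Phat - transitionMatrix(m))), 0.01)
    # all angles from an absorbing F state are Normal draws
    mAbs <- BehaviorHMM(rbind(c(1, 0, 0), c(0.5, 0.25, 0.25),
                              c(0.5, 0.25, 0.25)),
                        initial = c(1, 0, 0), sigmaF = 15)
    sim2 <- sampleStatesAndAngles(mAbs, 2000, seed = 8)
    expect_true(all(states(sim2$states) == "F"))
    expect_gt(shapiro.test(sim2$angles[1:1000])$p.value, 1e-4)
})

test_that("EM trace is non-decreasing and the stopping rule holds", {
    gt <- groundTruth()
    sess <- genBehaviorSessions(gt, 30, 60, seed = 11)
    fit <- suppressWarnings(
        fitBehaviorHMM(lapply(sess$bouts, `[[`, "dtheta_deg"),
                       hmmConfig(restarts = 2, seed = 11)))
    tr <- trainingTrace(fit)
    expect_true(all(diff(tr) >= -1e-6))
    expect_lte(length(tr), 500)
    n <- length(tr)
    expect_true(n == 500 || tr[n] - tr[n - 1] < 1e-6)
})

test_that("symmetric fit has exactly symmetric stationary distribution", {
    gt <- groundTruth()
    sess <- genBehaviorSessions(gt, 50, 60, seed = 19)
    fit <- fitBehaviorHMM(lapply(sess$bouts, `[[`, "dtheta_deg"),
                          hmmConfig(restarts = 2, seed = 19))
    P <- transitionMatrix(fit)
    expect_equal(P["F", "L"], P["F", "R"], tolerance = 1e-12)
    expect_equal(P["L", "L"], P["R", "R"], tolerance = 1e-12)
    pi <- stationaryDistribution(P)
    expect_equal(unname(pi["L"]), unname(pi["R"]), tolerance = 1e-10)
})

test_that("unconstrained fit on symmetric data learns symmetric parameters", {
    m <- BehaviorHMM(symmetricTransitionMatrix(0.6, 0.6, 0.1),
                     sigmaF = 8, alpha = 4, theta = 10)
    gt <- groundTruth(behavior = m)
    sess <- genBehaviorSessions(gt, 400, 60, seed = 23)
    fit <- fitBehaviorHMM(lapply(sess$bouts, `[[`, "dtheta_deg"),
                          hmmConfig(restarts = 3, seed = 23,
                                    symmetric = FALSE))
    p <- emissionParams(fit)
    expect_false(p$symmetric)
    expect_lt(abs(p$alphaL - p$alphaR) / p$alphaL, 0.15)
    expect_lt(abs(p$thetaL - p$thetaR) / p$thetaL, 0.15)
    P <- transitionMatrix(fit)
    expect_lt(abs(P["L", "L"] - P["R", "R"]), 0.05)
    expect_lt(abs(P["F", "L"] - P["F", "R"]), 0.05)
})

test_that("a short dataset warns", {
    m <- wellSeparatedBehaviorHMM()
    a <- sampleStatesAndAngles(m, 50, seed = 2)$angles
    w <- capture_warnings(fitBehaviorHMM(a, hmmConfig(restarts = 1,
                                                      maxIter = 5,
                                                      seed = 2)))
    expect_true(any(grepl("100", w)))
})
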