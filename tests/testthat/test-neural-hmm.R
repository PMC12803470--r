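test_that("Bernoulli emission log-probability matches the naive product", {
    set.seed(51)
    m <- randomNeuralHMM(K = 3, N = 8)
    for (rep in 1:10) {
        cfg <- rbinom(8, 1, 0.5)
        s <- sample(1:3, 1)
        p <- logistic(fieldsMatrix(m)[s, ])
        naive <- sum(log(ifelse(cfg == 1, p, 1 - p)))
        expect_equal(neuralEmissionLoglik(cfg, s, m), naive,
                     tolerance = 1e-12)
    }
    # all-zero fields: every configuration has probability 2^-N
    m0 <- NeuralHMM(matrix(1 / 3, 3, 3), matrix(0, 3, 8))
    expect_equal(neuralEmissionLoglik(rbinom(8, 1, 0.5), 1, m0),
                 -8 * log(2), tolerance = 1e-12)
    # saturation: strong fields, all firing
    mS <- NeuralHMM(matrix(1 / 3, 3, 3), matrix(10, 3, 8))
    expect_lt(abs(neuralEmissionLoglik(rep(1, 8), 2, mS) -
                  (-8 * log(1 + exp(-10)))), 1e-10)
})

test_that("raster forward/Viterbi agree with exhaustive enumeration", {
    set.seed(52)
    for (rep in 1:15) {
        m <- randomNeuralHMM(K = 3, N = 4)
        Tn <- sample(1:8, 1)
        r <- sampleRaster(m, Tn, frameRate = 2)
        X <- activityMatrix(r)
        logB <- neuralLogB(X, m)
        oracle <- bruteForceLoglik(logB, log(initialDistribution(m)),
                                   log(transitionMatrix(m)))
        expect_equal(rasterLoglik(r, m), oracle$loglik, tolerance = 1e-10)
        v <- decodeRaster(r, m, withScore = TRUE)
        expect_equal(v$score, oracle$best, tolerance = 1e-10)
        expect_equal(stateTimes(v$states), (seq_len(Tn) - 1) / 2)
    }
})

test_that("sampled rasters reproduce the stationary mean activity", {
    gt <- groundTruth(nNeurons = 20)
    m <- gt@neural
    r <- sampleRaster(m, 10000, seed = 53)
    emp <- rowMeans(activityMatrix(r))
    pred <- neuralMoments(m)$mean
    # persistent states (dwell ~25 frames) leave ~400 effective samples per
    # neuron; between-state activity spread ~0.35 puts the sd of a neuron's
    # time average near 0.018, so 3 sd over 20 neurons is ~0.055
    expect_lt(max(abs(emp - pred)), 0.06)
    # all-zero fields: every neuron fires at ~0.5
    m0 <- NeuralHMM(matrix(1 / 3, 3, 3), matrix(0, 3, 10))
    r0 <- sampleRaster(m0, 10000, seed = 54)
    se <- sqrt(0.25 / 10000)
    expect_lt(max(abs(rowMeans(activityMatrix(r0)) - 0.5)), 3 * se + 0.01)
})

test_that("lateralized fields separate mean activities by true state", {
    gt <- groundTruth(nNeurons = 30)
    sim <- genNeuralSession(gt, nFrames = 3000, seed = 55)
    X <- activityMatrix(sim$raster)
    side <- sideLabels(sim$raster)
    st <- states(sim$states)
    mL <- colMeans(X[side == "left", , drop = FALSE])
    mR <- colMeans(X[side == "right", , drop = FALSE])
    expect_gt(mean(mL[st == "L"]) - mean(mR[st == "L"]), 0.3)
    expect_gt(mean(mR[st == "R"]) - mean(mL[st == "R"]), 0.3)
})

test_that("K = 1 fit reduces to per-neuron firing frequencies", {
    gt <- groundTruth(nNeurons = 12)
    sim <- genNeuralSession(gt, nFrames = 500, seed = 56)
    fit <- fitNeuralHMM(sim$raster, K = 1,
                        config = hmmConfig(restarts = 1, seed = 56))
    pbar <- pmin(pmax(rowMeans(activityMatrix(sim$raster)), 1e-6), 1 - 1e-6)
    expect_equal(as.numeric(fieldsMatrix(fit)),
                 log(pbar) - log(1 - pbar), tolerance = 1e-6)
})

test_that("neural EM recovers fields and transitions from synthetic data", {
    gt <- groundTruth(nNeurons = 60,
        neural = NeuralHMM(symmetricTransitionMatrix(0.9, 0.9, 0.02),
                           swimHMM:::.defaultNeuralFields(60),
                           stateLabels = c("F", "L", "R")))
    sim <- genNeuralSession(gt, nFrames = 10000, seed = 17)
    fit <- fitNeuralHMM(sim$raster, K = 3,
                        config = hmmConfig(restarts = 3, seed = 17))
    lab <- labelNeuralStates(fit, sideLabels(sim$raster))
    expect_lt(sqrt(mean((fieldsMatrix(lab) -
                         fieldsMatrix(gt@neural))^2)), 0.1)
    expect_lt(max(abs(transitionMatrix(lab) -
                      transitionMatrix(gt@neural))), 0.02)
    tr <- trainingTrace(lab)
    expect_true(all(diff(tr) >= -1e-6))
})

test_that("state labeling orders by lateralized excitability", {
    side <- rep(c("left", "right"), each = 5)
    H <- rbind(c(rep(2, 5), rep(-2, 5)),    # left-active
               c(rep(-2, 5), rep(2, 5)),    # right-active
               rep(0, 10))                  # balanced
    m <- NeuralHMM(matrix(c(0.8, 0.1, 0.1,
                            0.1, 0.8, 0.1,
                            0.2, 0.2, 0.6), 3, 3, byrow = TRUE), H)
    lab <- labelNeuralStates(m, side)
    expect_equal(stateLabels(lab), c("F", "L", "R"))
    # canonical row order: F (balanced), L (left-active), R (right-active)
    expect_equal(unname(fieldsMatrix(lab)[1, ]), rep(0, 10))
    expect_equal(unname(fieldsMatrix(lab)["F", 1]), 0)
    expect_equal(unname(fieldsMatrix(lab)[2, 1]), 2)
    expect_equal(unname(fieldsMatrix(lab)[3, 1]), -2)
    # permutation invariance of the likelihood
    r <- sampleRaster(m, 200, seed = 57)
    expect_equal(rasterLoglik(r, m), rasterLoglik(r, lab),
                 tolerance = 1e-8)
    # tied excitabilities are a degenerate fit
    mTie <- NeuralHMM(matrix(1 / 3, 3, 3), matrix(0, 3, 10))
    expect_error(labelNeuralStates(mTie, side), "degenerate")
})

test_that("cross-validation prefers the generating state count", {
    gt <- groundTruth(nNeurons = 30,
        neural = NeuralHMM(symmetricTransitionMatrix(0.9, 0.9, 0.02),
                           swimHMM:::.defaultNeuralFields(30),
                           stateLabels = c("F", "L", "R")))
    sim <- genNeuralSession(gt, nFrames = 4000, seed = 58)
    cv <- crossValidateStates(sim$raster, Ks = 1:4, folds = 2,
                              config = hmmConfig(restarts = 2, maxIter = 100),
                              seed = 58)
    agg <- tapply(cv$heldoutLoglikPerFrame, cv$K, mean)
    expect_gt(agg["2"], agg["1"])
    expect_gt(agg["3"], agg["2"])
    # near-flat beyond the true K = 3
    expect_lt(abs(agg["4"] - agg["3"]), 0.5 * (agg["3"] - agg["2"]))
    # two-point moments: model-implied vs direct empirical oracle
    fit <- fitNeuralHMM(sim$raster, K = 3,
                        config = hmmConfig(restarts = 2, seed = 58))
    mom <- neuralMoments(fit)
    X <- activityMatrix(sim$raster)
    emp <- tcrossprod(X) / ncol(X)
    ut <- upper.tri(emp)
    expect_gt(cor(mom$second[ut], emp[ut]), 0.95)
    expect_gt(cor(mom$mean, rowMeans(X)), 0.99)
})

test_that("contralateral covariance is reproduced, ipsilateral underestimated
           when the generator adds within-state correlation", {
    set.seed(59)
    # heterogeneous neurons (per-neuron lateralization strength) plus a
    # shared within-state fluctuation on each side
    nN <- 24; Tn <- 6000
    side <- rep(c("left", "right"), each = nN / 2)
    amp <- runif(nN, 0.5, 3)
    P <- symmetricTransitionMatrix(0.9, 0.9, 0.02)
    st <- sampleMarkovChain(P, rep(1 / 3, 3), Tn)
    base <- rbind(rep(-1, nN),
                  ifelse(side == "left", amp, -amp),
                  ifelse(side == "left", -amp, amp))
    common <- matrix(rnorm(2 * Tn, 0, 1.2), 2, Tn)  # per-side shared noise
    X <- matrix(0L, nN, Tn)
    for (i in seq_len(nN)) {
        extra <- common[if (side[i] == "left") 1 else 2, ]
        X[i, ] <- as.integer(runif(Tn) < logistic(base[st, i] + extra))
    }
    raster <- NeuralRaster(X, side, 5.9)
    fit <- fitNeuralHMM(raster, K = 3,
                        config = hmmConfig(restarts = 2, seed = 59))
    synth <- sampleRaster(fit, Tn, seed = 60)
    covOf <- function(M) cov(t(M))
    empC <- covOf(X); genC <- covOf(activityMatrix(synth))
    contra <- outer(side == "left", side == "right") == 1
    ipsi <- (outer(side == "left", side == "left") == 1) & !diag(nN)
    # contralateral structure reproduced (correlated across pairs)
    expect_gt(cor(empC[contra], genC[contra]), 0.7)
    # ipsilateral covariance underestimated by the within-state
    # independence assumption
    expect_lt(mean(genC[ipsi]), 0.8 * mean(empC[ipsi]))
})
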