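test_that("bout times are rescaled intervals truncated at the duration", {
    # pool of constant 1 s intervals, f = 0.44: spacing 1/0.44 ~ 2.27 s
    tt <- sampleBoutTimes(1, f = 0.44, duration = 10, seed = 71)
    expect_length(tt, 4)
    expect_equal(tt, (1 / 0.44) * 1:4, tolerance = 1e-12)
    # f = 1: bout rate equals the behavioral rate
    set.seed(72)
    pool <- rexp(5000, 1)
    t1 <- sampleBoutTimes(pool, f = 1, duration = 2000, seed = 72)
    expect_lt(abs(length(t1) / 2000 - 1 / mean(pool)), 0.08)
    # mean rate scales with f
    t2 <- sampleBoutTimes(pool, f = 0.5, duration = 2000, seed = 72)
    expect_lt(abs(length(t2) / length(t1) - 0.5), 0.07)
    expect_error(sampleBoutTimes(numeric(0), 1, 10))
})

test_that("bout states use the floor (last frame at or before) lookup", {
    ns <- StateSequence(c("L", "L", "R"), times = c(0, 1, 2))
    expect_equal(assignBoutStates(ns, 1.4), "L")
    expect_equal(assignBoutStates(ns, 2.0), "R")   # exactly on a frame
    expect_equal(assignBoutStates(ns, c(0, 0.9, 1.1, 2.5)),
                 c("L", "L", "L", "R"))
    expect_error(assignBoutStates(ns, -0.1), "first frame")
})

test_that("dense bout states inherit the rescaled neural transitions", {
    gt <- groundTruth(
        behavior = BehaviorHMM(symmetricTransitionMatrix(0.8, 0.8, 0.05)),
        scalingFactor = 0.44, frameRate = 5.9)
    link <- genLinkedDataset(gt, seed = 73, nTraj = 2, boutsPerTraj = 10,
                             durationMin = 30)
    tt <- sampleBoutTimes(sampleNamedDist(link$truth@intervalDist, 5000),
                          f = 0.44, duration = max(stateTimes(link$neural$states)),
                          seed = 73)
    b <- assignBoutStates(link$neural$states, tt)
    Phat <- estimateTransitions(b)
    Pexp <- rescaleTransitions(transitionMatrix(link$truth@neural),
                               5.9, 0.44)
    expect_lt(max(abs(Phat - Pexp)), 0.08)
})

test_that("trajectory positions follow the heading/displacement recursion", {
    m <- wellSeparatedBehaviorHMM()
    # one bout, theta = 0 after mean ~ 0 forward angle: force with d pool
    tr <- synthesizeTrajectory("F", m, distancePool = 1, seed = 74)
    expect_equal(tr$x_mm, cos(tr$theta_deg * pi / 180), tolerance = 1e-12)
    # deterministic two-bout check of the cumulative-sum geometry
    tr2 <- data.frame(dtheta_deg = c(0, 90), d_mm = c(1, 1))
    theta <- cumsum(tr2$dtheta_deg)
    x <- cumsum(tr2$d_mm * cos(theta * pi / 180))
    y <- cumsum(tr2$d_mm * sin(theta * pi / 180))
    expect_equal(c(x[2], y[2]), c(1, 1), tolerance = 1e-12)
    # angle reconstruction from headings is exact
    b <- sampleStatesAndAngles(m, 50, seed = 75)
    tr3 <- synthesizeTrajectory(states(b$states), m,
                                distancePool = rlnorm(100), seed = 75)
    expect_equal(diff(c(0, tr3$theta_deg)), tr3$dtheta_deg,
                 tolerance = 1e-10)
})

test_that("MSR of i.i.d. angles is q times the variance", {
    set.seed(76)
    angs <- lapply(1:200, function(i) rnorm(100, 0, 12))
    v <- var(unlist(angs))
    out <- msr(angs, qMax = 10)
    expect_lt(max(abs(out$msr / (out$q * v) - 1)), 0.05)
    # constant angle: mean subtraction removes the drift entirely
    const <- lapply(1:5, function(i) rep(7, 30))
    expect_equal(msr(const, 5)$msr, rep(0, 5), tolerance = 1e-20)
})

test_that("MSR equals diffusive plus correlation terms identically", {
    set.seed(77)
    angs <- lapply(1:20, function(i) {
        e <- rnorm(60)
        as.numeric(stats::filter(e, 0.7, method = "recursive")) * 10
    })
    for (q in c(1, 3, 7)) {
        dec <- msrDecomposition(angs, q)
        expect_equal(dec$total, msr(angs, q)$msr[q], tolerance = 1e-8)
    }
    # positively autocorrelated angles: super-diffusive
    dec <- msrDecomposition(angs, 5)
    expect_gt(dec$correlation, 0)
    # i.i.d. angles: correlation term near zero
    set.seed(78)
    iid <- lapply(1:200, function(i) rnorm(100, 0, 10))
    dec2 <- msrDecomposition(iid, 5)
    expect_lt(abs(dec2$correlation), 0.05 * dec2$diffusive)
})

test_that("shuffling collapses persistent MSR onto the diffusive line", {
    # perfectly persistent +/-c alternating blocks
    set.seed(79)
    # sign-balanced blocks so each trajectory has zero mean (no drift term)
    angs <- lapply(1:100, function(i) {
        sgn <- rep(sample(rep(c(-1, 1), 5)), each = 10)
        sgn * 15
    })
    q <- 8
    raw <- msr(angs, q)$msr[q]
    sh <- shuffleControl(angs, seed = 79)
    shuf <- msr(sh, q)$msr[q]
    v <- var(unlist(angs))
    expect_gt(raw, 3 * q * v)           # super-diffusive before shuffling
    expect_lt(abs(shuf - q * v) / (q * v), 0.2)
    # permutation preserves the angle multiset
    expect_equal(sort(unlist(sh)), sort(unlist(angs)))
    # shuffling i.i.d. data leaves the MSR statistically unchanged
    iid <- lapply(1:100, function(i) rnorm(80, 0, 10))
    m1 <- msr(iid, 5)$msr[5]
    m2 <- msr(shuffleControl(iid, seed = 80), 5)$msr[5]
    expect_lt(abs(m1 - m2) / m1, 0.1)
})

test_that("all-forward trajectories diffuse like q * sigma^2", {
    m <- BehaviorHMM(symmetricTransitionMatrix(), sigmaF = 10)
    set.seed(81)
    trs <- lapply(1:300, function(i)
        synthesizeTrajectory(rep("F", 60), m, distancePool = 1))
    out <- msr(trs, 10)
    expect_lt(max(abs(out$msr / (out$q * 100) - 1)), 0.1)
})
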