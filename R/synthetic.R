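.defaultNeuralFields <- function(nNeurons, leftFraction = 0.5,
                                 lateral = 2, baseline = -1) {
    nLeft <- ceiling(leftFraction * nNeurons)
    left <- seq_len(nNeurons) <= nLeft
    H <- rbind(F = rep(baseline, nNeurons),
               L = ifelse(left, lateral, -lateral),
               R = ifelse(left, -lateral, lateral))
    attr(H, "side") <- ifelse(left, "left", "right")
    H
}

#' Construct a ground truth for the synthetic generators
#'
#' Defaults emulate the study conditions: a left-right symmetric behavioral
#' model (sigma = 15 deg, Gamma shape 2, scale 10 deg; self-transitions 0.5
#' with equal off-diagonals), a persistent lateralized neural model, a
#' neural-to-behavioral scaling factor of 0.44 at a 5.9 Hz frame rate,
#' Gamma-distributed inter-bout intervals (mean 1 s, shape 4) and
#' LogNormal travel distances (median 1 mm, sdlog 0.5).
#'
#' @param behavior a [BehaviorHMM-class]; default as described.
#' @param neural a [NeuralHMM-class]; default: lateralized fields (+/-2 in
#'   the turn states on the ipsi/contralateral side, -1 everywhere in F)
#'   over `nNeurons` neurons with persistent transitions.
#' @param scalingFactor f_N/B in (0, 1].
#' @param frameRate neural frame rate nu (Hz).
#' @param intervalDist,distanceDist named lists describing the inter-bout
#'   interval (s) and travel distance (mm) laws; see [sampleNamedDist()].
#' @param nNeurons,leftFraction size and left share of the default neural
#'   population.
#' @param seed integer root seed stored with the truth.
#' @return a [GroundTruth-class].
#' @export
groundTruth <- function(behavior = NULL, neural = NULL,
                        scalingFactor = 0.44, frameRate = 5.9,
                        intervalDist = list(name = "gamma", mean = 1,
                                            shape = 4),
                        distanceDist = list(name = "lognormal", median = 1,
                                            sdlog = 0.5),
                        nNeurons = 60, leftFraction = 0.5, seed = 1L) {
    if (is.null(behavior))
        behavior <- BehaviorHMM(symmetricTransitionMatrix(0.5, 0.5, 0.25),
                                sigmaF = 15, alpha = 2, theta = 10)
    if (is.null(neural)) {
        H <- .defaultNeuralFields(nNeurons, leftFraction)
        neural <- NeuralHMM(symmetricTransitionMatrix(0.96, 0.96, 0.005),
                            H, stateLabels = STATE_NAMES)
    }
    new("GroundTruth", behavior = behavior, neural = neural,
        scalingFactor = scalingFactor, frameRate = frameRate,
        intervalDist = intervalDist, distanceDist = distanceDist,
        seed = as.integer(seed))
}

.drawLength <- function(lengthLaw) {
    if (is.function(lengthLaw)) return(as.integer(lengthLaw(1)))
    if (is.numeric(lengthLaw)) return(as.integer(lengthLaw))
    switch(lengthLaw$name,
        constant = as.integer(lengthLaw$value),
        poisson = max(2L, stats::rpois(1, lengthLaw$mean)),
        stop("unknown length law '", lengthLaw$name, "'"))
}

#' Generate behavioral sessions with known hidden states
#'
#' Each trajectory is drawn by (i) sampling hidden states from the
#' behavioral transition matrix starting from its initial distribution,
#' (ii) sampling reorientation angles from the active state's emission law,
#' (iii) sampling inter-bout intervals and travel distances i.i.d. from the
#' truth's interval/distance laws. One root seed spawns an independent
#' substream per trajectory, so increasing `nTraj` never perturbs earlier
#' trajectories.
#'
#' @param truth a [GroundTruth-class].
#' @param nTraj number of trajectories (>= 1).
#' @param lengthLaw bout count per trajectory: an integer, a
#'   `list(name = "constant", value = )` / `list(name = "poisson", mean = )`,
#'   or a function returning one integer >= 2.
#' @param seed root seed (default: the truth's).
#' @return list with `bouts` (list of data.frames with columns t,
#'   dtheta_deg, dt_s, d_mm) and `states` (list of timed
#'   [StateSequence-class] ground-truth labels).
#' @export
genBehaviorSessions <- function(truth, nTraj, lengthLaw = 60L, seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), nTraj >= 1)
    if (is.null(seed)) seed <- truth@seed
    model <- truth@behavior
    bouts <- vector("list", nTraj)
    statesOut <- vector("list", nTraj)
    for (i in seq_len(nTraj)) {
        withSeed(substreamSeed(seed, i), {
            n <- .drawLength(lengthLaw)
            if (n < 2) stop("length law produced fewer than 2 bouts")
            sa <- sampleStatesAndAngles(model, n)
            dt <- sampleNamedDist(truth@intervalDist, n)
            d <- sampleNamedDist(truth@distanceDist, n)
            tt <- cumsum(c(0, dt[-n]))
            bouts[[i]] <- data.frame(t = tt, dtheta_deg = sa$angles,
                                     dt_s = dt, d_mm = d)
            statesOut[[i]] <- StateSequence(states(sa$states), times = tt)
        })
    }
    list(bouts = bouts, states = statesOut)
}

#' Generate a neural session with known hidden states
#'
#' Hidden states are sampled from the neural transition matrix at the
#' truth's frame rate; each neuron's binary activity is then sampled
#' independently per frame with probability logistic(h_i^s). The first
#' ceiling(leftFraction * N) neurons are labeled 'left'. The state chain
#' and each neuron use independent substreams of the root seed.
#'
#' @param truth a [GroundTruth-class].
#' @param nNeurons number of neurons; when it differs from the truth's
#'   field matrix, the default lateralized field pattern is rebuilt at this
#'   size.
#' @param nFrames number of frames (>= 2).
#' @param leftFraction proportion of left-side neurons in (0, 1).
#' @param seed root seed (default: the truth's, offset for the neural
#'   stream).
#' @return list with `raster` (a [NeuralRaster-class]) and `states` (timed
#'   ground-truth [StateSequence-class]).
#' @export
genNeuralSession <- function(truth, nNeurons = NULL, nFrames,
                             leftFraction = 0.5, seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), nFrames >= 2,
              leftFraction > 0, leftFraction < 1)
    if (is.null(seed)) seed <- substreamSeed(truth@seed, 104729L)
    model <- truth@neural
    H <- fieldsMatrix(model)
    if (!is.null(nNeurons) && nNeurons != ncol(H)) {
        stopifnot(nNeurons >= 2)
        H <- .defaultNeuralFields(nNeurons, leftFraction)
    }
    N <- ncol(H)
    nLeft <- ceiling(leftFraction * N)
    side <- rep(c("left", "right"), c(nLeft, N - nLeft))
    st <- withSeed(substreamSeed(seed, 0L),
        sampleMarkovChain(transitionMatrix(model),
                          initialDistribution(model), nFrames))
    p <- logistic(H)                               # K x N
    X <- matrix(0L, N, nFrames)
    for (i in seq_len(N)) {
        X[i, ] <- withSeed(substreamSeed(seed, i),
                           as.integer(runif(nFrames) < p[st, i]))
    }
    labs <- stateLabels(model)
    stlab <- if (all(is.na(labs))) as.character(st) else labs[st]
    tt <- (seq_len(nFrames) - 1) / truth@frameRate
    raster <- NeuralRaster(X, side, truth@frameRate)
    ss <- StateSequence(stlab, times = tt)
    S4Vectors::metadata(raster)$states <- ss
    list(raster = raster, states = ss)
}

.scaleIntervalDist <- function(dist, mean) {
    switch(dist$name,
        gamma = list(name = "gamma", mean = mean, shape = dist$shape),
        constant = list(name = "constant", value = mean),
        lognormal = list(name = "lognormal", median = mean,
                         sdlog = dist$sdlog),
        stop("unknown distribution '", dist$name, "'"))
}

#' Generate a linked behavioral + neural dataset
#'
#' Builds a world in which the neural and behavioral state dynamics are the
#' same process observed on two clocks. The neural per-frame transition
#' matrix is the principal k-th root of the behavioral per-bout matrix with
#' k = round(nu * f) (the inverse of the frame-exponent rescaling), and the
#' behavioral bout clock uses an inter-bout-interval mean of f * k / nu so
#' that neural state dwell times are, in distribution, the behavioral dwell
#' times divided by f. Under these conditions [fitScalingFactor()] recovers
#' f and [rescaleTransitions()] maps the neural matrix back onto the
#' behavioral one.
#'
#' @param truth a [GroundTruth-class] carrying both models, the scaling
#'   factor and the frame rate.
#' @param seed root seed (default: the truth's).
#' @param nTraj,boutsPerTraj behavioral session size.
#' @param durationMin neural recording duration in minutes.
#' @return list with `behavior` (as [genBehaviorSessions()]), `neural` (as
#'   [genNeuralSession()]), `exponent` (k), and `truth`, the effective
#'   ground truth (derived neural matrix, rescaled interval law).
#' @export
genLinkedDataset <- function(truth, seed = NULL, nTraj = 100,
                             boutsPerTraj = 60, durationMin = 20) {
    stopifnot(is(truth, "GroundTruth"))
    if (is.null(seed)) seed <- truth@seed
    f <- truth@scalingFactor
    nu <- truth@frameRate
    k <- roundHalfAway(nu * f)
    if (k < 1)
        stop("configuration error: rescaling exponent round(nu*f) = 0")
    Pb <- transitionMatrix(truth@behavior)
    Pn <- matrixRoot(Pb, k)
    linked <- truth
    linked@neural <- NeuralHMM(Pn, fieldsMatrix(truth@neural),
                               stateLabels = stateLabels(truth@neural))
    linked@intervalDist <- .scaleIntervalDist(truth@intervalDist,
                                              f * k / nu)
    linked@seed <- as.integer(seed)
    behavior <- genBehaviorSessions(linked, nTraj = nTraj,
                                    lengthLaw = boutsPerTraj, seed = seed)
    nFrames <- ceiling(durationMin * 60 * nu)
    neural <- genNeuralSession(linked, nFrames = nFrames,
                               seed = substreamSeed(seed, 104729L))
    list(behavior = behavior, neural = neural, exponent = k, truth = linked)
}
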