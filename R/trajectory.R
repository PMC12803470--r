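#' Sample bout times on the neural clock
#'
#' Draws inter-bout intervals i.i.d. from an empirical behavioral pool and
#' places them on the neural clock by dividing each interval by the
#' temporal scaling factor f (neural dynamics are slower: one behavioral
#' second spans 1/f seconds of neural recording). Bout times are the
#' cumulative sums, truncated at the recording duration.
#'
#' @param intervalPool numeric vector of behavioral inter-bout intervals
#'   (seconds); sampled with replacement.
#' @param f temporal scaling factor in (0, 1].
#' @param duration recording duration (seconds, neural clock).
#' @param seed integer seed.
#' @return numeric vector of bout times (seconds, neural clock).
#' @export
sampleBoutTimes <- function(intervalPool, f, duration, seed = NULL) {
    stopifnot(length(intervalPool) >= 1, duration > 0, f > 0, f <= 1)
    withSeed(seed, {
        nGuess <- ceiling(duration / (mean(intervalPool) / f)) + 10
        tt <- numeric(0)
        cur <- 0
        repeat {
            dts <- intervalPool[sample.int(length(intervalPool), nGuess,
                                           replace = TRUE)] / f
            tt <- c(tt, cur + cumsum(dts))
            cur <- tt[length(tt)]
            if (cur > duration) break
        }
        tt[tt <= duration]
    })
}

#' Assign neural states to bout times
#'
#' Each bout takes the state of the nearest frame at or before its time
#' (floor lookup).
#'
#' @param neuralStates a timed [StateSequence-class] (e.g. from
#'   [decodeRaster()]).
#' @param boutTimes numeric vector of bout times within the recording span.
#' @return character vector of per-bout states.
#' @export
assignBoutStates <- function(neuralStates, boutTimes) {
    tt <- stateTimes(neuralStates)
    if (!length(tt)) stop("neural states must carry frame timestamps")
    if (any(boutTimes < tt[1]))
        stop("bout time precedes the first frame")
    idx <- findInterval(boutTimes, tt)
    states(neuralStates)[idx]
}

#' Synthesize a planar swim trajectory from bout states
#'
#' For each bout the reorientation angle is drawn from the behavioral
#' model's emission law for that bout's state, and the travel distance
#' i.i.d. from an empirical pool (intervals and distances are not
#' conditioned on bout type). Headings are cumulative angle sums, with the
#' convention that bout n's reorientation applies before its displacement;
#' positions are the cumulative sums x_k = sum_n d_n cos(theta_n),
#' y_k = sum_n d_n sin(theta_n) (degrees converted to radians only inside
#' cos/sin).
#'
#' @param boutStates character vector of per-bout states (F/L/R).
#' @param model a [BehaviorHMM-class] providing the emissions.
#' @param distancePool numeric vector of travel distances (mm), sampled
#'   with replacement.
#' @param times optional bout times (seconds) stored in the output.
#' @param seed integer seed.
#' @return a data.frame (one row per bout) with columns n, t, state,
#'   dtheta_deg, d_mm, theta_deg, x_mm, y_mm.
#' @export
synthesizeTrajectory <- function(boutStates, model, distancePool,
                                 times = NULL, seed = NULL) {
    stopifnot(length(boutStates) >= 1, all(boutStates %in% STATE_NAMES),
              length(distancePool) >= 1)
    withSeed(seed, {
        n <- length(boutStates)
        p <- emissionParams(model)
        ang <- numeric(n)
        iF <- boutStates == "F"; iL <- boutStates == "L"; iR <- boutStates == "R"
        ang[iF] <- rnorm(sum(iF), 0, p$sigmaF)
        ang[iL] <- rgamma(sum(iL), shape = p$alphaL, scale = p$thetaL)
        ang[iR] <- -rgamma(sum(iR), shape = p$alphaR, scale = p$thetaR)
        d <- distancePool[sample.int(length(distancePool), n,
                                     replace = TRUE)]
        theta <- cumsum(ang)
        data.frame(n = seq_len(n),
                   t = if (is.null(times)) seq_len(n) - 1 else times,
                   state = boutStates,
                   dtheta_deg = ang, d_mm = d, theta_deg = theta,
                   x_mm = cumsum(d * cos(theta * pi / 180)),
                   y_mm = cumsum(d * sin(theta * pi / 180)))
    })
}

.angleList <- function(trajectories) {
    if (is.data.frame(trajectories)) trajectories <- list(trajectories)
    if (is.numeric(trajectories)) trajectories <- list(trajectories)
    lapply(trajectories, function(tr)
        if (is.data.frame(tr)) tr$dtheta_deg else as.numeric(tr))
}

#' Mean Square Reorientation
#'
#' MSR(q) = <(theta_{n+q} - theta_n)^2>, the orientational analogue of the
#' mean squared displacement, computed after subtracting the dataset-mean
#' angle (bias correction: a constant angular drift would otherwise
#' masquerade as diffusion). The average runs over all valid n within each
#' trajectory, then over trajectories; heading differences never cross
#' trajectory boundaries.
#'
#' @param trajectories a trajectory data.frame from
#'   [synthesizeTrajectory()], a numeric angle vector, or a list of either.
#' @param qMax largest lag (bouts).
#' @return data.frame with columns q and msr (degrees^2); msr is NA at lags
#'   exceeding every trajectory length.
#' @export
msr <- function(trajectories, qMax) {
    angs <- .angleList(trajectories)
    mu <- mean(unlist(angs))
    out <- vapply(seq_len(qMax), function(q) {
        per <- vapply(angs, function(a) {
            n <- length(a)
            if (n < q) return(NA_real_)
            th0 <- c(0, cumsum(a - mu))       # headings theta_0 .. theta_n
            dth <- th0[(1 + q):(n + 1)] - th0[1:(n + 1 - q)]
            mean(dth^2)
        }, numeric(1))
        if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
    }, numeric(1))
    if (anyNA(out))
        warning("MSR undefined at lags exceeding every trajectory length")
    data.frame(q = seq_len(qMax), msr = out)
}

#' Diffusive / correlation decomposition of the MSR
#'
#' Writes MSR(q) as the sum of a purely diffusive term (the q-window mean
#' square of the centered angles, ~ q * Var(angle)) and a correlation term
#' (twice the summed within-window cross products, arising from
#' time-correlations in bout-type selection). The two terms use the same
#' window averaging as [msr()], so their sum reproduces MSR(q) to machine
#' precision.
#'
#' @param trajectories as in [msr()].
#' @param q lag (bouts).
#' @return list with `diffusive`, `correlation`, and `total` (their sum).
#' @export
msrDecomposition <- function(trajectories, q) {
    angs <- .angleList(trajectories)
    mu <- mean(unlist(angs))
    per <- vapply(angs, function(a) {
        n <- length(a)
        if (n < q) return(c(NA_real_, NA_real_))
        a <- a - mu
        th0 <- c(0, cumsum(a))
        s1 <- th0[(1 + q):(n + 1)] - th0[1:(n + 1 - q)]  # window angle sums
        c2 <- c(0, cumsum(a^2))
        s2 <- c2[(1 + q):(n + 1)] - c2[1:(n + 1 - q)]    # window square sums
        c(mean(s2), mean(s1^2 - s2))
    }, numeric(2))
    diffusive <- mean(per[1, ], na.rm = TRUE)
    correlation <- mean(per[2, ], na.rm = TRUE)
    list(diffusive = diffusive, correlation = correlation,
         total = diffusive + correlation)
}

#' Within-trajectory shuffle control
#'
#' Permutes the angles of each trajectory uniformly at random (lengths and
#' angle multisets preserved), destroying temporal correlations: the MSR of
#' shuffled persistent data collapses onto the diffusive line.
#'
#' @param trajectories list of numeric angle vectors (or trajectory
#'   data.frames; angles are extracted).
#' @param seed integer seed.
#' @return list of shuffled angle vectors.
#' @export
shuffleControl <- function(trajectories, seed = NULL) {
    angs <- .angleList(trajectories)
    withSeed(seed, lapply(angs, function(a)
        if (length(a) > 1) a[sample.int(length(a))] else a))
}
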