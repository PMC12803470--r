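LOG_FLOOR <- -1e6  # finite log-density floor outside a state's support

#' EM training settings
#'
#' @param maxIter maximum Baum-Welch iterations (default 500).
#' @param tol stop when the gain in total log-likelihood in one iteration
#'   falls below this threshold (default 1e-6).
#' @param restarts number of random restarts; the fit with the best final
#'   log-likelihood is kept.
#' @param seed integer seed controlling initialization (NULL: leave the RNG
#'   stream untouched).
#' @param symmetric enforce left-right symmetry (behavioral models).
#' @param threshold angular threshold (degrees) used only to moment-match
#'   the emission initialization.
#' @return a list of settings consumed by the fitting functions.
#' @export
hmmConfig <- function(maxIter = 500, tol = 1e-6, restarts = 5, seed = NULL,
                      symmetric = TRUE, threshold = 10) {
    stopifnot(maxIter >= 1, tol > 0, restarts >= 1)
    list(maxIter = maxIter, tol = tol, restarts = restarts, seed = seed,
         symmetric = symmetric, threshold = threshold)
}

#' Emission log-density of a reorientation angle
#'
#' Forward angles are Normal(0, sigmaF); left (right) turn angles are Gamma
#' distributed in magnitude with a positive (negative) sign. Outside a turn
#' state's half-line support the log-density is a finite floor (-1e6) rather
#' than -Inf, keeping the dynamic programming NaN-free; the forward state's
#' full support guarantees every observation has finite total likelihood.
#'
#' @param angle numeric vector of angles (degrees).
#' @param state one of "F", "L", "R".
#' @param model a [BehaviorHMM-class].
#' @return log-density, vectorized over `angle`.
#' @export
emissionLogpdf <- function(angle, state, model) {
    state <- match.arg(state, STATE_NAMES)
    p <- emissionParams(model)
    out <- switch(state,
        F = dnorm(angle, 0, p$sigmaF, log = TRUE),
        L = ifelse(angle > 0,
                   dgamma(angle, shape = p$alphaL, scale = p$thetaL,
                          log = TRUE), LOG_FLOOR),
        R = ifelse(angle < 0,
                   dgamma(-angle, shape = p$alphaR, scale = p$thetaR,
                          log = TRUE), LOG_FLOOR))
    out[!is.finite(out)] <- LOG_FLOOR
    out
}

# T x 3 matrix of emission log-densities for a pooled angle vector
.behaviorLogB <- function(angles, model) {
    cbind(F = emissionLogpdf(angles, "F", model),
          L = emissionLogpdf(angles, "L", model),
          R = emissionLogpdf(angles, "R", model))
}

# Cache of per-angle transforms reused across EM iterations: the Normal and
# Gamma log-densities are affine in (x^2, log x, x) given the parameters.
.makeLogBCache <- function(angles) {
    pos <- angles > 0
    neg <- angles < 0
    list(x2 = angles^2, pos = pos, neg = neg,
         logPos = log(angles[pos]), xPos = angles[pos],
         logNeg = log(-angles[neg]), xNeg = -angles[neg],
         n = length(angles))
}

.fastLogB <- function(cache, p) {
    lF <- -cache$x2 / (2 * p$sigmaF^2) - log(p$sigmaF) - 0.5 * log(2 * pi)
    lL <- rep(LOG_FLOOR, cache$n)
    lL[cache$pos] <- (p$alphaL - 1) * cache$logPos - cache$xPos / p$thetaL -
        p$alphaL * log(p$thetaL) - lgamma(p$alphaL)
    lR <- rep(LOG_FLOOR, cache$n)
    lR[cache$neg] <- (p$alphaR - 1) * cache$logNeg - cache$xNeg / p$thetaR -
        p$alphaR * log(p$thetaR) - lgamma(p$alphaR)
    lL[lL < LOG_FLOOR | !is.finite(lL)] <- LOG_FLOOR
    lR[lR < LOG_FLOOR | !is.finite(lR)] <- LOG_FLOOR
    cbind(lF, lL, lR)
}

.logSafe <- function(x) {
    out <- suppressWarnings(log(x))
    out[x <= 0] <- -Inf
    out
}

#' Total log-likelihood of an angle sequence
#'
#' Exact marginalization over all hidden paths by the forward recursion in
#' log space.
#'
#' @param angles numeric vector (one trajectory) or list of vectors; lists
#'   are summed over trajectories.
#' @param model a [BehaviorHMM-class].
#' @return total log-likelihood.
#' @export
sequenceLoglik <- function(angles, model) {
    if (is.list(angles))
        return(sum(vapply(angles, sequenceLoglik, numeric(1), model = model)))
    stopifnot(length(angles) >= 1)
    hmm_forward_loglik(.behaviorLogB(angles, model),
                       .logSafe(initialDistribution(model)),
                       .logSafe(transitionMatrix(model)))
}

#' Viterbi decoding of an angle sequence
#'
#' Maximum-a-posteriori hidden path; ties are broken toward the fixed state
#' order F < L < R.
#'
#' @param angles numeric vector of angles (degrees).
#' @param model a [BehaviorHMM-class].
#' @param withScore if TRUE, return `list(states, score)` where `score` is
#'   the joint log-probability of the MAP path.
#' @return a [StateSequence-class] (or a list, see `withScore`).
#' @export
viterbiDecode <- function(angles, model, withScore = FALSE) {
    stopifnot(length(angles) >= 1)
    v <- hmm_viterbi(.behaviorLogB(angles, model),
                     .logSafe(initialDistribution(model)),
                     .logSafe(transitionMatrix(model)))
    ss <- StateSequence(STATE_NAMES[v$path])
    if (withScore) list(states = ss, score = v$score) else ss
}

#' Ancestral sampling from a behavioral HMM
#'
#' @param model a [BehaviorHMM-class].
#' @param n number of bouts.
#' @param seed integer seed (NULL: use current RNG state).
#' @return `list(states = StateSequence, angles = numeric)`.
#' @export
sampleStatesAndAngles <- function(model, n, seed = NULL) {
    stopifnot(n >= 1)
    withSeed(seed, {
        idx <- sampleMarkovChain(transitionMatrix(model),
                                 initialDistribution(model), n)
        p <- emissionParams(model)
        angles <- numeric(n)
        iF <- idx == 1; iL <- idx == 2; iR <- idx == 3
        angles[iF] <- rnorm(sum(iF), 0, p$sigmaF)
        angles[iL] <- rgamma(sum(iL), shape = p$alphaL, scale = p$thetaL)
        angles[iR] <- -rgamma(sum(iR), shape = p$alphaR, scale = p$thetaR)
        list(states = StateSequence(STATE_NAMES[idx]), angles = angles)
    })
}

# Weighted Gamma maximum likelihood on positive magnitudes. Solves
# log(alpha) - digamma(alpha) = log(wmean(x)) - wmean(log x) by Newton
# iterations from the method-of-moments start; if the unconstrained
# solution has alpha <= 1 it is clamped to 1 + 1e-6 and theta maximized
# given alpha (theta = wmean(x)/alpha).
weightedGammaMLE <- function(x, w) {
    keep <- x > 0 & w > 0
    x <- x[keep]; w <- w[keep]
    if (length(x) < 2 || sum(w) <= 0)
        return(c(alpha = 1 + 1e-6, theta = 10))
    w <- w / sum(w)
    m <- sum(w * x)
    s <- log(m) - sum(w * log(x))
    if (s <= 1e-12) {
        alpha <- 1e4
    } else {
        alpha <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
        for (i in 1:50) {
            step <- (log(alpha) - digamma(alpha) - s) /
                    (1 / alpha - trigamma(alpha))
            alphaNew <- alpha - step
            if (alphaNew <= 0) alphaNew <- alpha / 2
            if (abs(alphaNew - alpha) < 1e-12 * alpha) { alpha <- alphaNew; break }
            alpha <- alphaNew
        }
    }
    if (alpha <= 1) alpha <- 1 + 1e-6
    c(alpha = alpha, theta = m / alpha)
}

# moment-matched emission start from threshold labels, with jitter per restart
.initBehaviorParams <- function(pooled, threshold, jitter = TRUE) {
    jf <- function() if (jitter) runif(1, 0.8, 1.25) else 1
    fwd <- pooled[abs(pooled) <= threshold]
    sigma <- max(sqrt(mean(fwd^2)), 1) * jf()
    mag <- abs(pooled[abs(pooled) > threshold])
    if (length(mag) >= 10) {
        m <- mean(mag); v <- max(var(mag), 1e-6)
        alpha <- max(m^2 / v, 1.05) * jf()
        theta <- (m / max(m^2 / v, 1.05)) * jf()
    } else {
        alpha <- 2 * jf(); theta <- 10 * jf()
    }
    list(sigma = sigma, alpha = max(alpha, 1.01), theta = max(theta, 0.1))
}

.initBehaviorTransition <- function(symmetric) {
    if (symmetric) {
        g <- rgamma(3, 2)          # (pFF, pFT, pFT) direction
        rowF <- g / sum(g)
        rowF <- c(rowF[1], rep((1 - rowF[1]) / 2, 2))
        g <- rgamma(3, 2)
        rowT <- g / sum(g)         # (pTF, pTT, pSwitch)
        P <- rbind(rowF,
                   c(rowT[1], rowT[2], rowT[3]),
                   c(rowT[1], rowT[3], rowT[2]))
    } else {
        P <- matrix(rgamma(9, 2), 3, 3)
        P <- P / rowSums(P)
    }
    dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    P
}

.symmetrizeTransition <- function(P) {
    out <- P
    out["F", "L"] <- out["F", "R"] <- (P["F", "L"] + P["F", "R"]) / 2
    out["L", "L"] <- out["R", "R"] <- (P["L", "L"] + P["R", "R"]) / 2
    out["L", "R"] <- out["R", "L"] <- (P["L", "R"] + P["R", "L"]) / 2
    out["L", "F"] <- out["R", "F"] <- (P["L", "F"] + P["R", "F"]) / 2
    out / rowSums(out)
}

# Exact M-step under the left-right symmetry ties: pool the expected
# transition counts over tied cells (the turn rows share one parameter set,
# so their counts pool across rows), then normalize. Averaging estimated
# probabilities instead would not maximize the constrained likelihood.
.symmetrizeCounts <- function(C) {
    fTurn <- (C["F", "L"] + C["F", "R"]) / 2
    rowF <- c(C["F", "F"], fTurn, fTurn)
    tf <- C["L", "F"] + C["R", "F"]
    tt <- C["L", "L"] + C["R", "R"]
    sw <- C["L", "R"] + C["R", "L"]
    rowT <- c(tf, tt, sw) / 2
    P <- rbind(rowF / sum(rowF),
               rowT[c(1, 2, 3)] / sum(rowT),
               rowT[c(1, 3, 2)] / sum(rowT))
    dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    P
}

#' Fit a behavioral HMM by Baum-Welch
#'
#' Expectation-maximization with an exact E-step (forward-backward per
#' trajectory) and closed-form M-steps: transitions from expected counts
#' (left-right symmetry enforced by averaging tied entries when
#' `config$symmetric`), sigmaF from the posterior-weighted second moment
#' about zero, and the turn Gamma parameters by weighted maximum likelihood
#' on angle magnitudes with the shape clamped to (1, Inf). Training stops
#' when the log-likelihood gain in one iteration drops below `config$tol`
#' (default 1e-6) or after `config$maxIter` (default 500) iterations.
#' Several random restarts are run and the best final log-likelihood kept;
#' a restart whose posterior starves a state is discarded.
#'
#' @param sequences list of numeric angle vectors (one per trajectory), or a
#'   single vector.
#' @param config settings from [hmmConfig()].
#' @return a fitted [BehaviorHMM-class]; the EM log-likelihood trace (one
#'   value per iteration, non-decreasing) is available via
#'   [trainingTrace()].
#' @export
fitBehaviorHMM <- function(sequences, config = hmmConfig()) {
    if (is.numeric(sequences)) sequences <- list(sequences)
    stopifnot(length(sequences) >= 1, all(lengths(sequences) >= 1))
    pooled <- unlist(sequences, use.names = FALSE)
    if (length(pooled) < 100)
        warning("fewer than 100 pooled bouts; estimates will be unstable")
    withSeed(config$seed, {
        best <- NULL
        for (r in seq_len(config$restarts)) {
            init <- if (r == 1) .informedBehaviorInit(sequences, pooled,
                                                      config) else NULL
            fit <- .behaviorEMOnce(sequences, pooled, config,
                                   jitter = (r > 1), init = init)
            if (is.null(fit)) next
            if (is.null(best) || fit$loglik > best$loglik) best <- fit
        }
        if (is.null(best))
            stop("all EM restarts ended with a starved state; increase restarts")
        if (!best$converged)
            warning("EM did not converge within maxIter; returning best fit")
        best$model
    })
}

# First-restart initialization: static mixture EM on (a subsample of) the
# pooled angles for the emissions, and symmetrized threshold-label
# transition estimates. Starts Baum-Welch near the optimum; later restarts
# use jittered moment-matching with random transitions.
.informedBehaviorInit <- function(sequences, pooled, config) {
    sub <- if (length(pooled) > 3e4)
        pooled[seq(1, length(pooled), length.out = 3e4)] else pooled
    mix <- tryCatch(.mixtureEMOnce(sub, maxIter = 200, tol = 1e-8,
                                   jitter = FALSE),
                    error = function(e) NULL)
    P <- tryCatch({
        labs <- lapply(sequences, function(a)
            states(thresholdLabel(a, config$threshold)))
        Pt <- suppressWarnings(estimateTransitions(labs, prior = 1))
        if (isTRUE(config$symmetric)) .symmetrizeTransition(Pt) else Pt
    }, error = function(e) NULL)
    if (is.null(mix) && is.null(P)) return(NULL)
    list(sigma = if (!is.null(mix)) mix$sigmaF else NULL,
         alpha = if (!is.null(mix)) mix$alpha else NULL,
         theta = if (!is.null(mix)) mix$theta else NULL,
         P = P)
}

.behaviorEMOnce <- function(sequences, pooled, config, jitter,
                            init = NULL) {
    symmetric <- isTRUE(config$symmetric)
    em0 <- .initBehaviorParams(pooled, config$threshold, jitter)
    if (!is.null(init)) {
        if (!is.null(init$sigma)) em0$sigma <- init$sigma
        if (!is.null(init$alpha)) em0$alpha <- max(init$alpha, 1.01)
        if (!is.null(init$theta)) em0$theta <- init$theta
    }
    P <- if (!is.null(init$P)) init$P else .initBehaviorTransition(symmetric)
    model <- BehaviorHMM(P, initial = rep(1 / 3, 3), sigmaF = em0$sigma,
                         alpha = em0$alpha, theta = em0$theta,
                         alphaL = em0$alpha, thetaL = em0$theta,
                         alphaR = em0$alpha, thetaR = em0$theta,
                         symmetric = symmetric)
    lens <- lengths(sequences)
    ends <- as.integer(cumsum(lens))
    starts <- as.integer(ends - lens + 1)
    cache <- .makeLogBCache(pooled)
    trace <- numeric(0)
    prevLL <- -Inf
    converged <- FALSE

    for (iter in seq_len(config$maxIter)) {
        logB <- .fastLogB(cache, emissionParams(model))
        fb <- hmm_estep_batch(logB, .logSafe(initialDistribution(model)),
                              .logSafe(transitionMatrix(model)),
                              starts, ends)
        gamma <- fb$gamma
        xi <- fb$xi
        dimnames(xi) <- list(STATE_NAMES, STATE_NAMES)
        gamma1 <- fb$gamma1
        ll <- fb$loglik
        if (ll < prevLL - 1e-8 * max(1, abs(prevLL)))
            stop("EM log-likelihood decreased: ", prevLL, " -> ", ll)
        trace <- c(trace, ll)
        occup <- colSums(gamma)
        if (any(occup < 1e-8 * length(pooled)))
            return(NULL)  # degenerate posterior: caller restarts

        gain <- ll - prevLL
        prevLL <- ll
        # M-step
        initNew <- gamma1 / sum(gamma1)
        if (symmetric) {
            Pnew <- .symmetrizeCounts(xi)
            initNew[2:3] <- mean(initNew[2:3])
        } else {
            Pnew <- xi / rowSums(xi)
        }
        sigma <- max(sqrt(sum(gamma[, 1] * pooled^2) / occup[1]), 1e-3)
        if (symmetric) {
            g <- weightedGammaMLE(c(pooled, -pooled),
                                  c(gamma[, 2], gamma[, 3]))
            aL <- aR <- g["alpha"]; tL <- tR <- g["theta"]
        } else {
            gl <- weightedGammaMLE(pooled, gamma[, 2])
            gr <- weightedGammaMLE(-pooled, gamma[, 3])
            aL <- gl["alpha"]; tL <- gl["theta"]
            aR <- gr["alpha"]; tR <- gr["theta"]
        }
        model <- BehaviorHMM(Pnew, initial = initNew, sigmaF = sigma,
                             alphaL = unname(aL), thetaL = unname(tL),
                             alphaR = unname(aR), thetaR = unname(tR),
                             symmetric = symmetric)
        if (iter > 1 && gain < config$tol) { converged <- TRUE; break }
    }
    model@fit <- list(trace = trace, loglik = prevLL,
                      iterations = length(trace), converged = converged,
                      seed = config$seed)
    list(model = model, loglik = prevLL, converged = converged)
}
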