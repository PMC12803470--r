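#' @import methods
#' @importFrom stats dnorm dgamma pnorm pgamma rnorm rgamma rlnorm runif
#'   rbinom quantile var sd lm coef optimize setNames
#' @importFrom utils head tail read.csv write.csv
NULL

STATE_NAMES <- c("F", "L", "R")

.checkStochastic <- function(P, K = nrow(P), tol = 1e-8) {
    msgs <- character(0)
    if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
        msgs <- c(msgs, sprintf("transition matrix must be %d x %d", K, K))
    else {
        if (any(P < -tol) || any(P > 1 + tol))
            msgs <- c(msgs, "transition entries must lie in [0, 1]")
        rs <- rowSums(P)
        if (any(abs(rs - 1) > 1e-6))
            msgs <- c(msgs, "transition rows must sum to 1")
    }
    msgs
}

#' Ordered hidden-state labels, with optional timestamps
#'
#' A `StateSequence` holds one trajectory's (or recording's) ordered hidden
#' states from \{F, L, R\} (or integer-coded states for unlabeled neural
#' models), together with optional strictly increasing timestamps in seconds.
#'
#' @slot states character vector of state labels.
#' @slot times numeric vector of timestamps (seconds); length 0 when absent.
#'
#' @examples
#' s <- StateSequence(c("L", "L", "F"), times = c(0, 1.1, 2.4))
#' states(s)
#' @export
setClass("StateSequence",
    representation(states = "character", times = "numeric"),
    prototype(states = character(0), times = numeric(0)))

setValidity("StateSequence", function(object) {
    msgs <- character(0)
    n <- length(object@states)
    nt <- length(object@times)
    if (nt > 0 && nt != n)
        msgs <- c(msgs, "times must match states in length")
    if (nt > 1 && any(diff(object@times) <= 0))
        msgs <- c(msgs, "times must be strictly increasing")
    if (length(msgs)) msgs else TRUE
})

#' @param states character vector of state labels.
#' @param times optional numeric timestamps (seconds).
#' @rdname StateSequence-class
#' @export
StateSequence <- function(states, times = numeric(0)) {
    new("StateSequence", states = as.character(states),
        times = as.numeric(times))
}

#' Three-state behavioral hidden Markov model
#'
#' Transition matrix over \{F, L, R\}, initial distribution, and emission
#' parameters: reorientation angles are Normal(0, sigmaF) in the forward
#' state and signed Gamma(alpha, theta) in the turn states (positive angles
#' for L, negative for R; angles and theta in degrees). When `symmetric` is
#' TRUE the left-right symmetry constraints of the non-handedness hypothesis
#' hold: P(F->L)=P(F->R), P(L->L)=P(R->R), P(L->R)=P(R->L), P(L->F)=P(R->F),
#' and the two turn states share (alpha, theta).
#'
#' @slot transition 3x3 row-stochastic matrix with dimnames F, L, R.
#' @slot initial length-3 initial state distribution.
#' @slot sigmaF Normal scale of forward-state angles (degrees).
#' @slot alphaL,alphaR Gamma shapes (> 1) of the turn emissions.
#' @slot thetaL,thetaR Gamma scales (degrees) of the turn emissions.
#' @slot symmetric logical; left-right symmetry constraints enforced.
#' @slot fit list of training metadata (loglik trace, iterations, seed, ...).
#' @export
setClass("BehaviorHMM",
    representation(transition = "matrix", initial = "numeric",
        sigmaF = "numeric", alphaL = "numeric", thetaL = "numeric",
        alphaR = "numeric", thetaR = "numeric", symmetric = "logical",
        fit = "list"))

setValidity("BehaviorHMM", function(object) {
    msgs <- .checkStochastic(object@transition, 3)
    if (!identical(rownames(object@transition), STATE_NAMES) ||
        !identical(colnames(object@transition), STATE_NAMES))
        msgs <- c(msgs, "transition dimnames must be F, L, R")
    if (length(object@initial) != 3 || abs(sum(object@initial) - 1) > 1e-6 ||
        any(object@initial < -1e-12))
        msgs <- c(msgs, "initial must be a probability triple")
    if (object@sigmaF <= 0) msgs <- c(msgs, "sigmaF must be > 0")
    if (object@alphaL <= 1 || object@alphaR <= 1)
        msgs <- c(msgs, "Gamma shapes must be > 1")
    if (object@thetaL <= 0 || object@thetaR <= 0)
        msgs <- c(msgs, "Gamma scales must be > 0")
    if (object@symmetric) {
        P <- object@transition
        tol <- 1e-8
        if (abs(P["F", "L"] - P["F", "R"]) > tol ||
            abs(P["L", "L"] - P["R", "R"]) > tol ||
            abs(P["L", "R"] - P["R", "L"]) > tol ||
            abs(P["L", "F"] - P["R", "F"]) > tol)
            msgs <- c(msgs, "symmetric model violates transition symmetry")
        if (abs(object@alphaL - object@alphaR) > tol ||
            abs(object@thetaL - object@thetaR) > tol)
            msgs <- c(msgs, "symmetric model requires shared (alpha, theta)")
    }
    if (length(msgs)) msgs else TRUE
})

#' @param transition 3x3 row-stochastic matrix (rows/cols F, L, R).
#' @param initial probability triple; default: stationary distribution of
#'   `transition`.
#' @param sigmaF forward Normal scale in degrees.
#' @param alpha,theta Gamma shape (> 1) and scale (degrees) shared by the
#'   two turn states (symmetric model).
#' @param alphaL,thetaL,alphaR,thetaR per-side Gamma parameters for an
#'   unconstrained model; default to `alpha`, `theta`.
#' @param symmetric logical flag.
#' @param fit optional list of training metadata.
#' @rdname BehaviorHMM-class
#' @export
BehaviorHMM <- function(transition, initial = NULL, sigmaF = 15,
                        alpha = 2, theta = 10,
                        alphaL = alpha, thetaL = theta,
                        alphaR = alpha, thetaR = theta,
                        symmetric = TRUE, fit = list()) {
    transition <- as.matrix(transition)
    dimnames(transition) <- list(STATE_NAMES, STATE_NAMES)
    if (is.null(initial))
        initial <- stationaryDistribution(transition)
    new("BehaviorHMM", transition = transition,
        initial = as.numeric(initial), sigmaF = sigmaF,
        alphaL = alphaL, thetaL = thetaL, alphaR = alphaR, thetaR = thetaR,
        symmetric = symmetric, fit = fit)
}

#' K-state Bernoulli-emission neural hidden Markov model
#'
#' Emissions are independent per-neuron Bernoulli draws: neuron i fires in
#' state s with probability logistic(h_i^s), where h_i^s is the local field
#' (effective excitability). `stateLabels` maps states onto \{F, L, R\} once
#' the model has been labeled by lateralized excitability.
#'
#' @slot transition K x K row-stochastic matrix.
#' @slot initial length-K initial distribution.
#' @slot fields K x N matrix of local fields h_i^s (rows = states).
#' @slot stateLabels character of length K (\code{NA_character_} before
#'   labeling).
#' @slot fit list of training metadata.
#' @export
setClass("NeuralHMM",
    representation(transition = "matrix", initial = "numeric",
        fields = "matrix", stateLabels = "character", fit = "list"))

setValidity("NeuralHMM", function(object) {
    K <- nrow(object@transition)
    msgs <- .checkStochastic(object@transition, K)
    if (K < 1) msgs <- c(msgs, "K must be >= 1")
    if (length(object@initial) != K ||
        abs(sum(object@initial) - 1) > 1e-6 || any(object@initial < -1e-12))
        msgs <- c(msgs, "initial must be a length-K probability vector")
    if (nrow(object@fields) != K)
        msgs <- c(msgs, "fields must have one row per state")
    if (any(!is.finite(object@fields)))
        msgs <- c(msgs, "fields must be finite")
    if (!all(is.na(object@stateLabels))) {
        if (length(object@stateLabels) != K)
            msgs <- c(msgs, "stateLabels must have length K")
        if (K == 3 && !setequal(object@stateLabels, STATE_NAMES))
            msgs <- c(msgs, "3-state labels must be a permutation of F, L, R")
    }
    if (length(msgs)) msgs else TRUE
})

#' @param transition K x K row-stochastic matrix.
#' @param fields K x N field matrix.
#' @param initial probability vector; default stationary distribution.
#' @param stateLabels optional character of length K.
#' @param fit optional list of training metadata.
#' @rdname NeuralHMM-class
#' @export
NeuralHMM <- function(transition, fields, initial = NULL,
                      stateLabels = NA_character_, fit = list()) {
    transition <- as.matrix(transition)
    fields <- as.matrix(fields)
    if (is.null(initial))
        initial <- stationaryDistribution(transition)
    new("NeuralHMM", transition = transition, initial = as.numeric(initial),
        fields = fields, stateLabels = as.character(stateLabels), fit = fit)
}

#' Binarized neural raster
#'
#' A `NeuralRaster` extends [SummarizedExperiment::SummarizedExperiment]:
#' the `"activity"` assay is the binary neurons x frames spike matrix,
#' `rowData(x)$side` carries the left/right ARTR assignment of each neuron,
#' and `metadata(x)$frame_rate_hz` the acquisition rate.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("NeuralRaster", contains = "SummarizedExperiment")

setValidity("NeuralRaster", function(object) {
    msgs <- character(0)
    if (!"activity" %in% SummarizedExperiment::assayNames(object))
        return("missing 'activity' assay")
    a <- SummarizedExperiment::assay(object, "activity")
    if (!all(a %in% c(0, 1)))
        msgs <- c(msgs, "activity must be binary")
    side <- SummarizedExperiment::rowData(object)$side
    if (is.null(side) || !all(side %in% c("left", "right")))
        msgs <- c(msgs, "rowData(x)$side must be 'left'/'right'")
    else if (!all(c("left", "right") %in% side))
        msgs <- c(msgs, "need at least one neuron per side")
    nu <- S4Vectors::metadata(object)$frame_rate_hz
    if (is.null(nu) || !is.numeric(nu) || nu <= 0)
        msgs <- c(msgs, "metadata frame_rate_hz must be > 0")
    if (length(msgs)) msgs else TRUE
})

#' @param activity binary neurons x frames matrix.
#' @param side character vector ('left'/'right'), one entry per neuron.
#' @param frameRate acquisition rate in Hz.
#' @rdname NeuralRaster-class
#' @export
NeuralRaster <- function(activity, side, frameRate) {
    activity <- as.matrix(activity)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(activity = activity),
        rowData = S4Vectors::DataFrame(side = as.character(side)),
        metadata = list(frame_rate_hz = frameRate))
    new("NeuralRaster", se)
}

#' Ground truth for the synthetic-data generators
#'
#' Bundles a behavioral model, a neural model, the neural-to-behavioral
#' temporal scaling factor, the neural frame rate, and the inter-bout
#' interval / travel distance sampling laws, so that every downstream stage
#' can be validated against known parameters.
#'
#' @slot behavior a [BehaviorHMM-class].
#' @slot neural a [NeuralHMM-class].
#' @slot scalingFactor f_N/B in (0, 1]: behavioral sojourn times are, in
#'   distribution, scalingFactor times the neural ones.
#' @slot frameRate neural acquisition rate nu (Hz).
#' @slot intervalDist named list: inter-bout interval law (seconds).
#' @slot distanceDist named list: per-bout travel distance law (mm).
#' @slot seed integer root seed.
#' @export
setClass("GroundTruth",
    representation(behavior = "BehaviorHMM", neural = "NeuralHMM",
        scalingFactor = "numeric", frameRate = "numeric",
        intervalDist = "list", distanceDist = "list", seed = "integer"))

setValidity("GroundTruth", function(object) {
    msgs <- character(0)
    if (object@scalingFactor <= 0 || object@scalingFactor > 1)
        msgs <- c(msgs, "scalingFactor must lie in (0, 1]")
    if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
    for (d in list(object@intervalDist, object@distanceDist))
        if (is.null(d$name)) msgs <- c(msgs, "distributions need a 'name'")
    if (length(msgs)) msgs else TRUE
})
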