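log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Bernoulli emission log-probability of a neuronal configuration
#'
#' Under the independent-neuron emission model, a binary configuration
#' (sigma_1, ..., sigma_N) has, in state s,
#' log P = sum_i [h_i^s sigma_i - log(1 + exp(h_i^s))], evaluated with a
#' numerically stable log1p-exp.
#'
#' @param config binary vector of length N (one frame).
#' @param state state index (row of the field matrix).
#' @param model a [NeuralHMM-class].
#' @return log-probability.
#' @export
neuralEmissionLoglik <- function(config, state, model) {
    h <- fieldsMatrix(model)[state, ]
    stopifnot(length(config) == length(h))
    sum(h * config) - sum(log1pexp(h))
}

# T x K matrix of emission log-probabilities; X is the N x T activity matrix
.neuralLogB <- function(X, fields) {
    const <- rowSums(log1pexp(fields))          # per state
    sweep(crossprod(X, t(fields)), 2, const, "-")
}

#' Label neural states by lateralized excitability
#'
#' Computes, for each state s, the lateralized excitability
#' Delta h_s = <logistic(h_i^s)>_{i in left} - <logistic(h_i^s)>_{i in right}
#' and permutes the states so that Delta h_L > Delta h_F > Delta h_R. The
#' returned model is reordered into the canonical (F, L, R) state order;
#' relabeling is a pure permutation and leaves the data likelihood
#' unchanged.
#'
#' @param model a 3-state [NeuralHMM-class].
#' @param side per-neuron 'left'/'right' labels (e.g. [sideLabels()] of the
#'   raster the model was fitted to).
#' @return the labeled [NeuralHMM-class].
#' @export
labelNeuralStates <- function(model, side) {
    H <- fieldsMatrix(model)
    K <- nrow(H)
    if (K != 3) stop("state labeling is defined for 3-state models")
    stopifnot(length(side) == ncol(H), all(side %in% c("left", "right")))
    dh <- rowMeans(logistic(H[, side == "left", drop = FALSE])) -
          rowMeans(logistic(H[, side == "right", drop = FALSE]))
    if (min(abs(diff(sort(dh)))) < 1e-12)
        stop("degenerate fit: lateralized excitabilities are tied")
    ord <- order(dh)[c(2, 3, 1)]  # middle -> F, largest -> L, smallest -> R
    P <- transitionMatrix(model)[ord, ord, drop = FALSE]
    dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    H <- H[ord, , drop = FALSE]
    rownames(H) <- STATE_NAMES
    NeuralHMM(P, H,
              initial = initialDistribution(model)[ord],
              stateLabels = STATE_NAMES, fit = model@fit)
}

#' Viterbi decoding of a neural raster
#'
#' @param raster a [NeuralRaster-class].
#' @param model a labeled [NeuralHMM-class].
#' @param withScore if TRUE, return `list(states, score)`.
#' @return a [StateSequence-class] with frame timestamps
#'   (frame index - 1) / frame rate.
#' @export
decodeRaster <- function(raster, model, withScore = FALSE) {
    X <- activityMatrix(raster)
    v <- hmm_viterbi(.neuralLogB(X, fieldsMatrix(model)),
                     .logSafe(initialDistribution(model)),
                     .logSafe(transitionMatrix(model)))
    labs <- stateLabels(model)
    if (all(is.na(labs))) labs <- as.character(seq_len(nrow(fieldsMatrix(model))))
    ss <- StateSequence(labs[v$path],
                        times = (seq_len(ncol(X)) - 1) / frameRate(raster))
    if (withScore) list(states = ss, score = v$score) else ss
}

#' Total log-likelihood of a raster under a neural HMM
#'
#' @param raster a [NeuralRaster-class].
#' @param model a [NeuralHMM-class].
#' @return total log-likelihood (forward recursion).
#' @export
rasterLoglik <- function(raster, model) {
    hmm_forward_loglik(.neuralLogB(activityMatrix(raster),
                                   fieldsMatrix(model)),
                       .logSafe(initialDistribution(model)),
                       .logSafe(transitionMatrix(model)))
}

#' Sample a synthetic raster from a neural HMM
#'
#' Ancestral state sampling followed by independent per-neuron Bernoulli
#' emissions with firing probability logistic(h_i^s).
#'
#' @param model a [NeuralHMM-class].
#' @param nFrames number of frames.
#' @param frameRate acquisition rate (Hz) recorded in the output.
#' @param side per-neuron side labels; default: first half 'left'.
#' @param seed integer seed.
#' @return a [NeuralRaster-class]; the generating state sequence is kept in
#'   `metadata(x)$states`.
#' @export
sampleRaster <- function(model, nFrames, frameRate = 1, side = NULL,
                         seed = NULL) {
    stopifnot(nFrames >= 1)
    H <- fieldsMatrix(model)
    N <- ncol(H)
    if (is.null(side))
        side <- rep(c("left", "right"), c(ceiling(N / 2), floor(N / 2)))
    withSeed(seed, {
        st <- sampleMarkovChain(transitionMatrix(model),
                                initialDistribution(model), nFrames)
        p <- logistic(H)                       # K x N
        X <- matrix(runif(N * nFrames), N, nFrames) < t(p)[, st]
        storage.mode(X) <- "integer"
        labs <- stateLabels(model)
        stlab <- if (all(is.na(labs))) as.character(st) else labs[st]
        r <- NeuralRaster(X, side, frameRate)
        S4Vectors::metadata(r)$states <-
            StateSequence(stlab, times = (seq_len(nFrames) - 1) / frameRate)
        r
    })
}

.initNeuralModel <- function(X, K, jitter) {
    N <- nrow(X)   # neurons; columns of X are frames
    pbar <- pmin(pmax(rowMeans(X), 1e-3), 1 - 1e-3)
    H <- matrix(rep(logit(pbar), each = K), K, N)
    if (jitter || K > 1) H <- H + matrix(rnorm(K * N, 0, 1), K, N)
    A <- matrix(rgamma(K * K, 1), K, K) + diag(K, K)
    A <- A / rowSums(A)
    NeuralHMM(A, H, initial = rep(1 / K, K))
}

#' Fit a Bernoulli-emission neural HMM by Baum-Welch
#'
#' Exact E-step (forward-backward) and closed-form M-step: the field of
#' neuron i in state s is the logit of the posterior-weighted mean activity
#' of that neuron under state s, clipped to [1e-6, 1-1e-6] to keep fields
#' finite. No left-right handedness constraint is imposed. Stopping and
#' restart rules as in [fitBehaviorHMM()].
#'
#' @param raster a [NeuralRaster-class].
#' @param K number of hidden states (default 3).
#' @param config settings from [hmmConfig()].
#' @param segments optional list of frame-index vectors treated as
#'   independent contiguous recordings (used by cross-validation); default:
#'   the whole raster is one sequence.
#' @return a fitted, unlabeled [NeuralHMM-class]; apply
#'   [labelNeuralStates()] to map states onto F/L/R.
#' @export
fitNeuralHMM <- function(raster, K = 3, config = hmmConfig(),
                         segments = NULL) {
    X <- activityMatrix(raster)
    storage.mode(X) <- "double"
    if (ncol(X) < 10 * K)
        stop("need at least 10*K frames to fit ", K, " states")
    if (is.null(segments)) segments <- list(seq_len(ncol(X)))
    withSeed(config$seed, {
        best <- NULL
        for (r in seq_len(config$restarts)) {
            fit <- .neuralEMOnce(X, K, segments, config, jitter = (r > 1))
            if (is.null(fit)) next
            if (is.null(best) || fit$loglik > best$loglik) best <- fit
        }
        if (is.null(best))
            stop("all EM restarts ended with a starved state; increase restarts")
        best$model
    })
}

.neuralEMOnce <- function(X, K, segments, config, jitter) {
    model <- .initNeuralModel(X, K, jitter)
    Tn <- ncol(X)
    trace <- numeric(0)
    prevLL <- -Inf
    converged <- FALSE
    # segments may be non-contiguous in the raster: concatenate them once
    idxAll <- unlist(segments, use.names = FALSE)
    lens <- lengths(segments)
    segEnds <- as.integer(cumsum(lens))
    segStarts <- as.integer(segEnds - lens + 1)
    Xs <- X[, idxAll, drop = FALSE]
    for (iter in seq_len(config$maxIter)) {
        logB <- .neuralLogB(Xs, model@fields)
        fb <- hmm_estep_batch(logB, .logSafe(model@initial),
                              .logSafe(model@transition),
                              segStarts, segEnds)
        gamma <- fb$gamma
        xi <- fb$xi
        gamma1 <- fb$gamma1
        ll <- fb$loglik
        if (ll < prevLL - 1e-8 * max(1, abs(prevLL)))
            stop("EM log-likelihood decreased: ", prevLL, " -> ", ll)
        trace <- c(trace, ll)
        occup <- colSums(gamma)
        if (any(occup < 1e-8 * ncol(Xs))) return(NULL)
        gain <- ll - prevLL
        prevLL <- ll
        pis <- pmin(pmax(t(Xs %*% gamma) / occup, 1e-6), 1 - 1e-6)  # K x N
        H <- logit(pis)
        A <- if (K == 1) matrix(1, 1, 1) else xi / rowSums(xi)
        model <- NeuralHMM(A, H, initial = gamma1 / sum(gamma1),
                           stateLabels = NA_character_)
        if (iter > 1 && gain < config$tol) { converged <- TRUE; break }
    }
    model@fit <- list(trace = trace, loglik = prevLL,
                      iterations = length(trace), converged = converged,
                      seed = config$seed)
    list(model = model, loglik = prevLL, converged = converged)
}

#' Stationary one- and two-point moments implied by a neural HMM
#'
#' Mean activities <sigma_i> = sum_s pi_s p_i^s and, for i != j, second
#' moments <sigma_i sigma_j> = sum_s pi_s p_i^s p_j^s (neurons are
#' conditionally independent within a state).
#'
#' @param model a [NeuralHMM-class].
#' @return list with `mean` (length N) and `second` (N x N, diagonal =
#'   mean).
#' @export
neuralMoments <- function(model) {
    p <- logistic(fieldsMatrix(model))           # K x N
    pi <- stationaryDistribution(transitionMatrix(model))
    m <- as.numeric(pi %*% p)
    M2 <- t(p) %*% (pi * p)
    diag(M2) <- m
    list(mean = m, second = M2)
}

#' Cross-validation over the number of hidden states
#'
#' Splits the recording into contiguous blocks; for each held-out block a
#' model with K states is trained on the remaining blocks (treated as
#' independent sequences) and scored on the withheld frames: average
#' log-likelihood per frame, and the Pearson correlation between the
#' model-implied two-point moments <sigma_i sigma_j> and their empirical
#' counterparts on the withheld block.
#'
#' @param raster a [NeuralRaster-class].
#' @param Ks integer vector of state counts to compare.
#' @param folds number of contiguous blocks (default 3).
#' @param config settings from [hmmConfig()].
#' @param seed integer seed.
#' @return data.frame with one row per (K, fold): heldoutLoglikPerFrame and
#'   momentCorrelation.
#' @export
crossValidateStates <- function(raster, Ks, folds = 3,
                                config = hmmConfig(restarts = 2),
                                seed = NULL) {
    stopifnot(length(Ks) >= 1, folds >= 2)
    X <- activityMatrix(raster)
    Tn <- ncol(X)
    bounds <- floor(seq(0, Tn, length.out = folds + 1))
    if (min(diff(bounds)) < 10 * max(Ks))
        stop("cross-validation blocks too short for the largest K")
    blocks <- lapply(seq_len(folds),
                     function(f) (bounds[f] + 1):bounds[f + 1])
    out <- list()
    for (K in Ks) for (f in seq_len(folds)) {
        train <- blocks[-f]
        cfg <- config
        cfg$seed <- substreamSeed(if (is.null(seed)) 1L else seed,
                                  K * 100 + f)
        fit <- fitNeuralHMM(raster, K = K, config = cfg, segments = train)
        test <- blocks[[f]]
        Xt <- X[, test, drop = FALSE]
        pi <- stationaryDistribution(transitionMatrix(fit))
        ll <- hmm_forward_loglik(.neuralLogB(Xt, fieldsMatrix(fit)),
                                 .logSafe(pi),
                                 .logSafe(transitionMatrix(fit)))
        mom <- neuralMoments(fit)
        emp <- tcrossprod(Xt) / ncol(Xt)
        ut <- upper.tri(emp)
        out[[length(out) + 1]] <- data.frame(
            K = K, fold = f,
            heldoutLoglikPerFrame = ll / ncol(Xt),
            momentCorrelation = cor(mom$second[ut], emp[ut]))
    }
    do.call(rbind, out)
}

#' @importFrom stats cor
NULL
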