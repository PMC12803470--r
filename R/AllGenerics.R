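#' Accessors for swimHMM model and data classes
#'
#' @param object a swimHMM object.
#' @return `transitionMatrix` the row-stochastic transition matrix;
#'   `initialDistribution` the initial state distribution; `states` the
#'   ordered state labels of a [StateSequence-class]; `stateTimes` its
#'   timestamps (length 0 when absent); `emissionParams` a named list of
#'   emission parameters; `fieldsMatrix` the K x N local-field matrix;
#'   `stateLabels` the state -> \{F,L,R\} assignment; `sideLabels` the
#'   per-neuron left/right labels; `activityMatrix` the binary raster;
#'   `frameRate` the acquisition rate (Hz); `trainingTrace` the EM
#'   log-likelihood trace of a fitted model.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("initialDistribution", function(object) standardGeneric("initialDistribution"))
#' @rdname accessors
#' @export
setGeneric("states", function(object) standardGeneric("states"))
#' @rdname accessors
#' @export
setGeneric("stateTimes", function(object) standardGeneric("stateTimes"))
#' @rdname accessors
#' @export
setGeneric("emissionParams", function(object) standardGeneric("emissionParams"))
#' @rdname accessors
#' @export
setGeneric("fieldsMatrix", function(object) standardGeneric("fieldsMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("sideLabels", function(object) standardGeneric("sideLabels"))
#' @rdname accessors
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("trainingTrace", function(object) standardGeneric("trainingTrace"))

#' @rdname accessors
setMethod("transitionMatrix", "BehaviorHMM", function(object) object@transition)
#' @rdname accessors
setMethod("transitionMatrix", "NeuralHMM", function(object) object@transition)
#' @rdname accessors
setMethod("initialDistribution", "BehaviorHMM", function(object) object@initial)
#' @rdname accessors
setMethod("initialDistribution", "NeuralHMM", function(object) object@initial)
#' @rdname accessors
setMethod("states", "StateSequence", function(object) object@states)
#' @rdname accessors
setMethod("stateTimes", "StateSequence", function(object) object@times)
#' @rdname accessors
setMethod("emissionParams", "BehaviorHMM", function(object)
    list(sigmaF = object@sigmaF, alphaL = object@alphaL,
         thetaL = object@thetaL, alphaR = object@alphaR,
         thetaR = object@thetaR, symmetric = object@symmetric))
#' @rdname accessors
setMethod("fieldsMatrix", "NeuralHMM", function(object) object@fields)
#' @rdname accessors
setMethod("stateLabels", "NeuralHMM", function(object) object@stateLabels)
#' @rdname accessors
setMethod("sideLabels", "NeuralRaster", function(object)
    SummarizedExperiment::rowData(object)$side)
#' @rdname accessors
setMethod("activityMatrix", "NeuralRaster", function(object)
    SummarizedExperiment::assay(object, "activity"))
#' @rdname accessors
setMethod("frameRate", "NeuralRaster", function(object)
    S4Vectors::metadata(object)$frame_rate_hz)
#' @rdname accessors
setMethod("trainingTrace", "BehaviorHMM", function(object) object@fit$trace)
#' @rdname accessors
setMethod("trainingTrace", "NeuralHMM", function(object) object@fit$trace)

setMethod("length", "StateSequence", function(x) length(x@states))

setMethod("show", "StateSequence", function(object) {
    n <- length(object@states)
    cat(sprintf("StateSequence of %d states%s\n", n,
        if (length(object@times)) " (timed)" else ""))
    if (n) cat(" ", paste(head(object@states, 12), collapse = " "),
               if (n > 12) "..." else "", "\n")
})

setMethod("show", "BehaviorHMM", function(object) {
    cat(sprintf("BehaviorHMM (%s)\n",
        if (object@symmetric) "left-right symmetric" else "unconstrained"))
    cat("transition:\n")
    print(round(object@transition, 4))
    cat(sprintf("emissions: F ~ Normal(0, %.3g deg); turns ~ Gamma(shape %.3g/%.3g, scale %.3g/%.3g deg)\n",
        object@sigmaF, object@alphaL, object@alphaR,
        object@thetaL, object@thetaR))
    if (!is.null(object@fit$loglik))
        cat(sprintf("final log-likelihood: %.4f (%d EM iterations)\n",
            object@fit$loglik, object@fit$iterations))
})

setMethod("show", "NeuralHMM", function(object) {
    K <- nrow(object@transition)
    cat(sprintf("NeuralHMM: %d states, %d neurons%s\n", K,
        ncol(object@fields),
        if (all(is.na(object@stateLabels))) " (unlabeled)"
        else paste0(" [", paste(object@stateLabels, collapse = ","), "]")))
    cat("transition:\n")
    print(round(object@transition, 4))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: f_N/B = %.3g, nu = %.3g Hz, seed = %d\n",
        object@scalingFactor, object@frameRate, object@seed))
    cat(sprintf("intervals: %s; distances: %s\n",
        object@intervalDist$name, object@distanceDist$name))
})
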