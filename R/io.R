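SCHEMA_VERSION <- 1L

#' Read a bout table
#'
#' Bout tables are UTF-8 CSV files with a header and '.' decimal separator.
#' Required columns: trajectory_id, t (seconds), dtheta_deg; optional:
#' dt_s, d_mm, x_mm, y_mm. Rows are grouped by trajectory and ordered by t.
#'
#' @param path file path.
#' @return named list of per-trajectory data.frames (angles in degrees,
#'   times in seconds, distances in mm).
#' @export
readBoutTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("trajectory_id", "t", "dtheta_deg")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    keep <- intersect(c(need, "dt_s", "d_mm", "x_mm", "y_mm"), names(df))
    df <- df[keep]
    out <- split(df, df$trajectory_id)
    out <- lapply(out, function(tr) {
        tr <- tr[order(tr$t), , drop = FALSE]
        if (any(diff(tr$t) <= 0)) {
            bad <- which(diff(tr$t) <= 0)[1] + 1
            stop("non-monotone times in trajectory '", tr$trajectory_id[1],
                 "' at row ", bad)
        }
        rownames(tr) <- NULL
        tr[setdiff(names(tr), "trajectory_id")]
    })
    out
}

#' Write a bout table
#'
#' @param bouts list of per-trajectory data.frames (columns t, dtheta_deg,
#'   optionally dt_s, d_mm, x_mm, y_mm); names (or indices) become
#'   trajectory ids.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeBoutTable <- function(bouts, path) {
    ids <- names(bouts)
    if (is.null(ids)) ids <- as.character(seq_along(bouts))
    rows <- mapply(function(tr, id)
        cbind(trajectory_id = id, tr), bouts, ids, SIMPLIFY = FALSE)
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Serialize a behavioral HMM to JSON
#'
#' Keys: schema_version, states, transition (row-major 3x3), initial,
#' sigma_f, alpha, theta, symmetric, and training metadata (iterations,
#' final_loglik, seed).
#'
#' @param model a [BehaviorHMM-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBehaviorHMM <- function(model, path) {
    p <- emissionParams(model)
    obj <- list(schema_version = SCHEMA_VERSION,
                type = "behavior_hmm",
                states = STATE_NAMES,
                transition = as.numeric(t(transitionMatrix(model))),
                initial = initialDistribution(model),
                sigma_f = p$sigmaF,
                alpha = c(p$alphaL, p$alphaR),
                theta = c(p$thetaL, p$thetaR),
                symmetric = p$symmetric,
                training = list(iterations = model@fit$iterations,
                                final_loglik = model@fit$loglik,
                                seed = model@fit$seed))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read a behavioral HMM from JSON
#'
#' @param path path to a file written by [writeBehaviorHMM()].
#' @return a [BehaviorHMM-class].
#' @export
readBehaviorHMM <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "behavior_hmm"))
        stop("not a behavioral model file: ", path)
    P <- matrix(obj$transition, 3, 3, byrow = TRUE,
                dimnames = list(STATE_NAMES, STATE_NAMES))
    BehaviorHMM(P, initial = obj$initial, sigmaF = obj$sigma_f,
                alphaL = obj$alpha[1], thetaL = obj$theta[1],
                alphaR = obj$alpha[2], thetaR = obj$theta[2],
                symmetric = obj$symmetric,
                fit = list(iterations = obj$training$iterations,
                           loglik = obj$training$final_loglik,
                           seed = obj$training$seed))
}

#' Serialize a neural HMM to JSON
#'
#' @param model a [NeuralHMM-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNeuralHMM <- function(model, path) {
    K <- nrow(transitionMatrix(model))
    obj <- list(schema_version = SCHEMA_VERSION,
                type = "neural_hmm", K = K,
                transition = as.numeric(t(transitionMatrix(model))),
                initial = initialDistribution(model),
                fields = as.numeric(t(fieldsMatrix(model))),  # row-major K x N
                n_neurons = ncol(fieldsMatrix(model)),
                state_labels = stateLabels(model),
                training = list(iterations = model@fit$iterations,
                                final_loglik = model@fit$loglik,
                                seed = model@fit$seed))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read a neural HMM from JSON
#'
#' @param path path to a file written by [writeNeuralHMM()].
#' @return a [NeuralHMM-class].
#' @export
readNeuralHMM <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "neural_hmm"))
        stop("not a neural model file: ", path)
    K <- obj$K
    P <- matrix(obj$transition, K, K, byrow = TRUE)
    H <- matrix(obj$fields, K, obj$n_neurons, byrow = TRUE)
    labs <- obj$state_labels
    if (is.null(labs)) labs <- NA_character_
    NeuralHMM(P, H, initial = obj$initial, stateLabels = labs,
              fit = list(iterations = obj$training$iterations,
                         loglik = obj$training$final_loglik,
                         seed = obj$training$seed))
}

#' Serialize a ground truth to JSON
#'
#' Saves the generator configuration (embedded behavioral and neural model
#' files are written alongside with suffixes `.behavior.json` /
#' `.neural.json`).
#'
#' @param truth a [GroundTruth-class].
#' @param path output path for the main JSON.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    writeBehaviorHMM(truth@behavior, paste0(path, ".behavior.json"))
    writeNeuralHMM(truth@neural, paste0(path, ".neural.json"))
    obj <- list(schema_version = SCHEMA_VERSION, type = "ground_truth",
                scaling_factor = truth@scalingFactor,
                frame_rate_hz = truth@frameRate,
                interval_dist = truth@intervalDist,
                distance_dist = truth@distanceDist,
                seed = truth@seed,
                behavior_file = paste0(basename(path), ".behavior.json"),
                neural_file = paste0(basename(path), ".neural.json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write / read a neural raster as delimited text
#'
#' The raster is stored as a CSV whose first column is the per-neuron side
#' label and remaining columns the 0/1 activity per frame, plus a JSON
#' sidecar `<path>.meta.json` carrying the frame rate.
#'
#' @param raster a [NeuralRaster-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeNeuralRaster <- function(raster, path) {
    X <- activityMatrix(raster)
    df <- data.frame(side = sideLabels(raster), X)
    names(df) <- c("side", paste0("f", seq_len(ncol(X))))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                              frame_rate_hz = frameRate(raster)),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeNeuralRaster
#' @export
readNeuralRaster <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"side" %in% names(df)) stop("missing 'side' column")
    meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                                simplifyVector = TRUE)
    X <- as.matrix(df[setdiff(names(df), "side")])
    dimnames(X) <- NULL
    NeuralRaster(X, df$side, meta$frame_rate_hz)
}
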