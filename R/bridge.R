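#' Sojourn times of a timed state sequence
#'
#' For each maximal run of identical consecutive states the sojourn time is
#' the last minus the first timestamp of the run (length-1 runs contribute
#' 0 s).
#'
#' @param seq a [StateSequence-class] with timestamps, or a list of them;
#'   lists are pooled per state.
#' @return named list of numeric duration vectors, one per state observed.
#' @export
sojournTimes <- function(seq) {
    if (is.list(seq)) {
        parts <- lapply(seq, sojournTimes)
        statesSeen <- unique(unlist(lapply(parts, names)))
        return(setNames(lapply(statesSeen, function(s)
            unlist(lapply(parts, function(p) p[[s]]), use.names = FALSE)),
            statesSeen))
    }
    stopifnot(is(seq, "StateSequence"))
    tt <- stateTimes(seq)
    if (!length(tt)) stop("sojourn times require timestamps")
    st <- states(seq)
    r <- rle(st)
    ends <- cumsum(r$lengths)
    startsIdx <- ends - r$lengths + 1
    dur <- tt[ends] - tt[startsIdx]
    split(dur, r$values)
}

#' Optimal neural-to-behavioral temporal scaling factor
#'
#' Pools the sojourn times of all three states within each modality,
#' computes matched quantile vectors on an evenly spaced probability grid,
#' and finds the factor f in [0, 1] minimizing
#' RMSE(Q(behavioral), f * Q(neural)) by grid search (step `gridStep`) with
#' local refinement.
#'
#' @param behavior named list of behavioral sojourn-duration vectors
#'   (seconds), as returned by [sojournTimes()].
#' @param neural same, for the neural modality.
#' @param gridStep grid resolution in f (default 0.001).
#' @param nq number of quantile probabilities (default 101, evenly spaced
#'   on [0, 1]).
#' @return list with `f` (the argmin), `rmse` (value at the argmin), and
#'   `curve`, a data.frame of the full RMSE-vs-f curve on the grid.
#' @export
fitScalingFactor <- function(behavior, neural, gridStep = 0.001, nq = 101) {
    db <- unlist(behavior, use.names = FALSE)
    dn <- unlist(neural, use.names = FALSE)
    if (length(db) < 20 || length(dn) < 20)
        stop("need at least 20 sojourns per modality")
    if (all(db == 0) || all(dn == 0))
        stop("degenerate sojourn sample: all durations zero")
    probs <- seq(0, 1, length.out = nq)
    qb <- as.numeric(quantile(db, probs, type = 8))
    qn <- as.numeric(quantile(dn, probs, type = 8))
    grid <- seq(0, 1, by = gridStep)
    rmse <- vapply(grid, function(f) sqrt(mean((qb - f * qn)^2)), numeric(1))
    iBest <- which.min(rmse)
    lo <- max(grid[iBest] - gridStep, 0)
    hi <- min(grid[iBest] + gridStep, 1)
    ref <- optimize(function(f) sqrt(mean((qb - f * qn)^2)),
                    lower = lo, upper = hi)
    if (ref$objective <= rmse[iBest]) {
        f <- ref$minimum; val <- ref$objective
    } else {
        f <- grid[iBest]; val <- rmse[iBest]
    }
    list(f = f, rmse = val, curve = data.frame(f = grid, rmse = rmse))
}

#' Rescale a frame-rate transition matrix to the bout clock
#'
#' Raises the neural per-frame transition matrix to the nearest-integer
#' power round(nu * f) (halves rounded away from zero), mapping transition
#' probabilities measured at frame rate nu onto the temporally rescaled
#' (behavioral) clock. Matrix powers preserve row-stochasticity and the
#' stationary distribution exactly.
#'
#' @param P row-stochastic matrix.
#' @param nu frame rate (Hz).
#' @param f temporal scaling factor.
#' @return the rescaled matrix P^round(nu*f).
#' @export
rescaleTransitions <- function(P, nu, f) {
    msg <- .checkStochastic(as.matrix(P), nrow(P))
    if (length(msg)) stop(msg[1])
    k <- roundHalfAway(nu * f)
    if (k < 1) stop("rescaling exponent round(nu*f) = 0; cannot rescale")
    matrixPower(as.matrix(P), k)
}

#' Root-mean-square difference between transition matrices
#'
#' @param P,Q 3x3 transition matrices with matching state labels, or lists
#'   of such matrices (entries are then pooled before averaging).
#' @return scalar RMSE over all entries.
#' @export
transitionRMSE <- function(P, Q) {
    if (!is.list(P)) P <- list(P)
    if (!is.list(Q)) Q <- list(Q)
    stopifnot(length(P) == length(Q))
    d2 <- unlist(mapply(function(a, b) {
        a <- as.matrix(a); b <- as.matrix(b)
        stopifnot(all(dim(a) == dim(b)))
        if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
            !identical(rownames(a), rownames(b)))
            stop("state label mismatch between matrices")
        (a - b)^2
    }, P, Q, SIMPLIFY = FALSE))
    sqrt(mean(d2))
}

#' Switch-path ratio P(L->R) / P(L->F)
#'
#' A ratio much below 1 indicates that orientation switches preferentially
#' pass through the forward state rather than flipping directly.
#'
#' @param P a 3x3 transition matrix (rows/cols F, L, R), or a list of them.
#' @return scalar ratio (or numeric vector for a list); NA with a warning
#'   when P(L->F) = 0.
#' @export
switchPathRatio <- function(P) {
    if (is.list(P)) return(vapply(P, switchPathRatio, numeric(1)))
    P <- as.matrix(P)
    if (is.null(rownames(P)) || is.null(colnames(P)))
        dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    if (P["L", "F"] <= 0) {
        warning("P(L->F) is zero; switch-path ratio undefined")
        return(NA_real_)
    }
    unname(P["L", "R"] / P["L", "F"])
}
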