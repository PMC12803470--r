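#' Threshold-based bout labeling
#'
#' Classifies each reorientation angle into \{F, L, R\} by a fixed angular
#' threshold: angles above +threshold are left turns (positive = left),
#' below -threshold right turns, anything else forward. Angles whose
#' magnitude equals the threshold exactly are labeled F: the turn conditions
#' are strict inequalities and ties are measure-zero, assigned to the
#' closure of the central interval.
#'
#' @param angles numeric vector of reorientation angles (degrees).
#' @param threshold positive angular threshold in degrees; the field's
#'   conventional value is 10.
#' @return a [StateSequence-class]; empty input gives an empty sequence.
#' @examples
#' states(thresholdLabel(c(-15, 3, 12)))
#' @export
thresholdLabel <- function(angles, threshold = 10) {
    stopifnot(threshold > 0)
    s <- rep("F", length(angles))
    s[angles > threshold] <- "L"
    s[angles < -threshold] <- "R"
    StateSequence(s)
}

#' Estimate a 3-state transition matrix from labeled sequences
#'
#' Pools transition counts across trajectories (never across trajectory
#' boundaries) and normalizes each row:
#' P(s -> s') = #(s -> s') / sum_s'' #(s -> s'').
#'
#' @param sequences a [StateSequence-class], a character vector, or a list
#'   of either.
#' @param prior optional Dirichlet pseudo-count added to every transition
#'   cell; without it, a state with zero outgoing transitions (e.g. one
#'   appearing only as the last bout of trajectories) leaves its row
#'   undefined (NaN), flagged by a warning and the `"undefined"` attribute.
#' @return 3x3 row-stochastic matrix with a `"counts"` attribute holding the
#'   raw transition counts (and `"undefined"` naming any NaN rows).
#' @export
estimateTransitions <- function(sequences, prior = NULL) {
    seqs <- asStateList(sequences)
    counts <- matrix(0, 3, 3, dimnames = list(STATE_NAMES, STATE_NAMES))
    for (s in seqs) {
        st <- states(s)
        n <- length(st)
        if (n < 2) next
        from <- factor(st[-n], levels = STATE_NAMES)
        to <- factor(st[-1], levels = STATE_NAMES)
        counts <- counts + table(from, to)
    }
    counts <- matrix(as.numeric(counts), 3, 3,
                     dimnames = list(STATE_NAMES, STATE_NAMES))
    work <- if (is.null(prior)) counts else counts + prior
    rs <- rowSums(work)
    undefined <- STATE_NAMES[rs == 0]
    if (length(undefined))
        warning("no outgoing transitions observed from state(s): ",
                paste(undefined, collapse = ", "),
                "; row(s) undefined (supply a prior to regularize)")
    P <- work / ifelse(rs > 0, rs, NaN)
    attr(P, "counts") <- counts
    if (length(undefined)) attr(P, "undefined") <- undefined
    P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed from the eigenvector of the transposed matrix at eigenvalue 1,
#' normalized to sum to one; falls back to power iteration if the eigen
#' solve is ill-conditioned. Reducible or periodic chains (no unique
#' strictly positive stationary vector) raise an error naming the failure.
#'
#' @param P row-stochastic matrix.
#' @return probability vector pi with pi %*% P = pi.
#' @examples
#' stationaryDistribution(symmetricTransitionMatrix(0.5, 0.5, 0.25))
#' @export
stationaryDistribution <- function(P) {
    P <- as.matrix(P)
    msg <- .checkStochastic(P, nrow(P))
    if (length(msg)) stop(msg[1])
    K <- nrow(P)
    e <- eigen(t(P))
    iUnit <- which(abs(e$values - 1) < 1e-8)
    if (length(iUnit) > 1)
        stop("reducible transition matrix: stationary distribution not unique")
    if (any(abs(abs(e$values[-iUnit]) - 1) < 1e-10))
        stop("periodic transition matrix: no limiting distribution")
    pi <- NULL
    if (length(iUnit) == 1) {
        v <- Re(e$vectors[, iUnit])
        if (all(abs(Im(e$vectors[, iUnit])) < 1e-10) &&
            (all(v >= -1e-10) || all(v <= 1e-10)))
            pi <- abs(v) / sum(abs(v))
    }
    if (is.null(pi)) { # ill-conditioned eigen solve: power iteration
        pi <- rep(1 / K, K)
        for (i in seq_len(10000)) {
            nxt <- as.numeric(pi %*% P)
            if (max(abs(nxt - pi)) < 1e-14) break
            pi <- nxt
        }
        pi <- pi / sum(pi)
    }
    if (max(abs(as.numeric(pi %*% P) - pi)) > 1e-8)
        stop("power iteration failed to find a stationary distribution")
    names(pi) <- rownames(P)
    pi
}
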