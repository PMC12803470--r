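#' Streak-length histograms
#'
#' Counts maximal runs of identical consecutive states within each
#' trajectory. Forward streaks are tallied separately; turning streaks are
#' maximal runs of same-direction turns, pooled over L and R (a direction
#' change breaks the run).
#'
#' @param sequences a [StateSequence-class], character vector, or list of
#'   either.
#' @param dropTruncated if TRUE, runs touching a trajectory boundary are
#'   excluded (sensitivity flag; default keeps them).
#' @return list with integer-vector components `forward` and `turn`: counts
#'   of runs indexed by run length (names).
#' @examples
#' streakHistogram(c("F", "F", "L", "L", "L", "F"))
#' @export
streakHistogram <- function(sequences, dropTruncated = FALSE) {
    seqs <- asStateList(sequences)
    fwd <- integer(0); trn <- integer(0)
    for (s in seqs) {
        st <- states(s)
        if (!length(st)) next
        r <- rle(st)
        keep <- rep(TRUE, length(r$values))
        if (dropTruncated) {
            keep[1] <- FALSE
            keep[length(keep)] <- FALSE
        }
        fwd <- c(fwd, r$lengths[keep & r$values == "F"])
        trn <- c(trn, r$lengths[keep & r$values %in% c("L", "R")])
    }
    tab <- function(x) {
        if (!length(x)) return(integer(0))
        t <- table(factor(x, levels = seq_len(max(x))))
        setNames(as.integer(t), names(t))
    }
    list(forward = tab(fwd), turn = tab(trn))
}

#' Characteristic streak length from a histogram
#'
#' The streak-length distribution decays exponentially,
#' P(l) proportional to exp(-l / l1); l1 is estimated as -1/slope of the
#' least-squares line of log-counts against l, using only bins with at
#' least `minCount` runs.
#'
#' @param counts integer vector of run counts named by run length (one
#'   component of [streakHistogram()]).
#' @param minCount minimum bin occupancy entering the fit (default 5).
#' @return the characteristic length l1 (bouts).
#' @export
fitStreakLength <- function(counts, minCount = 5) {
    len <- as.numeric(names(counts))
    keep <- counts >= minCount
    if (sum(keep) < 3)
        stop("need at least 3 streak-length bins with >= ", minCount, " runs")
    fit <- lm(log(counts[keep]) ~ len[keep])
    slope <- unname(coef(fit)[2])
    if (slope >= 0) stop("streak histogram does not decay")
    -1 / slope
}

#' Theoretical persistence lengths and memory index
#'
#' Within a Markov model, the characteristic streak length of state s is
#' l1(s) = -1/log P(s->s); under the memoryless null with
#' P(s->s') = P(s'), it is l0(s) = -1/log P(s). Their ratio quantifies the
#' contribution of memory to bout-type persistence (1 = memoryless).
#'
#' @param P 3x3 row-stochastic matrix (rows/cols F, L, R).
#' @param pi stationary triple; computed from `P` when NULL.
#' @return data.frame with columns state, l1, l0, ratio.
#' @export
theoreticalLengths <- function(P, pi = NULL) {
    if (is.null(pi)) pi <- stationaryDistribution(P)
    self <- diag(as.matrix(P))
    if (any(self <= 0) || any(self >= 1))
        stop("self-transition probabilities must lie in (0, 1)")
    if (any(pi <= 0) || any(pi >= 1))
        stop("stationary probabilities must lie in (0, 1)")
    data.frame(state = STATE_NAMES,
               l1 = -1 / log(self),
               l0 = -1 / log(pi),
               ratio = log(pi) / log(self),
               row.names = NULL)
}

#' Empirical stubbornness factor
#'
#' Scans each trajectory for q-plets T1 -> F^q -> T2 with T1, T2 turns
#' (q = 0 means adjacent turns), counting same-direction (N_same) and
#' direction-switching (N_diff) occurrences; overlapping q-plets are all
#' counted and counts are pooled over trajectories. The factor is
#' f_q = N_same / N_diff, with the binomial-propagation uncertainty
#' Delta f_q = f_q * sqrt[(1/(N_same+N_diff)) * (N_same/N_diff + N_diff/N_same)].
#'
#' @param sequences a [StateSequence-class], character vector, or list.
#' @param q number of intermediary forward bouts (>= 0).
#' @return list with `q`, `nSame`, `nDiff`, `fq`, `deltaFq`, and `defined`
#'   (FALSE when N_diff = 0, in which case `fq` is NA).
#' @examples
#' stubbornnessEmpirical(c("L", "F", "L", "F", "R"), q = 1)
#' @export
stubbornnessEmpirical <- function(sequences, q) {
    stopifnot(q >= 0, q == round(q))
    nSame <- 0L; nDiff <- 0L
    for (s in asStateList(sequences)) {
        st <- states(s)
        idx <- which(st %in% c("L", "R"))
        if (length(idx) < 2) next
        gaps <- diff(idx) - 1L
        hit <- gaps == q
        if (!any(hit)) next
        same <- st[idx[-length(idx)]] == st[idx[-1]]
        nSame <- nSame + sum(hit & same)
        nDiff <- nDiff + sum(hit & !same)
    }
    defined <- nDiff > 0
    fq <- if (defined) nSame / nDiff else NA_real_
    dfq <- if (defined && nSame > 0)
        fq * sqrt((1 / (nSame + nDiff)) * (nSame / nDiff + nDiff / nSame))
    else NA_real_
    list(q = q, nSame = nSame, nDiff = nDiff, fq = fq, deltaFq = dfq,
         defined = defined)
}

#' Theoretical stubbornness factor of a 3-state chain
#'
#' For q = 0 the factor is
#' (P(L->L) + P(R->R)) / (P(L->R) + P(R->L)). For q >= 1 it follows from
#' the q-plet path probabilities S/W in which the common factor P(F->F)^q
#' cancels, leaving
#' (pi_L P(L->F) P(F->L) + pi_R P(R->F) P(F->R)) /
#' (pi_L P(L->F) P(F->R) + pi_R P(R->F) P(F->L)).
#' Under the non-handedness (left-right symmetry) hypothesis this equals 1
#' for every q >= 1.
#'
#' @param P 3x3 row-stochastic matrix (rows/cols F, L, R).
#' @param q number of intermediary forward bouts.
#' @param pi stationary triple; computed from `P` when NULL.
#' @return the ratio f_q; NA with a warning when the denominator is zero.
#' @export
stubbornnessTheoretical <- function(P, q, pi = NULL) {
    stopifnot(q >= 0, q == round(q))
    P <- as.matrix(P)
    if (is.null(rownames(P)) || is.null(colnames(P)))
        dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    if (q == 0) {
        den <- P["L", "R"] + P["R", "L"]
        if (den <= 0) { warning("zero denominator in f_0"); return(NA_real_) }
        return((P["L", "L"] + P["R", "R"]) / den)
    }
    if (is.null(pi)) pi <- stationaryDistribution(P)
    num <- pi["L"] * P["L", "F"] * P["F", "L"] +
           pi["R"] * P["R", "F"] * P["F", "R"]
    den <- pi["L"] * P["L", "F"] * P["F", "R"] +
           pi["R"] * P["R", "F"] * P["F", "L"]
    if (den <= 0) { warning("zero denominator in f_q"); return(NA_real_) }
    unname(num / den)
}

#' Persistence report table
#'
#' Convenience wrapper combining theoretical lengths and empirical
#' stubbornness over a range of q, as delimited-text-ready data.frames.
#'
#' @param sequences labeled state sequences.
#' @param P transition matrix (estimated from `sequences` when NULL).
#' @param qMax largest number of intermediary forward bouts.
#' @return list with `lengths` (state, l1, l0, ratio) and `stubbornness`
#'   (q, nSame, nDiff, fq, deltaFq).
#' @export
persistenceReport <- function(sequences, P = NULL, qMax = 3) {
    if (is.null(P)) P <- estimateTransitions(sequences)
    stub <- do.call(rbind, lapply(0:qMax, function(q) {
        r <- stubbornnessEmpirical(sequences, q)
        data.frame(q = q, nSame = r$nSame, nDiff = r$nDiff,
                   fq = r$fq, deltaFq = r$deltaFq)
    }))
    list(lengths = theoreticalLengths(P), stubbornness = stub)
}
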