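#' @useDynLib swimHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

# nearest integer, halves rounded away from zero (the |.| bracket of the
# transition-rescaling rule)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic substream seed: one root seed spawns independent per-unit
# seeds so changing the number of trajectories/neurons never perturbs
# earlier draws. Kept below 2^31 (R integers are 32-bit).
substreamSeed <- function(root, index) {
    as.integer((as.numeric(root) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(seed)
    }
    force(expr)
}

matrixPower <- function(P, k) {
    stopifnot(k >= 1, k == round(k))
    out <- diag(nrow(P))
    base <- P
    k <- as.integer(k)
    while (k > 0) {
        if (k %% 2L == 1L) out <- out %*% base
        base <- base %*% base
        k <- k %/% 2L
    }
    dimnames(out) <- dimnames(P)
    out
}

# Principal k-th root of a row-stochastic matrix via eigen-decomposition.
# Small negative entries from numerical error are clipped and rows
# renormalized; a root that is not approximately stochastic is rejected.
matrixRoot <- function(P, k) {
    stopifnot(k >= 1)
    if (k == 1) return(P)
    e <- eigen(P)
    V <- e$vectors
    lam <- as.complex(e$values)^(1 / k)
    R <- Re(V %*% diag(lam) %*% solve(V))
    if (min(R) < -1e-6)
        stop("transition matrix has no stochastic ", k, "-th root")
    R[R < 0] <- 0
    R <- R / rowSums(R)
    dimnames(R) <- dimnames(P)
    R
}

#' Sample a finite-state Markov chain
#'
#' Draws one uniform per step from R's RNG stream (so seeds govern
#' reproducibility) and runs the state walk in compiled code.
#'
#' @param P row-stochastic transition matrix.
#' @param initial initial state distribution.
#' @param n number of steps.
#' @return integer vector of 1-based state indices.
#' @export
sampleMarkovChain <- function(P, initial, n) {
    u <- runif(n)
    markov_chain_sample(P, initial, u)
}

asStateList <- function(x) {
    if (is(x, "StateSequence")) return(list(x))
    if (is.character(x)) return(list(StateSequence(x)))
    stopifnot(is.list(x))
    lapply(x, function(s) if (is(s, "StateSequence")) s else StateSequence(s))
}

#' Symmetric 3-state transition matrix from its free parameters
#'
#' A left-right symmetric (non-handed) chain over (F, L, R) has three free
#' transition parameters: the forward self-transition, the turn
#' self-transition, and the direct turn-switch probability; the remaining
#' entries follow from row normalization and the symmetry ties.
#'
#' @param pFF P(F->F).
#' @param pTT P(L->L) = P(R->R).
#' @param pSwitch P(L->R) = P(R->L).
#' @return 3x3 row-stochastic matrix with dimnames F, L, R.
#' @examples
#' symmetricTransitionMatrix(0.5, 0.5, 0.25)
#' @export
symmetricTransitionMatrix <- function(pFF = 0.5, pTT = 0.5, pSwitch = 0.25) {
    pFT <- (1 - pFF) / 2
    pTF <- 1 - pTT - pSwitch
    if (pFT < 0 || pTF < 0 || min(pFF, pTT, pSwitch) < 0)
        stop("invalid symmetric transition parameters")
    P <- rbind(c(pFF, pFT, pFT),
               c(pTF, pTT, pSwitch),
               c(pTF, pSwitch, pTT))
    dimnames(P) <- list(STATE_NAMES, STATE_NAMES)
    P
}

#' Sample from a named positive distribution
#'
#' Interval and distance laws are configured as named lists:
#' `list(name = "gamma", mean = , shape = )`,
#' `list(name = "lognormal", median = , sdlog = )`, or
#' `list(name = "constant", value = )`.
#'
#' @param dist named list as above.
#' @param n number of draws.
#' @return numeric vector of length n.
#' @export
sampleNamedDist <- function(dist, n) {
    switch(dist$name,
        gamma = rgamma(n, shape = dist$shape,
                       scale = dist$mean / dist$shape),
        lognormal = rlnorm(n, meanlog = log(dist$median),
                           sdlog = dist$sdlog),
        constant = rep(dist$value, n),
        stop("unknown distribution '", dist$name, "'"))
}
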