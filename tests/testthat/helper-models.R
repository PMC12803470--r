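# Shared fixtures: small models and exhaustive-enumeration oracles used
# across test files. Everything is built in code at test time.

logistic <- function(x) 1 / (1 + exp(-x))

wellSeparatedBehaviorHMM <- function(pStay = 0.9) {
    off <- (1 - pStay) / 2
    P <- matrix(off, 3, 3)
    diag(P) <- pStay
    dimnames(P) <- list(c("F", "L", "R"), c("F", "L", "R"))
    BehaviorHMM(P, sigmaF = 5, alpha = 8, theta = 8)  # turn mode ~ 56 deg
}

randomStochasticMatrix <- function(K = 3, named = TRUE) {
    P <- matrix(rgamma(K * K, 2), K, K)
    P <- P / rowSums(P)
    if (named && K == 3) dimnames(P) <- list(c("F", "L", "R"),
                                             c("F", "L", "R"))
    P
}

randomBehaviorHMM <- function() {
    BehaviorHMM(randomStochasticMatrix(), initial = {
        p <- rgamma(3, 2); p / sum(p)
    }, sigmaF = runif(1, 5, 25), alpha = runif(1, 1.2, 6),
       theta = runif(1, 3, 20), symmetric = FALSE)
}

randomNeuralHMM <- function(K = 3, N = 5) {
    NeuralHMM(randomStochasticMatrix(K, named = FALSE),
              matrix(rnorm(K * N, 0, 2), K, N),
              initial = { p <- rgamma(K, 2); p / sum(p) })
}

# Exhaustive-path oracles: sum / max over all K^T hidden paths.
bruteForceLoglik <- function(logB, logPi, logA) {
    Tn <- nrow(logB); K <- ncol(logB)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    lp <- apply(paths, 1, function(s) {
        v <- logPi[s[1]] + logB[1, s[1]]
        if (Tn > 1) for (t in 2:Tn)
            v <- v + logA[s[t - 1], s[t]] + logB[t, s[t]]
        v
    })
    m <- max(lp)
    list(loglik = m + log(sum(exp(lp - m))), best = max(lp))
}

behaviorLogB <- function(angles, model) {
    cbind(emissionLogpdf(angles, "F", model),
          emissionLogpdf(angles, "L", model),
          emissionLogpdf(angles, "R", model))
}

neuralLogB <- function(X, model) {
    K <- nrow(fieldsMatrix(model))
    t(vapply(seq_len(ncol(X)), function(t)
        vapply(seq_len(K), function(s)
            neuralEmissionLoglik(X[, t], s, model), numeric(1)),
        numeric(K)))
}
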