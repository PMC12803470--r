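#' Static Normal + signed-Gamma mixture fit of pooled angles
#'
#' Fits the three-component mixture
#' p(x) = wF * Normal(x; 0, sigma) + wL * Gamma(x; alpha, theta)
#'      + wR * Gamma(-x; alpha, theta)
#' by EM without any temporal structure, with the left-right symmetry ties
#' (shared alpha, theta). This is the static validation of the HMM emission
#' families: if the trimodal angle distribution is well described by the
#' mixture, the Normal/Gamma emission choice is adequate.
#'
#' @param angles pooled numeric vector of reorientation angles (degrees).
#' @param restarts random restarts (best log-likelihood kept).
#' @param maxIter,tol EM stopping rule.
#' @param nq number of quantile-quantile points returned.
#' @param seed integer seed for the restarts.
#' @return a list with components `weights` (wF, wL, wR), `sigmaF`, `alpha`,
#'   `theta`, `loglik`, `iterations`, `restartsUsed`, and `qq`, a data.frame
#'   of matched empirical vs fitted-mixture quantiles.
#' @export
fitAngleMixture <- function(angles, restarts = 3, maxIter = 500,
                            tol = 1e-8, nq = 199, seed = NULL) {
    stopifnot(length(angles) >= 100)
    withSeed(seed, {
        best <- NULL
        fails <- 0
        for (r in seq_len(restarts)) {
            fit <- tryCatch(
                .mixtureEMOnce(angles, maxIter, tol, jitter = (r > 1)),
                error = function(e) NULL)
            if (is.null(fit)) { fails <- fails + 1; next }
            if (is.null(best) || fit$loglik > best$loglik) best <- fit
        }
        if (is.null(best))
            stop("mixture EM failed in all ", restarts, " restarts")
        best$restartsUsed <- restarts - fails
        probs <- (seq_len(nq) - 0.5) / nq
        best$qq <- data.frame(
            empirical = as.numeric(quantile(angles, probs, type = 8)),
            fitted = .mixtureQuantile(probs, best),
            prob = probs)
        best
    })
}

.mixtureLogComponents <- function(x, w, sigma, alpha, theta) {
    lf <- log(w[1]) + dnorm(x, 0, sigma, log = TRUE)
    ll <- log(w[2]) + ifelse(x > 0,
        dgamma(x, shape = alpha, scale = theta, log = TRUE), -Inf)
    lr <- log(w[3]) + ifelse(x < 0,
        dgamma(-x, shape = alpha, scale = theta, log = TRUE), -Inf)
    cbind(lf, ll, lr)
}

.mixtureEMOnce <- function(x, maxIter, tol, jitter) {
    p0 <- .initBehaviorParams(x, 10, jitter)
    w <- c(0.5, 0.25, 0.25)
    if (jitter) { w <- w * runif(3, 0.6, 1.4); w <- w / sum(w) }
    sigma <- p0$sigma; alpha <- p0$alpha; theta <- p0$theta
    prevLL <- -Inf
    for (iter in seq_len(maxIter)) {
        lc <- .mixtureLogComponents(x, w, sigma, alpha, theta)
        m <- apply(lc, 1, max)
        ll <- sum(m + log(rowSums(exp(lc - m))))
        if (!is.finite(ll)) stop("mixture EM log-likelihood diverged")
        if (ll < prevLL - 1e-8 * max(1, abs(prevLL)))
            stop("mixture EM log-likelihood decreased")
        gain <- ll - prevLL
        prevLL <- ll
        r <- exp(lc - m - log(rowSums(exp(lc - m))))
        w <- colMeans(r)
        w <- pmax(w, 1e-12); w <- w / sum(w)
        sigma <- max(sqrt(sum(r[, 1] * x^2) / sum(r[, 1])), 1e-3)
        g <- weightedGammaMLE(c(x, -x), c(r[, 2], r[, 3]))
        alpha <- unname(g["alpha"]); theta <- unname(g["theta"])
        if (iter > 1 && gain < tol) break
    }
    list(weights = setNames(w, c("wF", "wL", "wR")), sigmaF = sigma,
         alpha = alpha, theta = theta, loglik = prevLL, iterations = iter)
}

#' Mixture density and distribution function
#'
#' @param x numeric vector of angles (degrees).
#' @param fit a mixture fit from [fitAngleMixture()] (or any list with
#'   `weights`, `sigmaF`, `alpha`, `theta`).
#' @return density (or CDF) values at `x`.
#' @export
mixtureDensity <- function(x, fit) {
    w <- fit$weights
    w[1] * dnorm(x, 0, fit$sigmaF) +
        w[2] * ifelse(x > 0, dgamma(x, shape = fit$alpha, scale = fit$theta), 0) +
        w[3] * ifelse(x < 0, dgamma(-x, shape = fit$alpha, scale = fit$theta), 0)
}

#' @rdname mixtureDensity
#' @export
mixtureCDF <- function(x, fit) {
    w <- fit$weights
    w[1] * pnorm(x, 0, fit$sigmaF) +
        w[2] * ifelse(x > 0, pgamma(x, shape = fit$alpha, scale = fit$theta), 0) +
        w[3] * ifelse(x < 0, pgamma(-x, shape = fit$alpha, scale = fit$theta,
                                    lower.tail = FALSE), 1)
}

# Quantiles by monotone interpolation of the CDF on a fine grid.
.mixtureQuantile <- function(probs, fit) {
    span <- max(10 * fit$sigmaF, fit$alpha * fit$theta * 10, 90)
    grid <- seq(-span, span, length.out = 20001)
    cdf <- mixtureCDF(grid, fit)
    keep <- c(TRUE, diff(cdf) > 0)
    approx(cdf[keep], grid[keep], xout = probs, rule = 2)$y
}

#' @importFrom stats approx
NULL
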