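#' Split a long session into contiguous time chunks
#'
#' Divides the session span into `nChunks` windows of equal duration and
#' assigns each trajectory to the chunk containing its start time; no
#' trajectory is split. A 2 h session with 10 chunks gives ~12 min windows.
#'
#' @param session list of bout-table data.frames (each with a `t` column of
#'   bout times on the common session clock).
#' @param nChunks number of chunks.
#' @return list of chunk datasets (each a list of trajectory data.frames);
#'   empty chunks are dropped with a warning.
#' @export
splitChunks <- function(session, nChunks) {
    stopifnot(length(session) >= 1, nChunks >= 1)
    starts <- vapply(session, function(tr) tr$t[1], numeric(1))
    span <- range(starts)
    if (diff(span) <= 0 && nChunks > 1)
        stop("session span too short to split into ", nChunks, " chunks")
    edges <- seq(span[1], span[2], length.out = nChunks + 1)
    bin <- pmin(findInterval(starts, edges, rightmost.closed = TRUE),
                nChunks)
    chunks <- lapply(seq_len(nChunks), function(k) session[bin == k])
    empty <- lengths(chunks) == 0
    if (any(empty)) {
        warning(sum(empty), " empty chunk(s) dropped")
        chunks <- chunks[!empty]
    }
    chunks
}

#' Relative-likelihood confusion matrix across individuals
#'
#' Computes the total test log-likelihood of each fish's data under each
#' fish's model; entry (i, j) of the returned log-relative matrix is
#' log L(data_i | model_j) - log L(data_i | model_i), so the diagonal is 0
#' (relative likelihood 1) by construction. For each model j the identified
#' fish is the argmax over data i.
#'
#' @param models list of per-fish [BehaviorHMM-class] objects.
#' @param testSets list (same length/order) of per-fish test data: each a
#'   list of numeric angle sequences.
#' @param perBout if TRUE, log-likelihoods are divided by each fish's total
#'   test bout count before comparison (fish differ in bout counts; the
#'   default total matches the relative-likelihood ratio definition).
#' @return list with `logRelative` (n x n matrix), `loglik` (raw totals),
#'   `identified` (per-model argmax index), `correct` (logical), and
#'   `nCorrect`. Ties in the argmax are flagged NA.
#' @export
likelihoodConfusion <- function(models, testSets, perBout = FALSE) {
    n <- length(models)
    stopifnot(n >= 2, length(testSets) == n)
    keep <- lengths(testSets) > 0
    if (!all(keep)) warning("fish with empty test sets excluded")
    ll <- matrix(NA_real_, n, n, dimnames = list(data = NULL, model = NULL))
    for (i in which(keep)) for (j in seq_len(n))
        ll[i, j] <- sequenceLoglik(testSets[[i]], models[[j]])
    if (perBout) {
        nb <- vapply(testSets, function(s) sum(lengths(s)), numeric(1))
        ll <- ll / ifelse(nb > 0, nb, NA_real_)
    }
    rel <- sweep(ll, 1, diag(ll), "-")
    # identification by relative likelihood: raw totals are not comparable
    # across fish (different test-set sizes), the per-fish ratio is
    identified <- vapply(seq_len(n), function(j) {
        col <- rel[, j]
        top <- which(col == max(col, na.rm = TRUE))
        if (length(top) != 1) NA_integer_ else top
    }, integer(1))
    correct <- identified == seq_len(n)
    list(logRelative = rel, loglik = ll, identified = identified,
         correct = correct, nCorrect = sum(correct, na.rm = TRUE))
}

#' Identification curve vs fraction of test data
#'
#' The study protocol: in each trial the trajectories of each fish are
#' randomly split 50/50 into train and test sets, a model is trained per
#' fish on its train set, a fraction f of the test trajectories is
#' subsampled, and the number of correctly identified fish is recorded.
#' Means and standard deviations are aggregated over trials.
#'
#' @param fishData list of per-fish datasets, each a list of numeric angle
#'   sequences (trajectories).
#' @param fractions vector of test-data fractions in (0, 1].
#' @param nTrials number of random-split trials (the study uses 100).
#' @param config settings from [hmmConfig()] for the per-trial fits.
#' @param seed integer root seed.
#' @return data.frame with columns fraction, meanCorrect, sdCorrect.
#' @export
identificationCurve <- function(fishData, fractions, nTrials = 10,
                                config = hmmConfig(restarts = 1),
                                seed = 1L) {
    stopifnot(all(fractions > 0), all(fractions <= 1), nTrials >= 1)
    nFish <- length(fishData)
    counts <- matrix(NA_real_, nTrials, length(fractions))
    for (trial in seq_len(nTrials)) {
        split <- withSeed(substreamSeed(seed, trial),
            lapply(fishData, function(tr) {
                n <- length(tr)
                idx <- sample.int(n, floor(n / 2))
                list(train = tr[idx], test = tr[-idx])
            }))
        models <- lapply(seq_len(nFish), function(i) {
            cfg <- config
            cfg$seed <- substreamSeed(seed, trial * 1000 + i)
            fitBehaviorHMM(split[[i]]$train, cfg)
        })
        for (fi in seq_along(fractions)) {
            f <- fractions[fi]
            testSets <- withSeed(substreamSeed(seed, trial * 31 + fi),
                lapply(split, function(s) {
                    m <- max(1, round(f * length(s$test)))
                    if (m > length(s$test)) m <- length(s$test)
                    s$test[sample.int(length(s$test), m)]
                }))
            if (any(lengths(testSets) == 0)) {
                warning("fraction ", f, " yielded an empty test set; skipped")
                next
            }
            counts[trial, fi] <-
                likelihoodConfusion(models, testSets)$nCorrect
        }
    }
    data.frame(fraction = fractions,
               meanCorrect = colMeans(counts, na.rm = TRUE),
               sdCorrect = apply(counts, 2, sd, na.rm = TRUE))
}
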