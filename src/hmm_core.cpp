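#include <Rcpp.h>
using namespace Rcpp;

// Log-space HMM primitives shared by the behavioral (angle) and neural
// (Bernoulli-raster) models. All inputs are log-scaled: logB is the T x K
// matrix of per-observation emission log-densities, logPi the length-K
// initial log-distribution, logA the K x K transition log-matrix.

static inline double logsumexp(const std::vector<double>& v) {
    double m = v[0];
    for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
    if (!std::isfinite(m)) return m;
    double s = 0.0;
    for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
    return m + std::log(s);
}

// [[Rcpp::export]]
double hmm_forward_loglik(const NumericMatrix& logB,
                          const NumericVector& logPi,
                          const NumericMatrix& logA) {
    const int T = logB.nrow(), K = logB.ncol();
    std::vector<double> a(K), anew(K), tmp(K);
    for (int k = 0; k < K; ++k) a[k] = logPi[k] + logB(0, k);
    for (int t = 1; t < T; ++t) {
        for (int j = 0; j < K; ++j) {
            for (int i = 0; i < K; ++i) tmp[i] = a[i] + logA(i, j);
            anew[j] = logsumexp(tmp) + logB(t, j);
        }
        a = anew;
    }
    return logsumexp(a);
}

// Forward-backward: returns posterior state marginals (gamma, T x K),
// summed expected transition counts (xi, K x K), the posterior of the first
// observation, and the sequence log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward(const NumericMatrix& logB,
                          const NumericVector& logPi,
                          const NumericMatrix& logA) {
    const int T = logB.nrow(), K = logB.ncol();
    NumericMatrix la(T, K), lb(T, K);
    std::vector<double> tmp(K);
    for (int k = 0; k < K; ++k) la(0, k) = logPi[k] + logB(0, k);
    for (int t = 1; t < T; ++t)
        for (int j = 0; j < K; ++j) {
            for (int i = 0; i < K; ++i) tmp[i] = la(t - 1, i) + logA(i, j);
            la(t, j) = logsumexp(tmp) + logB(t, j);
        }
    for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
    for (int t = T - 2; t >= 0; --t)
        for (int i = 0; i < K; ++i) {
            for (int j = 0; j < K; ++j)
                tmp[j] = logA(i, j) + logB(t + 1, j) + lb(t + 1, j);
            lb(t, i) = logsumexp(tmp);
        }
    for (int k = 0; k < K; ++k) tmp[k] = la(T - 1, k);
    const double ll = logsumexp(tmp);

    NumericMatrix gamma(T, K);
    for (int t = 0; t < T; ++t)
        for (int k = 0; k < K; ++k)
            gamma(t, k) = std::exp(la(t, k) + lb(t, k) - ll);

    NumericMatrix xi(K, K);
    for (int t = 0; t < T - 1; ++t)
        for (int i = 0; i < K; ++i)
            for (int j = 0; j < K; ++j)
                xi(i, j) += std::exp(la(t, i) + logA(i, j) +
                                     logB(t + 1, j) + lb(t + 1, j) - ll);
    return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Batched E-step over many independent sequences stored contiguously.
// logB stacks the emission log-densities of all sequences (total T x K);
// starts/ends give 1-based row ranges of each sequence. Returns pooled
// posterior marginals, summed expected transition counts, summed
// first-observation posteriors, and the total log-likelihood.
// [[Rcpp::export]]
List hmm_estep_batch(const NumericMatrix& logB,
                     const NumericVector& logPi,
                     const NumericMatrix& logA,
                     const IntegerVector& starts,
                     const IntegerVector& ends) {
    const int K = logB.ncol(), nSeq = starts.size(), Tall = logB.nrow();
    NumericMatrix gamma(Tall, K);
    NumericMatrix xi(K, K);
    NumericVector gamma1(K);
    double total = 0.0;

    // linear-space emissions with per-frame max subtraction (keeps the
    // scaled forward-backward recursion overflow-safe); offsets re-enter
    // the log-likelihood additively
    std::vector<double> B((size_t)Tall * K);
    for (int t = 0; t < Tall; ++t) {
        double m = logB(t, 0);
        for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
        for (int k = 0; k < K; ++k)
            B[(size_t)t * K + k] = std::exp(logB(t, k) - m);
        total += m;
    }
    std::vector<double> pi(K), A((size_t)K * K);
    for (int k = 0; k < K; ++k) pi[k] = std::exp(logPi[k]);
    for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
            A[(size_t)i * K + j] = std::exp(logA(i, j));

    std::vector<double> a, b, c;
    for (int q = 0; q < nSeq; ++q) {
        const int s0 = starts[q] - 1, s1 = ends[q] - 1;
        const int T = s1 - s0 + 1;
        a.assign((size_t)T * K, 0.0);
        b.assign((size_t)T * K, 0.0);
        c.assign(T, 0.0);
        // scaled forward pass
        for (int k = 0; k < K; ++k) {
            a[k] = pi[k] * B[(size_t)s0 * K + k];
            c[0] += a[k];
        }
        for (int k = 0; k < K; ++k) a[k] /= c[0];
        for (int t = 1; t < T; ++t) {
            for (int j = 0; j < K; ++j) {
                double s = 0.0;
                for (int i = 0; i < K; ++i)
                    s += a[(size_t)(t - 1) * K + i] * A[(size_t)i * K + j];
                const double v = s * B[(size_t)(s0 + t) * K + j];
                a[(size_t)t * K + j] = v;
                c[t] += v;
            }
            for (int j = 0; j < K; ++j) a[(size_t)t * K + j] /= c[t];
        }
        for (int t = 0; t < T; ++t) total += std::log(c[t]);
        // scaled backward pass
        for (int k = 0; k < K; ++k) b[(size_t)(T - 1) * K + k] = 1.0;
        for (int t = T - 2; t >= 0; --t)
            for (int i = 0; i < K; ++i) {
                double s = 0.0;
                for (int j = 0; j < K; ++j)
                    s += A[(size_t)i * K + j] *
                         B[(size_t)(s0 + t + 1) * K + j] *
                         b[(size_t)(t + 1) * K + j];
                b[(size_t)t * K + i] = s / c[t + 1];
            }
        // posteriors and expected transition counts
        for (int t = 0; t < T; ++t)
            for (int k = 0; k < K; ++k)
                gamma(s0 + t, k) = a[(size_t)t * K + k] *
                                   b[(size_t)t * K + k];
        for (int k = 0; k < K; ++k) gamma1[k] += gamma(s0, k);
        for (int t = 0; t < T - 1; ++t)
            for (int i = 0; i < K; ++i) {
                const double ai = a[(size_t)t * K + i];
                for (int j = 0; j < K; ++j)
                    xi(i, j) += ai * A[(size_t)i * K + j] *
                                B[(size_t)(s0 + t + 1) * K + j] *
                                b[(size_t)(t + 1) * K + j] / c[t + 1];
            }
    }
    return List::create(_["gamma"] = gamma, _["xi"] = xi,
                        _["gamma1"] = gamma1, _["loglik"] = total);
}

// Viterbi MAP path. Ties are broken toward the lower state index (fixed
// state order F < L < R) by using strict improvement when scanning
// predecessors and final states in increasing index order.
// [[Rcpp::export]]
List hmm_viterbi(const NumericMatrix& logB,
                 const NumericVector& logPi,
                 const NumericMatrix& logA) {
    const int T = logB.nrow(), K = logB.ncol();
    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);
    for (int k = 0; k < K; ++k) delta(0, k) = logPi[k] + logB(0, k);
    for (int t = 1; t < T; ++t)
        for (int j = 0; j < K; ++j) {
            double best = R_NegInf; int arg = 0;
            for (int i = 0; i < K; ++i) {
                const double v = delta(t - 1, i) + logA(i, j);
                if (v > best) { best = v; arg = i; }
            }
            delta(t, j) = best + logB(t, j);
            psi(t, j) = arg;
        }
    double best = R_NegInf; int arg = 0;
    for (int k = 0; k < K; ++k)
        if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
    IntegerVector path(T);
    path[T - 1] = arg;
    for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
    for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
    return List::create(_["path"] = path, _["score"] = best);
}

// Markov chain sampler driven by pre-drawn uniforms (one per step) so that
// reproducibility is governed entirely by R's RNG stream.
// [[Rcpp::export]]
IntegerVector markov_chain_sample(const NumericMatrix& A,
                                  const NumericVector& init,
                                  const NumericVector& u) {
    const int K = A.ncol(), n = u.size();
    IntegerVector s(n);
    double c = 0.0; int cur = K - 1;
    for (int k = 0; k < K; ++k) {
        c += init[k];
        if (u[0] <= c) { cur = k; break; }
    }
    s[0] = cur + 1;
    for (int t = 1; t < n; ++t) {
        c = 0.0; int nxt = K - 1;
        for (int k = 0; k < K; ++k) {
            c += A(cur, k);
            if (u[t] <= c) { nxt = k; break; }
        }
        cur = nxt;
        s[t] = cur + 1;
    }
    return s;
}
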