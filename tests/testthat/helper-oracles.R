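# Independent brute-force oracles, deliberately written from the textbook
# definitions and kept free of any package internals.

# Benjamini-Hochberg step-up from its definition:
# q_(i) = min_{j >= i} (p_(j) * m / j), capped at 1, in input order.
bhStepUpOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    running <- Inf
    for (i in m:1) {
        running <- min(running, ps[i] * m / i)
        q[i] <- min(running, 1)
    }
    out <- numeric(m)
    out[o] <- q
    out
}

# Hypergeometric upper tail P[X >= k] by exhaustive enumeration of draws.
hyperTailOracle <- function(k, K, N, n) {
    sum(vapply(k:min(K, n), function(x)
        choose(K, x) * choose(N - K, n - x), 0)) / choose(N, n)
}

# Two-pass covariance/variance Pearson correlation.
pearsonOracle <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs double loop over a correlation matrix: edges at |cc| > thr.
edgeListOracle <- function(cc, thr) {
    g <- rownames(cc)
    out <- NULL
    for (i in seq_along(g)) for (j in seq_along(g)) {
        if (i < j && abs(cc[i, j]) > thr)
            out <- rbind(out, data.frame(from = g[i], to = g[j],
                cc = cc[i, j]))
    }
    out
}
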