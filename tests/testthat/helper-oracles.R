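# Independent oracles and small fixture builders shared across tests.

# KS statistic straight from the ECDF definition: sup over the pooled
# values of |F_member - F_nonmember| (double loop, no shared code with
# the package's cumulative-sum path).
bruteKsStat <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                   numeric(1))))
}

# Exact permutation p-value by full enumeration of the C(m+n, m)
# interleavings; feasible for pooled sizes up to ~10.
bruteKsP <- function(a, b) {
    x <- c(a, b)
    m <- length(a)
    dObs <- bruteKsStat(a, b)
    picks <- utils::combn(length(x), m)
    ds <- apply(picks, 2, function(k) bruteKsStat(x[k], x[-k]))
    mean(ds >= dObs - 1e-12)
}

# Hand-derived Benjamini-Hochberg step-up: sort ascending, take
# m * p_(j) / j, enforce monotonicity by a reverse cumulative minimum,
# cap at 1, return in input order.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    raw <- m * p[o] / seq_len(m)
    adj <- rev(cummin(rev(raw)))
    pmin(adj, 1)[order(o)]
}

# A ranked input over n taxa with values 1..n (identifiers t1..tn).
ladderRanked <- function(n) {
    RankedTaxa(stats::setNames(as.numeric(seq_len(n)),
                               paste0("t", seq_len(n))))
}

tinyDb <- function(...) {
    TaxonSetDatabase(list(...))
}
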