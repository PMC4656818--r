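# Independent brute-force oracles used to pin the statistical operations.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped to input order.
bhStepUpOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m)) {
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    }
    out <- numeric(m)
    out[ord] <- q
    out
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) equally likely gene lists (feasible for N <= 12).
hyperEnumOracle <- function(N, K, n, O) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)   # which universe elements are pathway members
    hits <- apply(draws, 2, function(d) sum(d %in% marked))
    mean(hits >= O)
}

# Raw cosine similarity between columns of a matrix.
rawColumnCosines <- function(w) {
    nrm <- sqrt(colSums(w^2))
    nrm[nrm == 0] <- 1
    crossprod(sweep(w, 2, nrm, `/`))
}

# All permutations of a (short) numeric vector, as a list.
combinat_perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
        for (rest in combinat_perms(x[-i])) {
            out[[length(out) + 1]] <- c(x[i], rest)
        }
    }
    out
}

# A small hand-rolled signed-set generator for property tests.
randomSignedSet <- function(label, idPool, size) {
    ids <- sample(idPool, size)
    SignedGeneSet(label, stats::setNames(sample(c(-1L, 1L), size,
                                                replace = TRUE), ids))
}
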