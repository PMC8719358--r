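# Independent oracles used to verify the implementation. Each is a
# deliberately naive, brute-force computation kept separate from the
# package code paths it checks.

# Needleman-Wunsch global alignment by explicit dynamic programming:
# match +1, mismatch -1, linear gap -2 per position. Returns the optimal
# score and the number of exact matches on one optimal traceback
# (N never a match).
nwOracle <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    S <- matrix(0, n + 1, m + 1)
    S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sub <- S[i, j] + ifelse(a[i] == b[j] & a[i] != "N", 1, -1)
        S[i + 1, j + 1] <- max(sub, S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
    i <- n; j <- m; matches <- 0L; len <- 0L
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            S[i + 1, j + 1] == S[i, j] +
                ifelse(a[i] == b[j] & a[i] != "N", 1, -1)) {
            matches <- matches + (a[i] == b[j] && a[i] != "N")
            i <- i - 1; j <- j - 1
        } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
            i <- i - 1
        } else {
            j <- j - 1
        }
        len <- len + 1L
    }
    list(score = S[n + 1, m + 1], matches = matches, length = len)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(m+n, m) group assignments of the pooled sample (no ties assumed).
mwuEnumOracle <- function(a, b) {
    pool <- c(a, b)
    n1 <- length(a)
    r <- rank(pool)
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(length(pool), n1)
    uAll <- apply(combs, 2, function(idx)
        sum(r[idx]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# Exhaustive upper-tail hypergeometric probability: over all placements
# of K positives among N cells, the fraction with >= k positives inside
# a fixed cluster of size n.
hyperEnumOracle <- function(N, K, n, k) {
    placements <- combn(N, K)
    mean(apply(placements, 2, function(idx) sum(idx <= n) >= k))
}

# Connected components by naive union-find over above-threshold pairs.
unionFindOracle <- function(adj) {
    n <- nrow(adj)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (adj[i, j]) parent[find(j)] <- find(i)
    comp <- vapply(seq_len(n), find, integer(1))
    match(comp, unique(comp))
}

# Dense TF-IDF recomputation.
tfidfOracle <- function(m) {
    m <- as.matrix(m)
    N <- ncol(m)
    ng <- rowSums(m > 0)
    idf <- ifelse(ng == 0, 0, log(N / pmax(ng, 1)))
    m * idf
}
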