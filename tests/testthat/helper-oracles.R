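# Independent oracles used across the suite. Each is coded directly from
# first principles (explicit loops / enumeration), deliberately not
# sharing code with the package implementations it checks.

# Benjamini-Hochberg step-up by explicit min-over-suffix
bhOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adj <- numeric(m)
    for (i in seq_len(m)) {
        vals <- numeric(0)
        for (j in i:m) vals <- c(vals, sorted[j] * m / j)
        adj[i] <- min(1, min(vals))
    }
    out <- numeric(m)
    out[ord] <- adj
    out
}

# Upper-tail hypergeometric P(X >= k) by combinatorial enumeration
hyperOracle <- function(k, N, K, n) {
    tot <- 0
    for (j in k:min(K, n))
        tot <- tot + choose(K, j) * choose(N - K, n - j)
    tot / choose(N, n)
}

# Pattern classifier oracle: direct transcription of the relational
# screening conditions, one explicit test per pattern. Relations:
# "X = Y" comparison not significant; "X < Y" significant with means in
# that order.
patternOracle <- function(sigFM, dirFM, sigFH, dirFH, sigMH, dirMH) {
    FgtM <- sigFM && dirFM > 0; FltM <- sigFM && dirFM < 0
    FeqM <- !sigFM
    HgtF <- sigFH && dirFH > 0; HltF <- sigFH && dirFH < 0
    HeqF <- !sigFH
    HgtM <- sigMH && dirMH > 0; HltM <- sigMH && dirMH < 0
    HeqM <- !sigMH
    if (FgtM && HltF && HgtM) return("P1")   # M < H < F
    if (FltM && HgtF && HltM) return("P2")   # F < H < M
    if (FltM && HeqM && HgtF) return("P3")   # F < M, H = M
    if (FgtM && HeqM && HltF) return("P4")   # F > M, H = M
    if (FgtM && HeqF && HgtM) return("P5")   # F > M, H = F
    if (FltM && HeqF && HltM) return("P6")   # F < M, H = F
    if (FeqM && HltF && HltM) return("P7")   # H below both equal parents
    if (FgtM && HltF && HltM) return("P8")
    if (FltM && HltF && HltM) return("P9")
    if (FeqM && HgtF && HgtM) return("P10")  # H above both equal parents
    if (FgtM && HgtF && HgtM) return("P11")
    if (FltM && HgtF && HgtM) return("P12")
    "unclassified"
}

# Topological overlap by brute-force double loop
tomOracle <- function(a) {
    n <- nrow(a)
    out <- matrix(0, n, n)
    k <- numeric(n)
    for (i in seq_len(n))
        for (u in seq_len(n)) if (u != i) k[i] <- k[i] + a[i, u]
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) { out[i, j] <- 1; next }
            l <- 0
            for (u in seq_len(n))
                if (u != i && u != j) l <- l + a[i, u] * a[u, j]
            out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
        }
    }
    out
}

# small random symmetric adjacency with unit diagonal
randomAdjacency <- function(n) {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
}

# enumerate all 27 (significance, direction) call triples
allCallTriples <- function() {
    states <- list(c(FALSE, 0L), c(TRUE, 1L), c(TRUE, -1L))
    out <- expand.grid(fm = 1:3, fh = 1:3, mh = 1:3)
    data.frame(
        sigFM = vapply(out$fm, function(i) as.logical(states[[i]][1]), TRUE),
        dirFM = vapply(out$fm, function(i) as.integer(states[[i]][2]), 1L),
        sigFH = vapply(out$fh, function(i) as.logical(states[[i]][1]), TRUE),
        dirFH = vapply(out$fh, function(i) as.integer(states[[i]][2]), 1L),
        sigMH = vapply(out$mh, function(i) as.logical(states[[i]][1]), TRUE),
        dirMH = vapply(out$mh, function(i) as.integer(states[[i]][2]), 1L))
}
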