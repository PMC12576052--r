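## Independent brute-force implementations of the window-feature
## formulas, written as literal nested loops over reads and positions.
## They share no code with the package's vectorized versions and serve
## as the oracle in the equivalence tests.

ALPH <- c("A", "C", "G", "T", "D")

oracleMean <- function(Q) {
    n <- nrow(Q); w <- ncol(Q)
    M <- numeric(w)
    for (i in seq_len(w)) {
        s <- 0
        for (j in seq_len(n)) s <- s + Q[j, i]
        M[i] <- s / n
    }
    M
}

oracleCov <- function(Q) {
    n <- nrow(Q); w <- ncol(Q)
    M <- oracleMean(Q)
    V <- matrix(0, w, w)
    for (p in seq_len(w)) for (q in seq_len(w)) {
        s <- 0
        for (j in seq_len(n)) s <- s + (Q[j, p] - M[p]) * (Q[j, q] - M[q])
        V[p, q] <- s / (n - 1)
    }
    V
}

oracleSigma <- function(Q, ddof = 0) {
    n <- nrow(Q); w <- ncol(Q)
    M <- oracleMean(Q)
    s <- numeric(w)
    for (p in seq_len(w)) {
        acc <- 0
        for (j in seq_len(n)) acc <- acc + (Q[j, p] - M[p])^2
        s[p] <- sqrt(acc / (n - ddof))
    }
    s
}

oracleCoskew <- function(Q, ddof = 0) {
    n <- nrow(Q); w <- ncol(Q)
    M <- oracleMean(Q)
    sig <- oracleSigma(Q, ddof)
    S <- matrix(0, w, w)
    for (p in seq_len(w)) for (q in seq_len(w)) {
        if (sig[p] == 0 || sig[q] == 0) next
        acc <- 0
        for (j in seq_len(n))
            acc <- acc + (Q[j, p] - M[p])^2 * (Q[j, q] - M[q])
        S[p, q] <- acc / (n * sig[p]^2 * sig[q])
    }
    S
}

oracleCokurt <- function(Q, ddof = 0) {
    n <- nrow(Q); w <- ncol(Q)
    M <- oracleMean(Q)
    sig <- oracleSigma(Q, ddof)
    K <- matrix(0, w, w)
    for (p in seq_len(w)) for (q in seq_len(w)) {
        if (sig[p] == 0 || sig[q] == 0) next
        acc <- 0
        for (j in seq_len(n))
            acc <- acc + (Q[j, p] - M[p])^2 * (Q[j, q] - M[q])^2
        K[p, q] <- acc / (n * sig[p]^2 * sig[q]^2)
    }
    K
}

oracleErrorTensor <- function(R, ctx) {
    n <- nrow(R); w <- ncol(R)
    E <- array(0, dim = c(5, 5, w, w))
    for (j in seq_len(n)) for (p in seq_len(w)) for (q in seq_len(w)) {
        s <- R[j, p]; t <- R[j, q]
        if (s != ctx[p] && t != ctx[q]) {
            si <- match(s, ALPH); ti <- match(t, ALPH)
            E[si, ti, p, q] <- E[si, ti, p, q] + 1
        }
    }
    E / n
}

## Random rectangular pileup: QVs uniform integers, bases mostly matching
## the reference with a sprinkle of substitutions and deletions.
randomPileup <- function(n, flank = 10L, errRate = 0.15) {
    w <- 2L * flank + 1L
    ctx <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    Q <- matrix(as.numeric(sample(1:45, n * w, replace = TRUE)), n, w)
    R <- matrix(rep(ctx, each = n), n, w)
    nerr <- rbinom(1, n * w, errRate)
    if (nerr > 0) {
        cells <- sample(n * w, nerr)
        for (cell in cells) {
            j <- (cell - 1L) %% n + 1L
            p <- (cell - 1L) %/% n + 1L
            R[j, p] <- sample(setdiff(ALPH, ctx[p]), 1)
            if (R[j, p] == "D") Q[j, p] <- 0
        }
    }
    new("WindowPileup", Q = Q, R = R, context = ctx, chrom = "chrT",
        center = 50L, strand = "+", flank = flank)
}

makePileup <- function(Q, R = NULL, ctx = NULL) {
    w <- ncol(Q)
    flank <- (w - 1L) %/% 2L
    if (is.null(ctx)) ctx <- rep("A", w)
    if (is.null(R)) R <- matrix(rep(ctx, each = nrow(Q)), nrow(Q), w)
    new("WindowPileup", Q = Q, R = R, context = ctx, chrom = "chrT",
        center = 50L, strand = "+", flank = as.integer(flank))
}
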