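## Independent brute-force oracles used across the test files.  These are
## deliberately naive re-derivations that share no code with the package.

iupacMembers <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## nested-loop character-by-character scanner; N in the subject never
## matches; circular sequences are scanned on seq + first (k-1) letters
scanOracle <- function(seq, pattern, circular = FALSE) {
    sv <- strsplit(seq, "")[[1]]
    pv <- strsplit(pattern, "")[[1]]
    k <- length(pv)
    L <- length(sv)
    if (L < k) return(integer(0))
    if (circular) sv <- c(sv, sv[seq_len(k - 1L)])
    hits <- integer(0)
    for (s in 0:(L - 1L)) {
        if (s + k > length(sv)) next
        ok <- TRUE
        for (j in seq_len(k)) {
            ch <- sv[s + j]
            if (ch == "N" || !(ch %in% iupacMembers[[pv[j]]])) {
                ok <- FALSE
                break
            }
        }
        if (ok) hits <- c(hits, s)
    }
    hits
}

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

## exact one-sided (over-representation) hypergeometric p by summation
hyperOracle <- function(a, b, c, d) {
    N <- a + b + c + d
    K <- a + c      # genes with the property
    n <- a + b      # set size
    js <- max(0, n - (N - K)):min(n, K)
    probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
    sum(probs[js >= a])
}

## sort-based Benjamini-Hochberg adjustment
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(1, adj)
    out
}

revcompChar <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## small plan used by several files: quick to simulate, still carries the
## full planted structure
smallPlan <- function(seed = 11, ...) {
    args <- list(seed = seed, genomeLength = 2e5, nGenes = 120,
                 nUnder = 5L, nAsym = 3L)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(syntheticPlan, args)
}
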