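## Shared fixtures, built in code.

## Tiny V^G table: 4 genes, 2 tissues + mean, one gene uncovered.
tinyVGTable <- function() {
    m <- matrix(c(0.01, 0.03, 0.02, NA,
                  0.02, 0.01, NA, NA,
                  0.015, 0.015, 0.02, NA),
                nrow = 4,
                dimnames = list(c("ENSG01", "ENSG02", "ENSG03", "ENSG04"),
                                c("AE:Brain", "AE:Liver", "AE")))
    VGTable(m, weights = c(Brain = 2, Liver = 1))
}

tinyDETable <- function() {
    DEResultTable(c("ENSG01", "ENSG02", "ENSG03", "ENSG04"),
                  logFC = c(2.0, 0.5, 1.0, -3.0),
                  p = c(1e-6, 1e-5, 1e-4, 0.5),
                  pAdj = c(1e-5, 1e-4, 1e-3, 0.8))
}

## Reference study shared across tests (generated once per run).
refConfig <- function(seed = 101L, ...) simulationConfig(seed = seed, ...)

refStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateStudy(refConfig())
        cache
    }
})

## Brute-force Mann-Whitney oracle: full enumeration over combn().
mwEnumOracle <- function(a, b) {
    pooled <- c(a, b)
    nA <- length(a); N <- length(pooled)
    r <- rank(pooled)
    mu <- nA * length(b) / 2
    uOf <- function(idx) sum(r[idx]) - nA * (nA + 1) / 2
    uObs <- uOf(seq_len(nA))
    sets <- utils::combn(N, nA)
    us <- apply(sets, 2L, uOf)
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

## From-scratch BH step-up reference.
bhReference <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## Brute-force hypergeometric upper tail by pmf summation.
hyperTailOracle <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Brute-force binomial upper tail.
binomTailOracle <- function(k, n, p0) {
    js <- k:n
    sum(choose(n, js) * p0^js * (1 - p0)^(n - js))
}
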