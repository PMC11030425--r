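## Mann-Whitney U, native implementation.
##
## Exact two-sided p by enumeration of the rank-sum distribution when both
## samples are small (n <= exactMax each): the distribution of the rank
## sum over all equally likely assignments of the pooled (possibly tied)
## ranks is built with a generating-function dynamic program, which agrees
## with full combn() enumeration but scales to the mid sizes used for
## cross-checks. Larger samples use the normal approximation with tie
## correction and continuity correction.
mannWhitneyU <- function(a, b, exactMax = 8L) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    nA <- length(a); nB <- length(b)
    if (nA < 1L || nB < 1L) stop("both samples must be non-empty")
    pooled <- c(a, b)
    r <- rank(pooled)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    mu <- nA * nB / 2

    if (nA <= exactMax && nB <= exactMax) {
        ## exact: distribution of 2*ranksum over all size-nA subsets
        r2 <- as.integer(round(2 * r))          # half-ranks -> integers
        N <- nA + nB
        maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(nA)])
        ## counts[k+1, s+1] = number of subsets of size k with 2*ranksum s
        counts <- matrix(0, nrow = nA + 1L, ncol = maxS + 1L)
        counts[1L, 1L] <- 1
        done <- 0L
        for (x in r2) {
            done <- done + 1L
            for (k in seq(min(nA, done), 1L)) {
                src <- counts[k, seq_len(maxS + 1L - x)]
                counts[k + 1L, (x + 1L):(maxS + 1L)] <-
                    counts[k + 1L, (x + 1L):(maxS + 1L)] + src
            }
        }
        dist2 <- counts[nA + 1L, ]
        s <- which(dist2 > 0) - 1L              # achievable 2*ranksum
        w <- dist2[s + 1L]
        Us <- s / 2 - nA * (nA + 1) / 2
        dev <- abs(Us - mu)
        p <- sum(w[dev >= abs(U - mu) - 1e-9]) / sum(w)
        method <- "exact"
    } else {
        N <- nA + nB
        ties <- table(pooled)
        sig2 <- nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sig2 <= 0) {                         # all values identical
            return(list(U = U, p = 1, method = "normal"))
        }
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        method <- "normal"
    }
    list(U = U, p = min(1, p), method = method)
}

#' Compare a per-gene metric between two gene sets
#'
#' Two-sided Mann-Whitney U test of a gene-level value (V^G, absolute
#' fold change, ...) between two gene sets, e.g. ClinGen
#' haploinsufficient versus nonessential genes. Genes present in both
#' sets are removed from both before testing; genes without a value are
#' dropped. The exact null distribution is enumerated when both samples
#' have at most \code{exactMax} observations; otherwise a tie- and
#' continuity-corrected normal approximation is used.
#'
#' @param values named numeric vector, gene id -> value
#' @param setA,setB character vectors of gene ids
#' @param nameA,nameB labels for the report
#' @param exactMax per-sample size limit for the exact test
#' @return a [SetComparisonResult-class]
#' @export
compareGeneSets <- function(values, setA, setB, nameA = "A", nameB = "B",
                            exactMax = 8L) {
    if (is.null(names(values))) stop("'values' must be named by gene id")
    setA <- unique(setA); setB <- unique(setB)
    both <- intersect(setA, setB)
    setA <- setdiff(setA, both); setB <- setdiff(setB, both)
    va <- values[intersect(setA, names(values))]
    vb <- values[intersect(setB, names(values))]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb))
        stop("a set has no gene with a value after joining")
    res <- mannWhitneyU(va, vb, exactMax = exactMax)
    new("SetComparisonResult", setA = nameA, setB = nameB,
        nA = length(va), nB = length(vb),
        medianA = stats::median(va), medianB = stats::median(vb),
        statistic = res$U, p = res$p, method = res$method)
}

setMethod("show", "SetComparisonResult", function(object) {
    cat(sprintf(
        "Mann-Whitney U (two-sided, %s): %s (n=%d, median=%.4g) vs %s (n=%d, median=%.4g)\n  U = %g, p = %.4g\n",
        object@method, object@setA, object@nA, object@medianA,
        object@setB, object@nB, object@medianB, object@statistic, object@p))
})

#' Tissue with the lowest V^G per gene
#'
#' For each gene, the tissue whose V^G estimate is smallest, considering
#' only tissues with a calculated value; ties are broken by taking the
#' lexicographically first tissue. Genes without any tissue estimate map
#' to \code{NA}.
#'
#' @param vg a [VGTable-class]
#' @param source which track family to use (default \code{"AEML"})
#' @param genes optional gene subset; default all genes in the table
#' @return named character vector, gene -> tissue label (or \code{NA})
#' @export
lowestVGTissue <- function(vg, source = "AEML", genes = NULL) {
    stopifnot(is(vg, "VGTable"))
    tissues <- vgTissues(vg, source)
    if (!length(tissues))
        stop("no tissue-specific '", source, "' tracks in the table")
    m <- vg@vg[, vgTrackName(source, tissues), drop = FALSE]
    colnames(m) <- tissues
    m <- m[, order(colnames(m)), drop = FALSE]   # lexicographic tie-break
    if (!is.null(genes)) {
        m <- m[intersect(genes, rownames(m)), , drop = FALSE]
    }
    out <- apply(m, 1L, function(row) {
        if (all(is.na(row))) NA_character_ else names(row)[which.min(row)]
    })
    out
}

#' Enrichment of a gene set's lowest-V^G tissues in a tissue group
#'
#' Tests whether genes of interest (e.g. known disease genes) have their
#' lowest V^G disproportionately often in a given tissue group (e.g. the
#' brain tissues), against a background gene set. With \code{k} interest
#' genes assigned into the group out of \code{n} assigned at all, and the
#' background fraction \code{p0} computed over assigned background genes,
#' the p-value is the one-sided (greater) binomial tail
#' \code{P[X >= k]}, \code{X ~ Binomial(n, p0)}.
#'
#' @param interest,background character vectors of gene ids; background
#'   genes overlapping the interest set are removed from the background
#' @param vg a [VGTable-class] with tissue-specific tracks
#' @param tissueGroup character vector of tissue labels
#' @param source V^G track family (default \code{"AEML"})
#' @return list with \code{k}, \code{n}, \code{p0}, \code{p}
#' @export
lowestTissueEnrichment <- function(interest, background, vg, tissueGroup,
                                   source = "AEML") {
    if (!length(tissueGroup)) stop("empty tissue group")
    background <- setdiff(background, interest)
    assign_i <- lowestVGTissue(vg, source, genes = interest)
    assign_b <- lowestVGTissue(vg, source, genes = background)
    assign_i <- assign_i[!is.na(assign_i)]
    assign_b <- assign_b[!is.na(assign_b)]
    if (!length(assign_i) || !length(assign_b))
        stop("no assigned gene in interest or background set")
    k <- sum(assign_i %in% tissueGroup)
    n <- length(assign_i)
    p0 <- mean(assign_b %in% tissueGroup)
    if ((p0 == 0 && k > 0) || (p0 == 1 && k < n))
        stop("background fraction of ", p0,
             " contradicts the observed count; check the tissue group")
    p <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
    list(k = k, n = n, p0 = p0, p = p)
}

#' Background gene set by explicit subtraction
#'
#' The background universe for set comparisons: all genes with a V^G
#' value, minus the genes claimed by any foreground set.
#'
#' @param universe character vector of gene ids (e.g. all genes with an
#'   AE-based V^G)
#' @param ... any number of foreground gene sets (character vectors)
#' @return character vector
#' @export
backgroundSet <- function(universe, ...) {
    fg <- unique(unlist(list(...), use.names = FALSE))
    setdiff(unique(universe), fg)
}
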