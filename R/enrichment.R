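#' Select the top-ranked genes of a recalibrated table
#'
#' Takes the \code{n} best-ranked genes under either the nominal or the
#' recalibrated ordering. With \code{n = "auto"}, half of the ranked
#' (significant) genes are taken, rounded to the nearest 100 (half-up):
#' 4,000 significant genes give a top list of 2,000.
#'
#' @param table a [RecalibratedTable-class]
#' @param by \code{"recalibrated"} or \code{"nominal"}
#' @param n number of genes, or \code{"auto"}
#' @return character vector of gene ids, best rank first
#' @export
selectTopGenes <- function(table, by = c("recalibrated", "nominal"),
                           n = "auto") {
    stopifnot(is(table, "RecalibratedTable"))
    by <- match.arg(by)
    rk <- if (by == "recalibrated") table$rank_recal else table$rank_nominal
    ranked <- which(!is.na(rk))
    if (identical(n, "auto")) {
        n <- roundNearest100(0.5 * length(ranked))
    }
    n <- as.integer(n)
    if (n < 1L || n > length(ranked))
        stop("requested ", n, " genes but only ", length(ranked),
             " are ranked")
    ids <- rownames(table)[ranked]
    ids[order(rk[ranked])][seq_len(n)]
}

## Round half-up to the nearest 100 (R's round() is banker's rounding).
roundNearest100 <- function(x) 100 * floor(x / 100 + 0.5)

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene
#' set against a background universe. With \code{N} background genes,
#' \code{K} of them in the term, and a query of \code{n} genes of which
#' \code{k} are in the term, the p-value is the upper hypergeometric
#' tail \code{P[X >= k]}. Over-representation only; depletion is not
#' tested. BH adjustment is applied across the terms of the call, so
#' separate annotation namespaces (e.g. the GO BP/CC/MF resources)
#' should be tested in separate calls.
#'
#' @param query character vector of gene ids; must be a subset of
#'   \code{background}
#' @param background character vector: the gene universe (e.g. all genes
#'   with measured expression and a V^G estimate)
#' @param terms named list of character vectors, term id -> member genes;
#'   an optional \code{names()}-parallel attribute \code{"termNames"}
#'   (named character) supplies human-readable names
#' @param minSize drop terms with fewer in-background genes than this
#' @return [S4Vectors::DataFrame] with columns \code{term_id},
#'   \code{name}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p},
#'   \code{p_adj}, sorted by \code{p} then term id
#' @export
ora <- function(query, background, terms, minSize = 1L) {
    query <- unique(query); background <- unique(background)
    if (!length(query) || !length(background))
        stop("empty query or background")
    extra <- setdiff(query, background)
    if (length(extra))
        stop("query genes outside the background universe: ",
             paste(utils::head(extra, 5), collapse = ", "),
             if (length(extra) > 5) ", ...")
    if (!length(terms)) stop("no annotation terms supplied")
    termNames <- attr(terms, "termNames")
    N <- length(background)
    n <- length(query)
    rows <- lapply(names(terms), function(id) {
        tg <- intersect(unique(terms[[id]]), background)
        K <- length(tg)
        if (K < minSize) return(NULL)
        k <- length(intersect(tg, query))
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id, k = k, K = K, p = p)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) stop("no term overlaps the background")
    nm <- if (!is.null(termNames)) unname(termNames[rows$term_id]) else
        rows$term_id
    nm[is.na(nm)] <- rows$term_id[is.na(nm)]
    out <- DataFrame(term_id = rows$term_id, name = nm,
                     k = as.integer(rows$k), K = as.integer(rows$K),
                     n = n, N = N, p = rows$p,
                     p_adj = adjustBH(rows$p))
    out[order(out$p, out$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (values clipped at 1,
#' monotone in the sorted order). Thin validated wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0,1]
#' @return adjusted p-values, same order as the input
#' @export
adjustBH <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must be in [0,1] and non-missing")
    stats::p.adjust(p, method = "BH")
}

#' Compare term enrichment before and after recalibration
#'
#' Builds the union of terms significantly over-represented (adjusted
#' p <= alpha) in at least one of two ORA runs (nominal top-N selection
#' vs recalibrated top-N selection, against the same background). A term
#' not enriched on one side has that side imputed with p = 1 exactly.
#' Terms are classified by the \code{direction} column: \code{"after"}
#' when the adjusted p is smaller post-recalibration, \code{"before"}
#' when smaller pre-recalibration, \code{"unchanged"} otherwise.
#'
#' @param nominal,recal ORA result tables from [ora()] computed against
#'   the same background (checked via their \code{N})
#' @param alpha adjusted-p significance cutoff (default 0.05)
#' @return an [EnrichmentComparison-class] (possibly with zero rows)
#' @export
compareEnrichment <- function(nominal, recal, alpha = 0.05) {
    for (r in list(nominal, recal))
        if (!all(c("term_id", "name", "p_adj", "N") %in% colnames(r)))
            stop("inputs must be ora() result tables")
    if (nrow(nominal) && nrow(recal) &&
        nominal$N[1L] != recal$N[1L])
        stop("background mismatch: N = ", nominal$N[1L], " vs ",
             recal$N[1L], "; both runs must share one universe")
    sigN <- nominal[!is.na(nominal$p_adj) & nominal$p_adj <= alpha, ]
    sigR <- recal[!is.na(recal$p_adj) & recal$p_adj <= alpha, ]
    ids <- union(sigN$term_id, sigR$term_id)
    nm <- c(stats::setNames(nominal$name, nominal$term_id),
            stats::setNames(recal$name, recal$term_id))
    ## a side where the term was not enriched is imputed to exactly 1,
    ## mirroring tools that only report significant terms
    pn <- stats::setNames(sigN$p_adj, sigN$term_id)
    pr <- stats::setNames(sigR$p_adj, sigR$term_id)
    p_nominal <- ifelse(ids %in% names(pn), unname(pn[ids]), 1)
    p_recal <- ifelse(ids %in% names(pr), unname(pr[ids]), 1)
    direction <- ifelse(p_recal < p_nominal, "after",
                        ifelse(p_recal > p_nominal, "before", "unchanged"))
    df <- DataFrame(term_id = ids, name = unname(nm[ids]),
                    association = rep(NA_character_, length(ids)),
                    p_nominal = p_nominal, p_recal = p_recal,
                    direction = direction)
    df <- df[order(df$term_id), , drop = FALSE]
    bg <- if (nrow(nominal)) nominal$N[1L] else if (nrow(recal))
        recal$N[1L] else NA_integer_
    new("EnrichmentComparison", df, alpha = alpha,
        backgroundSize = as.integer(bg))
}

#' Label comparison terms by name-pattern association
#'
#' Assigns each term of an [EnrichmentComparison-class] the first label
#' whose pattern matches the term name as a case-insensitive substring
#' (e.g. \code{c(regulation = "regulation", response = "response")}).
#'
#' @param comparison an \code{EnrichmentComparison}
#' @param patterns named character vector, label -> substring
#' @return the comparison with its \code{association} column filled
#' @export
annotateAssociation <- function(comparison, patterns) {
    stopifnot(is(comparison, "EnrichmentComparison"))
    assoc <- comparison$association
    for (lab in rev(names(patterns))) {
        hit <- grepl(patterns[[lab]], comparison$name, ignore.case = TRUE,
                     fixed = FALSE)
        assoc[hit] <- lab
    }
    df <- as(comparison, "DFrame")
    df$association <- assoc
    new("EnrichmentComparison", df, alpha = comparison@alpha,
        backgroundSize = comparison@backgroundSize)
}

#' Log-mean enrichment of name-matched terms
#'
#' Summarises a term association group by the geometric mean of its
#' adjusted p-values, \code{10^mean(log10 p)}, separately for the
#' nominal and the recalibrated side; imputed (p = 1) entries
#' participate.
#'
#' @param comparison an [EnrichmentComparison-class]
#' @param pattern case-insensitive substring matched against term names
#' @return list with \code{terms} (matched ids), \code{logmeanNominal},
#'   \code{logmeanRecal}; empty \code{terms} and \code{NA} means (with a
#'   warning) when nothing matches
#' @export
associationLogMean <- function(comparison, pattern) {
    stopifnot(is(comparison, "EnrichmentComparison"))
    hit <- grepl(pattern, comparison$name, ignore.case = TRUE)
    if (!any(hit)) {
        warning("no term name matches '", pattern, "'")
        return(list(terms = character(0), logmeanNominal = NA_real_,
                    logmeanRecal = NA_real_))
    }
    list(terms = comparison$term_id[hit],
         logmeanNominal = 10^mean(log10(comparison$p_nominal[hit])),
         logmeanRecal = 10^mean(log10(comparison$p_recal[hit])))
}

setMethod("show", "EnrichmentComparison", function(object) {
    cat(sprintf(
        "EnrichmentComparison: %d terms significant at alpha = %g (N = %d)\n",
        nrow(object), object@alpha, object@backgroundSize))
    if (nrow(object))
        cat(sprintf("  more enriched after recalibration: %d, before: %d, unchanged: %d\n",
            sum(object$direction == "after"),
            sum(object$direction == "before"),
            sum(object$direction == "unchanged")))
    callNextMethod()
})
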