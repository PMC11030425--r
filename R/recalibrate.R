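#' Construct a DEResultTable
#'
#' @param geneId character vector of gene ids (Ensembl; version suffixes
#'   are stripped)
#' @param logFC signed log2 fold changes
#' @param p raw p-values in [0,1]
#' @param pAdj adjusted p-values in [0,1]; \code{NA} allowed
#' @param baseExpr optional mean expression (e.g. DESeq2 baseMean)
#' @return a [DEResultTable-class]
#' @export
DEResultTable <- function(geneId, logFC, p, pAdj = NA_real_,
                          baseExpr = NULL) {
    geneId <- stripEnsemblVersion(as.character(geneId))
    if (anyDuplicated(geneId))
        stop("duplicate gene id(s): ",
             paste(unique(geneId[duplicated(geneId)]), collapse = ", "))
    df <- DataFrame(log_fc = as.numeric(logFC), p = as.numeric(p),
                    p_adj = rep_len(as.numeric(pAdj), length(geneId)),
                    row.names = geneId)
    if (!is.null(baseExpr)) df$base_expr <- as.numeric(baseExpr)
    new("DEResultTable", df)
}

#' Recalibrate a log fold change by population dosage variance
#'
#' The recalibrated fold change expresses an observed expression change
#' in units of the natural population variability of that gene: the log
#' fold change is standardized by the standard deviation of genetically
#' regulated expression, \code{fc_star = log_fc / sqrt(vg)}. Direction is
#' always preserved; genes with small V^G (dosage-constrained) are
#' amplified relative to highly variable genes.
#'
#' @param logFC signed log fold change(s), finite
#' @param vg V^G variance(s), strictly positive and finite, same length
#'   or length 1
#' @return recalibrated log fold change(s)
#' @examples
#' recalibrateFC(0.5, 0.04)   # 2.5
#' @export
recalibrateFC <- function(logFC, vg) {
    if (any(!is.finite(logFC)))
        stop("log fold changes must be finite")
    if (any(!is.finite(vg)) || any(vg <= 0))
        stop("V^G must be strictly positive and finite")
    logFC / sqrt(vg)
}

## Deterministic 1-based ranks by descending |value|, ties broken by
## gene id (lexicographic). `eligible` marks rankable rows; others NA.
rankByAbs <- function(values, ids, eligible = rep(TRUE, length(values))) {
    r <- rep(NA_integer_, length(values))
    idx <- which(eligible & !is.na(values))
    if (length(idx)) {
        o <- idx[order(-abs(values[idx]), ids[idx], method = "radix")]
        r[o] <- seq_along(o)
    }
    r
}

#' Recalibrate a differential-expression table and re-rank its genes
#'
#' Joins a DE result table with a V^G track, divides each gene's log fold
#' change by \code{sqrt(V^G)}, and assigns 1-based ranks by descending
#' absolute value under both the nominal and the recalibrated ordering.
#' Genes without a usable V^G estimate are excluded under the default
#' \code{missingPolicy = "drop"} (the published behaviour) or retained
#' unscaled, flagged and unranked under \code{"keep"}. When
#' \code{sigThreshold} is given, only genes with \code{p_adj} strictly
#' below it are ranked; the rest stay in the table with \code{NA} ranks.
#'
#' @param de a [DEResultTable-class]
#' @param vg a [VGTable-class]
#' @param source V^G track source (\code{"AE"}, \code{"eQTL"},
#'   \code{"ML"}, \code{"AEML"})
#' @param tissue tissue label or \code{"MEAN"}
#' @param sigThreshold optional adjusted-p significance cutoff
#'   (strictly-less-than)
#' @param missingPolicy \code{"drop"} or \code{"keep"}
#' @return a [RecalibratedTable-class], rows ordered by recalibrated rank
#'   (unranked genes last, by gene id)
#' @examples
#' de <- DEResultTable(c("g1", "g2"), c(2, 0.5), c(1e-5, 1e-4), c(1e-4, 1e-3))
#' vg <- VGTable(matrix(c(1, 0.01), 2, dimnames = list(c("g1", "g2"), "AE")))
#' recalibrateTable(de, vg, source = "AE")
#' @export
recalibrateTable <- function(de, vg, source = "AE", tissue = "MEAN",
                             sigThreshold = NULL,
                             missingPolicy = c("drop", "keep")) {
    stopifnot(is(de, "DEResultTable"), is(vg, "VGTable"))
    missingPolicy <- match.arg(missingPolicy)
    if (nrow(de) == 0L) stop("empty DE table")
    v <- vgColumn(vg, source, tissue)
    vg_used <- unname(v[match(rownames(de), names(v))])

    keep <- if (missingPolicy == "drop") !is.na(vg_used) else
        rep(TRUE, nrow(de))
    if (!any(keep))
        stop("no gene retained: none of the ", nrow(de), " DE genes has a '",
             vgTrackName(source, tissue), "' V^G estimate")
    out <- as(de[keep, , drop = FALSE], "DFrame")
    vg_used <- vg_used[keep]

    fc <- out$log_fc
    fc_star <- rep(NA_real_, length(fc))
    ok <- !is.na(vg_used)
    fc_star[ok] <- recalibrateFC(fc[ok], vg_used[ok])
    out$fc_star <- fc_star
    out$vg_used <- vg_used
    if (missingPolicy == "keep") out$vg_missing <- !ok

    eligible <- ok
    if (!is.null(sigThreshold))
        eligible <- eligible & !is.na(out$p_adj) & out$p_adj < sigThreshold
    ids <- rownames(out)
    out$rank_nominal <- rankByAbs(fc, ids, eligible)
    out$rank_recal <- rankByAbs(fc_star, ids, eligible)

    rr <- out$rank_recal
    ord <- order(ifelse(is.na(rr), Inf, as.numeric(rr)), ids,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
    new("RecalibratedTable", out, source = source, tissue = tissue,
        sigThreshold = if (is.null(sigThreshold)) NA_real_ else sigThreshold,
        missingPolicy = missingPolicy)
}

#' @describeIn recalibrateTable number of ranked (significant, scaled)
#'   genes in a recalibrated table
#' @param x a \code{RecalibratedTable}
#' @export
nRanked <- function(x) {
    stopifnot(is(x, "RecalibratedTable"))
    sum(!is.na(x$rank_recal))
}

#' Pearson correlation of absolute fold changes
#'
#' Agreement between nominal and recalibrated fold changes is measured as
#' the Pearson correlation of their absolute values: directionality never
#' changes under recalibration, so correlating signed values would
#' inflate the estimate.
#'
#' @param nominal,recal equal-length numeric vectors (length >= 3)
#' @return correlation in [-1, 1]; \code{NA} with a warning when either
#'   vector is constant after taking absolute values
#' @export
absPearson <- function(nominal, recal) {
    if (length(nominal) != length(recal) || length(nominal) < 3L)
        stop("need two equal-length vectors of length >= 3")
    a <- abs(nominal); b <- abs(recal)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant absolute values; correlation undefined")
        return(NA_real_)
    }
    stats::cor(a, b)
}

#' Spearman correlation with a bootstrap percentile confidence interval
#'
#' Point estimate is Spearman's rho on the full sample; the confidence
#' interval is the percentile interval of rho over paired resamples with
#' replacement.
#'
#' @param x,y equal-length numeric vectors (length >= 10)
#' @param nBoot number of bootstrap resamples (>= 100)
#' @param seed RNG seed for the resampling (restored afterwards)
#' @param level confidence level (default 0.95)
#' @return list with \code{rho}, \code{ciLow}, \code{ciHigh}
#' @export
spearmanWithBootstrapCI <- function(x, y, nBoot = 1000L, seed = 1L,
                                    level = 0.95) {
    n <- length(x)
    if (length(y) != n || n < 10L)
        stop("need paired vectors of length >= 10")
    if (nBoot < 100L) stop("nBoot must be >= 100")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
        warning("all-tied vector; Spearman correlation undefined")
        return(list(rho = NA_real_, ciLow = NA_real_, ciHigh = NA_real_))
    }
    rho <- stats::cor(x, y, method = "spearman")
    boots <- withSeed(seed, {
        vapply(seq_len(nBoot), function(i) {
            idx <- sample.int(n, n, replace = TRUE)
            suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
        }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    list(rho = rho, ciLow = qs[1], ciHigh = qs[2])
}

setMethod("show", "RecalibratedTable", function(object) {
    cat(sprintf(
        "RecalibratedTable: %d genes (%d ranked), V^G track '%s'%s\n",
        nrow(object), sum(!is.na(object$rank_recal)),
        vgTrackName(object@source, object@tissue),
        if (is.na(object@sigThreshold)) "" else
            sprintf(", p_adj < %g", object@sigThreshold)))
    callNextMethod()
})
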