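#' Construct a VGTable
#'
#' @param vg numeric matrix (genes x tracks) with unique gene-id rownames
#'   and track colnames of the form \code{"<source>"} (cross-tissue mean)
#'   or \code{"<source>:<tissue>"}. Values strictly positive or \code{NA}.
#' @param weights optional named numeric vector of per-tissue TPM weights.
#' @param stripVersions strip Ensembl version suffixes (".1", ".12") from
#'   gene ids before storing, so tables from different releases join.
#' @return a [VGTable-class]
#' @examples
#' m <- matrix(c(0.01, 0.03, 0.02, NA), 2,
#'             dimnames = list(c("ENSG1", "ENSG2"), c("AE:Liver", "AE:Brain")))
#' VGTable(m, weights = c(Liver = 10, Brain = 5))
#' @export
VGTable <- function(vg, weights = numeric(0), stripVersions = TRUE) {
    vg <- as.matrix(vg)
    storage.mode(vg) <- "double"
    if (stripVersions && !is.null(rownames(vg)))
        rownames(vg) <- stripEnsemblVersion(rownames(vg))
    new("VGTable", vg = vg, weights = weights)
}

#' Strip Ensembl version suffixes from gene identifiers
#'
#' \code{"ENSG00000139618.15"} becomes \code{"ENSG00000139618"}. Ids
#' without a suffix pass through unchanged.
#'
#' @param ids character vector of gene ids
#' @return character vector
#' @export
stripEnsemblVersion <- function(ids) sub("\\.[0-9]+$", "", ids)

#' @rdname VGTable-class
#' @export
setMethod("vgMatrix", "VGTable", function(x) x@vg)

#' @rdname VGTable-class
#' @export
setMethod("geneIds", "VGTable", function(x) rownames(x@vg))

#' @rdname VGTable-class
#' @export
setMethod("tissueWeights", "VGTable", function(x) x@weights)

#' @rdname VGTable-class
#' @export
setReplaceMethod("tissueWeights", "VGTable", function(x, value) {
    x@weights <- value
    validObject(x)
    x
})

#' @describeIn VGTable-class number of genes / tracks
#' @export
setMethod("dim", "VGTable", function(x) dim(x@vg))

#' @describeIn VGTable-class subset genes (i) and tracks (j)
#' @param i,j,drop row (gene) and column (track) indices; \code{drop}
#'   ignored
#' @export
setMethod("[", "VGTable", function(x, i, j, ..., drop = FALSE) {
    m <- x@vg
    if (!missing(i)) m <- m[i, , drop = FALSE]
    if (!missing(j)) m <- m[, j, drop = FALSE]
    initialize(x, vg = m)
})

setMethod("show", "VGTable", function(object) {
    cat(sprintf("VGTable: %d genes x %d tracks\n", nrow(object@vg),
                ncol(object@vg)))
    if (ncol(object@vg)) {
        cover <- colSums(!is.na(object@vg))
        cat("tracks (genes covered):",
            paste0(colnames(object@vg), " (", cover, ")", collapse = ", "),
            "\n")
    }
    if (length(object@weights))
        cat(sprintf("tissue weights: %d tissues (TPM)\n",
                    length(object@weights)))
})

## ---- track-name helpers ------------------------------------------------

vgTrackName <- function(source, tissue = "MEAN") {
    n <- max(length(source), length(tissue))
    source <- rep_len(source, n)
    tissue <- rep_len(tissue, n)
    ifelse(tissue == "MEAN", source, paste0(source, ":", tissue))
}

vgTrackSource <- function(track) sub(":.*$", "", track)

vgTrackTissue <- function(track)
    ifelse(grepl(":", track), sub("^[^:]*:", "", track), "MEAN")

#' Extract one V^G track as a named vector
#'
#' @param x a [VGTable-class]
#' @param source estimate source: \code{"AE"}, \code{"eQTL"}, \code{"ML"}
#'   or \code{"AEML"}
#' @param tissue tissue label, or \code{"MEAN"} (default) for the
#'   cross-tissue mean track
#' @return named numeric vector over all genes of the table (\code{NA}
#'   where missing)
#' @export
vgColumn <- function(x, source, tissue = "MEAN") {
    stopifnot(is(x, "VGTable"))
    track <- vgTrackName(source, tissue)
    if (!track %in% colnames(x@vg))
        stop("no such V^G track: '", track, "' (available: ",
             paste(colnames(x@vg), collapse = ", "), ")")
    x@vg[, track]
}

#' Tissues available for a source in a VGTable
#' @inheritParams vgColumn
#' @return character vector of tissue labels (excluding MEAN), sorted
#' @export
vgTissues <- function(x, source) {
    tracks <- colnames(x@vg)
    keep <- vgTrackSource(tracks) == source & grepl(":", tracks)
    sort(vgTrackTissue(tracks[keep]))
}

## ---- aggregation -------------------------------------------------------

#' @rdname aggregateTissueVG
#' @param weights named non-negative numeric vector of tissue weights
#'   (TPM); must cover every tissue supplied with a value
#' @export
setMethod("aggregateTissueVG", "numeric", function(x, weights, ...) {
    if (is.null(names(x)) || is.null(names(weights)))
        stop("variances and weights must be named by tissue")
    if (any(!is.na(x) & x <= 0))
        stop("V^G values must be strictly positive")
    if (anyNA(weights) || any(weights < 0))
        stop("weights must be non-negative and non-missing")
    have <- names(x)[!is.na(x)]
    miss <- setdiff(have, names(weights))
    if (length(miss))
        stop("no weight for tissue(s): ", paste(miss, collapse = ", "))
    use <- have[weights[have] > 0]
    if (!length(use))
        return(NA_real_)
    w <- weights[use]
    sum(w) / sum(w / x[use])
})

#' @rdname aggregateTissueVG
#' @export
setMethod("aggregateTissueVG", "VGTable", function(x, source = "AE", ...) {
    tissues <- vgTissues(x, source)
    if (!length(tissues))
        stop("no tissue-specific '", source, "' tracks to aggregate")
    if (!length(x@weights))
        stop("the table carries no tissue weights; set tissueWeights() first")
    sub <- x@vg[, vgTrackName(source, tissues), drop = FALSE]
    colnames(sub) <- tissues
    mean_vg <- apply(sub, 1L, aggregateTissueVG, weights = x@weights)
    m <- x@vg
    m <- m[, setdiff(colnames(m), source), drop = FALSE]
    m <- cbind(m, mean_vg)
    colnames(m)[ncol(m)] <- source
    initialize(x, vg = m)
})

## ---- merge -------------------------------------------------------------

#' @rdname mergeVG
#' @export
setMethod("mergeVG", signature("numeric", "numeric"), function(ae, ml, ...) {
    if (length(ae) != length(ml))
        stop("'ae' and 'ml' must have the same length")
    out <- ae
    out[is.na(out)] <- ml[is.na(out)]
    out
})

#' @rdname mergeVG
#' @export
setMethod("mergeVG", signature("VGTable", "missing"),
    function(ae, ml, aeSource = "AE", mlSource = "ML", into = "AEML", ...) {
    x <- ae
    tracks <- colnames(x@vg)
    pick <- function(track) {
        if (track %in% tracks) x@vg[, track] else
            rep(NA_real_, nrow(x@vg))
    }
    tissues <- union(vgTissues(x, aeSource), vgTissues(x, mlSource))
    out_tracks <- vgTrackName(into, c("MEAN", tissues))
    src_ae <- vgTrackName(aeSource, c("MEAN", tissues))
    src_ml <- vgTrackName(mlSource, c("MEAN", tissues))
    merged <- mapply(function(a, b) mergeVG(pick(a), pick(b)),
                     src_ae, src_ml)
    colnames(merged) <- out_tracks
    keep <- setdiff(tracks, out_tracks)
    initialize(x, vg = cbind(x@vg[, keep, drop = FALSE], merged))
})

## ---- log-base conversion ----------------------------------------------

#' Convert a V^G estimate between log bases
#'
#' V^G is a variance of log-scale expression effects, so changing the log
#' base from \code{b1} to \code{b2} multiplies it by
#' \code{(ln b1 / ln b2)^2}. The package works in log2 throughout (the
#' unit of DESeq2 fold changes and allelic-fold-change-derived V^G), so
#' conversion is only needed for externally supplied tables on another
#' scale.
#'
#' @param vg variance(s), strictly positive (\code{NA} passes through)
#' @param from,to current and target log base; positive and != 1
#' @return converted variance(s)
#' @examples
#' convertLogBase(1.0, from = exp(1), to = 2)  # 1/log(2)^2
#' @export
convertLogBase <- function(vg, from = 2, to = 2) {
    for (b in c(from, to))
        if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0 || b == 1)
            stop("log bases must be positive and different from 1")
    if (any(!is.na(vg) & vg <= 0))
        stop("V^G values must be strictly positive")
    vg * (log(from) / log(to))^2
}

## ---- internal: seeded evaluation --------------------------------------

## Evaluate expr under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
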