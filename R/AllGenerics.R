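#' @rdname VGTable-class
#' @param x a \code{VGTable}
#' @export
setGeneric("vgMatrix", function(x) standardGeneric("vgMatrix"))

#' @rdname VGTable-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname VGTable-class
#' @export
setGeneric("tissueWeights", function(x) standardGeneric("tissueWeights"))

#' @rdname VGTable-class
#' @param value replacement value
#' @export
setGeneric("tissueWeights<-",
    function(x, value) standardGeneric("tissueWeights<-"))

#' Weighted harmonic-mean aggregation of tissue-specific V^G
#'
#' The cross-tissue mean V^G of a gene is the weighted harmonic mean of
#' its tissue-specific estimates, weighted by per-tissue mean expression
#' (TPM). Only tissues contributing both a variance estimate and a
#' strictly positive weight enter the aggregate; weights are implicitly
#' re-normalized over that subset, so the result always lies between the
#' smallest and largest contributing estimate.
#'
#' @param x a named numeric vector of per-tissue variances (strictly
#'   positive; \code{NA} allowed and skipped), or a [VGTable-class].
#' @param ... method arguments: \code{weights} (named non-negative
#'   numeric, tissue TPM) for the numeric method; \code{source} for the
#'   table method.
#' @return For the numeric method, a single variance, or \code{NA} when
#'   no tissue is usable. For the table method, a \code{VGTable} with the
#'   \code{"<source>"} mean column (re)computed from its
#'   \code{"<source>:<tissue>"} columns.
#' @examples
#' aggregateTissueVG(c(A = 0.01, B = 0.03), weights = c(A = 1, B = 1))
#' @export
setGeneric("aggregateTissueVG",
    function(x, ...) standardGeneric("aggregateTissueVG"))

#' Merge V^G tracks with allelic-expression precedence
#'
#' Combines an allelic-expression-derived estimate with a machine-learned
#' fallback: the AE value is used wherever present, the ML value fills the
#' gaps, and missingness propagates only where both are missing. Applied
#' element-wise this builds the AEML track (mean and per-tissue).
#'
#' @param ae primary estimates (numeric vector, \code{NA} = missing), or a
#'   [VGTable-class].
#' @param ml fallback estimates, same length as \code{ae} (numeric
#'   method).
#' @param ... table-method arguments: \code{aeSource}, \code{mlSource},
#'   \code{into} (default \code{"AE"}, \code{"ML"}, \code{"AEML"}).
#' @return numeric vector, or a \code{VGTable} gaining the merged columns.
#' @examples
#' mergeVG(c(0.02, NA, NA), c(0.05, 0.05, NA))
#' @export
setGeneric("mergeVG", function(ae, ml, ...) standardGeneric("mergeVG"))
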