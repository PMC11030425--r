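#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importFrom stats setNames
#' @importFrom utils head
NULL

#' VGTable: per-gene genetic dosage-variance estimates
#'
#' A \code{VGTable} holds per-gene estimates of the variance in gene
#' expression attributable to common cis-regulatory genetic variation in
#' the population (V^G), in squared log-fold-change units. Rows are genes
#' (Ensembl identifiers, version suffix stripped); columns are estimate
#' tracks named \code{"<source>"} for the cross-tissue mean or
#' \code{"<source>:<tissue>"} for a tissue-specific estimate, where source
#' is one of \code{AE} (allelic expression), \code{eQTL}, \code{ML}
#' (machine-learned) or \code{AEML} (AE with ML fallback).
#'
#' Missingness is explicit (\code{NA}); a stored value must be strictly
#' positive, because recalibration divides by its square root.
#'
#' @slot vg numeric matrix of variance estimates, genes x tracks.
#' @slot weights named non-negative numeric vector of per-tissue mean
#'   expression (TPM), used as weights in harmonic-mean aggregation.
#'   May be empty when no aggregation is required.
#'
#' @seealso [VGTable()] for construction, [aggregateTissueVG()],
#'   [mergeVG()], [readVGTable()]
#' @export
setClass("VGTable",
    representation(vg = "matrix", weights = "numeric"))

setValidity("VGTable", function(object) {
    m <- object@vg
    if (!is.numeric(m))
        return("'vg' must be a numeric matrix")
    if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == ""))
        return("all rows must be named by a non-empty gene id")
    if (anyDuplicated(rownames(m)))
        return("duplicate gene ids")
    if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
        return("columns must have unique '<source>' or '<source>:<tissue>' names")
    vals <- m[!is.na(m)]
    if (any(vals <= 0))
        return("V^G values must be strictly positive; encode missing as NA, never 0")
    w <- object@weights
    if (length(w)) {
        if (is.null(names(w)) || anyDuplicated(names(w)))
            return("'weights' must be uniquely named by tissue")
        if (anyNA(w) || any(w < 0))
            return("tissue weights must be non-negative and non-missing")
    }
    TRUE
})

#' DEResultTable: upstream differential-expression results
#'
#' One row per gene, holding the signed log fold change and (adjusted)
#' p-values produced by an upstream DE tool such as DESeq2. Columns:
#' \code{log_fc}, \code{p}, \code{p_adj} (may be \code{NA}, as DESeq2
#' emits for independent-filtering casualties) and optionally
#' \code{base_expr}. Row names are gene ids.
#'
#' @seealso [DEResultTable()], [readDETable()], [recalibrateTable()]
#' @export
setClass("DEResultTable", contains = "DFrame")

setValidity("DEResultTable", function(object) {
    need <- c("log_fc", "p", "p_adj")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("rows must be uniquely named by gene id")
    for (pc in c("p", "p_adj")) {
        v <- object[[pc]]
        bad <- !is.na(v) & (v < 0 | v > 1)
        if (any(bad))
            return(paste0("column '", pc, "' outside [0,1]"))
    }
    TRUE
})

#' RecalibratedTable: DE results rescaled by population dosage variance
#'
#' Extends [DEResultTable-class] with the recalibrated log fold change
#' \code{fc_star = log_fc / sqrt(vg_used)}, the variance applied
#' (\code{vg_used}), and 1-based ranks by descending absolute value under
#' the nominal (\code{rank_nominal}) and recalibrated (\code{rank_recal})
#' orderings. When a significance threshold was applied, only significant
#' genes carry ranks; others have \code{NA} ranks.
#'
#' @slot source which V^G track was used (AE, eQTL, ML or AEML).
#' @slot tissue tissue label, or "MEAN" for the cross-tissue mean.
#' @slot sigThreshold adjusted-p cutoff used for ranking, or NA.
#' @slot missingPolicy "drop" (genes without usable V^G removed, the
#'   default and the published behaviour) or "keep" (retained, flagged,
#'   unscaled and unranked).
#' @export
setClass("RecalibratedTable", contains = "DEResultTable",
    representation(source = "character", tissue = "character",
                   sigThreshold = "numeric", missingPolicy = "character"))

setValidity("RecalibratedTable", function(object) {
    need <- c("fc_star", "vg_used", "rank_nominal", "rank_recal")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
    fs <- object$fc_star; fc <- object$log_fc
    ok <- is.na(fs) | sign(fs) == sign(fc)
    if (!all(ok))
        return("recalibration must preserve the direction of regulation")
    TRUE
})

#' SetComparisonResult: two-set distribution comparison
#'
#' Result of a two-sided Mann-Whitney U comparison of a per-gene metric
#' between two gene sets (e.g. V^G of ClinGen haploinsufficient vs
#' nonessential genes).
#'
#' @slot setA,setB set labels.
#' @slot nA,nB number of genes with a value in each set after
#'   missing-value removal.
#' @slot medianA,medianB sample medians of the compared values.
#' @slot statistic the Mann-Whitney U statistic for set A.
#' @slot p two-sided p-value.
#' @slot method "exact" (rank enumeration) or "normal" (tie- and
#'   continuity-corrected approximation).
#' @export
setClass("SetComparisonResult",
    representation(setA = "character", setB = "character",
        nA = "integer", nB = "integer",
        medianA = "numeric", medianB = "numeric",
        statistic = "numeric", p = "numeric", method = "character"))

#' EnrichmentComparison: per-term enrichment before vs after recalibration
#'
#' One row per annotation term that was significantly over-represented
#' (adjusted p <= alpha) in at least one of the two selections (nominal
#' top-N vs recalibrated top-N). The side where a term was not enriched is
#' imputed with p = 1 exactly. Columns: \code{term_id}, \code{name},
#' \code{association} (label from name-pattern matching, NA until
#' annotated), \code{p_nominal}, \code{p_recal} (both BH-adjusted), and
#' \code{direction} (\code{"after"} when smaller post-recalibration,
#' \code{"before"} when smaller pre-recalibration, else
#' \code{"unchanged"}).
#'
#' @slot alpha adjusted-p significance cutoff used for inclusion.
#' @slot backgroundSize size of the shared background universe.
#' @export
setClass("EnrichmentComparison", contains = "DFrame",
    representation(alpha = "numeric", backgroundSize = "integer"))

setValidity("EnrichmentComparison", function(object) {
    need <- c("term_id", "name", "association", "p_nominal", "p_recal",
              "direction")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
    if (anyDuplicated(object$term_id))
        return("each term must appear exactly once")
    pv <- c(object$p_nominal, object$p_recal)
    if (anyNA(pv) || any(pv < 0 | pv > 1))
        return("p-values must be in [0,1]; non-tested sides are imputed to 1")
    TRUE
})

#' TrainedVGModel: gradient-boosted regressor of ln V^G
#'
#' Wraps a fitted xgboost ensemble predicting the natural logarithm of
#' V^G from a fixed schema of gene-level features (constraint scores,
#' expression level, enhancer counts, ...). Predictions are exponentiated
#' back to the variance scale, so they are strictly positive.
#'
#' @slot booster the fitted \code{xgb.Booster}.
#' @slot featureNames ordered training feature schema; prediction is only
#'   defined for matrices with exactly these columns.
#' @slot labelTransform "ln" (labels are natural-log transformed V^G).
#' @slot params the hyperparameter record the ensemble was fitted with.
#' @slot importances named per-feature gain shares; non-negative, summing
#'   to 1 (uniform when the ensemble contains no splits).
#' @export
setClass("TrainedVGModel",
    representation(booster = "ANY", featureNames = "character",
        labelTransform = "character", params = "list",
        importances = "numeric"))

setValidity("TrainedVGModel", function(object) {
    imp <- object@importances
    if (!identical(sort(names(imp)), sort(object@featureNames)))
        return("importances must be named by the training features")
    if (any(imp < 0) || abs(sum(imp) - 1) > 1e-9)
        return("importances must be non-negative and sum to 1")
    if (object@labelTransform != "ln")
        return("only natural-log label transform is supported")
    TRUE
})

#' SimulationConfig: parameters of the synthetic fixture generator
#'
#' Describes one synthetic study: a lognormal V^G landscape with tissue
#' structure and missingness, a DE experiment whose fold-change magnitude
#' is weakly coupled to V^G, planted low-V^G "driver" and high-V^G
#' "responder" gene blocks with annotation terms covering them, and a
#' gene-feature matrix with a known label function for model training.
#' See [simulationConfig()] for the meaning and defaults of each field.
#'
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer", nTissues = "integer",
        vgLogMean = "numeric", vgLogSd = "numeric", tissueSd = "numeric",
        vgCoverage = "numeric", missingRate = "numeric",
        fcVgCoupling = "numeric",
        nDriver = "integer", nResponder = "integer",
        driverEffect = "numeric", driverFcSd = "numeric",
        responderEffect = "numeric", responderFcSd = "numeric",
        backgroundFcScale = "numeric", nDecoy = "integer",
        featureMissingRate = "numeric", featureNoise = "numeric",
        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    probs <- c(object@vgCoverage, object@missingRate,
               object@featureMissingRate)
    if (any(probs < 0 | probs > 1))
        return("rates must be probabilities in [0,1]")
    if (object@nGenes < 1L || object@nTissues < 1L)
        return("sizes must be positive")
    if (object@nDriver + object@nResponder > object@nGenes)
        return("planted blocks exceed the number of genes")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("a seed is mandatory: fixtures must be reproducible")
    if (object@vgLogSd < 0 || object@tissueSd < 0)
        return("scale parameters must be non-negative")
    if (abs(object@fcVgCoupling) >= 1)
        return("fcVgCoupling must be a correlation in (-1,1)")
    TRUE
})
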