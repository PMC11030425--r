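#' K-nearest-neighbour imputation of a gene-feature matrix
#'
#' Fills missing feature values from the \code{k} nearest genes. Genes
#' missing more than \code{maxMissing} features are dropped entirely
#' (their ids are recorded in the \code{"dropped"} attribute); observed
#' cells are never altered. Distance between two genes is the Euclidean
#' distance over the features observed in both, computed on per-column
#' standardized values and normalized by the number of shared features,
#' so genes with different missingness patterns are comparable. Each
#' missing cell is replaced by the plain mean of that feature over the
#' \code{k} nearest genes that observe it.
#'
#' @param features numeric matrix, genes x features, \code{NA} = missing;
#'   rownames are gene ids
#' @param k number of donor neighbours (default 5)
#' @param maxMissing drop genes with more missing features than this
#'   (default 5)
#' @return imputed numeric matrix (attribute \code{"dropped"}: ids of
#'   removed genes), rows in the original order
#' @export
knnImpute <- function(features, k = 5L, maxMissing = 5L) {
    stopifnot(is.matrix(features), is.numeric(features))
    if (k < 1L) stop("k must be >= 1")
    nmiss <- rowSums(is.na(features))
    dropped <- rownames(features)[nmiss > maxMissing]
    x <- features[nmiss <= maxMissing, , drop = FALSE]
    out <- x
    if (anyNA(x)) {
        mu <- colMeans(x, na.rm = TRUE)
        sdev <- apply(x, 2L, stats::sd, na.rm = TRUE)
        sdev[!is.finite(sdev) | sdev == 0] <- 1
        z <- sweep(sweep(x, 2L, mu), 2L, sdev, "/")
        W <- !is.na(z) * 1
        Z <- z; Z[is.na(Z)] <- 0
        Z2 <- Z^2
        need <- which(rowSums(W == 0) > 0)
        ## squared distance over shared observed columns:
        ## d2_ij = sum_c W_ic W_jc (z_ic - z_jc)^2, nshared = W W^T
        chunk <- 512L
        for (start in seq(1L, length(need), by = chunk)) {
            qi <- need[start:min(start + chunk - 1L, length(need))]
            ## Z is 0 at unobserved cells, so each product below already
            ## restricts to columns observed in both rows
            d2 <- Z2[qi, , drop = FALSE] %*% t(W) +
                W[qi, , drop = FALSE] %*% t(Z2) -
                2 * (Z[qi, , drop = FALSE] %*% t(Z))
            nsh <- W[qi, , drop = FALSE] %*% t(W)
            d2 <- d2 / nsh
            d2[nsh == 0] <- Inf
            for (r in seq_along(qi)) {
                i <- qi[r]
                di <- d2[r, ]
                di[i] <- Inf                      # not its own donor
                for (cc in which(W[i, ] == 0)) {
                    donors <- which(W[, cc] == 1 & is.finite(di))
                    if (length(donors) < k)
                        stop("insufficient donors (", length(donors),
                             " < k = ", k, ") for feature '",
                             colnames(x)[cc], "'")
                    nb <- donors[order(di[donors], donors)][seq_len(k)]
                    out[i, cc] <- mean(x[nb, cc])
                }
            }
        }
    }
    attr(out, "dropped") <- dropped
    out
}

#' Deterministic train / hold-out split of labeled genes
#'
#' @param ids character vector of labeled gene ids (>= 10)
#' @param trainFrac fraction assigned to training (default 0.8); the
#'   train size is \code{trainFrac * n} rounded half-up
#' @param seed RNG seed (caller's RNG state is restored)
#' @return list with \code{train} and \code{test} id vectors (disjoint,
#'   exhaustive)
#' @export
splitTrainTest <- function(ids, trainFrac = 0.8, seed = 1L) {
    n <- length(ids)
    if (n < 10L) stop("need at least 10 labeled genes")
    if (trainFrac < 0 || trainFrac > 1) stop("trainFrac must be in [0,1]")
    nTrain <- min(n, floor(trainFrac * n + 0.5))
    idx <- withSeed(seed, sample.int(n, nTrain))
    list(train = ids[sort(idx)], test = ids[setdiff(seq_len(n), idx)])
}

#' Published hyperparameters of the V^G gradient-boosting model
#'
#' The shipped defaults are the final parameters selected upstream by
#' cross-validated search: tree depth 6, learning rate 0.0236, row
#' subsample 0.96, column subsample 0.746 per tree and 0.494 per level,
#' 344 boosting rounds, minimum split loss 2, L2 penalty 1.27 and L1
#' penalty 4.5.
#'
#' @param ... overrides for individual entries
#' @return named list of hyperparameters
#' @export
vgModelParams <- function(...) {
    p <- list(max_depth = 6, learning_rate = 0.0236, subsample = 0.96,
              colsample_bytree = 0.746, colsample_bylevel = 0.494,
              n_estimators = 344, min_split_loss = 2, reg_lambda = 1.27,
              reg_alpha = 4.5)
    utils::modifyList(p, list(...))
}

#' Train the gradient-boosted regressor of ln V^G
#'
#' Fits an xgboost ensemble to predict the natural logarithm of V^G from
#' gene-level features (constraint scores, expression level, enhancer
#' counts, tissue specificity, ...). Training is single-threaded with a
#' fixed seed so that identical data, parameters and seed give identical
#' models. Per-feature importances are gain shares normalized to sum to
#' 1; an ensemble with no splits (e.g. a constant label) gets uniform
#' importances.
#'
#' @param features numeric matrix, genes x features, fully observed (run
#'   [knnImpute()] first); rownames are gene ids
#' @param labels named or parallel numeric vector of ln V^G values,
#'   finite
#' @param params hyperparameters, see [vgModelParams()]
#' @param seed xgboost RNG seed
#' @param nthread threads (default 1 for determinism)
#' @return a [TrainedVGModel-class]
#' @export
trainVGModel <- function(features, labels, params = vgModelParams(),
                         seed = 1L, nthread = 1L) {
    stopifnot(is.matrix(features), !is.null(colnames(features)))
    if (!is.null(names(labels)))
        labels <- labels[rownames(features)]
    if (length(labels) != nrow(features))
        stop("features and labels are not aligned")
    if (anyNA(labels) || any(!is.finite(labels)))
        stop("labels must be finite ln V^G values")
    xgb_params <- list(
        objective = "reg:squarederror",
        max_depth = params$max_depth, eta = params$learning_rate,
        subsample = params$subsample,
        colsample_bytree = params$colsample_bytree,
        colsample_bylevel = params$colsample_bylevel,
        gamma = params$min_split_loss, lambda = params$reg_lambda,
        alpha = params$reg_alpha, nthread = nthread,
        seed = as.integer(seed))
    dtrain <- xgboost::xgb.DMatrix(features, label = as.numeric(labels))
    booster <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                                  nrounds = params$n_estimators,
                                  verbose = 0)
    imp <- tryCatch(xgboost::xgb.importance(model = booster),
                    error = function(e) NULL)
    importances <- stats::setNames(rep(0, ncol(features)),
                                   colnames(features))
    if (!is.null(imp) && nrow(imp))
        importances[imp$Feature] <- imp$Gain
    if (sum(importances) == 0) {
        importances[] <- 1 / length(importances)   # no splits: no signal
    } else {
        importances <- importances / sum(importances)
    }
    new("TrainedVGModel", booster = booster,
        featureNames = colnames(features), labelTransform = "ln",
        params = params, importances = importances)
}

#' Predict V^G for new genes
#'
#' Applies a trained model to a feature matrix with exactly the training
#' schema and exponentiates the ln-scale predictions back to the
#' variance scale, so every prediction is strictly positive.
#'
#' @param model a [TrainedVGModel-class]
#' @param features numeric matrix with the training feature columns
#' @return named numeric vector of V^G predictions (> 0)
#' @export
predictVG <- function(model, features) {
    stopifnot(is(model, "TrainedVGModel"), is.matrix(features))
    if (!identical(colnames(features), model@featureNames))
        stop("feature schema mismatch: expected columns ",
             paste(model@featureNames, collapse = ", "))
    pred <- stats::predict(model@booster,
                           xgboost::xgb.DMatrix(features))
    stats::setNames(exp(pred), rownames(features))
}

#' Evaluate a V^G model on a hold-out set
#'
#' @param model a [TrainedVGModel-class]
#' @param features hold-out feature matrix (training schema)
#' @param labels hold-out ln V^G values (named or parallel)
#' @return list with \code{rmseLog} (root mean squared error on the ln
#'   scale) and \code{spearman} (rank correlation of predicted vs
#'   observed)
#' @export
evaluateVGModel <- function(model, features, labels) {
    if (!is.null(names(labels))) labels <- labels[rownames(features)]
    if (!length(labels) || length(labels) != nrow(features))
        stop("empty or misaligned hold-out set")
    pred_ln <- log(predictVG(model, features))
    list(rmseLog = sqrt(mean((pred_ln - labels)^2)),
         spearman = stats::cor(pred_ln, labels, method = "spearman"))
}

#' Per-feature importances of a trained model
#' @param model a [TrainedVGModel-class]
#' @return named numeric vector summing to 1
#' @export
vgModelImportances <- function(model) {
    stopifnot(is(model, "TrainedVGModel"))
    model@importances
}

setMethod("show", "TrainedVGModel", function(object) {
    cat(sprintf(
        "TrainedVGModel: %d features, %d boosting rounds, ln-scale label\n",
        length(object@featureNames), object@params$n_estimators))
    top <- sort(object@importances, decreasing = TRUE)[1:min(3, length(object@importances))]
    cat("top importances:",
        paste0(names(top), " = ", signif(top, 3), collapse = ", "), "\n")
})

#' Train tissue-specific V^G models and merge with observed estimates
#'
#' For each tissue with at least \code{minLabeled} genes carrying an
#' AE-derived estimate, fits a model on the shared gene features plus the
#' tissue's own features (typically its TPM and eQTL-derived V^G),
#' predicts all genes, and merges predictions with the observed tissue
#' estimates, observed values taking precedence. Tissues below the
#' threshold are skipped with a warning.
#'
#' @param vg a [VGTable-class] with per-tissue tracks of
#'   \code{labelSource}
#' @param sharedFeatures fully observed feature matrix (genes x features)
#' @param tissueFeatures named list, tissue -> numeric matrix of
#'   tissue-specific feature columns over the same genes
#' @param labelSource track family providing labels (default \code{"AE"})
#' @param into merged output track family (default \code{"AEML"})
#' @param params,seed,nthread passed to [trainVGModel()]
#' @param minLabeled minimum labeled genes per tissue (default 50)
#' @return list with \code{models} (tissue -> [TrainedVGModel-class]) and
#'   \code{vg} (the input table gaining \code{"<into>:<tissue>"} merged
#'   tracks and \code{"ML:<tissue>"} prediction tracks)
#' @export
trainTissueVGModels <- function(vg, sharedFeatures, tissueFeatures,
                                labelSource = "AE", into = "AEML",
                                params = vgModelParams(), seed = 1L,
                                nthread = 1L, minLabeled = 50L) {
    stopifnot(is(vg, "VGTable"))
    tissues <- vgTissues(vg, labelSource)
    models <- list()
    m <- vg@vg
    for (tis in tissues) {
        lab_vg <- vgColumn(vg, labelSource, tis)
        feats <- sharedFeatures
        tf <- tissueFeatures[[tis]]
        if (!is.null(tf))
            feats <- cbind(feats, tf[rownames(feats), , drop = FALSE])
        labeled <- intersect(names(lab_vg)[!is.na(lab_vg)],
                             rownames(feats))
        if (length(labeled) < minLabeled) {
            warning("tissue '", tis, "' skipped: only ", length(labeled),
                    " labeled genes (< ", minLabeled, ")")
            next
        }
        model <- trainVGModel(feats[labeled, , drop = FALSE],
                              log(lab_vg[labeled]), params = params,
                              seed = seed, nthread = nthread)
        pred <- predictVG(model, feats)
        ae <- lab_vg[match(rownames(m), names(lab_vg))]
        ml <- pred[match(rownames(m), names(pred))]
        m <- m[, setdiff(colnames(m), vgTrackName(c("ML", into), tis)),
               drop = FALSE]
        m <- cbind(m, ml, mergeVG(unname(ae), unname(ml)))
        colnames(m)[ncol(m) - 1:0] <- vgTrackName(c("ML", into), tis)
        models[[tis]] <- model
    }
    list(models = models, vg = initialize(vg, vg = m))
}
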