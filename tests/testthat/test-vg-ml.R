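test_that("KNN imputation obeys the drop rule and never touches observed cells", {
    set.seed(51)
    n <- 60
    x <- matrix(rnorm(n * 14), n,
                dimnames = list(sprintf("g%03d", 1:n), paste0("f", 1:14)))
    x[1, 1:6] <- NA          # 6 missing -> dropped
    x[2, 1:5] <- NA          # 5 missing -> kept and imputed
    x[3, 7] <- NA
    imp <- knnImpute(x, k = 5, maxMissing = 5)
    expect_equal(attr(imp, "dropped"), "g001")
    expect_equal(nrow(imp), n - 1L)
    obs <- !is.na(x["g002", ])
    expect_identical(imp["g002", obs], x["g002", obs])
    expect_false(anyNA(imp))
    # fully observed matrix passes through identically
    y <- matrix(rnorm(40), 10, dimnames = list(paste0("h", 1:10), paste0("f", 1:4)))
    imp2 <- knnImpute(y)
    expect_identical(imp2[, ], y)
})

test_that("duplicate nearest neighbours force the imputed mean exactly", {
    # 6 identical donors sharing value 0.7 in the missing column sit at
    # distance 0 from the query on the observed columns
    donors <- matrix(rep(c(1, 2, 0.7), each = 6), 6)
    query <- c(1, 2, NA)
    x <- rbind(donors, query)
    rownames(x) <- c(paste0("d", 1:6), "q")
    colnames(x) <- paste0("f", 1:3)
    far <- matrix(rep(c(10, -10, 5), each = 4), 4,
                  dimnames = list(paste0("far", 1:4), paste0("f", 1:3)))
    imp <- knnImpute(rbind(x, far), k = 5, maxMissing = 2)
    expect_equal(unname(imp["q", "f3"]), 0.7)
    # insufficient donors is a hard error
    z <- matrix(c(1, 1, NA, 2), 2, dimnames = list(c("a", "b"), c("u", "v")))
    expect_error(knnImpute(z, k = 3, maxMissing = 2), "insufficient donors")
})

test_that("train/test split is disjoint, exhaustive, sized and deterministic", {
    ids <- sprintf("g%04d", 1:100)
    sp <- splitTrainTest(ids, 0.8, seed = 7)
    expect_length(sp$train, 80L)
    expect_length(sp$test, 20L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), ids)
    expect_identical(sp, splitTrainTest(ids, 0.8, seed = 7))
    expect_false(identical(sp, splitTrainTest(ids, 0.8, seed = 8)))
    all <- splitTrainTest(ids, 1.0, seed = 1)
    expect_length(all$test, 0L)
    expect_error(splitTrainTest(ids[1:5]), "at least 10")
})

test_that("shipped hyperparameters carry the published values", {
    p <- vgModelParams()
    expect_equal(p$max_depth, 6)
    expect_equal(p$learning_rate, 0.0236)
    expect_equal(p$subsample, 0.96)
    expect_equal(p$colsample_bytree, 0.746)
    expect_equal(p$colsample_bylevel, 0.494)
    expect_equal(p$n_estimators, 344)
    expect_equal(p$min_split_loss, 2)
    expect_equal(p$reg_lambda, 1.27)
    expect_equal(p$reg_alpha, 4.5)
    expect_equal(vgModelParams(max_depth = 3)$max_depth, 3)
})

test_that("constant labels train to a constant predictor with valid importances", {
    set.seed(53)
    x <- matrix(rnorm(200 * 14), 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("f", 1:14)))
    lab <- rep(log(0.02), 200)
    m <- trainVGModel(x, lab, seed = 1)
    pred <- predictVG(m, x)
    expect_true(all(pred > 0))
    expect_equal(unname(pred), rep(0.02, 200), tolerance = 1e-4)
    imp <- vgModelImportances(m)
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1, tolerance = 1e-9)
})

test_that("training is deterministic and prediction rejects schema mismatch", {
    set.seed(54)
    x <- matrix(rnorm(300 * 5), 300,
                dimnames = list(sprintf("g%03d", 1:300), paste0("f", 1:5)))
    lab <- x[, 1] - 4
    p <- vgModelParams(n_estimators = 30)
    m1 <- trainVGModel(x, lab, params = p, seed = 9)
    m2 <- trainVGModel(x, lab, params = p, seed = 9)
    expect_identical(predictVG(m1, x), predictVG(m2, x))
    bad <- x[, c(2, 1, 3, 4, 5)]
    expect_error(predictVG(m1, bad), "schema")
    expect_error(trainVGModel(x, c(lab[-1], NA), seed = 1), "finite")
})

test_that("evaluation returns zero error on perfect prediction and |d| on offset", {
    set.seed(55)
    x <- matrix(rnorm(500 * 3), 500,
                dimnames = list(sprintf("g%03d", 1:500), paste0("f", 1:3)))
    lab <- 2 * x[, 1] - 4
    m <- trainVGModel(x, lab, params = vgModelParams(
        n_estimators = 400, learning_rate = 0.3, min_split_loss = 0,
        reg_alpha = 0, subsample = 1, colsample_bytree = 1,
        colsample_bylevel = 1), seed = 2)
    ev <- evaluateVGModel(m, x, lab)
    expect_lt(ev$rmseLog, 0.05 * sd(lab))
    expect_gt(ev$spearman, 0.999)
    # closed form under a constant offset
    pred_ln <- log(predictVG(m, x))
    d <- 0.37
    ev2 <- evaluateVGModel(m, x, pred_ln - d)
    expect_equal(ev2$rmseLog, d, tolerance = 1e-9)
    # independent labels: near-zero rank correlation
    ev3 <- evaluateVGModel(m, x, sample(unname(lab)))
    expect_lt(abs(ev3$spearman), 0.1)
})

test_that("importances concentrate on planted signal features (noiseless)", {
    sim <- simulateFeatureMatrix(refConfig(seed = 909L, nGenes = 3000L,
                                           featureNoise = 0,
                                           featureMissingRate = 0))
    m <- trainVGModel(sim$features, sim$labels, seed = 3)
    imp <- vgModelImportances(m)
    expect_gt(sum(imp[sim$signalFeatures]), 0.9)
    # capacity: without shrinkage penalties the ensemble fits the
    # noiseless signal almost exactly on the training set
    flex <- trainVGModel(sim$features, sim$labels,
                         params = vgModelParams(learning_rate = 0.3,
                                                min_split_loss = 0,
                                                reg_alpha = 0,
                                                reg_lambda = 0),
                         seed = 3)
    ev <- evaluateVGModel(flex, sim$features, sim$labels)
    expect_lt(ev$rmseLog, 0.05 * sd(sim$labels))
})

test_that("tissue-specific models recover tissue-specific label functions", {
    set.seed(57)
    n <- 800
    ids <- sprintf("g%04d", 1:n)
    shared <- matrix(rnorm(n * 3), n,
                     dimnames = list(ids, paste0("s", 1:3)))
    tf <- list(
        TisA = matrix(rnorm(n), n, dimnames = list(ids, "vg_eqtl_t")),
        TisB = matrix(rnorm(n), n, dimnames = list(ids, "vg_eqtl_t")))
    # disjoint label functions per tissue
    labA <- exp(-4 + 1.5 * tf$TisA[, 1])
    labB <- exp(-4 + 1.5 * shared[, "s1"])
    maskA <- runif(n) < 0.7
    maskB <- runif(n) < 0.7
    m <- cbind(`AE:TisA` = ifelse(maskA, labA, NA),
               `AE:TisB` = ifelse(maskB, labB, NA))
    rownames(m) <- ids
    vg <- VGTable(m)
    fit <- trainTissueVGModels(vg, shared, tf,
                               params = vgModelParams(n_estimators = 150,
                                                      learning_rate = 0.1),
                               seed = 4, minLabeled = 50)
    expect_setequal(names(fit$models), c("TisA", "TisB"))
    out <- vgMatrix(fit$vg)
    # merged track equals AE wherever AE exists
    expect_identical(out[maskA, "AEML:TisA"], out[maskA, "AE:TisA"])
    # coverage strictly increases where ML fills AE-missing genes
    expect_gt(sum(!is.na(out[, "AEML:TisA"])), sum(!is.na(out[, "AE:TisA"])))
    # each model recovers its own tissue's function on AE-missing genes
    for (tis in c("TisA", "TisB")) {
        hold <- if (tis == "TisA") !maskA else !maskB
        truth <- if (tis == "TisA") labA[hold] else labB[hold]
        rho <- cor(out[hold, paste0("ML:", tis)], truth,
                   method = "spearman")
        expect_gt(rho, 0.9)
    }
})

test_that("tissues with too few labels are skipped with a warning", {
    n <- 100
    ids <- sprintf("g%03d", 1:n)
    shared <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("s1", "s2")))
    m <- cbind(`AE:Rare` = c(exp(rnorm(5, -4)), rep(NA, n - 5)))
    rownames(m) <- ids
    expect_warning(
        fit <- trainTissueVGModels(VGTable(m), shared, list(),
                                   minLabeled = 50),
        "skipped")
    expect_length(fit$models, 0L)
})

test_that("models round-trip through the self-describing file", {
    set.seed(58)
    x <- matrix(rnorm(200 * 4), 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("f", 1:4)))
    m <- trainVGModel(x, x[, 1] - 4,
                      params = vgModelParams(n_estimators = 25), seed = 5)
    path <- tempfile(fileext = ".json")
    saveVGModel(m, path)
    m2 <- loadVGModel(path)
    expect_identical(predictVG(m, x), predictVG(m2, x))
    expect_identical(m2@featureNames, m@featureNames)
    expect_equal(m2@importances, m@importances)
})
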