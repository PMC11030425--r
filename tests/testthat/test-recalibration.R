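test_that("recalibrated fold change is fc / sqrt(vg), direction preserved", {
    expect_equal(recalibrateFC(1.0, 1.0), 1.0)
    expect_equal(recalibrateFC(0.5, 0.04), 2.5)
    expect_equal(recalibrateFC(-0.3, 0.09), -1.0)
    expect_error(recalibrateFC(1, 0), "positive")
    expect_error(recalibrateFC(1, -0.1), "positive")
    expect_error(recalibrateFC(Inf, 0.1), "finite")
    set.seed(2)
    fc <- rnorm(100); vg <- exp(rnorm(100, -4))
    expect_identical(sign(recalibrateFC(fc, vg)), sign(fc))
})

test_that("recalibration is equivariant under c^2 scaling of V^G", {
    set.seed(4)
    fc <- rnorm(50); vg <- exp(rnorm(50, -4))
    cc <- 3.7
    expect_equal(recalibrateFC(fc, cc^2 * vg), recalibrateFC(fc, vg) / cc)
    ids <- sprintf("g%03d", 1:50)
    de <- DEResultTable(ids, fc, rep(1e-6, 50), rep(1e-5, 50))
    mk <- function(v) VGTable(matrix(v, 50, dimnames = list(ids, "AE")))
    r1 <- recalibrateTable(de, mk(vg))
    r2 <- recalibrateTable(de, mk(cc^2 * vg))
    expect_identical(r1$rank_recal, r2$rank_recal)
    expect_identical(rownames(r1), rownames(r2))
})

test_that("constant V^G leaves the ranking unchanged and abs-Pearson at 1", {
    set.seed(6)
    ids <- sprintf("g%03d", 1:80)
    fc <- rnorm(80)
    de <- DEResultTable(ids, fc, runif(80, 0, 1e-4), runif(80, 0, 1e-3))
    vg <- VGTable(matrix(0.02, 80, dimnames = list(ids, "AE")))
    rt <- recalibrateTable(de, vg)
    expect_identical(rt$rank_nominal, rt$rank_recal)
    expect_equal(rt$fc_star, rt$log_fc / sqrt(0.02))
    expect_equal(absPearson(rt$log_fc, rt$fc_star), 1.0)
})

test_that("fc_star is strictly decreasing in V^G at fixed |log FC|", {
    vgs <- sort(exp(rnorm(20, -4)))
    stars <- recalibrateFC(rep(1.5, 20), vgs)
    expect_true(all(diff(stars) < 0))
})

test_that("hand-worked 3-gene example reorders as expected", {
    de <- DEResultTable(c("g1", "g2", "g3"), c(2.0, 0.5, 1.0),
                        c(1e-6, 1e-6, 1e-6), c(1e-5, 1e-5, 1e-5))
    vg <- VGTable(matrix(c(1.0, 0.01, 0.25), 3,
                         dimnames = list(c("g1", "g2", "g3"), "AE")))
    rt <- recalibrateTable(de, vg)
    expect_equal(rt["g2", "fc_star"], 5.0)
    expect_equal(rt["g1", "fc_star"], 2.0)
    expect_equal(rt["g3", "fc_star"], 2.0)
    expect_equal(rt["g1", "rank_nominal"], 1L)
    expect_equal(rt["g3", "rank_nominal"], 2L)
    expect_equal(rt["g2", "rank_recal"], 1L)
    # |fc*| tie between g1 and g3 broken lexicographically by gene id
    expect_equal(rt["g1", "rank_recal"], 2L)
    expect_equal(rt["g3", "rank_recal"], 3L)
})

test_that("missing V^G drops genes by default and keeps them flagged on request", {
    de <- tinyDETable()
    vg <- tinyVGTable()
    rt <- recalibrateTable(de, vg, source = "AE")
    expect_false("ENSG04" %in% rownames(rt))
    expect_equal(nrow(rt), 3L)
    kept <- recalibrateTable(de, vg, source = "AE", missingPolicy = "keep")
    expect_equal(nrow(kept), 4L)
    expect_true(kept["ENSG04", "vg_missing"])
    expect_true(is.na(kept["ENSG04", "fc_star"]))
    expect_true(is.na(kept["ENSG04", "rank_recal"]))
    # nothing retained is an explicit error, not silent success
    deAlien <- DEResultTable("other", 1, 1e-6, 1e-5)
    expect_error(recalibrateTable(deAlien, vg), "no gene retained")
})

test_that("significance filter ranks only genes below the threshold", {
    de <- tinyDETable()
    vg <- tinyVGTable()
    rt <- recalibrateTable(de, vg, source = "AE", sigThreshold = 1e-3)
    # ENSG03 has p_adj exactly 1e-3: strictly-less-than excludes it
    expect_true(is.na(rt["ENSG03", "rank_recal"]))
    expect_equal(nRanked(rt), 2L)
    expect_equal(nrow(rt), 3L)
})

test_that("abs-Pearson matches the textbook value and flags degenerate input", {
    expect_equal(absPearson(c(1, 2, 3), c(-3, 2, -1)), -1.0)
    expect_equal(absPearson(c(1, -2, 3), c(1, 2, 4)),
                 1.5 / sqrt(1 * 7 / 3), tolerance = 1e-6)
    expect_warning(r <- absPearson(c(1, -1, 1), c(1, 2, 3)), "constant")
    expect_true(is.na(r))
    expect_error(absPearson(c(1, 2), c(1, 2)), "length")
})

test_that("abs-Pearson agreement decays as V^G dispersion grows", {
    # With |log FC| weakly coupled to V^G, stronger per-gene rescaling
    # (larger spread of ln V^G) degrades nominal/recalibrated agreement.
    cors <- vapply(c(0.2, 0.7, 1.4), function(sdlog) {
        sim <- simulateStudy(refConfig(seed = 404L, vgLogSd = sdlog,
                                       nGenes = 2000L))
        rt <- recalibrateTable(sim$de, sim$vg, source = "AE")
        absPearson(rt$log_fc, rt$fc_star)
    }, numeric(1))
    expect_true(all(diff(cors) < 0))
})

test_that("Spearman bootstrap CI brackets the point estimate", {
    set.seed(9)
    x <- rnorm(200); y <- 0.5 * x + rnorm(200, sd = sqrt(0.75))
    res <- spearmanWithBootstrapCI(x, y, nBoot = 500, seed = 10)
    expect_lte(res$ciLow, res$rho)
    expect_gte(res$ciHigh, res$rho)
    expect_equal(spearmanWithBootstrapCI(1:20, (1:20)^3, seed = 1)$rho, 1.0)
    expect_equal(spearmanWithBootstrapCI(1:20, -(1:20), seed = 1)$rho, -1.0)
    expect_warning(res2 <- spearmanWithBootstrapCI(rep(1, 20), 1:20),
                   "tied")
    expect_true(is.na(res2$rho))
    # determinism under a fixed seed
    a <- spearmanWithBootstrapCI(x, y, nBoot = 200, seed = 42)
    b <- spearmanWithBootstrapCI(x, y, nBoot = 200, seed = 42)
    expect_identical(a, b)
})

test_that("bootstrap CI achieves near-nominal coverage", {
    # Monte-Carlo: bivariate normal, rho close to 0.5 on ranks; the 95%
    # percentile interval should cover the true Spearman rho in most
    # replicates.
    set.seed(77)
    rhoPearson <- 0.5
    rhoSpearman <- 6 / pi * asin(rhoPearson / 2)
    hits <- vapply(1:60, function(i) {
        x <- rnorm(300)
        y <- rhoPearson * x + sqrt(1 - rhoPearson^2) * rnorm(300)
        ci <- spearmanWithBootstrapCI(x, y, nBoot = 300, seed = i)
        ci$ciLow <= rhoSpearman && rhoSpearman <= ci$ciHigh
    }, logical(1))
    expect_gte(mean(hits), 0.85)
})
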