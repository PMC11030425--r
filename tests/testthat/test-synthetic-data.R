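test_that("config validation rejects impossible studies and demands a seed", {
    expect_error(simulationConfig(), "seed")
    expect_error(simulationConfig(nGenes = 100, nDriver = 80,
                                  nResponder = 80, seed = 1),
                 "blocks exceed")
    expect_error(simulationConfig(missingRate = 1.5, seed = 1), "\\[0,1\\]")
})

test_that("V^G simulation respects missingness, coverage and the configured law", {
    cfg <- refConfig(seed = 202L, nGenes = 10000L, missingRate = 0,
                     vgCoverage = 1)
    sim <- simulateVGTable(cfg)
    m <- vgMatrix(sim$vg)
    tis <- grepl(":", colnames(m))
    expect_false(anyNA(m[, tis]))
    # empirical moments of gene-level ln V^G within 3 SE of configured
    ln <- sim$truth$lnVgGene
    se_mean <- cfg@vgLogSd / sqrt(cfg@nGenes)
    expect_lt(abs(mean(ln) - cfg@vgLogMean), 3 * se_mean)
    se_sd <- cfg@vgLogSd / sqrt(2 * (cfg@nGenes - 1))
    expect_lt(abs(sd(ln) - cfg@vgLogSd), 3 * se_sd)
    # degenerate lognormal: a single shared value
    d <- simulateVGTable(refConfig(seed = 203L, nGenes = 50L, vgLogSd = 0,
                                   tissueSd = 0, missingRate = 0,
                                   vgCoverage = 1, nDriver = 5L,
                                   nResponder = 5L))
    dm <- vgMatrix(d$vg)
    expect_equal(length(unique(as.vector(dm[, grepl(":", colnames(dm))]))),
                 1L)
    expect_equal(unname(dm[, "AE"]), rep(exp(log(0.02)), 50))
    # missingness close to its configured rate
    s2 <- simulateVGTable(refConfig(seed = 204L, nGenes = 10000L,
                                    vgCoverage = 1))
    m2 <- vgMatrix(s2$vg)[, tis]
    expect_lt(abs(mean(is.na(m2)) - 0.1), 0.01)
    # mean track equals core aggregation of the tissue tracks
    sub <- vgMatrix(s2$vg)
    i <- which(rowSums(!is.na(sub[, tis])) > 0)[1:50]
    for (g in i) {
        v <- sub[g, tis]
        names(v) <- sub(".*:", "", colnames(sub)[tis])
        expect_equal(sub[g, "AE"],
                     aggregateTissueVG(v, weights = tissueWeights(s2$vg)))
    }
})

test_that("DE simulation couples |log FC| to V^G at the configured strength", {
    cfg <- refConfig(seed = 205L, nGenes = 10000L)
    sim <- simulateStudy(cfg)
    v <- exp(sim$truth$vg$lnVgGene)
    names(v) <- sim$truth$vg$geneIds
    fc <- setNames(sim$de$log_fc, rownames(sim$de))
    bg <- sim$geneSets$background
    rho <- cor(abs(fc[bg]), v[bg], method = "spearman")
    expect_lt(abs(rho - cfg@fcVgCoupling), 0.05)
})

test_that("planted blocks sit in opposite V^G quartiles with the intended effects", {
    sim <- refStudy()
    truth <- sim$truth$vg
    v <- setNames(exp(truth$lnVgGene), truth$geneIds)
    cov <- v[truth$geneIds[truth$covered]]
    qs <- quantile(cov, c(0.25, 0.75))
    expect_true(all(v[sim$geneSets$driver] <= qs[1]))
    expect_true(all(v[sim$geneSets$responder] >= qs[2]))
    fc <- setNames(sim$de$log_fc, rownames(sim$de))
    # responders change more nominally; drivers exceed them after rescaling
    expect_gt(median(abs(fc[sim$geneSets$responder])),
              median(abs(fc[sim$geneSets$driver])))
    star <- abs(fc) / sqrt(v[names(fc)])
    expect_gt(median(star[sim$geneSets$driver]),
              median(star[sim$geneSets$responder]))
    # both blocks pass a stringent significance filter
    padj <- setNames(sim$de$p_adj, rownames(sim$de))
    expect_true(all(padj[c(sim$geneSets$driver,
                           sim$geneSets$responder)] < 0.001))
})

test_that("drivers with zero effect leave the regulation term unenriched", {
    cfg <- refConfig(seed = 206L, nGenes = 2000L, driverEffect = 0,
                     driverFcSd = 0)
    vgSim <- simulateVGTable(cfg)
    deSim <- simulateDEExperiment(vgSim, cfg)
    # zero driver effect floors at |fc*| = 1; rebuild without the floor
    fc <- setNames(deSim$de$log_fc, rownames(deSim$de))
    expect_lt(median(abs(fc[deSim$geneSets$driver])), 0.3)
    rt <- recalibrateTable(deSim$de, vgSim$vg, source = "AE",
                           sigThreshold = 0.05)
    bg <- rownames(rt)
    res <- ora(selectTopGenes(rt, "nominal"), bg, deSim$terms)
    expect_gt(res[res$term_id == "SIM:0000002", "p_adj"], 0.05)
})

test_that("feature matrix carries the documented missingness and label function", {
    cfg <- refConfig(seed = 207L, nGenes = 8000L)
    sim <- simulateFeatureMatrix(cfg)
    expect_equal(ncol(sim$features), 14L)
    # expected ~2% of genes exceed the 5-missing drop rule
    over <- mean(rowSums(is.na(sim$features)) > 5)
    pExpect <- pbinom(5, 14, cfg@featureMissingRate, lower.tail = FALSE)
    tol <- 3 * sqrt(pExpect * (1 - pExpect) / cfg@nGenes)
    expect_lt(abs(over - pExpect), tol)
    expect_gt(pExpect, 0.01); expect_lt(pExpect, 0.04)
    # noiseless labels are an exact function of the signal features
    s0 <- simulateFeatureMatrix(refConfig(seed = 208L, nGenes = 500L,
                                          featureNoise = 0,
                                          featureMissingRate = 0))
    x <- s0$features
    raw <- x[, "vg_eqtl_ln"] + 0.6 * x[, "loeuf"] + 0.4 * tanh(x[, "tpm_log"])
    rebuilt <- refConfig()@vgLogMean + refConfig()@vgLogSd * scale(raw)[, 1]
    expect_equal(unname(s0$labels), unname(rebuilt), tolerance = 1e-12)
})

test_that("simulation is deterministic and round-trips through its files", {
    cfg <- refConfig(seed = 209L, nGenes = 600L, nDriver = 40L,
                     nResponder = 40L, nDecoy = 20L)
    d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
    sim1 <- simulateStudy(cfg, dir = d1)
    sim2 <- simulateStudy(cfg, dir = d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
    # files re-read into the in-memory objects
    vg2 <- readVGTable(file.path(d1, "vg.tsv"),
                       weights = readTissueWeights(
                           file.path(d1, "tissue_weights.tsv")))
    expect_equal(vgMatrix(vg2)[geneIds(sim1$vg), colnames(vgMatrix(sim1$vg))],
                 vgMatrix(sim1$vg), tolerance = 1e-12)
    de2 <- readDETable(file.path(d1, "de.tsv"))
    expect_equal(de2[rownames(sim1$de), "log_fc"], sim1$de$log_fc,
                 tolerance = 1e-12)
    sets2 <- readGMT(file.path(d1, "gene_sets.gmt"))
    expect_setequal(sets2$driver, sim1$geneSets$driver)
    expect_setequal(sets2[["SIM:0000001"]], sim1$terms[["SIM:0000001"]])
    fm2 <- readFeatureMatrix(file.path(d1, "features.tsv"))
    expect_equal(fm2$features[rownames(sim1$features), ],
                 sim1$features, tolerance = 1e-12)
    expect_equal(fm2$labels[names(sim1$labels)], sim1$labels,
                 tolerance = 1e-12)
    unlink(c(d1, d2), recursive = TRUE)
})
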