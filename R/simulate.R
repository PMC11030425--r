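#' Configure a synthetic study
#'
#' Builds the parameter record for the fixture generator. The defaults
#' describe the reference "driver-responder" study: 5,000 genes across 5
#' tissues, gene-level ln V^G drawn normal with mean \code{log(0.02)}
#' (V^G of a typical gene is of order 0.01-0.05) and standard deviation
#' \code{sqrt(0.2)} (the dispersion observed for AE-derived estimates),
#' per-tissue lognormal scatter around the gene level, 10% of
#' (gene,tissue) cells missing and 10% of genes with no estimate at all;
#' a DE experiment whose background fold-change magnitude has Spearman
#' coupling ~0.148 with V^G; a planted block of 200 high-V^G "responder"
#' genes with large nominal fold changes (|log2 FC| ~ N(2, 0.15), i.e.
#' ~4-fold on the natural scale) and 200 low-V^G "driver" genes whose
#' effect is specified on the recalibrated scale (fc* ~ N(15, 0.8)), so
#' their nominal fold changes stay modest; and a 14-feature gene metric
#' matrix whose per-cell missing rate (0.155) makes ~2% of genes exceed
#' the 5-missing-features imputation limit.
#'
#' @param nGenes,nTissues study size
#' @param vgLogMean,vgLogSd mean and SD of gene-level ln V^G
#' @param tissueSd SD of per-tissue scatter of ln V^G around the gene
#'   level
#' @param vgCoverage fraction of genes with any V^G estimate
#' @param missingRate per-(gene,tissue) missingness probability among
#'   covered genes
#' @param fcVgCoupling target Spearman correlation between background
#'   |log FC| and V^G
#' @param nDriver,nResponder planted block sizes
#' @param driverEffect,driverFcSd mean/SD of driver effects on the
#'   recalibrated (fc*) scale
#' @param responderEffect,responderFcSd mean/SD of responder |log2 FC|
#' @param backgroundFcScale median background |log2 FC|
#' @param nDecoy background genes added to each planted annotation term
#' @param featureMissingRate per-cell missingness of the feature matrix
#' @param featureNoise label noise SD as a fraction of the signal SD
#' @param seed mandatory RNG seed
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(nGenes = 5000L, nTissues = 5L,
                             vgLogMean = log(0.02), vgLogSd = sqrt(0.2),
                             tissueSd = 0.3, vgCoverage = 0.9,
                             missingRate = 0.1, fcVgCoupling = 0.148,
                             nDriver = 200L, nResponder = 200L,
                             driverEffect = 15, driverFcSd = 0.8,
                             responderEffect = 2, responderFcSd = 0.15,
                             backgroundFcScale = 0.25, nDecoy = 100L,
                             featureMissingRate = 0.155,
                             featureNoise = 0.2, seed) {
    if (missing(seed)) stop("a seed is mandatory")
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
        vgLogMean = vgLogMean, vgLogSd = vgLogSd, tissueSd = tissueSd,
        vgCoverage = vgCoverage, missingRate = missingRate,
        fcVgCoupling = fcVgCoupling,
        nDriver = as.integer(nDriver), nResponder = as.integer(nResponder),
        driverEffect = driverEffect, driverFcSd = driverFcSd,
        responderEffect = responderEffect, responderFcSd = responderFcSd,
        backgroundFcScale = backgroundFcScale, nDecoy = as.integer(nDecoy),
        featureMissingRate = featureMissingRate,
        featureNoise = featureNoise, seed = as.integer(seed))
}

simGeneIds <- function(n) sprintf("ENSG%011d", seq_len(n))

simTissueNames <- function(n)
    sprintf("Tissue%02d", seq_len(n))

#' Simulate a V^G table with tissue structure and missingness
#'
#' Gene-level ln V^G is drawn normal; each tissue adds independent
#' normal scatter, giving a lognormal V^G landscape with correlated
#' tissues. A fraction of genes carries no estimate at all (emulating
#' genes whose allelic-expression data were too sparse), and covered
#' genes lose individual tissue cells at \code{missingRate}. Tissue TPM
#' weights are drawn lognormal, and the cross-tissue \code{"AE"} mean
#' track is computed with [aggregateTissueVG()].
#'
#' @param config a [SimulationConfig-class]
#' @return list with \code{vg} (a [VGTable-class] with \code{AE:tissue}
#'   tracks and the \code{AE} mean) and \code{truth} (gene-level true
#'   values and masks)
#' @export
simulateVGTable <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(config@seed, {
        n <- config@nGenes; nt <- config@nTissues
        ids <- simGeneIds(n)
        tis <- simTissueNames(nt)
        zGene <- stats::rnorm(n)
        lnVgGene <- config@vgLogMean + config@vgLogSd * zGene
        lnVgTissue <- lnVgGene +
            matrix(stats::rnorm(n * nt, sd = config@tissueSd), n, nt)
        m <- exp(lnVgTissue)
        dimnames(m) <- list(ids, vgTrackName("AE", tis))
        covered <- stats::runif(n) < config@vgCoverage
        m[!covered, ] <- NA_real_
        drop <- matrix(stats::runif(n * nt) < config@missingRate, n, nt)
        m[drop] <- NA_real_
        weights <- stats::setNames(exp(stats::rnorm(nt, 3, 1)), tis)
        vg <- VGTable(m, weights = weights)
        vg <- aggregateTissueVG(vg, source = "AE")
        list(vg = vg,
             truth = list(geneIds = ids, zGene = zGene,
                          lnVgGene = lnVgGene,
                          trueVgTissue = exp(lnVgTissue),
                          covered = covered, weights = weights,
                          config = config))
    })
}

#' Simulate a DE experiment with planted driver and responder blocks
#'
#' Produces a DESeq2-style result table over the simulated genes plus
#' the gene sets and annotation terms needed to exercise the enrichment
#' comparison. Background genes get null fold changes whose magnitude is
#' weakly coupled to V^G (Gaussian copula at the configured Spearman
#' target) and uniform p-values. The responder block is sampled from the
#' top V^G quartile of covered genes and given large nominal fold
#' changes; the driver block comes from the bottom quartile with effects
#' specified on the recalibrated scale, so its nominal fold changes are
#' modest but its fc* exceeds the responders'. Both blocks get tiny
#' p-values, and adjusted p-values are BH over the whole table, so both
#' blocks pass any reasonable significance filter. Two annotation terms
#' ("response-like", "regulation-like") cover the blocks plus random
#' decoy genes.
#'
#' @param vgSim output of [simulateVGTable()]
#' @param config the same [SimulationConfig-class]
#' @return list with \code{de} ([DEResultTable-class]), \code{geneSets}
#'   (driver/responder/background id vectors), \code{terms} (annotation
#'   list for [ora()]), and \code{truth} (block membership, true fc*)
#' @export
simulateDEExperiment <- function(vgSim, config) {
    stopifnot(is(config, "SimulationConfig"))
    truth <- vgSim$truth
    n <- config@nGenes
    ids <- truth$geneIds
    withSeed(config@seed + 1L, {
        trueVg <- exp(truth$lnVgGene)
        covered <- which(truth$covered)
        qs <- stats::quantile(trueVg[covered], c(0.25, 0.75))
        lowPool <- covered[trueVg[covered] <= qs[1]]
        highPool <- covered[trueVg[covered] >= qs[2]]
        driver <- sort(sample(lowPool, config@nDriver))
        responder <- sort(sample(setdiff(highPool, driver),
                                 config@nResponder))
        planted <- c(driver, responder)
        bg <- setdiff(seq_len(n), planted)

        ## background: |log FC| coupled to V^G through a Gaussian copula
        rho <- 2 * sin(pi * config@fcVgCoupling / 6)
        zFc <- rho * truth$zGene + sqrt(1 - rho^2) * stats::rnorm(n)
        logFc <- sample(c(-1, 1), n, replace = TRUE) *
            config@backgroundFcScale * exp(0.5 * zFc)
        p <- stats::runif(n)

        sgn <- sample(c(-1, 1), length(planted), replace = TRUE)
        logFc[responder] <- sgn[match(responder, planted)] *
            pmax(0.5, stats::rnorm(config@nResponder,
                                   config@responderEffect,
                                   config@responderFcSd))
        fcStarDriver <- pmax(1, stats::rnorm(config@nDriver,
                                             config@driverEffect,
                                             config@driverFcSd))
        logFc[driver] <- sgn[match(driver, planted)] *
            fcStarDriver * sqrt(trueVg[driver])
        p[planted] <- 10^stats::runif(length(planted), -12, -8)
        pAdj <- adjustBH(p)

        de <- DEResultTable(ids, logFc, p, pAdj)
        decoys <- sample(bg, 2L * config@nDecoy)
        respTerm <- sort(c(ids[responder],
                           ids[decoys[seq_len(config@nDecoy)]]))
        regTerm <- sort(c(ids[driver],
                          ids[decoys[config@nDecoy + seq_len(config@nDecoy)]]))
        terms <- list(`SIM:0000001` = respTerm, `SIM:0000002` = regTerm)
        attr(terms, "termNames") <- c(
            `SIM:0000001` = "response to simulated stimulus",
            `SIM:0000002` = "regulation of simulated process")
        list(de = de,
             geneSets = list(driver = ids[driver],
                             responder = ids[responder],
                             background = ids[bg]),
             terms = terms,
             truth = list(driver = ids[driver], responder = ids[responder],
                          fcStarDriver = fcStarDriver,
                          coupling = config@fcVgCoupling))
    })
}

#' Simulate a gene-feature matrix with a known label function
#'
#' Emits 14 gene-level metric columns (named after the constraint and
#' expression metrics the real model consumes) and ln V^G labels that
#' are a fixed monotone function of three of them --- the eQTL-derived
#' ln V^G, the loss-of-function constraint score and log expression ---
#' plus Gaussian noise scaled to \code{featureNoise} times the signal
#' SD. Per-cell missingness is injected at \code{featureMissingRate},
#' which makes a small fraction of genes exceed the 5-missing-features
#' imputation limit, exercising the drop rule.
#'
#' @param config a [SimulationConfig-class]
#' @return list with \code{features} (matrix with \code{NA}s),
#'   \code{labels} (named ln V^G vector, one per gene),
#'   \code{signalFeatures} (the three label-driving column names) and
#'   \code{truth} (noiseless labels and the missingness mask)
#' @export
simulateFeatureMatrix <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(config@seed + 2L, {
        n <- config@nGenes
        ids <- simGeneIds(n)
        cols <- c("vg_eqtl_ln", "loeuf", "tpm_log", "pli", "phaplo",
                  "ptriplo", "rvis", "nc_gerp", "nc_rvis", "nc_cadd",
                  "episcore", "tau", "n_enhancers", "n_super_enhancers")
        x <- matrix(stats::rnorm(n * length(cols)), n,
                    dimnames = list(ids, cols))
        x[, "n_enhancers"] <- stats::rpois(n, 8)
        x[, "n_super_enhancers"] <- stats::rpois(n, 1)
        x[, "tau"] <- stats::runif(n)
        signal <- x[, "vg_eqtl_ln"] + 0.6 * x[, "loeuf"] +
            0.4 * tanh(x[, "tpm_log"])
        noise <- stats::rnorm(n, sd = config@featureNoise *
                                  stats::sd(signal))
        labels <- config@vgLogMean + config@vgLogSd *
            scale(signal + noise)[, 1L]
        mask <- matrix(stats::runif(n * length(cols)) <
                           config@featureMissingRate, n, length(cols))
        feat <- x
        feat[mask] <- NA_real_
        list(features = feat,
             labels = stats::setNames(labels, ids),
             signalFeatures = c("vg_eqtl_ln", "loeuf", "tpm_log"),
             truth = list(noiselessSignal = signal, mask = mask))
    })
}

#' Run the full driver-responder simulation and write its files
#'
#' Generates the V^G table, DE experiment, gene sets, annotation terms
#' and feature matrix from one config and writes them in the package's
#' exchange formats (TSV, GMT, JSON ground-truth sidecar) into a
#' directory. Re-running with the same config yields byte-identical
#' files.
#'
#' @param config a [SimulationConfig-class]
#' @param dir output directory (created if needed); \code{NULL} to skip
#'   writing
#' @return (invisibly when writing) list with \code{vg}, \code{de},
#'   \code{geneSets}, \code{terms}, \code{features}, \code{labels},
#'   \code{truth}
#' @export
simulateStudy <- function(config, dir = NULL) {
    vgSim <- simulateVGTable(config)
    deSim <- simulateDEExperiment(vgSim, config)
    featSim <- simulateFeatureMatrix(config)
    out <- list(vg = vgSim$vg, de = deSim$de, geneSets = deSim$geneSets,
                terms = deSim$terms, features = featSim$features,
                labels = featSim$labels,
                truth = list(vg = vgSim$truth, de = deSim$truth,
                             features = featSim$truth,
                             signalFeatures = featSim$signalFeatures))
    if (is.null(dir)) return(out)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeVGTable(out$vg, file.path(dir, "vg.tsv"))
    writeTissueWeights(tissueWeights(out$vg),
                       file.path(dir, "tissue_weights.tsv"))
    writeDETable(out$de, file.path(dir, "de.tsv"))
    writeGMT(c(out$geneSets,
               stats::setNames(out$terms, names(out$terms))),
             file.path(dir, "gene_sets.gmt"),
             descriptions = c(driver = "planted low-V^G driver block",
                 responder = "planted high-V^G responder block",
                 background = "unplanted genes",
                 attr(out$terms, "termNames")))
    writeFeatureMatrix(out$features, out$labels,
                       file.path(dir, "features.tsv"))
    truth <- list(
        driver = out$truth$de$driver,
        responder = out$truth$de$responder,
        signalFeatures = out$truth$signalFeatures,
        lnVgGene = unname(out$truth$vg$lnVgGene),
        geneIds = out$truth$vg$geneIds,
        config = configAsList(config))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out)
}

configAsList <- function(config) {
    sl <- slotNames(config)
    stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d genes x %d tissues, seed %d\n",
        object@nGenes, object@nTissues, object@seed))
    cat(sprintf(
        "  ln V^G ~ N(%.3f, %.3f), tissue scatter %.2f, coverage %.2f, cell missingness %.2f\n",
        object@vgLogMean, object@vgLogSd, object@tissueSd,
        object@vgCoverage, object@missingRate))
    cat(sprintf(
        "  blocks: %d drivers (fc* ~ N(%g, %g)), %d responders (|log2FC| ~ N(%g, %g)), coupling %.3f\n",
        object@nDriver, object@driverEffect, object@driverFcSd,
        object@nResponder, object@responderEffect, object@responderFcSd,
        object@fcVgCoupling))
})
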