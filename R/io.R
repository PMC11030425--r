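## Delimiter auto-detection: tab or comma only, with explicit override.
## Silent guessing beyond these two corrupts gene ids.
detectSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) return("\t")
    if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a differential-expression result table
#'
#' Reads a delimited DE output (DESeq2-style by default) into a
#' [DEResultTable-class]. Column mapping is configurable; gene ids come
#' from a named column or, by default, the first column. \code{NA}
#' adjusted p-values are preserved as missing.
#'
#' @param path file path (TSV or CSV; delimiter auto-detected, override
#'   with \code{sep})
#' @param columnMap named character vector mapping the roles
#'   \code{logFC}, \code{p}, \code{pAdj} (and optionally \code{gene},
#'   \code{baseExpr}) to file columns; defaults follow DESeq2
#'   (\code{log2FoldChange}, \code{pvalue}, \code{padj})
#' @param sep field separator override
#' @return a [DEResultTable-class]
#' @export
readDETable <- function(path,
                        columnMap = c(logFC = "log2FoldChange",
                                      p = "pvalue", pAdj = "padj"),
                        sep = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- detectSep(path, sep)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "")
    geneCol <- if ("gene" %in% names(columnMap)) columnMap[["gene"]] else
        colnames(df)[1L]
    need <- c(geneCol, columnMap[c("logFC", "p", "pAdj")])
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("missing column(s) in ", path, ": ",
             paste(sQuote(miss), collapse = ", "))
    gid <- stripEnsemblVersion(as.character(df[[geneCol]]))
    if (anyDuplicated(gid))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(utils::head(unique(gid[duplicated(gid)]), 5),
                   collapse = ", "))
    be <- if ("baseExpr" %in% names(columnMap) &&
              columnMap[["baseExpr"]] %in% colnames(df))
        df[[columnMap[["baseExpr"]]]] else NULL
    DEResultTable(gid, df[[columnMap[["logFC"]]]],
                  df[[columnMap[["p"]]]], df[[columnMap[["pAdj"]]]],
                  baseExpr = be)
}

#' @rdname readDETable
#' @param de a [DEResultTable-class]
#' @export
writeDETable <- function(de, path) {
    stopifnot(is(de, "DEResultTable"))
    df <- as.data.frame(de)
    out <- data.frame(gene_id = rownames(df),
                      log2FoldChange = df$log_fc, pvalue = df$p,
                      padj = df$p_adj)
    if (!is.null(df$base_expr)) out$baseMean <- df$base_expr
    out <- out[order(out$gene_id), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write a V^G table
#'
#' The exchange format is tab-separated text with a header: the first
#' column holds gene ids, every further column one estimate track named
#' \code{"<source>"} (cross-tissue mean) or \code{"<source>:<tissue>"}.
#' Missing values are empty fields or \code{NA}; zero or negative
#' variances are rejected.
#'
#' @param path file path
#' @param weights optional named tissue-TPM vector to attach (e.g. from
#'   [readTissueWeights()])
#' @return a [VGTable-class]
#' @export
readVGTable <- function(path, weights = numeric(0)) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "", na.strings = c("NA", ""))
    if (ncol(df) < 2L) stop("V^G table needs a gene column and >= 1 track")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    if (any(!is.na(m) & m <= 0))
        stop("non-positive V^G value(s) in ", path,
             "; missing must be encoded as NA or an empty field, never 0")
    VGTable(m, weights = weights)
}

#' @rdname readVGTable
#' @param x a [VGTable-class]
#' @export
writeVGTable <- function(x, path) {
    stopifnot(is(x, "VGTable"))
    m <- vgMatrix(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    df <- df[order(df$gene_id), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read / write tissue weights
#'
#' Two-column TSV (tissue, TPM).
#' @param path file path
#' @return named numeric vector
#' @export
readTissueWeights <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    if (ncol(df) < 2L) stop("expected two columns (tissue, TPM) in ", path)
    stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname readTissueWeights
#' @param weights named numeric vector
#' @export
writeTissueWeights <- function(weights, path) {
    df <- data.frame(tissue = names(weights), tpm = unname(weights))
    df <- df[order(df$tissue), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, all
#' tab-separated. Lines with no member gene are rejected with their line
#' number; an empty file yields an empty collection with a warning.
#' Duplicate members are collapsed.
#'
#' @param path file path
#' @return named list of character vectors with attribute
#'   \code{"termNames"} (set name -> description), directly usable as
#'   the \code{terms} of [ora()]
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty GMT file: ", path)
        out <- list()
        attr(out, "termNames") <- character(0)
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1L], " in ", path,
             ": need name, description and >= 1 gene")
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate set name(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- ids
    attr(sets, "termNames") <-
        stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors
#' @param descriptions optional named character vector of set
#'   descriptions (defaults to the set names)
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("'sets' must be uniquely named")
    desc <- stats::setNames(names(sets), names(sets))
    if (!is.null(descriptions)) {
        hit <- intersect(names(descriptions), names(sets))
        desc[hit] <- descriptions[hit]
    }
    lines <- vapply(names(sets), function(nm) {
        g <- unique(sets[[nm]])
        if (!length(g)) stop("set '", nm, "' is empty")
        paste(c(nm, desc[[nm]], g), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene set from a one-gene-per-line text file
#' @param path file path
#' @return character vector of unique gene ids
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- trimws(readLines(path))
    unique(stripEnsemblVersion(lines[nzchar(lines)]))
}

#' Read / write a gene-feature matrix
#'
#' TSV with a gene-id first column, one column per metric, \code{NA} for
#' missing; an optional \code{label_ln_vg} column carries ln V^G labels.
#'
#' @param path file path
#' @return list with \code{features} (numeric matrix) and \code{labels}
#'   (named numeric vector, or \code{NULL} when the file has no label
#'   column)
#' @export
readFeatureMatrix <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "", na.strings = c("NA", ""))
    gid <- as.character(df[[1L]])
    labels <- NULL
    if ("label_ln_vg" %in% colnames(df)) {
        labels <- stats::setNames(df$label_ln_vg, gid)
        df$label_ln_vg <- NULL
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- gid
    list(features = m, labels = labels)
}

#' @rdname readFeatureMatrix
#' @param features numeric matrix, genes x metrics
#' @param labels optional named ln V^G label vector
#' @export
writeFeatureMatrix <- function(features, labels = NULL, path) {
    df <- data.frame(gene_id = rownames(features), features,
                     check.names = FALSE)
    if (!is.null(labels))
        df$label_ln_vg <- unname(labels[df$gene_id])
    df <- df[order(df$gene_id), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Write a recalibrated table
#'
#' TSV with the original DE columns plus \code{fc_star}, \code{vg_used},
#' \code{rank_nominal}, \code{rank_recal}, sorted by recalibrated rank
#' then gene id so that reruns diff cleanly.
#'
#' @param x a [RecalibratedTable-class]
#' @param path file path
#' @export
writeRecalibratedTable <- function(x, path) {
    stopifnot(is(x, "RecalibratedTable"))
    df <- as.data.frame(x)
    df <- data.frame(gene_id = rownames(df), df, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Write an enrichment comparison
#' @param x an [EnrichmentComparison-class]
#' @param path file path
#' @export
writeEnrichmentComparison <- function(x, path) {
    stopifnot(is(x, "EnrichmentComparison"))
    df <- as.data.frame(x)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Save / load a trained V^G model
#'
#' One self-describing JSON file embedding the feature schema, the
#' hyperparameter record, the label transform, the importances and the
#' serialized booster (base64).
#'
#' @param model a [TrainedVGModel-class]
#' @param path file path
#' @export
saveVGModel <- function(model, path) {
    stopifnot(is(model, "TrainedVGModel"))
    raw <- xgboost::xgb.save.raw(model@booster)
    obj <- list(format = "vgRecal-model-1",
                feature_names = model@featureNames,
                label_transform = model@labelTransform,
                params = model@params,
                importances = as.list(model@importances),
                booster_base64 = jsonlite::base64_enc(raw))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveVGModel
#' @return \code{loadVGModel}: the restored [TrainedVGModel-class]
#' @export
loadVGModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "vgRecal-model-1"))
        stop("not a saved V^G model: ", path)
    booster <- xgboost::xgb.load.raw(
        jsonlite::base64_dec(obj$booster_base64))
    new("TrainedVGModel", booster = booster,
        featureNames = obj$feature_names,
        labelTransform = obj$label_transform,
        params = obj$params,
        importances = unlist(obj$importances))
}
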