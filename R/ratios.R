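#' @include AllGenerics.R
NULL

#' Number of pairwise ratios for m features
#'
#' @param m number of features (>= 1).
#' @return m(m-1)/2, the number of ordered pairs i < j.
#' @examples
#' ratioCount(81)  # 3240
#' ratioCount(17)  # 136
#' @export
ratioCount <- function(m) {
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != round(m))
        stop("'m' must be a positive integer")
    as.integer(m * (m - 1) / 2)
}

#' Pairwise feature-ratio matrix
#'
#' For every unordered feature pair i < j (in the order of
#' \code{keptFeatures}) and every sample k, computes the ratio
#' r_ij(k) = f_i(k) / f_j(k) on the raw abundance scale. Ratio names are
#' \code{"<feature_i>/<feature_j>"}; columns (samples) inherit labels and mode
#' from the dataset.
#'
#' @param ds an imputed \linkS4class{OmicsDataset}.
#' @param keptFeatures ordered subset of features to use (>= 2); defaults to
#'   all features.
#' @return A \linkS4class{RatioMatrix} with m(m-1)/2 ratio rows.
#' @export
computeRatios <- function(ds, keptFeatures = rownames(ds)) {
    stopifnot(is(ds, "OmicsDataset"))
    keptFeatures <- as.character(keptFeatures)
    if (length(keptFeatures) < 2L)
        stop("need at least 2 features to form ratios")
    missing <- setdiff(keptFeatures, rownames(ds))
    if (length(missing))
        stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
    v <- assay(ds)[keptFeatures, , drop = FALSE]
    if (any(is.na(v) | v <= 0))
        stop("dataset contains missing/non-positive values; run imputeMissing() first")
    m <- length(keptFeatures)
    idx <- utils::combn(m, 2L)
    vals <- v[idx[1L, ], , drop = FALSE] / v[idx[2L, ], , drop = FALSE]
    rownames(vals) <- paste(keptFeatures[idx[1L, ]], keptFeatures[idx[2L, ]],
                            sep = "/")
    se <- SummarizedExperiment(
        assays = SimpleList(ratio = vals),
        rowData = DataFrame(numerator = keptFeatures[idx[1L, ]],
                            denominator = keptFeatures[idx[2L, ]]),
        colData = colData(ds))
    metadata(se) <- list(mode = datasetMode(ds), labelOrder = labelOrder(ds),
                         sourceFeatures = keptFeatures, vertexType = "ratio")
    out <- new("RatioMatrix", se)
    validObject(out)
    out
}

#' Use features themselves as network vertices
#'
#' The feature-level variant (MN-PCC): networks are built directly on the
#' features, with the identical downstream analysis. Returns a
#' \linkS4class{RatioMatrix} whose "ratios" are the selected features.
#'
#' @param ds an imputed \linkS4class{OmicsDataset}.
#' @param keptFeatures features to use as vertices; defaults to all.
#' @return A \linkS4class{RatioMatrix} with \code{vertexType == "feature"}.
#' @export
featureVertices <- function(ds, keptFeatures = rownames(ds)) {
    stopifnot(is(ds, "OmicsDataset"))
    keptFeatures <- as.character(keptFeatures)
    missing <- setdiff(keptFeatures, rownames(ds))
    if (length(missing))
        stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
    v <- assay(ds)[keptFeatures, , drop = FALSE]
    se <- SummarizedExperiment(assays = SimpleList(ratio = v),
                               colData = colData(ds))
    metadata(se) <- list(mode = datasetMode(ds), labelOrder = labelOrder(ds),
                         sourceFeatures = keptFeatures, vertexType = "feature")
    out <- new("RatioMatrix", se)
    validObject(out)
    out
}
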