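#' @include AllGenerics.R
NULL

# exact log for common bases; log(x)/log(b) loses the |log2(8)| == 3 boundary
.logBase <- function(x, base) {
    if (base == 2) log2(x)
    else if (base == 10) log10(x)
    else log(x) / log(base)
}

#' Fold-change based feature filtering
#'
#' Keeps a feature when the largest |log(fold change)| of its group means over
#' the compared label pairs reaches \code{threshold}. Fold change between
#' labels a and b is the ratio of arithmetic group means; all unordered label
#' pairs are compared unless \code{comparedLabels} restricts the comparison to
#' designated (e.g. stage-typical) labels.
#'
#' @param ds an imputed \linkS4class{OmicsDataset} (all values positive).
#' @param threshold non-negative cutoff on |log fold change|.
#' @param logBase logarithm base (default 2).
#' @param comparedLabels optional subset of labels whose pairs are evaluated.
#' @return A \linkS4class{FeatureFilterResult}.
#' @examples
#' m <- cbind(f1 = c(1, 1, 1, 8, 8, 8), f2 = c(2, 2, 2, 2.1, 2, 2.2))
#' rownames(m) <- paste0("s", 1:6)
#' ds <- OmicsDataset(m, rep(c("A", "B"), each = 3))
#' keptFeatures(foldChangeFilter(ds, threshold = 3))   # "f1"
#' @export
foldChangeFilter <- function(ds, threshold, logBase = 2,
                             comparedLabels = NULL) {
    stopifnot(is(ds, "OmicsDataset"))
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        stop("'threshold' must be a single non-negative number")
    if (!is.numeric(logBase) || logBase <= 1)
        stop("'logBase' must be > 1")
    v <- assay(ds)
    if (any(is.na(v) | v <= 0))
        stop("dataset contains missing/non-positive values; run imputeMissing() first")
    labs <- sampleLabels(ds)
    if (is.null(comparedLabels)) comparedLabels <- unique(labs)
    missingLab <- setdiff(comparedLabels, labs)
    if (length(missingLab))
        stop(sprintf("compared label(s) absent from dataset: %s",
                     paste(missingLab, collapse = ", ")))
    if (length(comparedLabels) < 2L)
        stop("need at least two labels to compare")
    means <- vapply(comparedLabels,
                    function(g) rowMeans(v[, labs == g, drop = FALSE]),
                    numeric(nrow(v)))
    if (is.null(dim(means))) means <- matrix(means, nrow = 1L,
                                             dimnames = list(rownames(v), comparedLabels))
    pairs <- utils::combn(length(comparedLabels), 2L)
    lfc <- abs(.logBase(means[, pairs[1L, ], drop = FALSE] /
                        means[, pairs[2L, ], drop = FALSE], logBase))
    maxAbs <- apply(lfc, 1L, max)
    names(maxAbs) <- rownames(v)
    kept <- rownames(v)[maxAbs >= threshold - 1e-9]
    new("FeatureFilterResult", keptFeatures = kept, maxAbsLogFC = maxAbs,
        threshold = threshold, logBase = logBase,
        comparedLabels = as.character(comparedLabels))
}
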