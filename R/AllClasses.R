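#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.MODES <- c("static", "time-series")

#' OmicsDataset: labeled abundance matrix
#'
#' Container for a samples-by-features abundance or expression matrix with a
#' per-sample group (static mode) or time-point (time-series mode) label.
#' Internally stored as a \linkS4class{SummarizedExperiment} with features as
#' rows and samples as columns, the Bioconductor convention. Values are
#' positive concentrations/expression levels; \code{NA} marks missing values
#' (non-positive entries are treated as missing by \code{\link{imputeMissing}},
#' since downstream ratios require strictly positive inputs).
#'
#' @slot .Data inherits all SummarizedExperiment slots; \code{colData} carries
#'   a \code{label} column, \code{metadata} carries \code{mode} and
#'   \code{labelOrder}.
#' @seealso \code{\link{readOmicsDataset}}, \code{\link{imputeMissing}},
#'   \code{\link{computeRatios}}
#' @exportClass OmicsDataset
setClass("OmicsDataset", contains = "SummarizedExperiment")

setValidity("OmicsDataset", function(object) {
    msg <- character()
    fn <- rownames(object)
    if (is.null(fn) || any(!nzchar(fn)))
        msg <- c(msg, "feature names must be present and non-empty")
    if (anyDuplicated(fn))
        msg <- c(msg, sprintf("duplicate feature names: %s",
                              paste(unique(fn[duplicated(fn)]), collapse = ", ")))
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'label' column")
    md <- metadata(object)
    if (!isTRUE(md$mode %in% .MODES))
        msg <- c(msg, "metadata$mode must be 'static' or 'time-series'")
    labs <- as.character(colData(object)$label)
    if (identical(md$mode, "time-series")) {
        lo <- md$labelOrder
        if (is.null(lo))
            msg <- c(msg, "time-series mode requires metadata$labelOrder")
        else if (!all(labs %in% lo))
            msg <- c(msg, sprintf("labels not in labelOrder: %s",
                                  paste(unique(setdiff(labs, lo)), collapse = ", ")))
    }
    v <- assay(object)
    if (any(is.infinite(v)))
        msg <- c(msg, "values must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsDataset
#'
#' @param values numeric matrix, samples as rows and features as columns
#'   (the usual delimited-file orientation); it is transposed into the
#'   features-by-samples assay internally.
#' @param sampleLabels character vector of group/time-point labels, one per
#'   sample (row of \code{values}).
#' @param mode \code{"static"} (unordered groups) or \code{"time-series"}
#'   (ordered time points).
#' @param labelOrder ordered label sequence; required in time-series mode.
#' @return An \linkS4class{OmicsDataset}. A warning is emitted for labels with
#'   fewer than 3 samples: per-label Pearson correlations need at least 3
#'   samples, and \code{\link{buildNetwork}} refuses smaller groups.
#' @examples
#' m <- matrix(rexp(24) + 0.5, nrow = 6,
#'             dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
#' ds <- OmicsDataset(m, rep(c("A", "B"), each = 3))
#' @export
OmicsDataset <- function(values, sampleLabels,
                         mode = c("static", "time-series"),
                         labelOrder = NULL) {
    mode <- match.arg(mode)
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("'values' must have feature names as column names")
    if (length(sampleLabels) != nrow(values))
        stop("'sampleLabels' must have one entry per sample (row)")
    sampleLabels <- as.character(sampleLabels)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("sample_%d", seq_len(nrow(values)))
    if (mode == "time-series") {
        if (is.null(labelOrder))
            stop("time-series mode requires 'labelOrder'")
        labelOrder <- as.character(labelOrder)
        bad <- setdiff(sampleLabels, labelOrder)
        if (length(bad))
            stop(sprintf("sample label(s) not in labelOrder: %s",
                         paste(unique(bad), collapse = ", ")))
    } else if (is.null(labelOrder)) {
        labelOrder <- sort(unique(sampleLabels))
    }
    se <- SummarizedExperiment(
        assays = SimpleList(abundance = t(values)),
        colData = DataFrame(label = sampleLabels,
                            row.names = rownames(values)))
    metadata(se) <- list(mode = mode, labelOrder = labelOrder)
    ds <- new("OmicsDataset", se)
    validObject(ds)
    small <- names(which(table(sampleLabels) < 3))
    if (length(small))
        warning(sprintf(
            "label(s) with fewer than 3 samples (%s): per-label networks cannot be built for them",
            paste(small, collapse = ", ")))
    ds
}

#' RatioMatrix: pairwise feature ratios per sample
#'
#' For m selected features, the m(m-1)/2 pairwise ratios r_ij = f_i / f_j
#' (i < j in feature order); rows are ratios, columns samples
#' (SummarizedExperiment convention). In the feature-level network variant the
#' "ratios" are the features themselves (\code{vertexType == "feature"}).
#'
#' @exportClass RatioMatrix
setClass("RatioMatrix", contains = "SummarizedExperiment")

setValidity("RatioMatrix", function(object) {
    msg <- character()
    md <- metadata(object)
    if (!isTRUE(md$vertexType %in% c("ratio", "feature")))
        msg <- c(msg, "metadata$vertexType must be 'ratio' or 'feature'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "ratio names must be unique")
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'label' column")
    v <- assay(object)
    if (identical(md$vertexType, "ratio") && any(!is.na(v) & v <= 0))
        msg <- c(msg, "ratio values must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' SignedNetwork: per-label signed correlation graph
#'
#' Graph over ratio (or feature) vertices for one group/time point. An edge
#' joins two vertices when the Pearson correlation of their values across that
#' label's samples satisfies |PCC| >= tau; the sign is +1 ("red", PCC >= tau)
#' or -1 ("green", PCC <= -tau). All vertices of the shared universe are kept
#' even when isolated, so networks of different labels are comparable.
#'
#' @slot label group or time-point label the network describes.
#' @slot vertices character vector, the full vertex universe.
#' @slot edges data.frame with columns \code{from}, \code{to} (from < to),
#'   \code{sign} (+1/-1) and \code{pcc}; lexicographically ordered.
#' @slot tau correlation threshold in (0, 1].
#' @exportClass SignedNetwork
setClass("SignedNetwork",
         representation(label = "character", vertices = "character",
                        edges = "data.frame", tau = "numeric"))

.validEdges <- function(object) {
    msg <- character()
    e <- object@edges
    need <- c("from", "to", "sign", "pcc")
    if (!all(need %in% names(e)))
        return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$from >= e$to))
            msg <- c(msg, "edges must satisfy from < to (lexicographic)")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicate edges")
        if (!all(c(e$from, e$to) %in% object@vertices))
            msg <- c(msg, "edge endpoints must be vertices")
        if (!all(e$sign %in% c(-1L, 1L)))
            msg <- c(msg, "edge signs must be +1 or -1")
        if (any(abs(e$pcc) < object@tau - 1e-12))
            msg <- c(msg, "every edge must satisfy |pcc| >= tau")
        if (any(sign(e$pcc) * e$sign < 0))
            msg <- c(msg, "edge sign must match the sign of pcc")
    }
    msg
}

setValidity("SignedNetwork", function(object) {
    msg <- .validEdges(object)
    if (length(object@label) != 1L)
        msg <- c(msg, "label must be a single string")
    if (length(object@tau) != 1L || is.na(object@tau) ||
        object@tau <= 0 || object@tau > 1)
        msg <- c(msg, "tau must lie in (0, 1]")
    if (anyDuplicated(object@vertices))
        msg <- c(msg, "vertices must be unique")
    if (length(msg)) msg else TRUE
})

#' DifferentialSubNetwork: edges behaving differently elsewhere
#'
#' Sub-network of a target label's \linkS4class{SignedNetwork} keeping the
#' edges that disappear or flip sign in at least
#' \code{ceiling(fraction * n_comparisons)} of the comparison networks
#' (all other groups in static mode; strictly earlier time points in
#' time-series mode). Vertices are the endpoints of the retained edges only.
#'
#' @slot comparisonLabels labels of the networks compared against.
#' @slot fraction the "most" threshold (default 2/3).
#' @slot requiredCount \code{ceiling(fraction * length(comparisonLabels))}.
#' @slot diffCount integer vector parallel to \code{edges}: in how many
#'   comparison networks each edge behaves differently.
#' @exportClass DifferentialSubNetwork
setClass("DifferentialSubNetwork", contains = "SignedNetwork",
         representation(comparisonLabels = "character", fraction = "numeric",
                        requiredCount = "integer", diffCount = "integer"))

setValidity("DifferentialSubNetwork", function(object) {
    msg <- character()
    if (length(object@diffCount) != nrow(object@edges))
        msg <- c(msg, "diffCount must parallel the edge table")
    if (length(object@diffCount) &&
        any(object@diffCount < object@requiredCount))
        msg <- c(msg, "every retained edge needs diffCount >= requiredCount")
    if (length(object@fraction) != 1L || object@fraction <= 0 ||
        object@fraction > 1)
        msg <- c(msg, "fraction must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' ProjectedSubNetwork: a differential sub-network seen in another label
#'
#' Same vertex set as the base differential sub-network; edge set is the
#' intersection with another label's network, each edge carrying the other
#' network's sign and correlation.
#'
#' @slot targetLabel label of the base differential sub-network.
#' @slot otherLabel label of the network projected into.
#' @exportClass ProjectedSubNetwork
setClass("ProjectedSubNetwork", contains = "SignedNetwork",
         representation(targetLabel = "character", otherLabel = "character"))

#' HubRanking: vertices ordered by degree
#'
#' @slot entries data.frame with columns \code{vertex} and \code{degree},
#'   non-increasing in degree; ties broken by the rule in \code{tieOrder}.
#' @slot tieOrder tie-breaking rule identifier ("lexicographic").
#' @exportClass HubRanking
setClass("HubRanking",
         representation(entries = "data.frame", tieOrder = "character"))

setValidity("HubRanking", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("vertex", "degree") %in% names(e)))
        msg <- c(msg, "entries needs columns vertex, degree")
    else if (nrow(e) > 1 && any(diff(e$degree) > 0))
        msg <- c(msg, "degrees must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' FeatureFilterResult: outcome of fold-change filtering
#'
#' @slot keptFeatures features passing the filter, input order preserved.
#' @slot maxAbsLogFC named vector: per feature, the max over compared label
#'   pairs of |log(fold change)|.
#' @slot threshold cutoff used.
#' @slot logBase base of the logarithm.
#' @slot comparedLabels labels whose pairs were evaluated.
#' @exportClass FeatureFilterResult
setClass("FeatureFilterResult",
         representation(keptFeatures = "character", maxAbsLogFC = "numeric",
                        threshold = "numeric", logBase = "numeric",
                        comparedLabels = "character"))

#' EvaluationResult: ROC/AUC of a logistic ratio classifier
#'
#' @slot auc area under the ROC curve (trapezoidal; equals the Mann-Whitney
#'   statistic with midpoint tie handling).
#' @slot rocPoints data.frame of (fpr, tpr) from (0,0) to (1,1).
#' @slot featuresUsed ratio names entering the model.
#' @slot positiveLabels labels forming the positive class.
#' @slot nPos,nNeg class sizes.
#' @slot converged did the IRLS fit converge.
#' @slot separation TRUE when fitted probabilities hit 0/1 (perfect
#'   separation; score order, hence AUC, is still well defined).
#' @exportClass EvaluationResult
setClass("EvaluationResult",
         representation(auc = "numeric", rocPoints = "data.frame",
                        featuresUsed = "character", positiveLabels = "character",
                        nPos = "integer", nNeg = "integer",
                        converged = "logical", separation = "logical"))

setValidity("EvaluationResult", function(object) {
    p <- object@rocPoints
    msg <- character()
    if (!all(c("fpr", "tpr") %in% names(p)))
        return("rocPoints needs columns fpr, tpr")
    if (nrow(p)) {
        if (abs(p$fpr[1]) > 1e-12 || abs(p$tpr[1]) > 1e-12 ||
            abs(p$fpr[nrow(p)] - 1) > 1e-12 || abs(p$tpr[nrow(p)] - 1) > 1e-12)
            msg <- c(msg, "ROC must run from (0,0) to (1,1)")
        if (any(diff(p$fpr) < -1e-12) || any(diff(p$tpr) < -1e-12))
            msg <- c(msg, "ROC must be monotone non-decreasing")
        trap <- sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
        if (abs(trap - object@auc) > 1e-9)
            msg <- c(msg, "auc must equal the trapezoidal area under rocPoints")
    }
    if (length(msg)) msg else TRUE
})
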