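#' @include AllClasses.R
NULL

#' Accessors for pbdsn classes
#'
#' Small accessor generics: prefer these over direct slot access.
#'
#' @param x a pbdsn object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("datasetMode", function(x) standardGeneric("datasetMode"))

#' @rdname accessors
#' @export
setGeneric("labelOrder", function(x) standardGeneric("labelOrder"))

#' @rdname accessors
#' @export
setGeneric("vertexNames", function(x) standardGeneric("vertexNames"))

#' @rdname accessors
#' @export
setGeneric("sourceFeatures", function(x) standardGeneric("sourceFeatures"))

#' @rdname accessors
#' @export
setGeneric("networkLabel", function(x) standardGeneric("networkLabel"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkTau", function(x) standardGeneric("networkTau"))

#' @rdname accessors
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))

#' @rdname accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' Impute missing / non-positive values
#'
#' @param ds an \linkS4class{OmicsDataset}.
#' @export
setGeneric("imputeMissing", function(ds) standardGeneric("imputeMissing"))

for (cl in c("OmicsDataset", "RatioMatrix")) {
    setMethod("sampleLabels", cl, function(x) as.character(colData(x)$label))
    setMethod("datasetMode", cl, function(x) metadata(x)$mode)
    setMethod("labelOrder", cl, function(x) metadata(x)$labelOrder)
}

setMethod("vertexNames", "RatioMatrix", function(x) rownames(x))
setMethod("vertexNames", "SignedNetwork", function(x) x@vertices)
setMethod("sourceFeatures", "RatioMatrix", function(x) metadata(x)$sourceFeatures)

setMethod("networkLabel", "SignedNetwork", function(x) x@label)
setMethod("networkTau", "SignedNetwork", function(x) x@tau)
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)
setMethod("networkEdges", "DifferentialSubNetwork", function(x) {
    e <- x@edges
    e$difference_count <- x@diffCount
    e
})

setMethod("keptFeatures", "FeatureFilterResult", function(x) x@keptFeatures)
setMethod("rankingTable", "HubRanking", function(x) x@entries)
setMethod("aucValue", "EvaluationResult", function(x) x@auc)
setMethod("rocPoints", "EvaluationResult", function(x) x@rocPoints)

setMethod("show", "OmicsDataset", function(object) {
    labs <- sampleLabels(object)
    cat(sprintf("OmicsDataset (%s): %d features x %d samples\n",
                datasetMode(object), nrow(object), ncol(object)))
    tab <- table(factor(labs, levels = labelOrder(object)))
    cat("labels:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    nmiss <- sum(is.na(assay(object)) | assay(object) <= 0)
    if (nmiss) cat(sprintf("%d missing/non-positive values (impute before use)\n", nmiss))
})

setMethod("show", "RatioMatrix", function(object) {
    cat(sprintf("RatioMatrix (%s vertices): %d x %d samples, %d source features\n",
                metadata(object)$vertexType, nrow(object), ncol(object),
                length(sourceFeatures(object))))
})

setMethod("show", "SignedNetwork", function(object) {
    e <- object@edges
    cat(sprintf("%s '%s': %d vertices, %d edges (%d red / %d green), tau = %g\n",
                class(object), object@label, length(object@vertices), nrow(e),
                sum(e$sign == 1L), sum(e$sign == -1L), object@tau))
})

setMethod("show", "DifferentialSubNetwork", function(object) {
    callNextMethod()
    cat(sprintf("differential vs %s (fraction %.3g -> >= %d of %d comparisons)\n",
                paste(object@comparisonLabels, collapse = ", "),
                object@fraction, object@requiredCount,
                length(object@comparisonLabels)))
})

setMethod("show", "HubRanking", function(object) {
    cat(sprintf("HubRanking: %d vertices (ties: %s)\n",
                nrow(object@entries), object@tieOrder))
    print(utils::head(object@entries, 5L), row.names = FALSE)
})

setMethod("show", "FeatureFilterResult", function(object) {
    cat(sprintf("FeatureFilterResult: %d/%d features kept at |log%g FC| >= %g\n",
                length(object@keptFeatures), length(object@maxAbsLogFC),
                object@logBase, object@threshold))
})

setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf("EvaluationResult: AUC = %.4f (%d pos vs %d neg; %s)\n",
                object@auc, object@nPos, object@nNeg,
                paste(object@featuresUsed, collapse = " + ")))
    if (object@separation)
        cat("note: perfect separation during the logistic fit\n")
})
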