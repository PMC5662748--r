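#' @include AllGenerics.R
NULL

#' Logistic-regression ROC/AUC of selected ratios
#'
#' Fits an unpenalized binary logistic model (intercept plus one linear
#' coefficient per named ratio) of the indicator "sample label is in
#' \code{positiveLabels}" and scores each sample by its fitted probability.
#' The ROC curve sweeps the unique scores; the trapezoidal AUC equals the
#' Mann-Whitney statistic with midpoint handling of score ties. Under perfect
#' separation the maximum-likelihood estimate diverges, but the ordering of
#' fitted scores -- and hence the AUC -- is well defined; the result is
#' flagged via the \code{separation} slot.
#'
#' For a single ratio the fitted sigmoid is monotone in the covariate, so the
#' AUC reduces to the rank (Mann-Whitney) AUC of the raw ratio.
#'
#' @param rm a \linkS4class{RatioMatrix}.
#' @param features ratio names entering the model jointly.
#' @param positiveLabels labels forming the positive class (e.g. one group
#'   vs rest, or the union of disease-stage time points).
#' @return An \linkS4class{EvaluationResult}.
#' @importFrom pROC roc auc
#' @export
logisticAUC <- function(rm, features, positiveLabels) {
    stopifnot(is(rm, "RatioMatrix"))
    features <- as.character(features)
    missing <- setdiff(features, rownames(rm))
    if (length(missing))
        stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
    labs <- sampleLabels(rm)
    y <- labs %in% positiveLabels
    if (!any(y) || all(y))
        stop("both classes must be non-empty")
    X <- t(assay(rm)[features, , drop = FALSE])
    df <- as.data.frame(X)
    names(df) <- sprintf("x%d", seq_along(features))
    df$.y <- y
    separation <- FALSE
    fit <- withCallingHandlers(
        stats::glm(.y ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
                separation <<- TRUE
            invokeRestart("muffleWarning")
        })
    scores <- as.numeric(stats::fitted(fit))
    ro <- pROC::roc(response = y, predictor = scores,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    pts <- data.frame(fpr = 1 - ro$specificities, tpr = ro$sensitivities)
    pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
    rownames(pts) <- NULL
    res <- new("EvaluationResult",
               auc = as.numeric(pROC::auc(ro)), rocPoints = pts,
               featuresUsed = features,
               positiveLabels = as.character(positiveLabels),
               nPos = sum(y), nNeg = sum(!y),
               converged = isTRUE(fit$converged), separation = separation)
    validObject(res)
    res
}

#' Per-label mean and standard error of one ratio
#'
#' Summary behind mean +/- SE trajectory plots: for each label (in
#' \code{labelOrder}), the arithmetic mean and the standard error
#' sd / sqrt(n) of the ratio's values. A single-sample label gets SE 0 and a
#' \code{degenerate} flag.
#'
#' @param rm a \linkS4class{RatioMatrix}.
#' @param feature a ratio name.
#' @return data.frame with columns label, n, mean, se, degenerate.
#' @export
groupSummary <- function(rm, feature) {
    stopifnot(is(rm, "RatioMatrix"))
    if (!feature %in% rownames(rm))
        stop(sprintf("unknown feature '%s'", feature))
    vals <- assay(rm)[feature, ]
    labs <- sampleLabels(rm)
    order_ <- labelOrder(rm)
    order_ <- order_[order_ %in% labs]
    out <- do.call(rbind, lapply(order_, function(g) {
        v <- vals[labs == g]
        n <- length(v)
        data.frame(label = g, n = n, mean = mean(v),
                   se = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
                   degenerate = n < 2L, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
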