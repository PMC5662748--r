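#' @include AllGenerics.R
NULL

#' Pipeline configuration
#'
#' Validates every parameter up front and returns the resolved configuration;
#' \code{\link{runPipeline}} echoes it to \code{config.yaml} next to its
#' outputs. Defaults are the reference settings of the method: tau = 0.7,
#' fraction = 2/3, k = 5, log base 2.
#'
#' @param mode "static" or "time-series".
#' @param labelColumn label column name used when reading from a file.
#' @param labelOrder ordered time points (time-series mode).
#' @param fcThreshold fold-change filter cutoff on |log FC| (0 keeps all).
#' @param logBase base for the fold-change logarithm.
#' @param compareLabels labels whose pairs the fold-change filter evaluates
#'   (e.g. stage-typical time points); NULL compares all pairs.
#' @param tau correlation threshold in (0, 1].
#' @param fraction "most" threshold for the differential rule, in (0, 1].
#' @param targetLabel static target group; NULL analyses every group
#'   one-vs-rest in turn.
#' @param targetIndex time-series target time point (>= 2); NULL uses the
#'   last time point.
#' @param k number of top-ranked vertices retained as candidate biomarkers.
#' @param positiveLabels labels forming the positive class of the AUC
#'   contrast; NULL derives it (static: the target group; time-series: the
#'   target time point and all later ones).
#' @param vertexType "ratio" (pairwise ratios) or "feature" (feature-level
#'   networks, identical downstream analysis).
#' @param perFeatureAUC also evaluate each selected vertex separately.
#' @return A validated list of class \code{RunConfig}.
#' @export
runConfig <- function(mode = c("static", "time-series"),
                      labelColumn = "label", labelOrder = NULL,
                      fcThreshold = 0, logBase = 2, compareLabels = NULL,
                      tau = 0.7, fraction = 2/3,
                      targetLabel = NULL, targetIndex = NULL, k = 5,
                      positiveLabels = NULL,
                      vertexType = c("ratio", "feature"),
                      perFeatureAUC = TRUE) {
    mode <- match.arg(mode)
    vertexType <- match.arg(vertexType)
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
        tau <= 0 || tau > 1)
        stop("'tau' must lie in (0, 1]")
    if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
    if (!is.numeric(fcThreshold) || fcThreshold < 0)
        stop("'fcThreshold' must be >= 0")
    if (!is.numeric(logBase) || logBase <= 1)
        stop("'logBase' must be > 1")
    if (!is.numeric(k) || k < 1 || k != round(k))
        stop("'k' must be a positive integer")
    if (mode == "time-series" && is.null(labelOrder))
        stop("time-series mode requires 'labelOrder'")
    if (!is.null(targetIndex) &&
        (!is.numeric(targetIndex) || targetIndex < 2))
        stop("'targetIndex' must be >= 2")
    structure(list(mode = mode, labelColumn = labelColumn,
                   labelOrder = labelOrder, fcThreshold = fcThreshold,
                   logBase = logBase, compareLabels = compareLabels,
                   tau = tau, fraction = fraction, targetLabel = targetLabel,
                   targetIndex = targetIndex, k = as.integer(k),
                   positiveLabels = positiveLabels, vertexType = vertexType,
                   perFeatureAUC = perFeatureAUC),
              class = "RunConfig")
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

#' Run the full differential sub-network pipeline
#'
#' Imputation, fold-change filtering, ratio (or feature-vertex) construction,
#' per-label signed networks, differential sub-network extraction,
#' projections into the other labels, hub star sub-network, degree ranking,
#' and logistic ROC/AUC evaluation of the selected vertices. All outputs are
#' plain text with fixed formatting and ordering, so identical runs produce
#' byte-identical files.
#'
#' @param input an \linkS4class{OmicsDataset} or a path to a delimited file
#'   readable by \code{\link{readOmicsDataset}}.
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @param outDir output directory (created if needed); NULL skips writing.
#' @return (invisibly) list with the dataset, filter result, ratio matrix,
#'   per-label networks, and per-target results (differential sub-network,
#'   projections, ranking, selected vertices, star, evaluations).
#' @export
runPipeline <- function(input, config = runConfig(), outDir = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    log <- character(0)
    say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
    if (is.character(input))
        input <- readOmicsDataset(input, labelColumn = config$labelColumn,
                                  mode = config$mode,
                                  labelOrder = config$labelOrder)
    stopifnot(is(input, "OmicsDataset"))
    ds <- imputeMissing(input)
    say("samples: %d  features: %d  labels: %s", ncol(ds), nrow(ds),
        paste(labelOrder(ds), collapse = ","))
    filt <- foldChangeFilter(ds, threshold = config$fcThreshold,
                             logBase = config$logBase,
                             comparedLabels = config$compareLabels)
    say("fold-change filter (|log%g FC| >= %g): kept %d/%d features",
        config$logBase, config$fcThreshold,
        length(keptFeatures(filt)), nrow(ds))
    rm <- if (config$vertexType == "ratio")
        computeRatios(ds, keptFeatures(filt))
    else featureVertices(ds, keptFeatures(filt))
    say("%s vertices: %d", config$vertexType, nrow(rm))
    nets <- buildNetworks(rm, tau = config$tau)
    for (g in names(nets))
        say("network %s: %d edges", g, nrow(networkEdges(nets[[g]])))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        yaml::write_yaml(unclass(config),
                         file.path(outDir, "config.yaml"))
        for (g in names(nets))
            writeEdgeList(nets[[g]], file.path(outDir,
                                               sprintf("network_%s.tsv", g)))
    }
    labs <- names(nets)
    targets <- if (config$mode == "static") {
        if (is.null(config$targetLabel)) labs else config$targetLabel
    } else {
        idx <- if (is.null(config$targetIndex)) length(labs)
               else config$targetIndex
        labs[idx]
    }
    results <- list()
    aucRows <- list()
    for (tg in targets) {
        dsn <- if (config$mode == "static")
            differentialSubnetwork(nets, tg, config$fraction)
        else differentialSubnetworkTS(nets, match(tg, labs), config$fraction)
        say("differential sub-network %s: %d edges, %d vertices",
            tg, nrow(networkEdges(dsn)), length(vertexNames(dsn)))
        projLabels <- if (config$mode == "static") setdiff(labs, tg)
                      else labs[seq_len(match(tg, labs) - 1L)]
        projections <- lapply(projLabels, function(g)
            projectSubnetwork(dsn, nets[[g]]))
        names(projections) <- projLabels
        empty <- nrow(dsn@edges) == 0L
        ranking <- if (empty) {
            say("differential sub-network %s is empty; no ranking", tg)
            new("HubRanking",
                entries = data.frame(vertex = character(0), degree = integer(0)),
                tieOrder = "lexicographic")
        } else rankByDegree(dsn)
        selected <- if (empty) character(0) else topK(ranking, config$k)
        star <- if (empty) NULL else starSubnetwork(dsn, selected[1L])
        if (!empty)
            say("target %s: hub %s (degree %d), top-%d: %s", tg,
                selected[1L], rankingTable(ranking)$degree[1L],
                config$k, paste(selected, collapse = ", "))
        pos <- config$positiveLabels
        if (is.null(pos))
            pos <- if (config$mode == "static") tg
                   else labs[seq(match(tg, labs), length(labs))]
        evals <- list()
        if (!empty) {
            contrast <- sprintf("%s_vs_rest", paste(pos, collapse = "+"))
            evals[[contrast]] <- logisticAUC(rm, selected, pos)
            aucRows[[length(aucRows) + 1L]] <- data.frame(
                comparison = contrast,
                features = paste(selected, collapse = ";"),
                auc = sprintf("%.6f", aucValue(evals[[contrast]])),
                n_pos = evals[[contrast]]@nPos,
                n_neg = evals[[contrast]]@nNeg, stringsAsFactors = FALSE)
            if (isTRUE(config$perFeatureAUC) && length(selected) > 1L)
                for (f in selected) {
                    ev <- logisticAUC(rm, f, pos)
                    evals[[paste(contrast, f, sep = "|")]] <- ev
                    aucRows[[length(aucRows) + 1L]] <- data.frame(
                        comparison = contrast, features = f,
                        auc = sprintf("%.6f", aucValue(ev)),
                        n_pos = ev@nPos, n_neg = ev@nNeg,
                        stringsAsFactors = FALSE)
                }
        }
        if (!is.null(outDir)) {
            writeEdgeList(dsn, file.path(outDir,
                                         sprintf("differential_%s.tsv", tg)))
            for (g in names(projections))
                writeEdgeList(projections[[g]],
                              file.path(outDir,
                                        sprintf("projection_%s_%s.tsv", tg, g)))
            rt <- rankingTable(ranking)
            .writeTSV(data.frame(rank = seq_len(nrow(rt)), rt),
                      file.path(outDir, sprintf("ranking_%s.tsv", tg)))
            if (!is.null(star))
                writeGraphML(star, file.path(outDir,
                                             sprintf("star_%s.graphml", tg)))
        }
        results[[tg]] <- list(differential = dsn, projections = projections,
                              ranking = ranking, selected = selected,
                              star = star, evaluations = evals)
    }
    if (!is.null(outDir)) {
        auc <- if (length(aucRows)) do.call(rbind, aucRows)
               else data.frame(comparison = character(0),
                               features = character(0), auc = character(0),
                               n_pos = integer(0), n_neg = integer(0))
        .writeTSV(auc, file.path(outDir, "auc_report.tsv"))
        writeLines(log, file.path(outDir, "run.log"))
    }
    invisible(list(dataset = ds, filter = filt, ratios = rm,
                   networks = nets, targets = results, log = log))
}
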