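#' @include AllGenerics.R
NULL

.inferSep <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labeled abundance matrix
#'
#' Reads a delimited text file (TSV/CSV, header row of feature names) with one
#' designated label column giving group membership (static mode) or time-point
#' membership (time-series mode).
#'
#' @param path file path.
#' @param labelColumn name of the label column.
#' @param mode "static" or "time-series".
#' @param labelOrder ordered time points, required in time-series mode.
#' @param sep field separator; inferred from the extension when NULL.
#' @param featuresAsRows set TRUE for transposed files whose first column
#'   holds feature identifiers and whose columns are samples; the row whose
#'   identifier equals \code{labelColumn} supplies the sample labels.
#' @return An \linkS4class{OmicsDataset}.
#' @export
readOmicsDataset <- function(path, labelColumn = "label",
                             mode = c("static", "time-series"),
                             labelOrder = NULL, sep = NULL,
                             featuresAsRows = FALSE) {
    mode <- match.arg(mode)
    if (is.null(sep)) sep <- .inferSep(path)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    if (featuresAsRows) {
        ids <- as.character(tab[[1L]])
        body <- as.matrix(tab[, -1L, drop = FALSE])
        if (!labelColumn %in% ids)
            stop(sprintf("label row '%s' not found", labelColumn))
        labs <- as.character(body[match(labelColumn, ids), ])
        keep <- ids != labelColumn
        values <- t(apply(body[keep, , drop = FALSE], c(1, 2), as.numeric))
        colnames(values) <- ids[keep]
        rownames(values) <- colnames(tab)[-1L]
    } else {
        if (!labelColumn %in% names(tab))
            stop(sprintf("label column '%s' not found", labelColumn))
        labs <- as.character(tab[[labelColumn]])
        feat <- names(tab)[names(tab) != labelColumn]  # keep duplicates visible
        if (anyDuplicated(feat))
            stop(sprintf("duplicate feature names: %s",
                         paste(unique(feat[duplicated(feat)]), collapse = ", ")))
        values <- as.matrix(tab[, feat, drop = FALSE])
        storage.mode(values) <- "double"
        rownames(values) <- if (!is.null(attr(tab, "row.names")) &&
                                !is.integer(attr(tab, "row.names")))
            rownames(tab) else sprintf("sample_%d", seq_len(nrow(tab)))
    }
    OmicsDataset(values, labs, mode = mode, labelOrder = labelOrder)
}

#' Write a dataset back to delimited text
#'
#' Samples as rows, label column first; round-trips with
#' \code{\link{readOmicsDataset}}.
#'
#' @param ds an \linkS4class{OmicsDataset}.
#' @param path output path; extension picks the separator.
#' @param labelColumn header of the label column.
#' @export
writeOmicsDataset <- function(ds, path, labelColumn = "label") {
    sep <- .inferSep(path)
    v <- t(assay(ds))
    out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                      lab = sampleLabels(ds))
    names(out) <- labelColumn
    out <- cbind(out, as.data.frame(v, check.names = FALSE))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Minimum-value imputation of missing abundances
#'
#' Missing (and non-positive, which ratio construction cannot use) values of a
#' feature within a label group are replaced by the minimum strictly positive
#' value of that feature among the group's samples; when a group has no
#' positive value for the feature, the global minimum positive value of the
#' feature is used instead. Idempotent; never alters an already-positive value.
#'
#' @param ds an \linkS4class{OmicsDataset}.
#' @return The imputed dataset (all values strictly positive).
#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "OmicsDataset", function(ds) {
    v <- assay(ds)
    labs <- sampleLabels(ds)
    bad <- is.na(v) | v <= 0
    if (!any(bad)) return(ds)
    pos <- v
    pos[bad] <- NA
    globalMin <- apply(pos, 1L, function(r)
        if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    dead <- rownames(v)[is.na(globalMin)]
    if (length(dead))
        stop(sprintf("feature(s) with no positive value anywhere: %s",
                     paste(dead, collapse = ", ")))
    for (g in unique(labs)) {
        cols <- labs == g
        sub <- pos[, cols, drop = FALSE]
        gmin <- apply(sub, 1L, function(r)
            if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
        gmin[is.na(gmin)] <- globalMin[is.na(gmin)]
        idx <- which(bad[, cols, drop = FALSE], arr.ind = TRUE)
        if (nrow(idx)) {
            blk <- v[, cols, drop = FALSE]
            blk[idx] <- gmin[idx[, 1L]]
            v[, cols] <- blk
        }
    }
    SummarizedExperiment::assay(ds, "abundance") <- v
    validObject(ds)
    ds
})

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a signed network as an edge-list TSV
#'
#' Columns \code{vertex_u}, \code{vertex_v}, \code{sign}, \code{pcc}, one row
#' per edge, lexicographically ordered by vertex pair. Comment lines
#' (\code{# label=}, \code{# tau=}, \code{# vertices=}) preserve the metadata
#' needed for an identical round-trip via \code{\link{readEdgeList}}.
#' Differential sub-networks gain a \code{difference_count} column.
#'
#' @param net a \linkS4class{SignedNetwork} (or subclass).
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
    stopifnot(is(net, "SignedNetwork"))
    e <- networkEdges(net)
    e <- e[order(e$from, e$to, method = "radix"), , drop = FALSE]
    hdr <- c(sprintf("# label=%s", net@label),
             sprintf("# tau=%s", .fmtNum(net@tau)),
             sprintf("# vertices=%s", paste(net@vertices, collapse = ",")))
    cols <- c("vertex_u", "vertex_v", "sign", "pcc",
              if ("difference_count" %in% names(e)) "difference_count")
    lines <- c(hdr, paste(cols, collapse = "\t"))
    if (nrow(e)) {
        body <- paste(e$from, e$to, sprintf("%+d", e$sign), .fmtNum(e$pcc),
                      sep = "\t")
        if ("difference_count" %in% names(e))
            body <- paste(body, e$difference_count, sep = "\t")
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read an edge-list TSV written by \code{writeEdgeList}
#'
#' @param path file path.
#' @return A \linkS4class{SignedNetwork}.
#' @export
readEdgeList <- function(path) {
    all <- readLines(path)
    hdr <- grep("^#", all, value = TRUE)
    get <- function(key) {
        ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
        if (!length(ln)) stop(sprintf("missing '# %s=' header", key))
        sub(sprintf("^# %s=", key), "", ln[1L])
    }
    label <- get("label")
    tau <- as.numeric(get("tau"))
    vertices <- strsplit(get("vertices"), ",", fixed = TRUE)[[1L]]
    body <- all[!grepl("^#", all)]
    tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        sign = integer(0), pcc = numeric(0),
                        stringsAsFactors = FALSE)
    if (nrow(tab))
        edges <- data.frame(from = as.character(tab$vertex_u),
                            to = as.character(tab$vertex_v),
                            sign = as.integer(tab$sign),
                            pcc = as.numeric(tab$pcc),
                            stringsAsFactors = FALSE)
    new("SignedNetwork", label = label, vertices = vertices,
        edges = edges, tau = tau)
}

#' Export a network as GraphML
#'
#' Edges carry \code{sign} (+1/-1), \code{pcc} and a \code{color} attribute
#' ("red" for positive, "green" for negative correlation) for visualization
#' tools; isolated vertices are kept.
#'
#' @param net a \linkS4class{SignedNetwork}.
#' @param path output path.
#' @importFrom igraph graph_from_data_frame write_graph
#' @export
writeGraphML <- function(net, path) {
    stopifnot(is(net, "SignedNetwork"))
    e <- net@edges
    df <- data.frame(from = e$from, to = e$to, sign = e$sign, pcc = e$pcc,
                     color = ifelse(e$sign > 0, "red", "green"),
                     stringsAsFactors = FALSE)
    g <- graph_from_data_frame(df, directed = FALSE,
                               vertices = data.frame(name = net@vertices))
    write_graph(g, path, format = "graphml")
    invisible(path)
}
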