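#' @include AllGenerics.R
NULL

#' Rank sub-network vertices by degree
#'
#' Vertices of a (differential) sub-network in descending degree order; ties
#' broken lexicographically by vertex name so the ranking is deterministic
#' across runs and platforms.
#'
#' @param net a \linkS4class{SignedNetwork} or subclass (typically a
#'   \linkS4class{DifferentialSubNetwork}).
#' @return A \linkS4class{HubRanking}; empty, with a warning, when the
#'   network has no edges.
#' @export
rankByDegree <- function(net) {
    stopifnot(is(net, "SignedNetwork"))
    e <- net@edges
    if (!nrow(e)) {
        warning("network has no edges; ranking is empty")
        return(new("HubRanking",
                   entries = data.frame(vertex = character(0),
                                        degree = integer(0)),
                   tieOrder = "lexicographic"))
    }
    deg <- table(c(e$from, e$to))
    entries <- data.frame(vertex = names(deg),
                          degree = as.integer(deg),
                          stringsAsFactors = FALSE)
    entries <- entries[order(-entries$degree, entries$vertex,
                             method = "radix"), , drop = FALSE]
    rownames(entries) <- NULL
    new("HubRanking", entries = entries, tieOrder = "lexicographic")
}

#' Top-k candidate biomarkers of a ranking
#'
#' @param ranking a \linkS4class{HubRanking}.
#' @param k number of vertices to select (>= 1); truncated to the ranking
#'   length.
#' @return Character vector of the first min(k, length) vertices.
#' @export
topK <- function(ranking, k) {
    stopifnot(is(ranking, "HubRanking"))
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
        k != round(k))
        stop("'k' must be a positive integer")
    utils::head(ranking@entries$vertex, k)
}
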