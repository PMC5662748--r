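#' @include AllGenerics.R
NULL

.edgeKey <- function(from, to) paste(from, to, sep = "\r")

# float guard keeps exact products like (2/3)*3 from rounding up
.requiredCount <- function(fraction, nComparisons) {
    as.integer(ceiling(fraction * nComparisons - 1e-9))
}

#' Does an edge behave differently in another network?
#'
#' An edge behaves differently when the unordered vertex pair is absent from
#' the other network ("disappears") or present with the opposite sign ("has a
#' different color").
#'
#' @param from,to edge endpoints (any order).
#' @param sign edge sign, +1 or -1.
#' @param other a \linkS4class{SignedNetwork} to compare against.
#' @return \code{TRUE} when the edge disappears or flips sign in \code{other}.
#' @export
edgeBehaviorDiffers <- function(from, to, sign, other) {
    stopifnot(is(other, "SignedNetwork"))
    u <- pmin(from, to)
    w <- pmax(from, to)
    oe <- other@edges
    hit <- match(.edgeKey(u, w), .edgeKey(oe$from, oe$to))
    is.na(hit) | oe$sign[hit] != sign
}

.differential <- function(target, comparisons, fraction) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
    if (!length(comparisons))
        stop("at least one comparison network is required")
    taus <- vapply(comparisons, slot, numeric(1), "tau")
    if (any(abs(taus - target@tau) > 1e-12))
        warning("comparison networks built with a different tau")
    e <- target@edges
    diffCount <- integer(nrow(e))
    if (nrow(e))
        for (net in comparisons)
            diffCount <- diffCount +
                as.integer(edgeBehaviorDiffers(e$from, e$to, e$sign, net))
    req <- .requiredCount(fraction, length(comparisons))
    keep <- diffCount >= req
    kept <- e[keep, , drop = FALSE]
    rownames(kept) <- NULL
    new("DifferentialSubNetwork",
        label = target@label,
        vertices = sort(unique(c(kept$from, kept$to))),
        edges = kept, tau = target@tau,
        comparisonLabels = vapply(comparisons, slot, character(1), "label"),
        fraction = fraction, requiredCount = req,
        diffCount = diffCount[keep])
}

#' Differential sub-network of a target group (static mode)
#'
#' Retains the target network's edges that behave differently (disappear or
#' flip sign) in at least \code{ceiling(fraction * n_other)} of the other
#' groups' networks. With 4 groups and the default fraction 2/3 an edge must
#' differ in 2 of the 3 other networks.
#'
#' @param networks named list of \linkS4class{SignedNetwork}s sharing one
#'   vertex universe and tau (one per group).
#' @param targetLabel label of the target network.
#' @param fraction the "most" threshold, in (0, 1]; default 2/3.
#' @return A \linkS4class{DifferentialSubNetwork}. Vertices are the endpoints
#'   of retained edges only (isolated vertices are dropped: degree ranking is
#'   over participating vertices).
#' @export
differentialSubnetwork <- function(networks, targetLabel, fraction = 2/3) {
    labs <- vapply(networks, slot, character(1), "label")
    names(networks) <- labs
    if (length(networks) < 2L)
        stop("need at least 2 networks")
    if (!targetLabel %in% labs)
        stop(sprintf("target label '%s' not among the networks", targetLabel))
    .differential(networks[[targetLabel]],
                  networks[labs != targetLabel], fraction)
}

#' Differential sub-network of a time point (time-series mode)
#'
#' Identical rule, but the comparison networks are only the strictly earlier
#' time points G_1 .. G_{t-1}; an edge that is new or sign-flipped relative to
#' most of the past is a prospective warning signal for the stage starting at
#' time point t.
#'
#' @param networks list of \linkS4class{SignedNetwork}s in time order.
#' @param targetIndex index t >= 2 of the target time point.
#' @param fraction the "most" threshold, in (0, 1]; default 2/3.
#' @return A \linkS4class{DifferentialSubNetwork}.
#' @export
differentialSubnetworkTS <- function(networks, targetIndex, fraction = 2/3) {
    if (!is.numeric(targetIndex) || length(targetIndex) != 1L ||
        targetIndex != round(targetIndex))
        stop("'targetIndex' must be a single integer")
    if (targetIndex < 2L || targetIndex > length(networks))
        stop("'targetIndex' must be in 2..length(networks) (no earlier networks exist for t = 1)")
    .differential(networks[[targetIndex]],
                  networks[seq_len(targetIndex - 1L)], fraction)
}

#' Project a differential sub-network into another label's network
#'
#' Keeps the vertex set of the differential sub-network and the edges that
#' also exist in the other network, with the other network's signs and
#' correlations (the projected image SG_target-other with
#' E = E(SG_target) intersect E(G_other)).
#'
#' @param dsn a \linkS4class{DifferentialSubNetwork}.
#' @param other a \linkS4class{SignedNetwork}.
#' @return A \linkS4class{ProjectedSubNetwork}.
#' @export
projectSubnetwork <- function(dsn, other) {
    stopifnot(is(dsn, "DifferentialSubNetwork"), is(other, "SignedNetwork"))
    oe <- other@edges
    hit <- match(.edgeKey(dsn@edges$from, dsn@edges$to),
                 .edgeKey(oe$from, oe$to))
    edges <- oe[hit[!is.na(hit)], , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    new("ProjectedSubNetwork",
        label = sprintf("%s-%s", dsn@label, other@label),
        vertices = dsn@vertices, edges = edges, tau = other@tau,
        targetLabel = dsn@label, otherLabel = other@label)
}

#' Star sub-network around a hub vertex
#'
#' All edges incident to \code{center}, with their signs; vertices are the
#' center plus its neighbors, so the edge count equals the center's degree.
#'
#' @param net a \linkS4class{SignedNetwork} (or subclass).
#' @param center a vertex of \code{net}.
#' @return A \linkS4class{SignedNetwork}.
#' @export
starSubnetwork <- function(net, center) {
    stopifnot(is(net, "SignedNetwork"))
    if (!center %in% net@vertices)
        stop(sprintf("unknown vertex '%s'", center))
    e <- net@edges[net@edges$from == center | net@edges$to == center, ,
                   drop = FALSE]
    e <- e[, c("from", "to", "sign", "pcc"), drop = FALSE]
    rownames(e) <- NULL
    new("SignedNetwork", label = sprintf("%s|star:%s", net@label, center),
        vertices = unique(c(center, e$from, e$to)), edges = e, tau = net@tau)
}
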