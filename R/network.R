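#' @include AllGenerics.R
NULL

#' Pearson correlation of two value sequences
#'
#' Sample Pearson correlation (n-1 denominator), clamped to [-1, 1] against
#' floating-point overshoot. A zero-variance argument is a degenerate input:
#' \code{NA} is returned, and network construction treats such pairs as
#' having no edge.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or \code{NA} when either input has zero
#'   standard deviation.
#' @examples
#' pearsonCC(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearsonCC <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 paired observations")
    if (anyNA(x) || anyNA(y))
        stop("inputs must not contain missing values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(NA_real_)
    min(1, max(-1, stats::cor(x, y)))
}

#' Build the signed correlation network of one label
#'
#' For the samples carrying \code{label}, computes the Pearson correlation of
#' every unordered pair of ratio (or feature) vertices and adds a signed edge
#' when |PCC| >= tau: sign +1 ("red") for PCC >= tau, -1 ("green") for
#' PCC <= -tau. All vertices are retained, including isolated ones, so the
#' networks of different labels share one vertex universe. Pairs involving a
#' zero-variance vertex (possible after minimum-value imputation of a fully
#' missing group) contribute no edge.
#'
#' @param rm a \linkS4class{RatioMatrix}.
#' @param label a label with >= 3 samples in \code{rm}.
#' @param tau threshold in (0, 1]; the boundary |PCC| == tau yields an edge.
#' @return A \linkS4class{SignedNetwork}.
#' @export
buildNetwork <- function(rm, label, tau = 0.7) {
    stopifnot(is(rm, "RatioMatrix"))
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
        tau <= 0 || tau > 1)
        stop("'tau' must lie in (0, 1]")
    labs <- sampleLabels(rm)
    if (!label %in% labs)
        stop(sprintf("label '%s' not present", label))
    cols <- labs == label
    if (sum(cols) < 3L)
        stop(sprintf("label '%s' has %d samples; at least 3 are required",
                     label, sum(cols)))
    X <- t(assay(rm)[, cols, drop = FALSE])
    sds <- apply(X, 2L, stats::sd)
    ok <- which(sds > 0)
    edges <- data.frame(from = character(0), to = character(0),
                        sign = integer(0), pcc = numeric(0),
                        stringsAsFactors = FALSE)
    if (length(ok) >= 2L) {
        C <- suppressWarnings(stats::cor(X[, ok, drop = FALSE]))
        C[C > 1] <- 1
        C[C < -1] <- -1
        hit <- which(abs(C) >= tau & upper.tri(C), arr.ind = TRUE)
        if (nrow(hit)) {
            u <- colnames(C)[hit[, 1L]]
            w <- colnames(C)[hit[, 2L]]
            swap <- u > w
            tmp <- u[swap]; u[swap] <- w[swap]; w[swap] <- tmp
            pcc <- C[hit]
            o <- order(u, w, method = "radix")
            edges <- data.frame(from = u[o], to = w[o],
                                sign = ifelse(pcc[o] >= 0, 1L, -1L),
                                pcc = pcc[o], stringsAsFactors = FALSE)
        }
    }
    net <- new("SignedNetwork", label = as.character(label),
               vertices = rownames(rm), edges = edges, tau = tau)
    validObject(net)
    net
}

#' Build one network per label
#'
#' Convenience wrapper over \code{\link{buildNetwork}}; labels follow
#' \code{labelOrder} (time order in time-series mode).
#'
#' @param rm a \linkS4class{RatioMatrix}.
#' @param tau threshold in (0, 1].
#' @return Named list of \linkS4class{SignedNetwork}s.
#' @export
buildNetworks <- function(rm, tau = 0.7) {
    labs <- labelOrder(rm)
    labs <- labs[labs %in% sampleLabels(rm)]
    nets <- lapply(labs, function(g) buildNetwork(rm, g, tau))
    names(nets) <- labs
    nets
}
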