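#' @include AllGenerics.R
NULL

#' Specification of a synthetic planted-hub dataset
#'
#' @slot nLabels number of groups (static) or time points (time-series).
#' @slot samplesPerLabel samples per group/time point.
#' @slot nFeatures number of features (>= 2).
#' @slot nPartners number of ratios correlated with the planted hub ratio in
#'   the target label (<= nFeatures - 2).
#' @slot targetLabel label at which the hub structure is planted.
#' @slot withinTargetPCC intended |PCC| between hub and partner ratios in the
#'   target label (log-scale solve; the raw-scale value is mildly attenuated
#'   by the log-normal transform).
#' @slot backgroundPCC intended |PCC| of the same pairs in the other labels.
#' @slot noiseSd per-feature log-scale noise standard deviation.
#' @slot mode "static" or "time-series".
#' @slot seed RNG seed; fully determines the output.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(nLabels = "integer", samplesPerLabel = "integer",
                        nFeatures = "integer", nPartners = "integer",
                        targetLabel = "character",
                        withinTargetPCC = "numeric", backgroundPCC = "numeric",
                        noiseSd = "numeric", mode = "character",
                        seed = "integer"))

.specLabels <- function(mode, n) {
    sprintf(if (mode == "static") "G%d" else "S%d", seq_len(n))
}

#' Construct a SyntheticSpec
#'
#' Defaults describe the reference scenario used throughout the test suite:
#' 4 groups of 20 samples, 10 features, a hub ratio with 8 planted partners at
#' |PCC| 0.95 in the target group and ~0 elsewhere.
#'
#' @param nLabels,samplesPerLabel,nFeatures,nPartners,targetLabel,withinTargetPCC,backgroundPCC,noiseSd,mode,seed
#'   see the class slots.
#' @return A validated \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nLabels = 4, samplesPerLabel = 20, nFeatures = 10,
                          nPartners = 8, targetLabel = NULL,
                          withinTargetPCC = 0.95, backgroundPCC = 0,
                          noiseSd = 0.1, mode = c("static", "time-series"),
                          seed = 1) {
    mode <- match.arg(mode)
    if (nFeatures < 2) stop("'nFeatures' must be >= 2")
    if (nPartners < 0 || nPartners > nFeatures - 2)
        stop("'nPartners' must be in 0 .. nFeatures - 2 (hub uses two features)")
    if (nLabels < 2) stop("'nLabels' must be >= 2")
    if (samplesPerLabel < 3) stop("'samplesPerLabel' must be >= 3")
    if (withinTargetPCC <= 0 || withinTargetPCC >= 1)
        stop("'withinTargetPCC' must lie in (0, 1)")
    if (backgroundPCC < 0 || backgroundPCC >= withinTargetPCC)
        stop("'backgroundPCC' must lie in [0, withinTargetPCC)")
    labels <- .specLabels(mode, nLabels)
    if (is.null(targetLabel))
        targetLabel <- if (mode == "static") labels[1L] else labels[nLabels]
    if (!targetLabel %in% labels)
        stop(sprintf("targetLabel must be one of %s", paste(labels, collapse = ", ")))
    new("SyntheticSpec", nLabels = as.integer(nLabels),
        samplesPerLabel = as.integer(samplesPerLabel),
        nFeatures = as.integer(nFeatures), nPartners = as.integer(nPartners),
        targetLabel = targetLabel, withinTargetPCC = withinTargetPCC,
        backgroundPCC = backgroundPCC, noiseSd = noiseSd, mode = mode,
        seed = as.integer(seed))
}

# log-scale sd of the always-on factor shared by the hub features and (via
# the shared denominator) the partner ratios; keeps partner-partner edges
# present in every label so only hub-partner edges are differential
.SU <- 0.3

# z-loading c = alpha + 1/2 solving corr(hub, partner) = rho on the log scale
.zLoading <- function(rho, s, su = .SU) {
    denom <- 1 - rho^2 * (1 + 2 * s^2)
    if (denom <= 0)
        stop("requested PCC is infeasible at this noise level")
    sqrt(rho^2 * (1 + 2 * s^2) * (su^2 + 2 * s^2) / denom)
}

#' Generate a dataset with a planted differential correlation hub
#'
#' Samples a log-normal latent model in which the designated hub ratio
#' f01/f02 is strongly correlated (|PCC| about \code{withinTargetPCC}) with
#' \code{nPartners} partner ratios f02/f0j in the target label and near
#' \code{backgroundPCC} elsewhere. The hub features share an always-on
#' log-scale factor u that cancels inside the hub ratio but dominates any
#' ratio containing only one of them, and the partner ratios share the
#' denominator f02, so partner-partner correlations persist in every label
#' (those edges are therefore not differential). The expected differential
#' sub-network at the target is a star centered on the hub. In time-series
#' mode the structure appears only at the target time point, emulating a
#' stage-onset warning signal.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return List with elements \code{dataset} (an
#'   \linkS4class{OmicsDataset}) and \code{truth} (hub name, partner ratio
#'   names, planted edge table, partner features, target label).
#' @export
generateSynthetic <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    set.seed(spec@seed)
    m <- spec@nFeatures
    P <- spec@nPartners
    s <- spec@noiseSd
    width <- max(2L, nchar(as.character(m)))
    feats <- sprintf("f%0*d", width, seq_len(m))
    labels <- .specLabels(spec@mode, spec@nLabels)
    cload <- .zLoading(spec@withinTargetPCC, s)
    # partner features load z negatively so the stored ratio f02/f0j carries
    # +cload*z, matching the hub's sign: positive raw-scale correlations
    # survive the log-normal transform, strongly negative ones do not
    alpha <- -(cload + 0.5)
    kapBg <- if (spec@backgroundPCC <= 0) 0 else {
        corrAt <- function(k) {
            k^2 * cload / sqrt((k^2 + 2 * s^2) * (k^2 * cload^2 + .SU^2 + 2 * s^2))
        }
        stats::uniroot(function(k) corrAt(k) - spec@backgroundPCC,
                       c(1e-6, 1))$root
    }
    mu <- stats::rnorm(m, 4, 1)
    n <- spec@samplesPerLabel
    blocks <- lapply(labels, function(g) {
        # nPartners == 0 means nothing is planted: no signal anywhere
        kap <- if (P == 0) 0 else if (g == spec@targetLabel) 1 else kapBg
        u <- stats::rnorm(n, 0, .SU)
        z <- stats::rnorm(n)
        L <- matrix(rep(mu, each = n), n, m) +
            matrix(stats::rnorm(n * m, 0, s), n, m)
        L[, 1L] <- L[, 1L] + u + 0.5 * kap * z
        L[, 2L] <- L[, 2L] + u - 0.5 * kap * z
        if (P > 0)
            L[, 2L + seq_len(P)] <- L[, 2L + seq_len(P)] + alpha * kap * z
        rownames(L) <- sprintf("%s_s%02d", g, seq_len(n))
        L
    })
    values <- exp(do.call(rbind, blocks))
    colnames(values) <- feats
    ds <- OmicsDataset(values, rep(labels, each = n), mode = spec@mode,
                       labelOrder = labels)
    hub <- paste(feats[1L], feats[2L], sep = "/")
    partnerFeatures <- if (P > 0) feats[2L + seq_len(P)] else character(0)
    partnerRatios <- if (P > 0) paste(feats[2L], partnerFeatures, sep = "/")
                     else character(0)
    planted <- data.frame(from = rep(hub, P), to = partnerRatios,
                          stringsAsFactors = FALSE)
    list(dataset = ds,
         truth = list(hub = hub, partnerRatios = partnerRatios,
                      plantedEdges = planted,
                      partnerFeatures = partnerFeatures,
                      targetLabel = spec@targetLabel))
}

#' Mask values at random, respecting per-group coverage
#'
#' Each value is masked (set to \code{NA}) independently with probability
#' \code{rate}, except that a feature is never left without any observed
#' value within a label group (one masked entry is restored when that would
#' happen), so \code{\link{imputeMissing}} can always apply its within-group
#' rule.
#'
#' @param ds an \linkS4class{OmicsDataset}.
#' @param rate masking probability in [0, 1).
#' @param seed RNG seed; the mask is deterministic given the seed.
#' @return The masked dataset.
#' @export
addMissingness <- function(ds, rate, seed = 1) {
    stopifnot(is(ds, "OmicsDataset"))
    if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
        stop("'rate' must lie in [0, 1)")
    if (rate == 0) return(ds)
    set.seed(seed)
    v <- assay(ds)
    mask <- matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v))
    labs <- sampleLabels(ds)
    for (g in unique(labs)) {
        cols <- which(labs == g)
        sub <- mask[, cols, drop = FALSE]
        gone <- which(rowSums(!sub) == 0L)
        for (i in gone) {
            j <- cols[sample.int(length(cols), 1L)]
            mask[i, j] <- FALSE
        }
    }
    v[mask] <- NA_real_
    SummarizedExperiment::assay(ds, "abundance") <- v
    ds
}
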