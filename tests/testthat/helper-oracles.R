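suppressPackageStartupMessages(library(SummarizedExperiment))

# naive two-pass sample Pearson correlation: mean/sd first, then the
# normalized cross product with the n-1 denominator
naivePearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n
    my <- sum(y) / n
    sx <- sqrt(sum((x - mx)^2) / (n - 1))
    sy <- sqrt(sum((y - my)^2) / (n - 1))
    sum(((x - mx) / sx) * ((y - my) / sy)) / (n - 1)
}

# hand-built signed network; edgeSpec is a list of c(u, v, sign) triples
mkNet <- function(label, edgeSpec = list(), vertices = letters[1:5],
                  tau = 0.7) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = integer(0), pcc = numeric(0),
                        stringsAsFactors = FALSE)
    if (length(edgeSpec)) {
        edges <- do.call(rbind, lapply(edgeSpec, function(e) {
            u <- min(e[1], e[2]); w <- max(e[1], e[2])
            s <- as.integer(e[3])
            data.frame(from = u, to = w, sign = s, pcc = s * 0.9,
                       stringsAsFactors = FALSE)
        }))
        edges <- edges[order(edges$from, edges$to), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("SignedNetwork", label = label, vertices = vertices, edges = edges,
        tau = tau)
}

# random family of signed networks on a shared vertex universe
randomNetworkFamily <- function(nLabels, nVertices = 8, edgeProb = 0.4,
                                tau = 0.7) {
    verts <- letters[seq_len(nVertices)]
    pairs <- t(combn(verts, 2))
    lapply(seq_len(nLabels), function(i) {
        pick <- runif(nrow(pairs)) < edgeProb
        spec <- lapply(which(pick), function(r)
            c(pairs[r, 1], pairs[r, 2], sample(c(-1, 1), 1)))
        mkNet(sprintf("L%d", i), spec, vertices = verts, tau = tau)
    })
}

# exhaustive per-edge evaluation of the differential rule
bruteDifferential <- function(target, comparisons, fraction) {
    req <- ceiling(fraction * length(comparisons) - 1e-9)
    e <- networkEdges(target)
    keep <- logical(nrow(e))
    cnt <- integer(nrow(e))
    for (i in seq_len(nrow(e))) {
        c0 <- 0L
        for (net in comparisons) {
            oe <- networkEdges(net)
            j <- which(oe$from == e$from[i] & oe$to == e$to[i])
            if (!length(j) || oe$sign[j] != e$sign[i]) c0 <- c0 + 1L
        }
        cnt[i] <- c0
        keep[i] <- c0 >= req
    }
    list(edges = e[keep, c("from", "to", "sign"), drop = FALSE],
         counts = cnt[keep], required = req)
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties count 1/2)
mwAUC <- function(scores, positive) {
    pos <- scores[positive]
    neg <- scores[!positive]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# small labeled dataset from an explicit samples-by-features matrix
mkDataset <- function(values, labels, ...) {
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("f%d", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("s%d", seq_len(nrow(values)))
    OmicsDataset(values, labels, ...)
}
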