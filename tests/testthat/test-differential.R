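test_that("edge behavior comparison detects disappearance and sign flips", {
    other <- mkNet("G2", list(c("a", "b", 1), c("c", "d", -1)))
    expect_false(edgeBehaviorDiffers("a", "b", 1L, other))   # same behavior
    expect_true(edgeBehaviorDiffers("a", "c", 1L, other))    # disappears
    expect_true(edgeBehaviorDiffers("c", "d", 1L, other))    # flipped color
    # vectorized and order-insensitive in the endpoints
    expect_equal(edgeBehaviorDiffers(c("b", "d"), c("a", "c"), c(1L, -1L),
                                     other),
                 c(FALSE, FALSE))
})

test_that("the static rule retains edges differing in enough other groups", {
    # edge (a,b): differs in 2 of 3 others -> kept at fraction 2/3
    # edge (c,d): differs in 1 of 3 others -> dropped
    # edge (a,e): same sign everywhere     -> dropped
    target <- mkNet("T", list(c("a", "b", 1), c("c", "d", 1), c("a", "e", 1)))
    others <- list(
        mkNet("O1", list(c("a", "b", -1), c("c", "d", 1), c("a", "e", 1))),
        mkNet("O2", list(c("c", "d", 1), c("a", "e", 1))),
        mkNet("O3", list(c("a", "b", 1), c("c", "d", -1), c("a", "e", 1))))
    dsn <- differentialSubnetwork(c(list(target), others), "T", 2/3)
    expect_equal(dsn@requiredCount, 2L)
    e <- networkEdges(dsn)
    expect_equal(nrow(e), 1L)
    expect_equal(e$from, "a")
    expect_equal(e$to, "b")
    expect_equal(e$difference_count, 2L)
    expect_equal(vertexNames(dsn), c("a", "b"))
})

test_that("differential extraction equals exhaustive rule evaluation", {
    set.seed(41)
    for (rep in 1:25) {
        nLab <- sample(3:6, 1)
        fam <- randomNetworkFamily(nLab, nVertices = sample(5:8, 1),
                                   edgeProb = runif(1, 0.2, 0.6))
        frac <- sample(c(1/2, 2/3, 3/4, 1), 1)
        # static: compare against all other groups
        tgt <- sample(nLab, 1)
        dsn <- differentialSubnetwork(fam, sprintf("L%d", tgt), frac)
        oracle <- bruteDifferential(fam[[tgt]], fam[-tgt], frac)
        got <- networkEdges(dsn)
        expect_equal(got[, c("from", "to", "sign")], oracle$edges,
                     ignore_attr = TRUE)
        expect_equal(got$difference_count, oracle$counts)
        expect_equal(dsn@requiredCount, as.integer(oracle$required))
        # time-series: compare against earlier time points only
        t <- sample(2:nLab, 1)
        dts <- differentialSubnetworkTS(fam, t, frac)
        ots <- bruteDifferential(fam[[t]], fam[seq_len(t - 1)], frac)
        expect_equal(networkEdges(dts)[, c("from", "to", "sign")],
                     ots$edges, ignore_attr = TRUE)
    }
})

test_that("time-series comparisons use only earlier time points", {
    # sign-flipping edge at t = 3 under fraction 1/2; the stable (c,d) edge
    # is present with the same sign at both earlier points
    nets <- list(mkNet("S1", list(c("a", "b", 1), c("c", "d", 1))),
                 mkNet("S2", list(c("a", "b", 1), c("c", "d", 1))),
                 mkNet("S3", list(c("a", "b", -1), c("c", "d", 1))))
    dsn <- differentialSubnetworkTS(nets, 3, 1/2)
    e <- networkEdges(dsn)
    expect_equal(nrow(e), 1L)
    expect_equal(paste(e$from, e$to), "a b")
    # an edge absent at every earlier time point is maximally differential
    nets2 <- list(mkNet("S1"), mkNet("S2"), mkNet("S3"),
                  mkNet("S4", list(c("a", "b", 1))))
    d4 <- differentialSubnetworkTS(nets2, 4, 2/3)
    expect_equal(networkEdges(d4)$difference_count, 3L)
    expect_error(differentialSubnetworkTS(nets, 1, 2/3), "no earlier")
})

test_that("required counts follow ceil(fraction x comparisons)", {
    fam5 <- randomNetworkFamily(5)
    expect_equal(differentialSubnetworkTS(fam5, 5, 2/3)@requiredCount, 3L)
    expect_equal(differentialSubnetwork(fam5, "L1", 2/3)@requiredCount, 3L)
    fam4 <- randomNetworkFamily(4)
    expect_equal(differentialSubnetwork(fam4, "L1", 2/3)@requiredCount, 2L)
    expect_equal(differentialSubnetwork(fam4, "L1", 1)@requiredCount, 3L)
})

test_that("lowering the fraction never removes differential edges", {
    set.seed(42)
    fam <- randomNetworkFamily(5, nVertices = 8, edgeProb = 0.5)
    fracs <- c(1, 3/4, 1/2, 1/4)
    keys <- lapply(fracs, function(f) {
        e <- networkEdges(differentialSubnetwork(fam, "L1", f))
        paste(e$from, e$to)
    })
    for (i in seq_len(length(fracs) - 1L))
        expect_true(all(keys[[i]] %in% keys[[i + 1L]]))
})

test_that("a target compared against copies of itself is empty", {
    net <- mkNet("T", list(c("a", "b", 1), c("b", "c", -1)))
    cp1 <- mkNet("C1", list(c("a", "b", 1), c("b", "c", -1)))
    cp2 <- mkNet("C2", list(c("a", "b", 1), c("b", "c", -1)))
    dsn <- differentialSubnetwork(list(net, cp1, cp2), "T", 2/3)
    expect_equal(nrow(networkEdges(dsn)), 0L)
    expect_length(vertexNames(dsn), 0L)
})

test_that("projection intersects edges and takes the other network's signs", {
    target <- mkNet("T", list(c("a", "b", 1), c("c", "d", 1)))
    others <- list(mkNet("O1"), mkNet("O2"))
    dsn <- differentialSubnetwork(c(list(target), others), "T", 2/3)
    other <- mkNet("G9", list(c("a", "b", -1), c("x", "y", 1)),
                   vertices = c(letters[1:5], "x", "y"))
    proj <- projectSubnetwork(dsn, other)
    e <- networkEdges(proj)
    expect_equal(nrow(e), 1L)
    expect_equal(e$sign, -1L)                     # sign from the other network
    expect_equal(vertexNames(proj), vertexNames(dsn))  # vertex set copied
    # disjoint other network: empty projection, vertices kept
    projEmpty <- projectSubnetwork(dsn, mkNet("G0", list(c("x", "y", 1)),
                                              vertices = c(letters[1:5], "x", "y")))
    expect_equal(nrow(networkEdges(projEmpty)), 0L)
    expect_equal(vertexNames(projEmpty), vertexNames(dsn))
    # projecting into the target's own network returns the dsn edges
    projSelf <- projectSubnetwork(dsn, target)
    expect_equal(networkEdges(projSelf)[, c("from", "to", "sign")],
                 networkEdges(dsn)[, c("from", "to", "sign")])
})

test_that("star sub-networks collect exactly the incident edges", {
    path <- mkNet("P", list(c("a", "b", 1), c("b", "c", -1)),
                  vertices = c("a", "b", "c", "z"))
    star <- starSubnetwork(path, "b")
    expect_equal(nrow(networkEdges(star)), 2L)
    expect_setequal(vertexNames(star), c("a", "b", "c"))
    # isolated center: single-vertex zero-edge star
    star0 <- starSubnetwork(path, "z")
    expect_equal(nrow(networkEdges(star0)), 0L)
    expect_equal(vertexNames(star0), "z")
    expect_error(starSubnetwork(path, "q"), "unknown vertex")
    # |star edges| == degree(center) on a random graph
    set.seed(43)
    g <- randomNetworkFamily(1, nVertices = 8, edgeProb = 0.5)[[1]]
    e <- networkEdges(g)
    for (vtx in vertexNames(g)) {
        deg <- sum(e$from == vtx) + sum(e$to == vtx)
        expect_equal(nrow(networkEdges(starSubnetwork(g, vtx))), deg)
    }
})
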