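test_that("pearsonCC reproduces hand-computed correlations", {
    expect_equal(pearsonCC(c(1, 2, 3), c(1, 2, 3)), 1.0)
    expect_equal(pearsonCC(c(1, 2, 3), c(3, 2, 1)), -1.0)
    expect_equal(pearsonCC(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
    expect_error(pearsonCC(1:4, 1:3), "equal length")
    expect_error(pearsonCC(1:2, 2:1), "at least 3")
    expect_true(is.na(pearsonCC(c(2, 2, 2), c(1, 2, 3))))
})

test_that("pearsonCC agrees with the naive two-pass oracle", {
    set.seed(31)
    for (i in 1:60) {
        n <- sample(3:50, 1)
        x <- rnorm(n) * runif(1, 0.1, 10)
        y <- rnorm(n) + x * runif(1, -2, 2)
        expect_equal(pearsonCC(x, y), naivePearson(x, y), tolerance = 1e-12)
    }
})

test_that("pearsonCC is symmetric and affine-invariant", {
    set.seed(32)
    for (i in 1:20) {
        x <- rnorm(10); y <- rnorm(10)
        expect_equal(pearsonCC(x, y), pearsonCC(y, x), tolerance = 1e-12)
        a <- runif(1, 0.1, 5); b <- rnorm(1)
        expect_equal(pearsonCC(a * x + b, y), pearsonCC(x, y),
                     tolerance = 1e-10)
    }
})

test_that("networks contain exactly the |PCC| >= tau pairs with correct signs", {
    set.seed(33)
    # planted block: r1, r2, r3 strongly correlated, r4 independent
    n <- 30
    base <- rnorm(n, 0, 0.3)
    X <- cbind(r1 = base + rnorm(n, 0, 0.05),
               r2 = base + rnorm(n, 0, 0.05),
               r3 = -base + rnorm(n, 0, 0.05),
               r4 = rnorm(n, 0, 0.3))
    v <- exp(X)   # positive abundances; modest spread keeps raw-scale
                  # correlations close to their latent values
    rm <- computeRatios(mkDataset(cbind(v, ref = rep(1, n)), rep("A", n)),
                        keptFeatures = c("r1", "r2", "r3", "r4", "ref"))
    # keep only the ratios over the unit reference: values equal the columns
    net <- buildNetwork(rm, "A", tau = 0.7)
    e <- networkEdges(net)
    inBlock <- c("r1/ref", "r2/ref", "r3/ref")
    blockEdges <- e[e$from %in% inBlock & e$to %in% inBlock, ]
    expect_equal(nrow(blockEdges), 3L)
    expect_equal(blockEdges$sign[blockEdges$from == "r1/ref" &
                                 blockEdges$to == "r2/ref"], 1L)
    expect_equal(sum(blockEdges$sign == -1L), 2L)  # r3 anti-correlated
    expect_false(any((e$from == "r4/ref" & e$to %in% inBlock) |
                     (e$to == "r4/ref" & e$from %in% inBlock)))
})

test_that("edge presence and sign match brute-force pairwise evaluation", {
    set.seed(34)
    n <- 30; p <- 20
    X <- matrix(rexp(n * p) + 0.05, n, p,
                dimnames = list(NULL, sprintf("f%02d", 1:p)))
    ds <- mkDataset(X, rep("A", n))
    fv <- featureVertices(ds)
    tau <- 0.35
    net <- buildNetwork(fv, "A", tau = tau)
    e <- networkEdges(net)
    key <- paste(e$from, e$to)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
        r <- naivePearson(X[, i], X[, j])
        k <- paste(colnames(X)[i], colnames(X)[j])
        if (abs(r) >= tau) {
            expect_true(k %in% key)
            row <- e[key == k, ]
            expect_equal(row$pcc, r, tolerance = 1e-12)
            expect_equal(row$sign, ifelse(r >= 0, 1L, -1L))
        } else {
            expect_false(k %in% key)
        }
    }
})

test_that("raising tau never adds edges", {
    set.seed(35)
    X <- matrix(rexp(200) + 0.05, 20, 10,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    fv <- featureVertices(mkDataset(X, rep("A", 20)))
    taus <- c(0.2, 0.4, 0.6, 0.8, 0.95)
    keys <- lapply(taus, function(t) {
        e <- networkEdges(buildNetwork(fv, "A", t))
        paste(e$from, e$to)
    })
    for (i in seq_len(length(taus) - 1L))
        expect_true(all(keys[[i + 1L]] %in% keys[[i]]))
})

test_that("degenerate and invalid network inputs are handled", {
    X <- cbind(const = rep(2, 5), var1 = c(1, 2, 3, 4, 5),
               var2 = c(2, 4, 6, 8, 10))
    fv <- featureVertices(mkDataset(X, rep("A", 5)))
    net <- buildNetwork(fv, "A", 0.7)
    e <- networkEdges(net)
    # zero-variance vertex contributes no edge but stays a vertex
    expect_false(any(e$from == "const" | e$to == "const"))
    expect_true("const" %in% vertexNames(net))
    expect_equal(e$pcc[e$from == "var1" & e$to == "var2"], 1.0)

    expect_error(buildNetwork(fv, "A", 1.0 + 1e-9), "tau")
    expect_error(buildNetwork(fv, "A", 0), "tau")
    expect_error(buildNetwork(fv, "B", 0.7), "not present")
    tiny <- featureVertices(suppressWarnings(
        mkDataset(X[1:2, ], rep("A", 2))))
    expect_error(buildNetwork(tiny, "A", 0.7), "at least 3")
})

test_that("the boundary |PCC| == tau yields an edge", {
    X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
    fv <- featureVertices(mkDataset(X, rep("A", 4)))
    net <- buildNetwork(fv, "A", tau = 1.0)   # pcc exactly 1 == tau
    expect_equal(nrow(networkEdges(net)), 1L)
    expect_equal(networkEdges(net)$sign, 1L)
})
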