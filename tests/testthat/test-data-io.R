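test_that("delimited files parse into labeled datasets", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("label\tg1\tg2\tg3",
                 "A\t1.0\t2.0\t3.0",
                 "A\t1.5\t2.5\t3.5",
                 "B\t4.0\t5.0\t6.0",
                 "B\t4.5\t5.5\t6.5"), path)
    expect_warning(ds <- readOmicsDataset(path, "label"),
                   "fewer than 3 samples")
    expect_s4_class(ds, "OmicsDataset")
    expect_equal(nrow(ds), 3L)            # features
    expect_equal(ncol(ds), 4L)            # samples
    expect_setequal(unique(sampleLabels(ds)), c("A", "B"))
    expect_equal(unname(assay(ds)["g2", 3L]), 5.0)
})

test_that("duplicate feature columns are rejected", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("label\tg1\tg1", "A\t1\t2", "B\t3\t4"), path)
    expect_error(readOmicsDataset(path, "label"), "duplicate feature names")
})

test_that("a time-series label outside the declared order is rejected", {
    path <- withr::local_tempfile(fileext = ".tsv")
    lines <- c("label\tg1\tg2",
               sprintf("S%d\t%g\t%g", c(1:6, 9), 1:7, 2:8))
    writeLines(lines, path)
    expect_error(
        readOmicsDataset(path, "label", mode = "time-series",
                         labelOrder = sprintf("S%d", 1:6)),
        "S9")
    expect_error(
        OmicsDataset(matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))),
                     c("S1", "S2"), mode = "time-series"),
        "labelOrder")
})

test_that("missing label column is an input error", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("g1\tg2", "1\t2"), path)
    expect_error(readOmicsDataset(path, "label"), "label column")
})

test_that("datasets survive a write/read round trip", {
    set.seed(11)
    v <- round(matrix(rexp(60) + 0.1, 10, 6), 4)
    colnames(v) <- sprintf("feat%d", 1:6)
    # the delimited format carries no sample-id column; use canonical ids
    rownames(v) <- sprintf("sample_%d", 1:10)
    ds <- mkDataset(v, rep(c("A", "B"), each = 5))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeOmicsDataset(ds, path)
    ds2 <- readOmicsDataset(path, "label")
    expect_equal(assay(ds2), assay(ds))
    expect_equal(sampleLabels(ds2), sampleLabels(ds))
})

test_that("group-minimum imputation follows the within-group rule", {
    v <- rbind(c(NA, 2.0, 5.0, 1.0, 3.0, 2.0))   # one feature
    ds <- mkDataset(t(v), rep(c("A", "B"), each = 3))
    imp <- imputeMissing(ds)
    expect_equal(unname(assay(imp)[1L, ]), c(2, 2, 5, 1, 3, 2))

    # all-missing group falls back to the global minimum positive value
    v2 <- cbind(f1 = c(NA, NA, 4.0, 1.0, 3.0, 2.0))
    ds2 <- mkDataset(v2, rep(c("A", "B"), each = 3))
    imp2 <- imputeMissing(ds2)
    expect_equal(unname(assay(imp2)["f1", 1:3]), c(4, 4, 4))

    # fully dead feature is an error naming the feature
    v3 <- cbind(f1 = c(1, 2, 3), dead = c(0, 0, NA))
    expect_error(imputeMissing(mkDataset(v3, rep("A", 3))), "dead")
})

test_that("imputation is idempotent and never touches positive values", {
    set.seed(7)
    v <- matrix(rexp(80) + 0.05, 16, 5,
                dimnames = list(sprintf("s%d", 1:16), sprintf("f%d", 1:5)))
    labs <- rep(c("A", "B"), each = 8)
    ds <- addMissingness(mkDataset(v, labs), rate = 0.2, seed = 42)
    was <- assay(ds)
    imp <- imputeMissing(ds)
    expect_true(all(assay(imp) > 0))
    keepMask <- !is.na(was) & was > 0
    expect_equal(assay(imp)[keepMask], was[keepMask])
    expect_equal(assay(imputeMissing(imp)), assay(imp))
    # untouched dataset comes back unchanged
    clean <- mkDataset(v, labs)
    expect_identical(assay(imputeMissing(clean)), assay(clean))
})

test_that("non-positive entries are treated as missing", {
    v <- cbind(f1 = c(0, -2, 4, 5, 6, 7))
    ds <- mkDataset(v, rep(c("A", "B"), each = 3))
    expect_equal(unname(assay(imputeMissing(ds))["f1", 1:2]), c(4, 4))
})

test_that("edge lists round-trip including isolated vertices and metadata", {
    net <- mkNet("EWS", list(c("a/b", "c/d", 1), c("a/b", "e/f", -1)),
                 vertices = c("a/b", "c/d", "e/f", "g/h"))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(net, path)
    back <- readEdgeList(path)
    expect_equal(networkLabel(back), "EWS")
    expect_equal(networkTau(back), networkTau(net))
    expect_equal(vertexNames(back), vertexNames(net))
    expect_equal(networkEdges(back), networkEdges(net))

    # empty network: header-only file, identical round trip
    e0 <- mkNet("BL", list(), vertices = c("x", "y"))
    writeEdgeList(e0, path)
    back0 <- readEdgeList(path)
    expect_equal(nrow(networkEdges(back0)), 0L)
    expect_equal(vertexNames(back0), c("x", "y"))
})

test_that("GraphML export carries signs as colors", {
    net <- mkNet("G1", list(c("a", "b", 1), c("b", "c", -1)),
                 vertices = letters[1:4])
    path <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(net, path)
    g <- igraph::read_graph(path, format = "graphml")
    expect_equal(igraph::vcount(g), 4)
    expect_setequal(igraph::E(g)$color, c("red", "green"))
})
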