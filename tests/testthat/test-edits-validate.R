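test_that("vertex removal strips incident arms, as in irregular array edits", {
    g <- makeTessellation("triangular", 4, 4, 32)
    deg <- vertexDegrees(g)
    vid <- as.integer(names(deg)[deg == 6][1])
    nbr <- orderArms(g, vid)
    g2 <- applyEdits(g, list(list(op = "remove_vertex", id = vid)))
    expect_identical(nVertices(g2), nVertices(g) - 1L)
    expect_identical(nEdges(g2), nEdges(g) - 6L)
    d2 <- vertexDegrees(g2)
    for (nb in nbr)
        expect_identical(d2[[as.character(nb)]], deg[[as.character(nb)]] - 1L)
})

test_that("edge edits resize and rewire; the empty edit list is the identity", {
    g <- makeTessellation("square", 2, 2, 32)
    expect_identical(applyEdits(g, list()), g)
    e1 <- graphEdges(g)$id[1]
    g2 <- applyEdits(g, list(list(op = "set_edge_length", id = e1,
                                  length_bp = 54L)))
    expect_identical(graphEdges(g2)$length_bp[1], 54L)
    expect_identical(nFaces(g2), nFaces(g))     # faces survive length edits
    g3 <- applyEdits(g, list(list(op = "remove_edge", id = e1)))
    expect_identical(nEdges(g3), nEdges(g) - 1L)
    expect_lt(nFaces(g3), nFaces(g))
    expect_error(applyEdits(g, list(list(op = "remove_vertex", id = 999L))),
                 "missing vertex")
    expect_error(applyEdits(g, list(list(op = "warp"))), "unknown edit")
})

test_that("edits cannot push a vertex past the seven-arm cap", {
    # a star with 7 arms is fine; the 8th is rejected
    v <- data.frame(id = 1:9, x = c(0, cos(2 * pi * (1:8) / 8)),
                    y = c(0, sin(2 * pi * (1:8) / 8)), z = 0)
    e <- data.frame(v1 = 1, v2 = 2:8, length_bp = 32)
    g <- wireframeGraph(v, e)
    expect_identical(max(vertexDegrees(g)), 7L)
    expect_error(
        applyEdits(g, list(list(op = "add_edge", v1 = 1, v2 = 9,
                                length_bp = 32))),
        "8 arms")
})

test_that("the validator reports arm caps, short edges, and turn warnings", {
    v <- data.frame(id = 1:10, x = c(0, cos(2 * pi * (1:9) / 9)),
                    y = c(0, sin(2 * pi * (1:9) / 9)), z = 0)
    e <- data.frame(v1 = 1, v2 = 2:10, length_bp = 32)
    g8 <- wireframeGraph(v, e)    # degree 9 hub
    rep <- validateGraph(g8)
    expect_true(any(rep$severity == "error" & rep$code == "too_many_arms"))
    expect_identical(nrow(validateGraph(g8, maxArms = 9L)), 0L)

    g31 <- singleEdgeGraph(31L)
    rep31 <- validateGraph(g31, requireFullTurns = TRUE)
    expect_true(any(rep31$code == "not_full_turn" &
                    rep31$severity == "warning"))
    expect_identical(nrow(validateGraph(g31)), 0L)

    gshort <- singleEdgeGraph(10L)
    expect_true(any(validateGraph(gshort)$code == "edge_too_short"))

    expect_identical(nrow(validateGraph(makePolyhedron("icosahedron", 32))), 0L)
    empty <- new("WireframeGraph",
                 vertices = data.frame(id = integer(), x = numeric(),
                                       y = numeric(), z = numeric()),
                 edges = data.frame(id = integer(), v1 = integer(),
                                    v2 = integer(), length_bp = integer(),
                                    role = character()),
                 faces = list(), metadata = list(shape = "empty"))
    expect_true(any(validateGraph(empty)$code == "empty_graph"))

    # disconnected graphs are flagged
    v2 <- data.frame(id = 1:4, x = c(0, 11, 100, 111) * 0.34, y = 0, z = 0)
    e2 <- data.frame(v1 = c(1, 3), v2 = c(2, 4), length_bp = 32)
    gd <- wireframeGraph(v2, e2)
    expect_true(any(validateGraph(gd)$code == "disconnected"))
})

test_that("graph union stitches blocks for chimeric patterns", {
    a <- makeTessellation("square", 2, 1, 32)
    b <- makeTessellation("square", 2, 1, 32)
    # shift the second block so its left column coincides with a's right
    vb <- graphVertices(b)
    vb$x <- vb$x + 1 * 32 * 0.34
    b@vertices <- vb
    m <- mergeGraphs(a, b)
    # 3 shared vertices merge away; duplicate edges collapse
    expect_identical(nVertices(m), nVertices(a) + nVertices(b) - 3L)
    expect_identical(nrow(validateGraph(m)), 0L)
})
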