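test_that("edge lengths quantize to whole helical turns with half-to-even ties", {
    expect_identical(quantizeFullTurns(31.5), 32L)   # 3 turns print as 32 bp
    expect_identical(quantizeFullTurns(42), 42L)     # exact 4 turns
    expect_identical(quantizeFullTurns(52.5), 52L)   # 5 turns print as 52 bp
    expect_error(quantizeFullTurns(-3), "helical turn")
    expect_error(quantizeFullTurns(4), "helical turn")
    # quantization moves a length by at most half a turn plus the
    # half-bp print rounding
    x <- seq(5.25, 200, by = 0.25)
    q <- quantizeFullTurns(x)
    expect_true(all(abs(q - x) <= 5.75))
    expect_identical(q, quantizeFullTurns(x))     # deterministic
    # outputs are fixed points of the quantizer
    expect_identical(quantizeFullTurns(as.numeric(q)), q)
})

test_that("tessellation patches have the pattern's coordination number", {
    coord <- c(hexagonal = 3L, square = 4L, triangular = 6L,
               trihexagonal = 4L, snub_trihexagonal = 5L)
    for (pat in names(coord)) {
        g <- makeTessellation(pat, 3, 3, 32)
        deg <- vertexDegrees(g)
        expect_identical(max(deg), coord[[pat]])       # attained in interior
        expect_true(all(graphEdges(g)$length_bp == 32L))
        # interior faces of a connected planar patch: V - E + F = 1
        expect_identical(nVertices(g) - nEdges(g) + nFaces(g), 1L)
        expect_identical(nrow(validateGraph(g)), 0L)
    }
    expect_error(makeTessellation("penrose", 2, 2, 32), "unknown")
})

test_that("the unit square cell is 4 vertices, 4 edges, 1 face", {
    g <- makeTessellation("square", 1, 1, 32)
    expect_identical(c(nVertices(g), nEdges(g), nFaces(g)), c(4L, 4L, 1L))
    # geometric edge length is 32 bp x 0.34 nm
    v <- graphVertices(g); e <- graphEdges(g)
    d <- sqrt((v$x[e$v1] - v$x[e$v2])^2 + (v$y[e$v1] - v$y[e$v2])^2)
    expect_equal(d, rep(32 * 0.34, 4), tolerance = 1e-9)
})

test_that("polyhedra have the textbook counts and satisfy Euler's formula", {
    specs <- list(
        tetrahedron   = c(4, 6, 4, 3),
        cube          = c(8, 12, 6, 3),
        octahedron    = c(6, 12, 8, 4),
        cuboctahedron = c(12, 24, 14, 4),
        icosahedron   = c(12, 30, 20, 5),
        buckyball     = c(60, 90, 32, 3))
    for (nm in names(specs)) {
        g <- makePolyhedron(nm, 32)
        expect_identical(c(nVertices(g), nEdges(g), nFaces(g)),
                         as.integer(specs[[nm]][1:3]), label = nm)
        expect_identical(unique(unname(vertexDegrees(g))),
                         as.integer(specs[[nm]][4]), label = nm)
        expect_identical(nVertices(g) - nEdges(g) + nFaces(g), 2L)
        expect_identical(nrow(validateGraph(g)), 0L)
    }
    b <- makePolyhedron("buckyball", 32)
    expect_identical(as.integer(table(lengths(graphFaces(b)))),
                     c(12L, 20L))   # 12 pentagons, 20 hexagons
    expect_error(makePolyhedron("dodecahedron", 32), "unknown")
})

test_that("triangulation adds one centroid per non-triangular face", {
    for (nm in c("tetrahedron", "cube", "octahedron", "cuboctahedron",
                 "icosahedron", "buckyball")) {
        g <- makePolyhedron(nm, 32)
        t <- triangulateFaces(g)
        sizes <- lengths(graphFaces(g))
        nontri <- sum(sizes > 3)
        expect_identical(nVertices(t), nVertices(g) + nontri, label = nm)
        expect_identical(nEdges(t), nEdges(g) + as.integer(sum(sizes[sizes > 3])),
                         label = nm)
        expect_true(all(lengths(graphFaces(t)) == 3L), label = nm)
        expect_identical(nVertices(t) - nEdges(t) + nFaces(t), 2L)
    }
})

test_that("triangulated buckyball and cube match the published geometry", {
    t <- triangulateFaces(makePolyhedron("buckyball", 32))
    expect_identical(c(nVertices(t), nFaces(t), nEdges(t)), c(92L, 180L, 270L))
    tc <- triangulateFaces(makePolyhedron("cube", 32))
    expect_identical(c(nVertices(tc), nEdges(tc), nFaces(tc)), c(14L, 36L, 24L))
    expect_identical(max(vertexDegrees(tc)), 6L)
    # centroid-corner edges quantize the geometric distance: a square face
    # of side s has centroid-corner distance s/sqrt(2)
    expect_identical(sort(unique(graphEdges(tc)$length_bp)),
                     c(quantizeFullTurns(32 / sqrt(2)), 32L))
    # triangular faces pass through untouched
    tt <- makePolyhedron("tetrahedron", 32)
    expect_identical(triangulateFaces(tt), tt)
    g <- tt; g@faces <- list()
    expect_error(triangulateFaces(g), "faces")
})
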