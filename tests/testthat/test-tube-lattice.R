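test_that("straight tubes are uniform 6-arm triangulated meshes", {
    g <- makeTube(8, 6, 32)
    expect_true(all(graphEdges(g)$length_bp == 32L))
    deg <- vertexDegrees(g)
    expect_identical(max(deg), 6L)
    # all rings except the two end rings are interior
    expect_identical(sum(deg == 6L), 8L * 4L)
    expect_identical(nrow(validateGraph(g)), 0L)
})

test_that("bent tubes shorten concave and lengthen convex rows per the arc model", {
    n <- 8L; m <- 16L; bp <- 32L
    g <- makeTube(n, m, bp, mode = "bent", bendAngleDeg = 180, struts = 8)
    e <- graphEdges(g)
    expect_identical(sum(e$role == "strut"), 8L)
    lon <- e$length_bp[e$role == "frame" & e$length_bp != bp]
    expect_true(min(lon) < bp && max(lon) > bp)
    # independent arc oracle: local radius ratio at the innermost and
    # outermost longitudinal lines
    h <- bp * 0.34
    rho <- n * bp * 0.34 / (2 * pi)
    Rc <- (m - 1) * h / pi
    expect_identical(min(lon), quantizeFullTurns(bp * (Rc - rho) / Rc))
    expect_identical(max(lon), quantizeFullTurns(bp * (Rc + rho) / Rc))
    # every assigned length is a whole number of turns
    expect_identical(e$length_bp, quantizeFullTurns(as.numeric(e$length_bp)))
    # a bend so sharp the concave side vanishes is rejected
    expect_error(makeTube(8, 4, 32, mode = "bent", bendAngleDeg = 180),
                 "bend requires")
    expect_error(makeTube(8, 6, 32, mode = "bent", bendAngleDeg = 270),
                 "bendAngleDeg")
})

test_that("donuts close the long axis into a torus", {
    g <- makeTube(6, 30, 32, mode = "donut")
    deg <- vertexDegrees(g)
    expect_true(all(deg == 6L))              # no boundary rings remain
    expect_identical(nVertices(g), 180L)
    expect_identical(nEdges(g), 540L)        # 3 edges per vertex on a torus
    expect_identical(nrow(validateGraph(g)), 0L)
})

test_that("rectangular 3D lattices obey the grid counting formula", {
    # brute-force neighbour-enumeration oracle
    gridCounts <- function(a, b, c) {
        pts <- expand.grid(i = seq_len(a), j = seq_len(b), k = seq_len(c))
        n <- 0L
        for (r in seq_len(nrow(pts))) {
            p <- pts[r, ]
            for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
                q <- p + d
                if (q$i <= a && q$j <= b && q$k <= c) n <- n + 1L
            }
        }
        c(nrow(pts), n)
    }
    for (dims in list(c(2, 2, 2), c(3, 2, 4), c(4, 4, 4))) {
        g <- makeLattice3D("grid", dims[1], dims[2], dims[3], 32)
        expect_identical(c(nVertices(g), nEdges(g)),
                         gridCounts(dims[1], dims[2], dims[3]),
                         label = paste(dims, collapse = "x"))
    }
    g <- makeLattice3D("grid", 8, 8, 4, 32)
    expect_identical(c(nVertices(g), nEdges(g)), c(256L, 640L))
    expect_error(makeLattice3D("fcc", 2, 2, 2, 32), "unknown")
})

test_that("diamond-cubic and cross lattices have 4-arm vertices in two classes", {
    g <- makeLattice3D("diamond_cubic", 7, 4, 4, 32)
    expect_identical(nVertices(g), 112L)
    deg <- vertexDegrees(g)
    expect_identical(max(deg), 4L)
    expect_identical(nrow(validateGraph(g)), 0L)
    # tetrahedral vertices: three in-layer arms + at most one inter-layer
    e <- graphEdges(g)
    v <- graphVertices(g)
    interlayer <- abs(v$z[match(e$v1, v$id)] - v$z[match(e$v2, v$id)]) > 1e-9
    perv <- table(factor(c(e$v1[interlayer], e$v2[interlayer]),
                         levels = v$id))
    expect_true(all(perv <= 1L))

    g2 <- makeLattice3D("cross", 7, 4, 4, 32)
    expect_identical(max(vertexDegrees(g2)), 4L)
    expect_identical(nrow(validateGraph(g2)), 0L)
    # inter-layer arms exist only in the alternating (odd) columns
    e2 <- graphEdges(g2)
    v2 <- graphVertices(g2)
    il <- abs(v2$z[match(e2$v1, v2$id)] - v2$z[match(e2$v2, v2$id)]) > 1e-9
    xcol <- round(v2$x[match(e2$v1[il], v2$id)] / (32 * 0.34))
    expect_true(all(xcol %% 2 == 1))
})
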