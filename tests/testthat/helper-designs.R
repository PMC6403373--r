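# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

scheme1110 <- function() segmentationScheme(11, 10)

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

# a single 32-bp edge between two 1-arm vertices: 4 strands
singleEdgeGraph <- function(bp = 32L) {
    wireframeGraph(
        data.frame(id = 1:2, x = c(0, bp * 0.34), y = 0, z = 0),
        data.frame(v1 = 1, v2 = 2, length_bp = bp),
        metadata = list(shape = "edge"))
}

singleEdgeStrands <- function(bp = 32L) {
    g <- singleEdgeGraph(bp)
    suppressWarnings(buildStrands(g, planEdges(g, scheme1110()),
                                  spacers = c(`1` = 0L, `2` = 0L)))
}

icosaStrands <- function() fixture("icosa", function() {
    g <- makePolyhedron("icosahedron", 32)
    buildStrands(g, planEdges(g, scheme1110()))
})

grid444Strands <- function() fixture("grid444", function() {
    g <- makeLattice3D("grid", 4, 4, 4, 32)
    buildStrands(g, planEdges(g, scheme1110()))
})

grid884Strands <- function() fixture("grid884", function() {
    g <- makeLattice3D("grid", 8, 8, 4, 32)
    buildStrands(g, planEdges(g, scheme1110()))
})

# strand sets of every built-in structure family, at modest sizes
builtinStrandSets <- function() fixture("builtins", function() {
    sch <- scheme1110()
    shapes <- list(
        tetrahedron = makePolyhedron("tetrahedron", 32),
        octahedron = makePolyhedron("octahedron", 42),
        icosahedron = makePolyhedron("icosahedron", 32),
        tri_cube = triangulateFaces(makePolyhedron("cube", 42)),
        square_tess = makeTessellation("square", 3, 3, 32),
        triangular_tess = makeTessellation("triangular", 3, 3, 32),
        hexagonal_tess = makeTessellation("hexagonal", 2, 2, 32),
        kagome_tess = makeTessellation("trihexagonal", 2, 2, 32),
        snub_tess = makeTessellation("snub_trihexagonal", 1, 1, 32),
        tube = makeTube(6, 4, 32),
        grid = makeLattice3D("grid", 3, 3, 2, 32),
        diamond = makeLattice3D("diamond_cubic", 4, 3, 2, 32),
        cross = makeLattice3D("cross", 4, 3, 2, 32))
    lapply(shapes, function(g)
        suppressWarnings(buildStrands(g, planEdges(g, sch, warn = FALSE))))
})

# independent conservation oracle: sum of strand lengths must equal
# twice the duplexed bases plus the unpaired spacer bases
expectedTotalNt <- function(graph, spacers) {
    deg <- vertexDegrees(graph)
    2 * sum(graphEdges(graph)$length_bp) +
        sum(pmax(deg - 1L, 0L) * spacers[names(deg)])
}
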