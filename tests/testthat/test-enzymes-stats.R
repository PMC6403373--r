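icosaSiteDesign <- function() fixture("icosa_sites", function() {
    d <- designWireframe(makePolyhedron("icosahedron", 32))
    e <- graphEdges(designGraph(d))
    plc <- data.frame(
        edge = e$id[1:13], offset = 14L,
        enzyme = c(rep(c("AclI", "BamHI", "BsiWI", "BstZ17I", "MfeI",
                         "MluI"), 2), "MluI"))
    d <- placeSites(d, plc)
    sequenceDesign(d, seqConstraints(
        seed = 5,
        fixedMotifs = designConstraints(d)@fixedMotifs,
        forbiddenMotifs = designConstraints(d)@forbiddenMotifs))
})

test_that("the bundled enzyme table is sane and round-trips", {
    tab <- enzymeTable()
    expect_true(all(c("AclI", "BamHI", "BsiWI", "BstZ17I", "MfeI", "MluI")
                    %in% tab$name))
    expect_true(all(nchar(tab$site) == 6L))
    # palindromic recognition sites
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(tab$site)))
    expect_identical(rc, tab$site)
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(list(schema = "wireframeDNA-enzyme-table-1",
                              enzymes = tab),
                         tmp, auto_unbox = TRUE, digits = NA)
    expect_identical(enzymeTable(tmp), tab)
})

test_that("site placement fixes motifs and forbids them elsewhere", {
    d <- icosaSiteDesign()
    cons <- designConstraints(d)
    expect_identical(nrow(cons@fixedMotifs), 13L)
    expect_identical(length(cons@forbiddenMotifs), 6L)
    # the generated design satisfies all constraints
    expect_identical(nrow(verifySequences(designStrands(d),
                                          strandSequences(d), cons)), 0L)
})

test_that("invalid placements are rejected", {
    d0 <- designWireframe(makePolyhedron("icosahedron", 32))
    # too close to the edge-end nick
    expect_error(placeSites(d0, data.frame(edge = 1L, offset = 2L,
                                           enzyme = "BamHI")), "nick")
    # overlapping the root/stem nick
    expect_error(placeSites(d0, data.frame(edge = 1L, offset = 9L,
                                           enzyme = "BamHI")), "nick")
    # overlapping placements on one edge
    expect_error(placeSites(d0, data.frame(edge = c(1L, 1L),
                                           offset = c(14L, 16L),
                                           enzyme = "BamHI")), "overlap")
    expect_error(placeSites(d0, data.frame(edge = 1L, offset = 14L,
                                           enzyme = "XhoI")), "not in the table")
    expect_identical(placeSites(d0, data.frame(edge = integer(),
                                               offset = integer(),
                                               enzyme = character())), d0)
})

test_that("digestion cuts exactly the designated edges", {
    d <- icosaSiteDesign()
    plc <- d@metadata$placements
    cocktailI <- c("BsiWI", "BstZ17I", "MfeI", "MluI")
    res <- digestDesign(d, cocktailI)
    expect_setequal(cutEdges(res), plc$edge[plc$enzyme %in% cocktailI])
    expect_identical(nEdges(res@cleavedGraph),
                     30L - length(unique(plc$edge[plc$enzyme %in% cocktailI])))
    # independent oracle: naive motif scan over every strand sequence
    tab <- enzymeTable()
    sq <- as.character(strandSequences(d))
    st <- strandTable(designStrands(d))
    hit_edges <- integer(0)
    for (enz in cocktailI) {
        site <- tab$site[tab$name == enz]
        hits <- vapply(sq, function(s) grepl(site, s, fixed = TRUE),
                       logical(1))
        hit_edges <- c(hit_edges, st$edge[st$role == "edge" & hits[st$name]])
    }
    expect_setequal(cutEdges(res), unique(hit_edges))
    # the full six-enzyme cocktail cleaves all 13 designated sites
    resIII <- digestDesign(d, unique(plc$enzyme))
    expect_identical(nrow(resIII@cuts), 13L)
    expect_setequal(cutEdges(resIII), plc$edge)
    # an empty cocktail is the identity on the graph
    res0 <- digestDesign(d, character())
    expect_identical(graphEdges(res0@cleavedGraph),
                     graphEdges(designGraph(d)))
    expect_error(digestDesign(d, "XbaI"), "not in the table")
})

test_that("digestion fragments have the lengths implied by the cut offsets", {
    d <- icosaSiteDesign()
    plc <- d@metadata$placements
    bam <- plc$edge[plc$enzyme == "BamHI"][1]
    res <- digestDesign(d, "BamHI")
    fr <- res@fragments
    en <- strandTable(designStrands(d))
    ename <- en$name[en$role == "edge" & !is.na(en$edge) & en$edge == bam]
    # BamHI = G^GATCC at offset 14: top cut after 14 nt of the 32-nt strand
    expect_identical(fr$length[fr$strand == ename], c(14L, 18L))
    # bottom-strand cut at offset 13 + 5 = coordinate 18: the 10-nt stem
    # strand (covering coordinates 11..21, running B->A) splits 3 + 7
    sname <- en$name[en$role == "stem" & !is.na(en$edge) & en$edge == bam]
    expect_identical(sort(fr$length[fr$strand == sname]), c(3L, 7L))
})

test_that("design statistics reproduce published scale figures", {
    dt <- designWireframe(makePolyhedron("tetrahedron", 32))
    st <- computeStats(dt)
    expect_identical(st@totalNt, 384L)       # 2 x 6 edges x 32 bp
    expect_identical(st@strandCount, 16L)
    # the smallest polyhedron sits at the ~120 kDa end of the range
    expect_lt(abs(st@molecularWeight - 120e3) / 120e3, 0.10)

    d8 <- fixture("grid884_doc", function()
        new("DesignDocument", graph = grid884Strands()@graph,
            plans = grid884Strands()@plans,
            spacers = grid884Strands()@spacers,
            strands = grid884Strands(), sequences = NULL,
            constraints = NULL, metadata = list(shape = "grid_8x8x4")))
    expect_identical(computeStats(d8)@strandCount, 1536L)

    oct <- designWireframe(makePolyhedron("octahedron", 32))
    so <- computeStats(oct)
    expect_identical(as.integer(so@degreeHistogram), 6L)
    expect_identical(names(so@degreeHistogram), "4")

    # per-nucleotide mass bounds and monotonicity in total nt
    for (s in list(st, so)) {
        ratio <- s@molecularWeight / s@totalNt
        expect_gt(ratio, 289); expect_lt(ratio, 330)
    }
    expect_gt(computeStats(d8)@molecularWeight, so@molecularWeight)

    # sequence-based MW agrees with the base-composition calculation
    dts <- sequenceDesign(dt, seqConstraints(seed = 2))
    sts <- computeStats(dts)
    expect_lt(abs(sts@molecularWeight - st@molecularWeight) /
              st@molecularWeight, 0.02)
})
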