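Package: wireframeDNA
Title: Design of Scaffold-Free Wireframe DNA Nanostructures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design pipeline for wireframe DNA nanostructures assembled
    entirely from short synthetic strands. Generates node-edge graphs for
    2D tessellations, tubes, polyhedra and multi-layer 3D lattices,
    segments duplex edges into complementary root/stem domains, lays out
    junction, edge and stem strands with a base-level pairing map, and
    populates strands with nucleotide sequences under sequence-symmetry
    (k-mer uniqueness), homopolymer-run and motif constraints. Supports
    restriction-site programming with in-silico digestion, design
    statistics, and export to a versioned design XML, FASTA/CSV synthesis
    sheets, JSON graphs and OBJ meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
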