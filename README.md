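# wireframeDNA

Design pipeline for **scaffold-free wireframe DNA nanostructures** —
objects whose shape is a node-edge mesh of DNA duplexes meeting at
multi-arm junctions, self-assembled entirely from short synthetic
strands (no scaffold, no routing). It is aimed at DNA nanotechnologists
who want to go from an abstract graph to an orderable strand list.

The pipeline is:

1. **Graph** — a `WireframeGraph` with vertices (junctions, ≤ 7 arms),
   duplex edges (lengths in bp, rounded to whole helical turns of
   10.5 bp) and faces. Built-in generators cover 2D tessellations
   (hexagonal, square, triangular, trihexagonal, snub trihexagonal),
   tubes (straight, donut, bent with reinforcement struts), polyhedra
   (tetrahedron … buckyball, with centroid triangulation) and
   multi-layer 3D lattices (rectangular grid, diamond-cubic,
   cross-like).
2. **Segmentation** — each edge splits into two root domains flanking a
   stem domain (default 11/10 for 32-bp edges); crowded vertices get
   unpaired T spacers (T2 at 5- and 6-arm vertices).
3. **Layout** — one junction strand per vertex, one edge strand and one
   stem strand per edge: `V + 2E` strands with a base-level
   Watson–Crick pairing involution.
4. **Sequences** — seeded random generation under the design rules:
   complementarity forced by the pairing map; no homopolymer run over
   3; no (k+1)-mer at two locations not related by designed
   complementarity (identical *or* reverse-complement; k = 8 by
   default); fixed and forbidden motifs for restriction-site
   programming. A brute-force verifier re-checks everything
   independently.
5. **Applications / I/O** — in-silico restriction digestion, design
   statistics (strand counts, molecular weight), a versioned design
   XML with the segment pairing map, FASTA/CSV synthesis sheets, JSON
   graphs, OBJ meshes, and a command-line front end
   (`inst/scripts/wireframe-cli.R`).

## Worked example

```r
library(wireframeDNA)

g <- makePolyhedron("icosahedron", 32)
g
#> WireframeGraph 'icosahedron': 12 vertices, 30 edges, 20 faces
#>   arm counts: 5-arm x12
#>   edge lengths (bp): 32

d <- designWireframe(g)                       # segment + lay out strands
d <- sequenceDesign(d, seqConstraints(seed = 1))
computeStats(d)
#> DesignStats: 72 strands, 2016 nt, MW 6.24e+05 Da (6.2e+02 kDa)
#>   arms: 5-arm x12
#>   edge lengths (bp): 32 x30

head(strandSequences(d), 3)
#> DNAStringSet object of length 3:
#>     width seq                                               names
#> [1]    63 AACACGACTGCTTTGTCCCTGGT...TGTGCTCGGCTTGGATACCGGCA icosahedron_J1
#> [2]    63 GTCTCAGATCTTTCCCTTAAATA...AGGAAGAGGTTTGGCATTAAATA icosahedron_J2
#> [3]    63 TATAATCCTAATTAAGATAACTC...CTATGCACATTTCGCTCAGGGAA icosahedron_J3

verifySequences(designStrands(d), strandSequences(d), designConstraints(d))
#> [1] type     strand   position detail      <0 rows> (no violations)
```

The 72 strands are the 12 junction strands (5 × 11-nt roots + 4 × T2
spacers = 63 nt each), 30 edge strands (32 nt) and 30 stem strands
(10 nt); 2016 nt total = 2 × 960 duplexed bases + 96 spacer bases.

Restriction sites can be programmed into chosen edges and cleaved in
silico — placement fixes the recognition motif there and forbids it
everywhere else, so each enzyme cocktail cuts exactly its designated
edges:

```r
plc <- data.frame(edge = c(1L, 7L, 15L), offset = 14L,
                  enzyme = c("BamHI", "MluI", "MfeI"))
d2 <- placeSites(designWireframe(g), plc)
d2 <- sequenceDesign(d2, seqConstraints(seed = 1,
          fixedMotifs = designConstraints(d2)@fixedMotifs,
          forbiddenMotifs = designConstraints(d2)@forbiddenMotifs))
digestDesign(d2, c("BamHI", "MluI"))
#> DigestResult: 2 cut(s) on 2 edge(s); cleaved graph has 28 edges
```

Export for synthesis or viewing:

```r
exportStrands(d, "icosahedron.fasta", "fasta")  # or "csv"
writeDesignXML(d, "icosahedron.xml")            # lossless, byte-stable
exportOBJ(designGraph(d), "icosahedron.obj")
```

The same pipeline from a shell:

```sh
Rscript inst/scripts/wireframe-cli.R generate --shape icosahedron \
    --edge-bp 32 --out ico.xml
Rscript inst/scripts/wireframe-cli.R seq --in ico.xml --seed 1 --out ico_seq.xml
Rscript inst/scripts/wireframe-cli.R stats --in ico_seq.xml
Rscript inst/scripts/wireframe-cli.R export --in ico_seq.xml \
    --format fasta --out ico.fasta
```

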