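---
title: "Designing scaffold-free wireframe DNA nanostructures"
author: "wireframeDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing scaffold-free wireframe DNA nanostructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wireframeDNA)
```

## The design problem

A wireframe DNA nanostructure renders a target shape as a node-edge
mesh: nodes are multi-arm junctions where several DNA duplexes meet, and
edges are simple duplexes of chosen lengths. In the scaffold-free
approach the whole object self-assembles from short synthetic strands —
there is no long scaffold to route, so structure size is limited only by
the number of distinct strands, and arbitrary graphs can be realized
directly. The price is that every strand must find its place by local
hybridization alone, which puts the burden on careful segmentation and
on sequence design that makes every intended duplex unique.

The pipeline in this package mirrors that workflow:

1. **Geometry** — build a `WireframeGraph` for the target: 2D
   tessellations (`makeTessellation`), tubes including donuts and bent
   tubes (`makeTube`), polyhedra with optional face triangulation
   (`makePolyhedron`, `triangulateFaces`), and multi-layer 3D lattices
   (`makeLattice3D`); or read a user graph from JSON.
2. **Segmentation** — partition each edge into two root domains flanking
   a stem domain (`planEdge`), and assign unpaired T spacers at crowded
   vertices (`assignSpacers`).
3. **Layout** — emit one junction strand per vertex and one edge plus
   one stem strand per edge, with a domain-level complementarity
   involution (`buildStrands`).
4. **Sequences** — populate the strands with nucleotides under
   uniqueness, run-length and motif constraints (`generateSequences`),
   and re-check the result with an independent scanner
   (`verifySequences`).
5. **Applications and I/O** — restriction-site programming and
   in-silico digestion (`placeSites`, `digestDesign`), design statistics
   (`computeStats`), and export (design XML, FASTA/CSV, JSON, OBJ).

## Geometric conventions and constraints

**Full-turn edge lengths.** B-form DNA completes a helical turn every
~10.5 bp. Keeping every edge at a whole number of turns keeps the
crossover geometry at both ends of an edge in register. The quantizer
first rounds the target to the nearest turn count and then rounds the
resulting bp value half-to-even, which is the convention that renders
3 turns as 32 bp and 5 turns as 52 bp. Note the two-stage rounding can
move a length by up to 5.75 bp (half a turn plus the final half-bp
rounding).

**Arm-count cap.** Junction strands thread one root domain per arm;
beyond seven arms the crossovers crowd the vertex beyond what a single
strand with short spacers can relieve, so `validateGraph` treats more
than seven arms as an error (the cap is a policy argument).

**Coordinates are advisory.** Vertex positions (nm, at 0.34 nm/bp) fix
the cyclic order of arms at each vertex and feed the OBJ export; they
never constrain topology. For planar designs the arm order is the
counter-clockwise angular order; in 3D arms are projected onto the plane
perpendicular to the vertex normal (the mean arm direction, or the
best-fit-plane normal when arms balance out). Ties break by neighbour
id, and the cycle starts at the lowest-id neighbour, which makes layout
fully deterministic.

**Bent tubes.** Bent tubes gain curvature from shorter concave and
longer convex edges. Exact per-row lengths for the published designs
are not available, so
the package uses an explicit arc model: rings sit on a circular arc of
the requested bend angle; each longitudinal edge is scaled by the ratio
of its local radius (centerline radius plus the radial component of its
position on the tube circumference) to the centerline radius, then
quantized to full turns. Reinforcement struts are simple duplex chords
across the lumen in the bend plane, in evenly spaced rings. A bend that
would drive a longitudinal edge below twice the minimal domain length is
rejected rather than silently clamped.

**Cross-like lattices.** The published description of the cross-like
array leaves the in-layer wiring ambiguous; the package implements the
unique consistent assignment in which even columns carry four in-layer
arms and odd columns carry the row edges plus both inter-layer arms, so
both vertex classes are 4-arm, in alternating columns.

## Segmentation

A typical edge becomes `[root, stem, root]` with equal roots; the
default scheme is 11-bp roots with a 10-bp stem (32-bp edges). Schemes
of 13/6 and 16/10 are equally valid and tested. Edges whose length is
not `2*root + stem` keep the scheme's roots and absorb the difference
into the stem — this keeps the vertex-side geometry identical across
variable-length edges, so irregular arrays change nothing at the
junctions. Domains shorter than 6 bp are errors and domains shorter
than 10 bp draw a warning, reflecting the stability floor for paired
domains.

Edges whose single-piece edge strand would exceed 80 nt (the preferred
synthesis cap; the hard cap is 100 nt) are split: the interior becomes
alternating stems and 20-bp internal roots, the edge strand is nicked at
the midpoint of each internal root, and the complementary side gains one
short strand per interior domain. No structure in the shipped generators
needs this (the longest published edges, 70 bp, fit under the cap), but
user graphs may.

**Spacers.** Crowded vertices need slack between consecutive root
domains of the junction strand. The default policy inserts no spacer up
to 4 arms, 2 T at 5 and 6 arms (the T2 linkers used for the published
arrays) and 3 T at 7 arms — the 7-arm value is an extrapolation and the
policy is a plain lookup table the user can override. A junction strand
passing through k arms has k−1 internal transitions, so a vertex
receives (k−1) × spacer unpaired bases.

## Strand layout

The standard architecture places, for every edge, one **edge strand**
spanning the full duplex on one side; the opposite side is covered by
the A-vertex root (on A's junction strand), the **stem strand**, and the
B-vertex root (on B's junction strand). Every vertex contributes one
**junction strand** concatenating its root complements in cyclic arm
order with policy spacers between them. This gives exactly V + 2E
strands, which uniquely reproduces the published 1536-strand count for
the 8×8×4 array (256 vertices, 640 edges). All pairing is antiparallel:
base j of a domain pairs with base length−1−j of its partner, and the
domain-level partner map is a symmetric involution with spacers
unpaired.

The junction-strand crossover geometry at the vertex is not observable
at the level of the pairing topology; any consistent direction
convention yields the same constraint system for sequence design, and
the package fixes one (all junction/stem domains run antiparallel to
their edge strand, 5' start at the lowest-id arm) for reproducibility.

A known discrepancy: the reported strand count for the largest
published wireframe polyhedron — 540 for a triangulated buckyball —
does not match V + 2E = 92 + 540 = 632 under this architecture, while
the same architecture does reproduce the reported 1536 strands of the
8×8×4 array. The package implements the architecture uniformly and
records the polyhedron figure as unexplained (plausibly a different
strand accounting in the original design) rather than special-casing
it.

## Sequence generation

Four rules govern sequences: (1) free bases are drawn uniformly at
random one by one; (2) partnered bases are forced to the Watson–Crick
complement of their partner; (3) no "repeating segment" longer than k
nucleotides — implemented as: no (k+1)-mer may occur at two locations
that are not a designed pair, counting both identical and
reverse-complement occurrences (an unintended identical window permits
strand–strand identity; an unintended reverse-complement window permits
spurious hybridization; designed pairs are reverse complements by
construction and are exempt, as are palindromic windows inside designed
duplexes); (4) no four identical consecutive bases. k may be 7 or 8;
the default is 8 because the capacity check below classifies k = 7 as
saturated for the largest shipped design. Spacer Ts participate in the
run-length and window scans by default (slightly stricter than adding
spacers after sequence assignment, which a `spacerStrict = FALSE` mode
reproduces).

**Search strategy.** The generator scans strands in id order, 5'→3'.
Placing a free base immediately places its partner (mirror placement),
and every constraint that the placement *completes* is checked at that
moment: the maximal homopolymer run through either position, forbidden
motifs covering either position, and every (k+1)-window, on any strand,
whose last unset base was just filled. Checking windows at completion
time rather than at scan time is what makes violations local to the
current decision. On a violation the current base is redrawn without
replacement; an exhausted position triggers chronological backtracking
over the most recent free placements (default window 16). Two bounded
escapes handle the residual non-local cases — a window that is mostly
forced by a junction root drawn long ago can make a stem locally
unsatisfiable — first a conflict-directed backjump to the most recent
free variable of the violated constraint (undoing and then replaying the
intermediate placements verbatim), then a re-randomization of the
conflict variables, and finally a full restart with a fresh random
stream, up to `maxRestarts`. If the budget is exhausted the error names
the binding constraint. All randomness flows from one seed through R's
Mersenne-Twister in a locally scoped RNG, so identical inputs give
byte-identical sequences on every platform.

**Capacity.** A design consuming w windows of length k+1 draws from a
pool of 4^(k+1) words, halved because every used window also excludes
its reverse complement. Random sequential search degrades well before
the pool is full; the feasibility check reports the occupancy ratio and
classifies designs at or above 0.9 as infeasible (the 8×8×4 array at
k = 7 sits at ~0.97) and warns above 0.5. These thresholds describe
when the randomized search stops converging, not an information-theoretic
bound.

**Verification.** `verifySequences` re-derives every property with
logic disjoint from the generator: complementarity via
`Biostrings::reverseComplement` on extracted domain sequences, runs via
run-length encoding, the repeat rule by brute-force enumeration of all
windows grouped by canonical form, motifs by exact string search. Only
the layout's base-level pairing map — the design contract itself — is
shared input.

## Restriction programming and digestion

Placing an enzyme site on an edge fixes its recognition sequence at the
given offset of the edge strand (the complementary bases follow through
the pairing map) and adds the motif of every used enzyme to the
forbidden list outside the placements, so any cocktail of placed enzymes
cuts exactly its designated edges. Sites must sit at least 2 bp
(configurable) from every nick — edge ends, root/stem boundaries and
split-edge nicks — because the enzymes require intact duplex; on a
standard 32-bp edge under the 11/10 scheme this leaves exactly the
central six positions, i.e. a centred 6-cutter site. Digestion scans
each edge duplex for sites on either strand, removes every cut edge from
the cleaved graph (both strands are severed), and reports fragment
lengths per strand from the top- and bottom-strand cut offsets.

Molecular weight uses average per-residue masses (A 313.21, C 289.18,
G 329.21, T 304.20 Da) plus 18.02 Da per strand, the 5'-OH/3'-OH
convention appropriate for unphosphorylated synthetic oligos; without
sequences the mean residue mass is used.

## What the built-in generators do and do not emulate

The generators reproduce the *combinatorial* content of the published
designs — vertex configurations, edge counts, segmentation arithmetic,
strand counts — and an idealized geometry (regular tessellations, exact
polyhedral coordinates, circular-arc tubes). They do not model
mechanical flexibility, electrostatics, or assembly thermodynamics; a
passing test suite therefore certifies the design artifacts (graphs,
strand sets, sequences, digestion predictions), not assembly yield or
structural rigidity of the physical object. Where the original work
measured those properties the information lives in gels and microscopy,
outside this package's scope.

## Numerical and testing choices

Problem sizes in the test suite are chosen so the whole suite runs in a
few minutes on one CPU: property suites loop over a panel of thirteen
small structures from every family; sequence-level checks use the
icosahedron (2016 nt) and the 4×4×4 array (~9.8k nt); the full 8×8×4
array (~42.6k nt) is generated and verified once in a test marked
"slow" in its name. Geometry is exact integer arithmetic except vertex
coordinates, which are compared at 1e-8 tolerances after XML round
trips (coordinates serialize at 9 significant digits). Face extraction
uses rotation-system tracing (counter-clockwise neighbour order; the
outer face of a planar patch is dropped by signed area), which is
deterministic for the non-degenerate embeddings the generators produce.

## Known limitations

- Tube faces are not populated (the mesh is already triangulated); OBJ
  export of tubes shows edges only.
- The arc model for bent tubes and the strut anchoring are documented
  substitutes for unpublished geometry; both are parameterized.
- Exact per-structure spacer choices of the published designs are not
  public; the shipped policy encodes the general T2-linker guidance and
  is fully overridable.
- Sequence generation is randomized search with bounded repair; for
  adversarial user designs near the capacity limit it reports failure
  rather than guaranteeing a solution exists or finding one.
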