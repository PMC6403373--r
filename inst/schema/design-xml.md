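# wireframeDNA design XML, schema version 1.0

Root element `<wireframeDesign version="1.0" tool="wireframeDNA">`.
All element ordering is deterministic (ascending ids), so a design
serializes byte-identically across runs.

## `<metadata>`
Attributes: `shape`, `version` (tool version), `seed` (when sequences
were generated). One `<scheme>` child with `root_bp`, `stem_bp`,
`min_domain_bp`, `preferred_min_bp`.

## `<graph>`
- `<vertex id x y z>` — coordinates in nm (`%.9g`).
- `<edge id v1 v2 length_bp role>` — `role` is `frame` or `strut`;
  `v1 < v2`.
- `<face vertices="a b c ...">` — ordered vertex-id cycle.

## `<plans>`
`<plan edge domains>` — `domains` is the space-separated ordered domain
lengths of that edge (`root stem ... root`); they sum to the edge's
`length_bp`.

## `<spacers>`
`<spacer vertex nt>` — unpaired T bases inserted between consecutive
root domains of that vertex's junction strand.

## `<strands>`
`<strand id name role length [vertex] [edge] [sequence]>` with one
`<domain>` child per domain in 5'→3' order:
`<domain id index length role [partner] [edge] [start]>`.
`partner` is the domain-level pairing map (a symmetric involution;
spacers have none). `start` is the 0-based duplex coordinate of the
domain's low end, counted from the lower-id vertex of `edge`. Base-level
pairing is antiparallel: base j of a domain pairs with base
`length - 1 - j` of its partner.

## `<modifications>` (optional)
`<modification strand position label>` — 1-based nt position.

## `<constraints>` (optional)
Attributes `k`, `max_run`, `seed`, `max_restarts`, `backtrack_window`,
`spacer_strict`. Children: `<fixedMotif strand position motif>` and
`<forbiddenMotif motif>` — the sequence-exclusion rules used for
generation (restriction-site programming writes both).
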