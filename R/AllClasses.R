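#' @import methods
NULL

#' WireframeGraph: node-edge representation of a wireframe DNA design
#'
#' A wireframe structure is modelled as a graph whose vertices are multi-arm
#' DNA junctions (with advisory 3D coordinates in nm) and whose edges are
#' DNA duplexes of an integer number of base pairs. Faces, when present,
#' are ordered vertex cycles used for triangulation and OBJ export.
#'
#' @slot vertices data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (nm).
#' @slot edges data.frame with columns \code{id}, \code{v1}, \code{v2},
#'   \code{length_bp}, \code{role} (\code{"frame"} or \code{"strut"}).
#' @slot faces list of integer vectors (vertex id cycles, length >= 3).
#' @slot metadata list; at least \code{shape} (character scalar).
#'
#' @export
setClass("WireframeGraph",
    representation(vertices = "data.frame", edges = "data.frame",
                   faces = "list", metadata = "list"))

setValidity("WireframeGraph", function(object) {
    v <- object@vertices; e <- object@edges
    msgs <- character()
    need_v <- c("id", "x", "y", "z")
    need_e <- c("id", "v1", "v2", "length_bp", "role")
    if (!all(need_v %in% names(v)))
        return(paste("vertices must have columns", paste(need_v, collapse = ", ")))
    if (!all(need_e %in% names(e)))
        return(paste("edges must have columns", paste(need_e, collapse = ", ")))
    if (anyDuplicated(v$id)) msgs <- c(msgs, "duplicate vertex ids")
    if (nrow(e)) {
        if (anyDuplicated(e$id)) msgs <- c(msgs, "duplicate edge ids")
        if (!all(e$v1 %in% v$id) || !all(e$v2 %in% v$id))
            msgs <- c(msgs, "edge endpoint references a missing vertex id")
        if (any(e$v1 == e$v2)) msgs <- c(msgs, "self-loop edge (endpoints must differ)")
        key <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
        if (anyDuplicated(key)) msgs <- c(msgs, "more than one edge between a vertex pair")
        if (any(e$length_bp < 1) || any(e$length_bp != round(e$length_bp)))
            msgs <- c(msgs, "edge length_bp must be a positive integer")
        if (!all(e$role %in% c("frame", "strut")))
            msgs <- c(msgs, "edge role must be 'frame' or 'strut'")
    }
    if (nrow(v) && !all(is.finite(as.matrix(v[, c("x", "y", "z")]))))
        msgs <- c(msgs, "vertex positions must be finite")
    if (length(object@faces)) {
        ekey <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
        for (f in object@faces) {
            if (length(f) < 3) { msgs <- c(msgs, "face with fewer than 3 vertices"); break }
            if (!all(f %in% v$id)) { msgs <- c(msgs, "face references a missing vertex id"); break }
            nxt <- c(f[-1], f[1])
            if (!all(paste(pmin(f, nxt), pmax(f, nxt)) %in% ekey)) {
                msgs <- c(msgs, "consecutive face vertices are not joined by an edge"); break
            }
        }
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SegmentationScheme: root/stem domain lengths for edge segmentation
#'
#' A typical edge is segmented into two root domains of the same length
#' flanking a central stem domain. Paired domains must be at least
#' \code{minDomainBp} (default 6 bp) and preferably at least
#' \code{preferredMinBp} (default 10 bp).
#'
#' @slot rootBp integer, root domain length in bp.
#' @slot stemBp integer, nominal stem domain length in bp.
#' @slot minDomainBp integer, hard lower bound on any paired domain.
#' @slot preferredMinBp integer, soft lower bound (warning below).
#'
#' @export
setClass("SegmentationScheme",
    representation(rootBp = "integer", stemBp = "integer",
                   minDomainBp = "integer", preferredMinBp = "integer"))

setValidity("SegmentationScheme", function(object) {
    if (object@rootBp < object@minDomainBp) return("rootBp below minDomainBp")
    if (object@stemBp < object@minDomainBp) return("stemBp below minDomainBp")
    if (object@minDomainBp < 1) return("minDomainBp must be positive")
    TRUE
})

#' EdgePlanSet: per-edge domain partitions
#'
#' @slot plans named list (names = edge ids) of integer vectors; each vector
#'   is the ordered domain lengths \code{[root, stem, ..., root]} of that edge.
#' @slot scheme the \linkS4class{SegmentationScheme} used.
#'
#' @export
setClass("EdgePlanSet",
    representation(plans = "list", scheme = "SegmentationScheme"))

#' SpacerPolicy: unpaired T linkers at junctions, by arm count
#'
#' Crowded vertices (5+ arms) receive unpaired thymidine spacers between
#' consecutive root domains of the junction strand to relieve electrostatic
#' strain. The default policy maps arm counts 1-4 to 0 nt, 5 and 6 to 2 nt
#' (T2 linkers) and 7 to 3 nt.
#'
#' @slot map named integer vector; names are arm counts "1".."7",
#'   values are spacer lengths in nt (0-3).
#'
#' @export
setClass("SpacerPolicy", representation(map = "integer"))

setValidity("SpacerPolicy", function(object) {
    if (!all(object@map %in% 0:3)) return("spacer lengths must be 0-3 nt")
    if (is.null(names(object@map))) return("map must be named by arm count")
    TRUE
})

#' StrandSet: the strand diagram of a design before sequences
#'
#' One junction strand per vertex, one edge strand and one stem strand per
#' edge (standard architecture; long edges may split into more pieces),
#' with a domain-level complementarity involution.
#'
#' @slot strands data.frame: \code{id}, \code{name}, \code{role}
#'   (junction/edge/stem), \code{vertex}, \code{edge} (NA where not
#'   applicable), \code{length} (nt).
#' @slot domains data.frame: \code{id}, \code{strand}, \code{index} (1-based
#'   within strand, 5'->3'), \code{length}, \code{role} (root, stem_span,
#'   edge_span, spacer), \code{partner} (domain id or NA), \code{edge}
#'   (edge id or NA), \code{start} (duplex coordinate of the domain's
#'   low end, 0-based from the lower-id vertex; NA for spacers).
#' @slot graph the source \linkS4class{WireframeGraph}.
#' @slot plans the \linkS4class{EdgePlanSet} used.
#' @slot spacers named integer vector, vertex id -> spacer nt.
#' @slot modifications data.frame: \code{strand}, \code{position} (1-based
#'   nt within strand), \code{label}.
#'
#' @export
setClass("StrandSet",
    representation(strands = "data.frame", domains = "data.frame",
                   graph = "WireframeGraph", plans = "EdgePlanSet",
                   spacers = "integer", modifications = "data.frame"))

setValidity("StrandSet", function(object) {
    d <- object@domains
    msgs <- character()
    p <- d$partner
    has <- !is.na(p)
    if (any(has)) {
        back <- d$partner[match(p[has], d$id)]
        if (any(is.na(back)) || any(back != d$id[has]))
            msgs <- c(msgs, "pairing map is not a symmetric involution")
        if (any(d$length[match(p[has], d$id)] != d$length[has]))
            msgs <- c(msgs, "partnered domains differ in length")
    }
    if (any(d$role == "spacer" & has))
        msgs <- c(msgs, "spacer domains must be unpaired")
    if (any(d$role != "spacer" & !has))
        msgs <- c(msgs, "non-spacer domain without a partner")
    len <- tapply(d$length, d$strand, sum)
    sl <- object@strands$length[match(as.integer(names(len)), object@strands$id)]
    if (any(len != sl)) msgs <- c(msgs, "strand length != sum of its domain lengths")
    if (anyDuplicated(object@strands$name)) msgs <- c(msgs, "strand names not unique")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SeqConstraints: parameters of constrained sequence generation
#'
#' @slot k integer, 7 or 8: no (k+1)-mer may occur at two locations not
#'   related by designed complementarity (identical or reverse-complement).
#' @slot maxRun integer, maximum homopolymer run (default 3: no four
#'   consecutive identical bases).
#' @slot fixedMotifs data.frame: \code{strand}, \code{position} (1-based),
#'   \code{motif} (ACGT string) - bases forced verbatim (partners forced by
#'   complementarity).
#' @slot forbiddenMotifs character vector of motifs excluded everywhere
#'   except at fixed placements of the identical motif.
#' @slot seed integer RNG seed.
#' @slot maxRestarts integer, restarts before giving up.
#' @slot backtrackWindow integer, how many free positions a backtrack
#'   episode may unwind.
#' @slot spacerStrict logical; if TRUE (default) spacer Ts participate in
#'   run-length and k-mer window scans.
#'
#' @export
setClass("SeqConstraints",
    representation(k = "integer", maxRun = "integer",
                   fixedMotifs = "data.frame", forbiddenMotifs = "character",
                   seed = "integer", maxRestarts = "integer",
                   backtrackWindow = "integer", spacerStrict = "logical"))

setValidity("SeqConstraints", function(object) {
    if (!object@k %in% c(7L, 8L)) return("k must be 7 or 8")
    if (object@k < object@maxRun) return("k must be >= maxRun")
    TRUE
})

#' DesignDocument: a complete wireframe design
#'
#' Bundles the graph, segmentation plans, spacer assignment, strand layout,
#' optional sequences and generation constraints; serializable to a
#' versioned design XML.
#'
#' @slot graph \linkS4class{WireframeGraph}.
#' @slot plans \linkS4class{EdgePlanSet}.
#' @slot spacers named integer vector (vertex id -> spacer nt).
#' @slot strands \linkS4class{StrandSet}.
#' @slot sequences \code{DNAStringSet} named by strand name, or NULL.
#' @slot constraints \linkS4class{SeqConstraints} or NULL.
#' @slot metadata list (tool version, seed, scheme, shape).
#'
#' @export
setClass("DesignDocument",
    representation(graph = "WireframeGraph", plans = "EdgePlanSet",
                   spacers = "integer", strands = "StrandSet",
                   sequences = "ANY", constraints = "ANY",
                   metadata = "list"))

#' DigestResult: outcome of an in-silico restriction digestion
#'
#' @slot cleavedGraph \linkS4class{WireframeGraph} with cut edges removed.
#' @slot cuts data.frame: \code{edge}, \code{enzyme}, \code{site_start}
#'   (1-based duplex coordinate of the recognition site on the edge).
#' @slot fragments data.frame: \code{strand} (name), \code{fragment}
#'   (index), \code{length} (nt).
#'
#' @export
setClass("DigestResult",
    representation(cleavedGraph = "WireframeGraph", cuts = "data.frame",
                   fragments = "data.frame"))

#' DesignStats: summary statistics of a design
#'
#' @slot strandCount integer.
#' @slot totalNt integer, total nucleotides over all strands.
#' @slot molecularWeight numeric, estimated MW in Da.
#' @slot degreeHistogram table of vertex arm counts.
#' @slot edgeLengthHistogram table of edge lengths (bp).
#'
#' @export
setClass("DesignStats",
    representation(strandCount = "integer", totalNt = "integer",
                   molecularWeight = "numeric", degreeHistogram = "table",
                   edgeLengthHistogram = "table"))
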