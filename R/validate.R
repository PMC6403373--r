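#' Validate a wireframe graph against design policy
#'
#' Returns a report rather than throwing. Errors: empty graph, vertex arm
#' count above \code{maxArms} (junction strands cannot host more than
#' seven arms), disconnected graph, edge shorter than
#' \code{2 * minDomainBp}. Warnings: edge lengths that are not whole
#' helical turns (only when \code{requireFullTurns}).
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param maxArms maximum arms per vertex (default 7).
#' @param requireFullTurns if TRUE, warn on edge lengths that are not
#'   rounded multiples of 10.5 bp.
#' @param minDomainBp minimal paired-domain length used for the edge-length
#'   floor (default 6, i.e. edges must be >= 12 bp).
#' @return data.frame with columns \code{severity} ("error"/"warning"),
#'   \code{code}, \code{item} (vertex/edge id) and \code{message};
#'   zero rows for a fully valid graph.
#' @examples
#' v <- validateGraph(makePolyhedron("icosahedron", 32))
#' nrow(v)   # 0
#' @export
validateGraph <- function(graph, maxArms = 7L, requireFullTurns = FALSE,
                          minDomainBp = 6L) {
    rep <- data.frame(severity = character(), code = character(),
                      item = character(), message = character())
    add <- function(rep, severity, code, item, message)
        rbind(rep, data.frame(severity = severity, code = code,
                              item = as.character(item), message = message))
    if (!nVertices(graph))
        return(add(rep, "error", "empty_graph", NA, "graph has no vertices"))
    deg <- vertexDegrees(graph)
    for (vid in names(deg)[deg > maxArms])
        rep <- add(rep, "error", "too_many_arms", vid,
                   sprintf("vertex %s has %d arms (cap %d)", vid,
                           deg[[vid]], maxArms))
    e <- graphEdges(graph)
    short <- e$id[e$length_bp < 2L * minDomainBp]
    for (eid in short)
        rep <- add(rep, "error", "edge_too_short", eid,
                   sprintf("edge %d is %d bp, below 2 x minDomainBp = %d",
                           eid, e$length_bp[match(eid, e$id)], 2L * minDomainBp))
    if (requireFullTurns && nrow(e)) {
        bad <- e$id[!.isFullTurn(e$length_bp)]
        for (eid in bad)
            rep <- add(rep, "warning", "not_full_turn", eid,
                       sprintf("edge %d length %d bp is not a whole number of helical turns",
                               eid, e$length_bp[match(eid, e$id)]))
    }
    if (nVertices(graph) > 1L) {
        if (nrow(e)) {
            ig <- igraph::graph_from_data_frame(
                e[, c("v1", "v2")], directed = FALSE,
                vertices = data.frame(name = graph@vertices$id))
            conn <- igraph::is_connected(ig)
        } else conn <- FALSE
        if (!conn)
            rep <- add(rep, "error", "disconnected", NA,
                       "graph is not connected")
    }
    rownames(rep) <- NULL
    rep
}
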