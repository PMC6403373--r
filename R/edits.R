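#' Apply a list of edits to a wireframe graph
#'
#' Edits are applied in order. Each edit is a list with an \code{op}
#' field:
#' \describe{
#'   \item{\code{remove_vertex}}{\code{id}: drop the vertex and all its
#'     incident edges (its neighbours each lose one arm).}
#'   \item{\code{add_edge}}{\code{v1}, \code{v2}, \code{length_bp},
#'     optional \code{role}.}
#'   \item{\code{remove_edge}}{\code{id} (edge id) or \code{v1}/\code{v2}.}
#'   \item{\code{set_edge_length}}{\code{id} (or \code{v1}/\code{v2}) and
#'     \code{length_bp}.}
#' }
#' Faces touching a removed vertex or edge are dropped; other structural
#' edits leave faces untouched and \code{set_edge_length} preserves them.
#' The edited graph is re-validated: a resulting vertex of more than
#' \code{maxArms} arms is an error, as is a dangling id reference.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param edits list of edit lists (empty list returns the graph
#'   unchanged).
#' @param maxArms arm-count cap re-validated after editing (default 7).
#' @return The edited \linkS4class{WireframeGraph}.
#' @export
applyEdits <- function(graph, edits, maxArms = 7L) {
    if (!length(edits)) return(graph)
    v <- graph@vertices; e <- graph@edges; faces <- graph@faces
    findEdge <- function(ed) {
        if (!is.null(ed$id)) {
            i <- match(ed$id, e$id)
            if (is.na(i)) .stopf("edit references missing edge id %s", ed$id)
            return(i)
        }
        if (is.null(ed$v1) || is.null(ed$v2))
            .stopf("edge edit needs 'id' or 'v1'/'v2'")
        i <- which(e$v1 == min(ed$v1, ed$v2) & e$v2 == max(ed$v1, ed$v2))
        if (!length(i)) .stopf("no edge between vertices %s and %s", ed$v1, ed$v2)
        i
    }
    for (ed in edits) {
        if (is.null(ed$op)) .stopf("edit without an 'op' field")
        switch(ed$op,
            remove_vertex = {
                if (is.na(match(ed$id, v$id)))
                    .stopf("edit references missing vertex id %s", ed$id)
                v <- v[v$id != ed$id, , drop = FALSE]
                e <- e[e$v1 != ed$id & e$v2 != ed$id, , drop = FALSE]
                faces <- Filter(function(f) !(ed$id %in% f), faces)
            },
            add_edge = {
                if (is.na(match(ed$v1, v$id)) || is.na(match(ed$v2, v$id)))
                    .stopf("add_edge references a missing vertex id")
                if (is.null(ed$length_bp) || ed$length_bp < 1)
                    .stopf("add_edge requires a positive length_bp")
                e <- rbind(e, data.frame(
                    id = if (nrow(e)) max(e$id) + 1L else 1L,
                    v1 = min(ed$v1, ed$v2), v2 = max(ed$v1, ed$v2),
                    length_bp = as.integer(ed$length_bp),
                    role = if (is.null(ed$role)) "frame" else ed$role))
            },
            remove_edge = {
                i <- findEdge(ed)
                a <- e$v1[i]; b <- e$v2[i]
                e <- e[-i, , drop = FALSE]
                faces <- Filter(function(f) {
                    nxt <- c(f[-1], f[1])
                    !any((f == a & nxt == b) | (f == b & nxt == a))
                }, faces)
            },
            set_edge_length = {
                i <- findEdge(ed)
                if (is.null(ed$length_bp) || ed$length_bp < 1)
                    .stopf("set_edge_length requires a positive length_bp")
                e$length_bp[i] <- as.integer(ed$length_bp)
            },
            .stopf("unknown edit op '%s'", ed$op))
    }
    md <- graph@metadata
    md$edited <- TRUE
    out <- new("WireframeGraph", vertices = v,
               edges = e[order(e$v1, e$v2), , drop = FALSE],
               faces = .canonicalizeFaces(faces), metadata = md)
    out@edges$id <- seq_len(nrow(out@edges))
    rownames(out@edges) <- NULL
    validObject(out)
    deg <- vertexDegrees(out)
    if (length(deg) && max(deg) > maxArms)
        .stopf("edit would create a vertex of %d arms (cap %d)",
               max(deg), maxArms)
    out
}

#' Merge two wireframe graphs into one
#'
#' Used to stitch individual blocks of regular patterns into chimeric
#' designs: vertices of \code{g2} closer than \code{tol} nm to a vertex
#' of \code{g1} are identified with it; remaining \code{g2} vertices are
#' renumbered above \code{g1}'s ids. Duplicate edges collapse to the
#' \code{g1} copy. Faces are recomputed only for planar inputs via
#' \code{\link{applyEdits}}-style invalidation (faces of both inputs are
#' kept when their vertices survive).
#'
#' @param g1,g2 \linkS4class{WireframeGraph} objects.
#' @param tol vertex-merge tolerance in nm.
#' @return A \linkS4class{WireframeGraph}.
#' @export
mergeGraphs <- function(g1, g2, tol = 1e-6) {
    v1 <- g1@vertices; v2 <- g2@vertices
    remap <- integer(nrow(v2)); names(remap) <- v2$id
    nextid <- if (nrow(v1)) max(v1$id) else 0L
    vout <- v1
    for (r in seq_len(nrow(v2))) {
        d2 <- (v1$x - v2$x[r])^2 + (v1$y - v2$y[r])^2 + (v1$z - v2$z[r])^2
        hit <- if (nrow(v1)) which(d2 <= tol^2) else integer()
        if (length(hit)) {
            remap[r] <- v1$id[hit[1]]
        } else {
            nextid <- nextid + 1L
            remap[r] <- nextid
            vout <- rbind(vout, data.frame(id = nextid, x = v2$x[r],
                                           y = v2$y[r], z = v2$z[r]))
        }
    }
    e2 <- g2@edges
    e2$v1 <- remap[as.character(e2$v1)]
    e2$v2 <- remap[as.character(e2$v2)]
    eall <- rbind(g1@edges[, c("v1", "v2", "length_bp", "role")],
                  e2[, c("v1", "v2", "length_bp", "role")])
    lo <- pmin(eall$v1, eall$v2); hi <- pmax(eall$v1, eall$v2)
    eall$v1 <- lo; eall$v2 <- hi
    eall <- eall[!duplicated(paste(eall$v1, eall$v2)), , drop = FALSE]
    f2 <- lapply(g2@faces, function(f) unname(remap[as.character(f)]))
    faces <- c(g1@faces, f2)
    faces <- faces[!duplicated(vapply(.canonicalizeFaces(faces),
                                      paste, character(1), collapse = ","))]
    g <- wireframeGraph(vout, eall, faces = faces,
        metadata = list(shape = paste0(g1@metadata$shape, "+",
                                       g2@metadata$shape)))
    validObject(g)
    g
}
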