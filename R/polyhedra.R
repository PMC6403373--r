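#' Generate a wireframe polyhedron
#'
#' Vertex coordinates lie on the circumscribed sphere, scaled so that the
#' geometric edge length equals \code{edgeBp} x 0.34 nm. Faces are
#' populated; the buckyball is the truncated icosahedron (60 vertices,
#' 90 edges, 12 pentagonal + 20 hexagonal faces).
#'
#' @param name one of \code{"tetrahedron"}, \code{"cube"},
#'   \code{"octahedron"}, \code{"cuboctahedron"}, \code{"icosahedron"},
#'   \code{"buckyball"}.
#' @param edgeBp edge duplex length in bp (a full-turn length such as 32).
#' @return A \linkS4class{WireframeGraph}.
#' @examples
#' makePolyhedron("icosahedron", 32)   # 12 vertices, 30 edges, 20 faces
#' @export
makePolyhedron <- function(name, edgeBp = 32L) {
    shapes <- c("tetrahedron", "cube", "octahedron", "cuboctahedron",
                "icosahedron", "buckyball")
    if (!is.character(name) || length(name) != 1L || !name %in% shapes)
        .stopf("unknown polyhedron '%s' (choose one of: %s)",
               paste(name, collapse = ","), paste(shapes, collapse = ", "))
    if (!.is_count(edgeBp, 2L)) .stopf("edgeBp must be a positive integer")
    P <- .polyhedronCoords(name)
    # edges join vertex pairs at the minimal pairwise distance
    D <- as.matrix(stats::dist(P))
    dmin <- min(D[D > 1e-9])
    idx <- which(D < dmin * (1 + 1e-6) & upper.tri(D), arr.ind = TRUE)
    scale <- edgeBp * .BP_NM / dmin
    v <- data.frame(id = seq_len(nrow(P)), x = P[, 1] * scale,
                    y = P[, 2] * scale, z = P[, 3] * scale)
    e <- data.frame(v1 = idx[, 1], v2 = idx[, 2], length_bp = edgeBp)
    g <- wireframeGraph(v, e, metadata = list(shape = name, edge_bp = edgeBp))
    g@faces <- .canonicalizeFaces(.convexFaces(g@vertices, g@edges))
    validObject(g)
    g
}

.polyhedronCoords <- function(name) {
    phi <- (1 + sqrt(5)) / 2
    cyc <- function(m) {
        # all cyclic permutations of each coordinate row
        rbind(m, m[, c(2, 3, 1), drop = FALSE], m[, c(3, 1, 2), drop = FALSE])
    }
    signs <- function(v) {
        # all sign combinations of the nonzero components
        s <- expand.grid(lapply(v, function(x) if (x == 0) 0 else c(x, -x)))
        unique(as.matrix(s))
    }
    P <- switch(name,
        tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
        cube        = signs(c(1, 1, 1)),
        octahedron  = cyc(signs(c(1, 0, 0))),
        cuboctahedron = cyc(signs(c(1, 1, 0))),
        icosahedron = cyc(signs(c(0, 1, phi))),
        buckyball   = cyc(rbind(signs(c(0, 1, 3 * phi)),
                                signs(c(1, 2 + phi, 2 * phi)),
                                signs(c(2, 1 + 2 * phi, phi)))))
    unique(round(P, 10))
}

#' Triangulate the non-triangular faces of a wireframe graph
#'
#' Every face with more than three vertices gains one centroid vertex and
#' one new edge to each corner; triangular faces are untouched.
#' Rigidification by triangulation turns, e.g., the 60-vertex buckyball
#' into a 92-vertex, 270-edge, 180-face mesh. New edge lengths default to
#' the centroid-corner distance converted at 0.34 nm/bp and rounded to
#' full turns.
#'
#' @param graph a \linkS4class{WireframeGraph} with faces populated.
#' @param newEdgeBp optional fixed bp length for all new centroid edges,
#'   overriding the geometric default.
#' @return A \linkS4class{WireframeGraph} with all faces triangular.
#' @examples
#' b <- makePolyhedron("buckyball", 32)
#' t <- triangulateFaces(b)   # 92 vertices, 270 edges, 180 faces
#' @export
triangulateFaces <- function(graph, newEdgeBp = NULL) {
    if (!nFaces(graph))
        .stopf("graph has no faces; triangulation requires populated faces")
    v <- graph@vertices; e <- graph@edges
    faces_out <- list()
    next_id <- max(v$id) + 1L
    new_v <- NULL; new_e <- NULL
    for (f in graph@faces) {
        if (length(f) == 3L) {
            faces_out[[length(faces_out) + 1L]] <- f
            next
        }
        vi <- match(f, v$id)
        cx <- mean(v$x[vi]); cy <- mean(v$y[vi]); cz <- mean(v$z[vi])
        cid <- next_id; next_id <- next_id + 1L
        new_v <- rbind(new_v, data.frame(id = cid, x = cx, y = cy, z = cz))
        for (k in seq_along(f)) {
            corner <- vi[k]
            if (is.null(newEdgeBp)) {
                d <- sqrt((v$x[corner] - cx)^2 + (v$y[corner] - cy)^2 +
                          (v$z[corner] - cz)^2)
                bp <- quantizeFullTurns(d / .BP_NM)
            } else bp <- as.integer(newEdgeBp)
            new_e <- rbind(new_e,
                data.frame(v1 = f[k], v2 = cid, length_bp = bp))
            faces_out[[length(faces_out) + 1L]] <-
                c(f[k], f[if (k == length(f)) 1L else k + 1L], cid)
        }
    }
    if (is.null(new_v)) return(graph)   # already fully triangular
    md <- graph@metadata
    md$shape <- paste0("triangulated_", md$shape)
    g <- wireframeGraph(rbind(v, new_v),
        rbind(e[, c("v1", "v2", "length_bp", "role")],
              data.frame(new_e, role = "frame")),
        metadata = md)
    g@faces <- .canonicalizeFaces(faces_out)
    validObject(g)
    g
}
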