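#' Construct a WireframeGraph
#'
#' Low-level constructor used by the shape generators and the readers.
#'
#' @param vertices data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (coordinates in nm; \code{z} defaults to 0 if missing).
#' @param edges data.frame with columns \code{v1}, \code{v2},
#'   \code{length_bp} and optionally \code{id} and \code{role}.
#' @param faces list of integer vectors (ordered vertex-id cycles).
#' @param metadata list of shape metadata; \code{shape} defaults to
#'   \code{"custom"}.
#'
#' @return A \linkS4class{WireframeGraph}.
#' @export
wireframeGraph <- function(vertices, edges, faces = list(), metadata = list()) {
    vertices <- as.data.frame(vertices)
    edges <- as.data.frame(edges)
    if (is.null(vertices$z)) vertices$z <- 0
    vertices <- data.frame(id = as.integer(vertices$id),
                           x = as.numeric(vertices$x),
                           y = as.numeric(vertices$y),
                           z = as.numeric(vertices$z))
    if (nrow(edges)) {
        if (is.null(edges$role)) edges$role <- "frame"
        lo <- pmin(edges$v1, edges$v2); hi <- pmax(edges$v1, edges$v2)
        edges <- data.frame(v1 = as.integer(lo), v2 = as.integer(hi),
                            length_bp = as.integer(edges$length_bp),
                            role = as.character(edges$role))
        edges <- edges[order(edges$v1, edges$v2), , drop = FALSE]
        edges <- data.frame(id = seq_len(nrow(edges)), edges)
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(id = integer(), v1 = integer(), v2 = integer(),
                            length_bp = integer(), role = character())
    }
    if (is.null(metadata$shape)) metadata$shape <- "custom"
    faces <- lapply(faces, as.integer)
    new("WireframeGraph", vertices = vertices, edges = edges,
        faces = .canonicalizeFaces(faces), metadata = metadata)
}

# rotate each face cycle to start at its smallest vertex id, orient it so the
# second element is the smaller neighbour, then sort faces lexicographically
.canonicalizeFaces <- function(faces) {
    canon <- lapply(faces, function(f) {
        i <- which.min(f)
        f <- c(f[i:length(f)], f[seq_len(i - 1L)])
        if (length(f) > 2L && f[length(f)] < f[2L])
            f <- c(f[1L], rev(f[-1L]))
        f
    })
    if (length(canon) > 1L) {
        key <- vapply(canon, function(f) paste(f, collapse = ","), character(1))
        canon <- canon[order(key)]
    }
    canon
}

#' Graph accessors
#'
#' @param x A \linkS4class{WireframeGraph}.
#' @return \code{graphVertices}/\code{graphEdges} return data.frames,
#'   \code{graphFaces} a list of integer vectors, \code{nVertices}/
#'   \code{nEdges}/\code{nFaces} integer counts, \code{vertexDegrees} a
#'   named integer vector (vertex id -> arm count), and
#'   \code{graphMetadata} a list.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
graphVertices <- function(x) x@vertices

#' @rdname graph-accessors
#' @export
graphEdges <- function(x) x@edges

#' @rdname graph-accessors
#' @export
graphFaces <- function(x) x@faces

#' @rdname graph-accessors
#' @export
nVertices <- function(x) nrow(x@vertices)

#' @rdname graph-accessors
#' @export
nEdges <- function(x) nrow(x@edges)

#' @rdname graph-accessors
#' @export
nFaces <- function(x) length(x@faces)

#' @rdname graph-accessors
#' @export
graphMetadata <- function(x) x@metadata

#' @rdname graph-accessors
#' @export
vertexDegrees <- function(x) {
    ids <- x@vertices$id
    deg <- integer(length(ids))
    names(deg) <- ids
    if (nrow(x@edges)) {
        t1 <- table(factor(x@edges$v1, levels = ids))
        t2 <- table(factor(x@edges$v2, levels = ids))
        deg <- as.integer(t1 + t2)
        names(deg) <- ids
    }
    deg
}

setMethod("show", "WireframeGraph", function(object) {
    cat(sprintf("WireframeGraph '%s': %d vertices, %d edges, %d faces\n",
                object@metadata$shape, nVertices(object), nEdges(object),
                nFaces(object)))
    if (nEdges(object)) {
        deg <- vertexDegrees(object)
        cat(sprintf("  arm counts: %s\n",
                    paste(sprintf("%s-arm x%d", names(table(deg)),
                                  as.integer(table(deg))), collapse = ", ")))
        lens <- sort(unique(object@edges$length_bp))
        cat(sprintf("  edge lengths (bp): %s\n", paste(lens, collapse = ", ")))
    }
    invisible(NULL)
})

#' Round a target length to the nearest whole number of helical turns
#'
#' B-form DNA completes one helical turn every ~10.5 bp; edge lengths are
#' kept at whole turns so that crossover geometry repeats in register. The
#' target is first rounded to the nearest number of turns, and the
#' resulting (possibly half-integral) bp count is rounded half-to-even:
#' 3 turns gives 32 bp, 5 turns gives 52 bp.
#'
#' @param targetBp positive numeric vector of target lengths in bp
#'   (each at least half a turn, 5.25 bp).
#' @return integer vector of full-turn bp lengths.
#' @examples
#' quantizeFullTurns(31.5)  # 32
#' quantizeFullTurns(52.5)  # 52
#' @export
quantizeFullTurns <- function(targetBp) {
    if (!is.numeric(targetBp) || !length(targetBp) || any(!is.finite(targetBp)))
        .stopf("targetBp must be finite numeric")
    if (any(targetBp < 10.5 / 2))
        .stopf("targetBp must be at least half a helical turn (5.25 bp)")
    turns <- pmax(1, round(targetBp / 10.5))
    as.integer(round(10.5 * turns))
}

# TRUE where length is a full-turn value (a fixed point of the quantizer)
.isFullTurn <- function(bp) bp == quantizeFullTurns(pmax(bp, 6L))
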