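#' Generate a 2D wireframe tessellation patch
#'
#' Builds a planar patch of one of five tessellation patterns. Interior
#' vertices have the pattern's coordination number: 3 (hexagonal),
#' 4 (square), 6 (triangular), 4 (trihexagonal / kagome) or
#' 5 (snub trihexagonal); boundary vertices have fewer arms. All edges
#' carry the same duplex length \code{edgeBp} and faces are populated.
#'
#' @param pattern one of \code{"hexagonal"}, \code{"square"},
#'   \code{"triangular"}, \code{"trihexagonal"}, \code{"snub_trihexagonal"}.
#' @param rows,cols patch size in pattern repeat units (>= 1).
#' @param edgeBp edge duplex length in bp (a full-turn length such as 32).
#' @return A \linkS4class{WireframeGraph}.
#' @examples
#' makeTessellation("square", 1, 1, 32)      # 4 vertices, 4 edges, 1 face
#' makeTessellation("triangular", 3, 3, 32)  # interior vertices: 6 arms
#' @export
makeTessellation <- function(pattern, rows, cols, edgeBp = 32L) {
    patterns <- c("hexagonal", "square", "triangular", "trihexagonal",
                  "snub_trihexagonal")
    if (!is.character(pattern) || length(pattern) != 1L ||
        !pattern %in% patterns)
        .stopf("unknown tessellation pattern '%s' (choose one of: %s)",
               paste(pattern, collapse = ","), paste(patterns, collapse = ", "))
    if (!.is_count(rows) || !.is_count(cols)) .stopf("rows and cols must be >= 1")
    if (!.is_count(edgeBp, 2L)) .stopf("edgeBp must be a positive integer")
    g <- switch(pattern,
        square            = .tessSquare(rows, cols),
        triangular        = .tessTriangular(rows, cols),
        hexagonal         = .tessHexagonal(rows, cols),
        trihexagonal      = .tessKagome(rows, cols),
        snub_trihexagonal = .tessSnub(rows, cols))
    s <- edgeBp * .BP_NM      # unit edge -> nm
    v <- g$vertices
    v$x <- v$x * s; v$y <- v$y * s
    e <- g$edges
    e$length_bp <- edgeBp
    vg <- wireframeGraph(v, e,
        metadata = list(shape = pattern, pattern = pattern,
                        rows = rows, cols = cols, edge_bp = edgeBp))
    vg@faces <- .canonicalizeFaces(.planarFaces(vg@vertices, vg@edges))
    validObject(vg)
    vg
}

# -- pattern builders return unit-edge vertices/edges ------------------------

.mkVE <- function(xy, edges_idx) {
    v <- data.frame(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2], z = 0)
    e <- data.frame(v1 = edges_idx[, 1], v2 = edges_idx[, 2], length_bp = 1L)
    list(vertices = v, edges = e)
}

.tessSquare <- function(rows, cols) {
    grid <- expand.grid(j = 0:cols, i = 0:rows)
    xy <- cbind(grid$j, grid$i)
    id <- function(i, j) i * (cols + 1L) + j + 1L
    e <- NULL
    for (i in 0:rows) for (j in 0:cols) {
        if (j < cols) e <- rbind(e, c(id(i, j), id(i, j + 1L)))
        if (i < rows) e <- rbind(e, c(id(i, j), id(i + 1L, j)))
    }
    .mkVE(xy, e)
}

.tessTriangular <- function(rows, cols) {
    pts <- expand.grid(j = 0:cols, i = 0:rows)
    xy <- cbind(pts$j + pts$i / 2, pts$i * sqrt(3) / 2)
    id <- function(i, j) i * (cols + 1L) + j + 1L
    e <- NULL
    for (i in 0:rows) for (j in 0:cols) {
        if (j < cols) e <- rbind(e, c(id(i, j), id(i, j + 1L)))
        if (i < rows) e <- rbind(e, c(id(i, j), id(i + 1L, j)))
        if (i < rows && j > 0L) e <- rbind(e, c(id(i, j), id(i + 1L, j - 1L)))
    }
    .mkVE(xy, e)
}

.tessHexagonal <- function(rows, cols) {
    # pointy-top honeycomb of rows x cols hexagon cells, circumradius 1
    corners <- cbind(cos(pi / 6 + (0:5) * pi / 3), sin(pi / 6 + (0:5) * pi / 3))
    keymap <- new.env(parent = emptyenv())
    xs <- numeric(); ys <- numeric()
    e <- NULL
    for (r in 0:(rows - 1L)) for (c0 in 0:(cols - 1L)) {
        cx <- (c0 + 0.5 * (r %% 2L)) * sqrt(3)
        cy <- r * 1.5
        idc <- integer(6)
        for (k in 1:6) {
            px <- cx + corners[k, 1]; py <- cy + corners[k, 2]
            key <- .coord_key(px, py)
            if (is.null(keymap[[key]])) {
                xs <- c(xs, px); ys <- c(ys, py)
                keymap[[key]] <- length(xs)
            }
            idc[k] <- keymap[[key]]
        }
        e <- rbind(e, cbind(idc, c(idc[-1], idc[1])))
    }
    e <- unique(t(apply(e, 1, sort)))
    .mkVE(cbind(xs, ys), e)
}

.tessKagome <- function(rows, cols) {
    # vertices = midpoints of a triangular patch's edges; edges connect the
    # three midpoints of every small triangle (unit edge after 2x scaling)
    tg <- .tessTriangular(rows, cols)
    v <- tg$vertices; te <- tg$edges
    mx <- (v$x[te$v1] + v$x[te$v2]) / 2
    my <- (v$y[te$v1] + v$y[te$v2]) / 2
    # triangles of the parent patch
    id <- function(i, j) i * (cols + 1L) + j + 1L
    ekey <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(te)))
        ekey[[paste(min(te$v1[k], te$v2[k]), max(te$v1[k], te$v2[k]))]] <- k
    midOf <- function(a, b) ekey[[paste(min(a, b), max(a, b))]]
    e <- NULL
    for (i in 0:(rows - 1L)) for (j in 0:cols) {
        # upward triangle (i,j) (i,j+1) (i+1,j)
        if (j < cols) {
            tri <- c(midOf(id(i, j), id(i, j + 1L)),
                     midOf(id(i, j), id(i + 1L, j)),
                     midOf(id(i, j + 1L), id(i + 1L, j)))
            e <- rbind(e, cbind(tri, c(tri[-1], tri[1])))
        }
        # downward triangle (i,j) (i+1,j) (i+1,j-1)
        if (j > 0L) {
            tri <- c(midOf(id(i, j), id(i + 1L, j)),
                     midOf(id(i, j), id(i + 1L, j - 1L)),
                     midOf(id(i + 1L, j), id(i + 1L, j - 1L)))
            e <- rbind(e, cbind(tri, c(tri[-1], tri[1])))
        }
    }
    e <- unique(t(apply(e, 1, sort)))
    out <- .mkVE(cbind(mx * 2, my * 2), e)  # rescale so edges are unit
    out
}

.tessSnub <- function(rows, cols) {
    # triangular lattice with the index-7 sublattice removed: every
    # remaining lattice point is adjacent to exactly one removed point,
    # giving the 3.3.3.3.6 snub trihexagonal vertex configuration
    R <- 3L * rows + 3L; C <- 3L * cols + 3L
    keep <- expand.grid(j = 0:C, i = 0:R)
    removed <- (3L * keep$i + keep$j) %% 7L == 0L
    keep <- keep[!removed, , drop = FALSE]
    key <- paste(keep$i, keep$j)
    idmap <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(keep))) idmap[[key[k]]] <- k
    xy <- cbind(keep$j + keep$i / 2, keep$i * sqrt(3) / 2)
    e <- NULL
    dirs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, -1L))
    for (k in seq_len(nrow(keep))) {
        for (d in seq_len(3L)) {
            ni <- keep$i[k] + dirs[d, 1]; nj <- keep$j[k] + dirs[d, 2]
            nid <- idmap[[paste(ni, nj)]]
            if (!is.null(nid)) e <- rbind(e, c(k, nid))
        }
    }
    .mkVE(xy, e)
}
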