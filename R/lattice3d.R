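#' Generate a multi-layer 3D lattice
#'
#' Three families of fully addressable 3D arrays:
#' \describe{
#'   \item{\code{"grid"}}{rectangular lattice of 6-arm vertices (arms to
#'     front/back/left/right within a layer plus up/down between layers).}
#'   \item{\code{"diamond_cubic"}}{4-arm vertices branching tetrahedrally:
#'     three in-layer arms (honeycomb connectivity) and one arm up or
#'     down, alternating.}
#'   \item{\code{"cross"}}{planar 4-arm vertices in two alternating column
#'     classes: even columns carry four in-layer arms, odd columns two
#'     in-layer arms along the row direction plus two inter-layer arms.}
#' }
#' Faces are not populated for 3D lattices.
#'
#' @param kind \code{"grid"}, \code{"diamond_cubic"} or \code{"cross"}.
#' @param nx,ny vertices per layer in x and y (>= 1).
#' @param nz number of layers (>= 1).
#' @param edgeBp edge duplex length in bp.
#' @return A \linkS4class{WireframeGraph}.
#' @examples
#' makeLattice3D("grid", 4, 4, 4, 32)   # 64 vertices, 144 edges
#' @export
makeLattice3D <- function(kind = c("grid", "diamond_cubic", "cross"),
                          nx, ny, nz, edgeBp = 32L) {
    if (is.character(kind) && length(kind) == 1L &&
        !kind %in% c("grid", "diamond_cubic", "cross"))
        .stopf("unknown lattice kind '%s'", kind)
    kind <- match.arg(kind)
    if (!.is_count(nx) || !.is_count(ny) || !.is_count(nz))
        .stopf("nx, ny, nz must be >= 1")
    if (!.is_count(edgeBp, 2L)) .stopf("edgeBp must be a positive integer")
    s <- edgeBp * .BP_NM
    nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
    vid <- function(i, j, k) ((k * ny + j) * nx + i) + 1L  # 0-based i,j,k
    idx <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
    e <- NULL
    addE <- function(e, a, b) rbind(e, cbind(a, b))
    if (kind == "grid") {
        v <- data.frame(id = vid(idx$i, idx$j, idx$k),
                        x = idx$i * s, y = idx$j * s, z = idx$k * s)
        for (r in seq_len(nrow(idx))) {
            i <- idx$i[r]; j <- idx$j[r]; k <- idx$k[r]
            if (i < nx - 1L) e <- addE(e, vid(i, j, k), vid(i + 1L, j, k))
            if (j < ny - 1L) e <- addE(e, vid(i, j, k), vid(i, j + 1L, k))
            if (k < nz - 1L) e <- addE(e, vid(i, j, k), vid(i, j, k + 1L))
        }
    } else if (kind == "diamond_cubic") {
        # in-layer honeycomb (brick-wall rendering): row edges everywhere,
        # column edges where i+j is even; the fourth arm goes up where
        # i+j+k is even, down otherwise
        v <- data.frame(id = vid(idx$i, idx$j, idx$k),
                        x = idx$i * s, y = idx$j * s, z = idx$k * s)
        for (r in seq_len(nrow(idx))) {
            i <- idx$i[r]; j <- idx$j[r]; k <- idx$k[r]
            if (i < nx - 1L) e <- addE(e, vid(i, j, k), vid(i + 1L, j, k))
            if (j < ny - 1L && (i + j) %% 2L == 0L)
                e <- addE(e, vid(i, j, k), vid(i, j + 1L, k))
            if (k < nz - 1L && (i + j + k) %% 2L == 0L)
                e <- addE(e, vid(i, j, k), vid(i, j, k + 1L))
        }
    } else {    # cross
        # even columns (i even): 4 in-layer arms; odd columns: in-layer
        # arms along x plus inter-layer arms along z
        v <- data.frame(id = vid(idx$i, idx$j, idx$k),
                        x = idx$i * s, y = idx$j * s, z = idx$k * s)
        for (r in seq_len(nrow(idx))) {
            i <- idx$i[r]; j <- idx$j[r]; k <- idx$k[r]
            if (i < nx - 1L) e <- addE(e, vid(i, j, k), vid(i + 1L, j, k))
            if (j < ny - 1L && i %% 2L == 0L)
                e <- addE(e, vid(i, j, k), vid(i, j + 1L, k))
            if (k < nz - 1L && i %% 2L == 1L)
                e <- addE(e, vid(i, j, k), vid(i, j, k + 1L))
        }
    }
    e <- data.frame(v1 = e[, 1], v2 = e[, 2], length_bp = edgeBp)
    g <- wireframeGraph(v, e,
        metadata = list(shape = paste0(kind, "_", nx, "x", ny, "x", nz),
                        kind = kind, nx = nx, ny = ny, nz = nz,
                        edge_bp = edgeBp))
    validObject(g)
    g
}
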