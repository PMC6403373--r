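# Face extraction from embedded graphs via rotation-system tracing.
#
# Both helpers build, for every vertex, the cyclic (counter-clockwise)
# order of its neighbours in the embedding plane, then walk directed
# edges with the rule next(u -> v) = neighbour of v immediately before u
# in ccw order. Every directed edge lies on exactly one traced cycle.

# neighbours of each vertex sorted ccw; `angles` is a function(vi, nbr_idx)
.traceCycles <- function(n, nbrs_sorted) {
    cycles <- list()
    used <- new.env(parent = emptyenv())
    key <- function(u, v) paste0(u, ">", v)
    for (u0 in seq_len(n)) {
        for (v0 in nbrs_sorted[[u0]]) {
            if (!is.null(used[[key(u0, v0)]])) next
            cyc <- integer()
            u <- u0; v <- v0
            repeat {
                used[[key(u, v)]] <- TRUE
                cyc <- c(cyc, u)
                nb <- nbrs_sorted[[v]]
                i <- match(u, nb)
                w <- nb[if (i == 1L) length(nb) else i - 1L]
                u <- v; v <- w
                if (u == u0 && v == v0) break
                if (length(cyc) > 4L * n) stop("face tracing failed to close")
            }
            cycles[[length(cycles) + 1L]] <- cyc
        }
    }
    cycles
}

# faces of a connected planar straight-line embedded graph; drops the
# outer face (the traced cycle of largest absolute signed area)
.planarFaces <- function(vertices, edges) {
    n <- nrow(vertices)
    if (!nrow(edges)) return(list())
    vi <- match(edges$v1, vertices$id)
    wi <- match(edges$v2, vertices$id)
    nbrs <- vector("list", n)
    for (k in seq_along(vi)) {
        nbrs[[vi[k]]] <- c(nbrs[[vi[k]]], wi[k])
        nbrs[[wi[k]]] <- c(nbrs[[wi[k]]], vi[k])
    }
    x <- vertices$x; y <- vertices$y
    nbrs_sorted <- lapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        if (is.null(nb)) return(integer())
        ang <- atan2(y[nb] - y[i], x[nb] - x[i])
        nb[order(ang, vertices$id[nb])]
    })
    cycles <- .traceCycles(n, nbrs_sorted)
    area <- vapply(cycles, function(cyc) {
        xs <- x[cyc]; ys <- y[cyc]
        sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2
    }, numeric(1))
    if (length(cycles) > 1L)
        cycles <- cycles[-which.max(abs(area))]
    lapply(cycles, function(cyc) vertices$id[cyc])
}

# faces of a convex polyhedron centred at the origin: rotation order at
# each vertex is ccw around the outward normal (the vertex direction)
.convexFaces <- function(vertices, edges) {
    n <- nrow(vertices)
    vi <- match(edges$v1, vertices$id)
    wi <- match(edges$v2, vertices$id)
    nbrs <- vector("list", n)
    for (k in seq_along(vi)) {
        nbrs[[vi[k]]] <- c(nbrs[[vi[k]]], wi[k])
        nbrs[[wi[k]]] <- c(nbrs[[wi[k]]], vi[k])
    }
    P <- as.matrix(vertices[, c("x", "y", "z")])
    ctr <- colMeans(P)
    nbrs_sorted <- lapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        nrm <- P[i, ] - ctr
        nrm <- nrm / sqrt(sum(nrm^2))
        d0 <- P[nb[1], ] - P[i, ]
        e1 <- d0 - sum(d0 * nrm) * nrm
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
                nrm[3] * e1[1] - nrm[1] * e1[3],
                nrm[1] * e1[2] - nrm[2] * e1[1])
        ang <- vapply(nb, function(j) {
            d <- P[j, ] - P[i, ]
            atan2(sum(d * e2), sum(d * e1))
        }, numeric(1))
        nb[order(ang, vertices$id[nb])]
    })
    cycles <- .traceCycles(n, nbrs_sorted)
    lapply(cycles, function(cyc) vertices$id[cyc])
}
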