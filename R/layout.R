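#' Cyclic arm order at a vertex
#'
#' Arms are sorted by the angle of their edge direction projected onto
#' the plane perpendicular to the vertex normal (the mean of the incident
#' unit directions; for degenerate means, the normal of the best-fit
#' plane of the arm directions). Ties are broken by neighbour vertex id,
#' and the cycle starts at the lowest-id neighbour. Degree-1 and degree-2
#' vertices are ordered by neighbour id directly.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param vertexId a vertex id.
#' @return Integer vector of neighbour vertex ids in cyclic order.
#' @export
orderArms <- function(graph, vertexId) {
    v <- graph@vertices; e <- graph@edges
    i <- match(vertexId, v$id)
    if (is.na(i)) .stopf("unknown vertex id %s", vertexId)
    inc <- e[e$v1 == vertexId | e$v2 == vertexId, , drop = FALSE]
    nbr <- ifelse(inc$v1 == vertexId, inc$v2, inc$v1)
    if (length(nbr) <= 2L) return(sort(nbr))
    P <- as.matrix(v[, c("x", "y", "z")])
    dirs <- P[match(nbr, v$id), , drop = FALSE] -
        matrix(P[i, ], nrow = length(nbr), ncol = 3, byrow = TRUE)
    nl <- sqrt(rowSums(dirs^2))
    if (any(nl < 1e-12)) .stopf("zero-length edge vector at vertex %s", vertexId)
    dirs <- dirs / nl
    nrm <- colMeans(dirs)
    if (sqrt(sum(nrm^2)) < 1e-8) {
        # arms balance out (e.g. a planar cross): use the normal of the
        # best-fit plane through the arm directions
        ev <- eigen(crossprod(dirs), symmetric = TRUE)
        nrm <- ev$vectors[, 3]
        if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
    }
    nrm <- nrm / sqrt(sum(nrm^2))
    d0 <- dirs[1, ] - sum(dirs[1, ] * nrm) * nrm
    if (sqrt(sum(d0^2)) < 1e-9) d0 <- dirs[2, ] - sum(dirs[2, ] * nrm) * nrm
    e1 <- d0 / sqrt(sum(d0^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    ang <- atan2(dirs %*% e2, dirs %*% e1)[, 1]
    ord <- order(round(ang, 9), nbr)
    cyc <- nbr[ord]
    s <- which.min(cyc)
    c(cyc[s:length(cyc)], cyc[seq_len(s - 1L)])
}

#' Build the strand diagram of a segmented graph
#'
#' Standard architecture: per edge, one edge strand spanning the full
#' duplex on one side and one stem strand complementary to the central
#' stem region; per vertex, one junction strand concatenating (in cyclic
#' arm order) the root-region complements of its incident edges, with
#' policy spacers between consecutive roots. The strand count is
#' \code{V + 2E}. Edges planned with internal splits (see
#' \code{\link{planEdge}}) contribute additional edge/stem pieces.
#'
#' @param graph a validated \linkS4class{WireframeGraph}.
#' @param plans an \linkS4class{EdgePlanSet} covering every edge.
#' @param spacers named integer vector from \code{\link{assignSpacers}}
#'   (defaults to the default policy).
#' @param warnShortNt junction strands below this length draw a warning
#'   (synthesis practicality; default 16 nt).
#' @param warnCapNt,hardCapNt soft (80 nt) and hard (100 nt) strand
#'   length caps; exceeding the hard cap is an error.
#' @return A \linkS4class{StrandSet}.
#' @examples
#' g <- makePolyhedron("tetrahedron", 32)
#' ss <- buildStrands(g, planEdges(g, segmentationScheme(11, 10)))
#' nrow(strandTable(ss))   # 16 strands: 4 junction + 6 edge + 6 stem
#' @export
buildStrands <- function(graph, plans,
                         spacers = assignSpacers(graph, spacerPolicy()),
                         warnShortNt = 16L, warnCapNt = 80L,
                         hardCapNt = 100L) {
    e <- graphEdges(graph)
    v <- graphVertices(graph)
    pl <- plans@plans
    miss <- setdiff(as.character(e$id), names(pl))
    if (length(miss))
        .stopf("plans missing for edge id(s): %s", paste(miss, collapse = ", "))
    if (is.null(names(spacers)))
        .stopf("spacers must be a named vector (vertex id -> nt)")
    shape <- graph@metadata$shape

    # --- per-edge interval decomposition ------------------------------
    # Duplex coordinates run 0..L-1 from the lower-id vertex (A). The X
    # side (edge strands) runs A->B; the Y side (roots and stems) runs
    # B->A. Y nicks sit at every domain boundary; X nicks at the midpoint
    # of each interior root.
    edgeInfo <- vector("list", nrow(e))
    for (k in seq_len(nrow(e))) {
        p <- pl[[as.character(e$id[k])]]
        L <- e$length_bp[k]
        if (sum(p) != L)
            .stopf("plan for edge %d sums to %d, edge is %d bp",
                   e$id[k], sum(p), L)
        nd <- length(p)
        cum <- cumsum(p)
        ycuts <- cum[-nd]                       # interior domain boundaries
        xcuts <- integer(0)
        if (nd > 3L) {
            starts <- c(0L, cum[-nd])
            for (j in seq(3L, nd - 2L, by = 2L))   # interior roots
                xcuts <- c(xcuts, starts[j] + p[j] %/% 2L)
        }
        bounds <- sort(unique(c(0L, ycuts, xcuts, L)))
        iv <- data.frame(start = bounds[-length(bounds)],
                         end = bounds[-1])
        iv$len <- iv$end - iv$start
        # domain role of each interval: from the plan domain containing it
        dom_of <- findInterval(iv$start, c(0L, cum), rightmost.closed = FALSE)
        iv$plan_dom <- dom_of
        iv$is_root <- dom_of %% 2L == 1L
        edgeInfo[[k]] <- list(eid = e$id[k], L = L, plan = p, iv = iv,
                              xcuts = xcuts, ycuts = ycuts,
                              A = e$v1[k], B = e$v2[k])
    }

    # --- assemble strands ---------------------------------------------
    # column accumulators (a data.frame per row is too slow at scale)
    s_name <- character(); s_role <- character()
    s_vertex <- integer(); s_edge <- integer()
    d_strand <- integer(); d_index <- integer(); d_length <- integer()
    d_role <- character(); d_edge <- integer(); d_start <- integer()
    # interval partner bookkeeping: key "<eid>:<start>" -> domain id
    xdom <- new.env(parent = emptyenv())
    ydom <- new.env(parent = emptyenv())
    sid <- 0L; did <- 0L
    addStrand <- function(name, role, vertex, edge) {
        sid <<- sid + 1L
        s_name[sid] <<- name; s_role[sid] <<- role
        s_vertex[sid] <<- vertex; s_edge[sid] <<- edge
        sid
    }
    addDomain <- function(strand, index, length, role, edge, start, side) {
        did <<- did + 1L
        d_strand[did] <<- strand; d_index[did] <<- index
        d_length[did] <<- length; d_role[did] <<- role
        d_edge[did] <<- edge; d_start[did] <<- start
        if (!is.na(edge)) {
            key <- paste0(edge, ":", start)
            if (side == "X") xdom[[key]] <<- did else ydom[[key]] <<- did
        }
        did
    }

    # junction strands, in vertex id order
    for (vi in seq_len(nrow(v))) {
        vid <- v$id[vi]
        nbrs <- orderArms(graph, vid)
        sp <- spacers[[as.character(vid)]]
        if (is.null(sp) || is.na(sp))
            .stopf("no spacer assignment for vertex %s", vid)
        s <- addStrand(sprintf("%s_J%d", shape, vid), "junction", vid,
                       NA_integer_)
        idx <- 0L
        for (a in seq_along(nbrs)) {
            ek <- which((e$v1 == vid & e$v2 == nbrs[a]) |
                        (e$v2 == vid & e$v1 == nbrs[a]))
            info <- edgeInfo[[ek]]
            if (info$A == vid) {        # A-end root: first plan domain
                rlen <- info$plan[1]
                rstart <- 0L
            } else {                    # B-end root: last plan domain
                rlen <- info$plan[length(info$plan)]
                rstart <- info$L - rlen
            }
            idx <- idx + 1L
            addDomain(s, idx, rlen, "root", info$eid, rstart, "Y")
            if (a < length(nbrs) && sp > 0L) {
                idx <- idx + 1L
                addDomain(s, idx, as.integer(sp), "spacer", NA_integer_,
                          NA_integer_, "none")
            }
        }
    }

    # edge and stem strands, in edge id order
    for (k in seq_len(nrow(e))) {
        info <- edgeInfo[[k]]
        iv <- info$iv
        # X side: pieces between consecutive x cuts
        xb <- c(0L, info$xcuts, info$L)
        npiece <- length(xb) - 1L
        for (pc in seq_len(npiece)) {
            nm <- if (npiece == 1L) sprintf("%s_E%d", shape, info$eid)
                  else sprintf("%s_E%d%s", shape, info$eid, letters[pc])
            s <- addStrand(nm, "edge", NA_integer_, info$eid)
            sel <- which(iv$start >= xb[pc] & iv$end <= xb[pc + 1L])
            # X runs A->B: increasing coordinate
            for (j in seq_along(sel))
                addDomain(s, j, iv$len[sel[j]], "edge_span", info$eid,
                          iv$start[sel[j]], "X")
        }
        # Y side interior segments (between the two roots), each its own
        # stem strand; Y runs B->A: decreasing coordinate
        rA <- info$plan[1]; rB <- info$plan[length(info$plan)]
        yb <- sort(unique(c(rA, info$ycuts, info$L - rB)))
        yb <- yb[yb >= rA & yb <= info$L - rB]
        segs <- data.frame(lo = yb[-length(yb)], hi = yb[-1])
        segs <- segs[order(-segs$lo), , drop = FALSE]   # B->A order
        for (sg in seq_len(nrow(segs))) {
            nm <- if (nrow(segs) == 1L) sprintf("%s_S%d", shape, info$eid)
                  else sprintf("%s_S%d%s", shape, info$eid, letters[sg])
            s <- addStrand(nm, "stem", NA_integer_, info$eid)
            sel <- which(iv$start >= segs$lo[sg] & iv$end <= segs$hi[sg])
            sel <- sel[order(-iv$start[sel])]   # decreasing coordinate
            for (j in seq_along(sel))
                addDomain(s, j, iv$len[sel[j]], "stem_span",
                          info$eid, iv$start[sel[j]], "Y")
        }
    }

    strands <- data.frame(id = seq_len(sid), name = s_name, role = s_role,
                          vertex = s_vertex, edge = s_edge, length = 0L)
    domains <- data.frame(id = seq_len(did), strand = d_strand,
                          index = d_index, length = d_length, role = d_role,
                          partner = NA_integer_, edge = d_edge,
                          start = d_start)

    # partner linking: every on-edge interval has one X and one Y domain
    for (key in ls(xdom)) {
        dx <- xdom[[key]]; dy <- ydom[[key]]
        if (is.null(dy)) .stopf("internal: unpaired X interval %s", key)
        domains$partner[dx] <- dy
        domains$partner[dy] <- dx
    }

    strands$length <- as.integer(tapply(domains$length, domains$strand,
                                        sum)[as.character(strands$id)])
    over <- strands$name[strands$length > hardCapNt]
    if (length(over))
        .stopf(paste0("strand(s) exceed the %d nt synthesis cap: %s ",
                      "(consider long-edge splitting via planEdge)"),
               hardCapNt, paste(over, collapse = ", "))
    soft <- strands$name[strands$length > warnCapNt]
    if (length(soft))
        warning(sprintf("strand(s) over %d nt (preferred cap): %s",
                        warnCapNt, paste(soft, collapse = ", ")),
                call. = FALSE)
    shortJ <- strands$name[strands$role == "junction" &
                           strands$length < warnShortNt]
    if (length(shortJ))
        warning(sprintf("junction strand(s) below %d nt: %s", warnShortNt,
                        paste(shortJ, collapse = ", ")), call. = FALSE)

    ss <- new("StrandSet", strands = strands, domains = domains,
              graph = graph, plans = plans,
              spacers = vapply(spacers, as.integer, integer(1)),
              modifications = data.frame(strand = integer(),
                                         position = integer(),
                                         label = character()))
    validObject(ss)
    ss
}

#' StrandSet accessors
#'
#' @param x a \linkS4class{StrandSet}.
#' @return \code{strandTable}/\code{domainTable} return data.frames;
#'   \code{pairingMap} an integer vector mapping domain id to partner
#'   domain id (NA for spacers); \code{nStrands} the strand count;
#'   \code{strandModifications} the modification table.
#' @name strandset-accessors
NULL

#' @rdname strandset-accessors
#' @export
strandTable <- function(x) x@strands

#' @rdname strandset-accessors
#' @export
domainTable <- function(x) x@domains

#' @rdname strandset-accessors
#' @export
pairingMap <- function(x) {
    p <- x@domains$partner
    names(p) <- x@domains$id
    p
}

#' @rdname strandset-accessors
#' @export
nStrands <- function(x) nrow(x@strands)

#' @rdname strandset-accessors
#' @export
strandModifications <- function(x) x@modifications

setMethod("show", "StrandSet", function(object) {
    s <- object@strands
    cat(sprintf("StrandSet: %d strands (%d junction, %d edge, %d stem), %d nt total\n",
                nrow(s), sum(s$role == "junction"), sum(s$role == "edge"),
                sum(s$role == "stem"), sum(s$length)))
    invisible(NULL)
})

#' Record chemical modifications on strand positions
#'
#' Modifications (e.g. biotin groups for protein display) are annotations
#' on strand coordinates; sequence generation is unaffected. Each spec
#' entry addresses an edge strand through its edge id and 1-based duplex
#' offsets, or any strand directly via \code{strand} (strand name) and
#' \code{position}.
#'
#' @param strandset a \linkS4class{StrandSet}.
#' @param spec list of entries; each a list with either \code{edge} and
#'   \code{offsets} (vector of 1-based positions along the edge duplex)
#'   or \code{strand} (name) and \code{position}, plus a \code{label}.
#' @return The \linkS4class{StrandSet} with modifications recorded.
#' @examples
#' g <- makePolyhedron("octahedron", 32)
#' ss <- buildStrands(g, planEdges(g, segmentationScheme(11, 10)))
#' spec <- lapply(graphEdges(g)$id, function(e)
#'     list(edge = e, offsets = c(8, 24), label = "biotin"))
#' ss <- annotateModification(ss, spec)
#' nrow(strandModifications(ss))   # 24: two sites per edge
#' @export
annotateModification <- function(strandset, spec) {
    if (!length(spec)) return(strandset)
    s <- strandset@strands; d <- strandset@domains
    mods <- strandset@modifications
    for (entry in spec) {
        if (is.null(entry$label)) .stopf("modification entry without a label")
        if (!is.null(entry$edge)) {
            es <- s[s$role == "edge" & !is.na(s$edge) & s$edge == entry$edge, ,
                    drop = FALSE]
            if (!nrow(es)) .stopf("no edge strand for edge id %s", entry$edge)
            L <- sum(s$length[s$id %in% es$id])
            for (off in entry$offsets) {
                if (off < 1L || off > L)
                    .stopf("offset %d outside edge %s (1..%d)", off,
                           entry$edge, L)
                # locate the edge-strand piece containing duplex coord off-1
                coord <- off - 1L
                dd <- d[d$strand %in% es$id & !is.na(d$start), , drop = FALSE]
                hit <- dd[coord >= dd$start & coord < dd$start + dd$length, ,
                          drop = FALSE]
                sidx <- hit$strand[1]
                prior <- dd[dd$strand == sidx & dd$index < hit$index[1], ,
                            drop = FALSE]
                pos <- sum(prior$length) + (coord - hit$start[1]) + 1L
                mods <- rbind(mods, data.frame(strand = sidx, position = pos,
                                               label = entry$label))
            }
        } else if (!is.null(entry$strand)) {
            i <- match(entry$strand, s$name)
            if (is.na(i)) .stopf("unknown strand name '%s'", entry$strand)
            if (entry$position < 1L || entry$position > s$length[i])
                .stopf("position %d outside strand '%s'", entry$position,
                       entry$strand)
            # warn when the position lands on an unpaired spacer base
            dd <- d[d$strand == s$id[i], , drop = FALSE]
            dd <- dd[order(dd$index), , drop = FALSE]
            ends <- cumsum(dd$length)
            j <- which(entry$position <= ends)[1]
            if (dd$role[j] == "spacer")
                warning(sprintf("modification on a spacer base of '%s'",
                                entry$strand), call. = FALSE)
            mods <- rbind(mods, data.frame(strand = s$id[i],
                                           position = as.integer(entry$position),
                                           label = entry$label))
        } else .stopf("modification entry needs 'edge' or 'strand'")
    }
    rownames(mods) <- NULL
    strandset@modifications <- mods
    strandset
}
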