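#' Create a segmentation scheme
#'
#' @param rootBp root domain length in bp (e.g. 11, 13 or 16).
#' @param stemBp nominal stem domain length in bp (e.g. 10 or 6).
#' @param minDomainBp hard floor for any paired domain (default 6 bp).
#' @param preferredMinBp soft floor; shorter planned domains draw a
#'   warning (default 10 bp).
#' @return A \linkS4class{SegmentationScheme}.
#' @examples
#' segmentationScheme(11, 10)   # the typical {11,10} arrangement
#' @export
segmentationScheme <- function(rootBp, stemBp, minDomainBp = 6L,
                               preferredMinBp = 10L) {
    s <- new("SegmentationScheme", rootBp = as.integer(rootBp),
             stemBp = as.integer(stemBp), minDomainBp = as.integer(minDomainBp),
             preferredMinBp = as.integer(preferredMinBp))
    validObject(s)
    s
}

#' Partition one edge length into root/stem domains
#'
#' An edge of exactly \code{2*rootBp + stemBp} becomes
#' \code{[root, stem, root]}. Other lengths keep the scheme's roots and
#' absorb the difference into the stem, so vertex-side geometry stays
#' uniform across variable-length edges. When the resulting single edge
#' strand would exceed \code{splitAboveNt} (default 80 nt, the preferred
#' synthesis cap), the interior is split into alternating stem/root
#' domains (\code{[root, stem, root', stem', root]}, ...), introducing
#' internal nicks so that no strand exceeds the cap.
#'
#' @param lengthBp edge length in bp
#'   (>= \code{2*rootBp + minDomainBp}).
#' @param scheme a \linkS4class{SegmentationScheme}.
#' @param splitAboveNt edge strands longer than this are split (default
#'   80).
#' @param warn if TRUE, warn when a planned domain is below the scheme's
#'   preferred minimum.
#' @return Integer vector of ordered domain lengths; odd positions are
#'   root domains, even positions stems; the vector sums to
#'   \code{lengthBp}.
#' @examples
#' planEdge(32, segmentationScheme(11, 10))   # 11 10 11
#' planEdge(32, segmentationScheme(13, 6))    # 13  6 13
#' planEdge(42, segmentationScheme(16, 10))   # 16 10 16
#' @export
planEdge <- function(lengthBp, scheme, splitAboveNt = 80L, warn = TRUE) {
    r <- scheme@rootBp; s <- scheme@stemBp; mn <- scheme@minDomainBp
    if (!.is_count(lengthBp, 1L)) .stopf("lengthBp must be a positive integer")
    if (lengthBp < 2L * r + mn)
        .stopf("edge of %d bp cannot host two %d-bp roots and a >= %d bp stem",
               lengthBp, r, mn)
    if (lengthBp <= splitAboveNt) {
        plan <- c(r, as.integer(lengthBp) - 2L * r, r)
    } else {
        # interior roots of 2*preferredMin bp give the edge-strand nick
        # >= preferredMin clearance on both sides
        ri <- 2L * scheme@preferredMinBp
        interior <- as.integer(lengthBp) - 2L * r
        k <- 1L
        repeat {
            # k interior stems separated by k-1 interior roots
            stems_total <- interior - (k - 1L) * ri
            if (stems_total < k * mn)
                .stopf("edge of %d bp cannot be split under scheme {%d,%d}",
                       lengthBp, r, s)
            stem_each <- as.integer(ceiling(stems_total / k))
            # worst-case edge-strand piece: outer root + stem + half an
            # interior root (the nick sits mid interior root)
            longest <- r + stem_each + ri %/% 2L
            if (longest <= splitAboveNt) break
            k <- k + 1L
            if (k > 64L) .stopf("cannot split a %d bp edge", lengthBp)
        }
        stems <- rep(stems_total %/% k, k)
        stems[seq_len(stems_total %% k)] <- stems[seq_len(stems_total %% k)] + 1L
        plan <- integer(0)
        for (i in seq_len(k)) {
            plan <- c(plan, stems[i])
            if (i < k) plan <- c(plan, ri)
        }
        plan <- c(r, plan, r)
    }
    plan <- as.integer(plan)
    stopifnot(sum(plan) == lengthBp, all(plan >= mn))
    if (warn && any(plan < scheme@preferredMinBp))
        warning(sprintf(
            "edge of %d bp: planned domain of %d bp is below the preferred %d bp minimum",
            lengthBp, min(plan), scheme@preferredMinBp), call. = FALSE)
    plan
}

#' Plan all edges of a graph
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param scheme a \linkS4class{SegmentationScheme}.
#' @param splitAboveNt passed to \code{\link{planEdge}}.
#' @param warn passed to \code{\link{planEdge}}.
#' @return An \linkS4class{EdgePlanSet} whose \code{plans} list is named
#'   by edge id.
#' @export
planEdges <- function(graph, scheme, splitAboveNt = 80L, warn = TRUE) {
    e <- graphEdges(graph)
    plans <- lapply(seq_len(nrow(e)), function(i)
        planEdge(e$length_bp[i], scheme, splitAboveNt, warn))
    names(plans) <- e$id
    new("EdgePlanSet", plans = plans, scheme = scheme)
}

#' @rdname graph-accessors
#' @param planset an \linkS4class{EdgePlanSet}.
#' @export
edgePlans <- function(planset) planset@plans

#' Create a spacer policy
#'
#' @param ... overrides as \code{armcount = nt} pairs, e.g.
#'   \code{spacerPolicy(`3` = 1)}.
#' @param default named integer vector giving the base policy; the shipped
#'   default adds no spacers at vertices of up to 4 arms, T2 linkers at
#'   5- and 6-arm vertices and T3 at 7-arm vertices.
#' @return A \linkS4class{SpacerPolicy}.
#' @export
spacerPolicy <- function(..., default = c(`1` = 0L, `2` = 0L, `3` = 0L,
                                          `4` = 0L, `5` = 2L, `6` = 2L,
                                          `7` = 3L)) {
    ov <- c(...)
    map <- default
    if (length(ov)) {
        if (is.null(names(ov)) || any(!nzchar(names(ov))))
            .stopf("spacer overrides must be named by arm count")
        map[names(ov)] <- as.integer(ov)
    }
    p <- new("SpacerPolicy", map = vapply(map, as.integer, integer(1)))
    validObject(p)
    p
}

#' Assign junction spacers to every vertex of a graph
#'
#' Looks up each vertex's arm count in the policy; the value is the
#' number of unpaired T bases inserted between consecutive root domains
#' of that vertex's junction strand.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param policy a \linkS4class{SpacerPolicy}.
#' @return Named integer vector: vertex id -> spacer length (nt).
#' @examples
#' g <- makePolyhedron("icosahedron", 32)
#' assignSpacers(g, spacerPolicy())   # all 2 (5-arm vertices)
#' @export
assignSpacers <- function(graph, policy = spacerPolicy()) {
    deg <- vertexDegrees(graph)
    key <- as.character(deg)
    miss <- setdiff(unique(key), names(policy@map))
    if (length(miss))
        .stopf("spacer policy has no entry for arm count(s): %s",
               paste(miss, collapse = ", "))
    out <- policy@map[key]
    names(out) <- names(deg)
    out
}
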