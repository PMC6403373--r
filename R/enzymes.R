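#' Bundled restriction enzyme table
#'
#' Recognition sites and top-strand cut offsets for the enzymes used in
#' cleavage programming (palindromic 6-cutters from standard references),
#' shipped as a JSON resource. \code{cut5} is the number of bases 5' of
#' the top-strand cut within the site (e.g. G^GATCC has \code{cut5 = 1});
#' the bottom strand is cut symmetrically at \code{width - cut5}.
#'
#' @param path optional path to a user table with the same JSON schema.
#' @return data.frame with columns \code{name}, \code{site}, \code{cut5}.
#' @examples
#' enzymeTable()
#' @export
enzymeTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "restriction_enzymes.json",
                            package = "wireframeDNA", mustWork = TRUE)
    j <- jsonlite::fromJSON(path)
    tab <- as.data.frame(j$enzymes)
    tab$site <- toupper(tab$site)
    tab$cut5 <- as.integer(tab$cut5)
    if (any(nchar(tab$site) < 4L))
        .stopf("recognition sites must be at least 4 bp")
    if (any(tab$cut5 < 0L | tab$cut5 > nchar(tab$site)))
        .stopf("cut offsets must lie within the recognition span")
    tab
}

#' Program restriction sites into designated edges
#'
#' Each placement fixes an enzyme's recognition sequence at a given
#' offset inside an edge duplex, and every used enzyme's motif is added
#' to the forbidden list outside its placements - so a digestion cocktail
#' cleaves exactly the designated edges. Sites must sit in fully duplexed
#' edge interior: at least \code{clearance} bp away from every nick
#' (edge ends and internal domain boundaries on the nicked side are all
#' nicks) and never overlapping a spacer.
#'
#' @param design a \linkS4class{DesignDocument} (sequences not yet
#'   generated).
#' @param placements data.frame with columns \code{edge} (edge id),
#'   \code{offset} (1-based bp position of the site start within the
#'   edge, counted from the lower-id vertex) and \code{enzyme} (name in
#'   the table).
#' @param enzymes enzyme table (see \code{\link{enzymeTable}}).
#' @param clearance minimal distance in bp between a site and any nick
#'   (default 2).
#' @return The design with updated \code{constraints} (fixed motifs on
#'   the corresponding edge strands; forbidden motifs for all used
#'   enzymes).
#' @export
placeSites <- function(design, placements, enzymes = enzymeTable(),
                       clearance = 2L) {
    if (!nrow(placements)) return(design)
    ss <- design@strands
    st <- ss@strands; dm <- ss@domains
    e <- graphEdges(design@graph)
    pl <- ss@plans@plans
    cons <- design@constraints
    if (is.null(cons)) cons <- seqConstraints()
    fm <- cons@fixedMotifs
    # reject overlapping placements on the same edge
    key <- order(placements$edge, placements$offset)
    placements <- placements[key, , drop = FALSE]
    for (i in seq_len(nrow(placements) - 1L)) {
        a <- placements[i, ]; b <- placements[i + 1L, ]
        wa <- nchar(enzymes$site[match(a$enzyme, enzymes$name)])
        if (a$edge == b$edge && b$offset <= a$offset + wa - 1L)
            .stopf("placements overlap on edge %d", a$edge)
    }
    for (i in seq_len(nrow(placements))) {
        p <- placements[i, ]
        row <- match(p$enzyme, enzymes$name)
        if (is.na(row)) .stopf("enzyme '%s' not in the table", p$enzyme)
        site <- enzymes$site[row]
        w <- nchar(site)
        ei <- match(p$edge, e$id)
        if (is.na(ei)) .stopf("placement references missing edge id %s", p$edge)
        L <- e$length_bp[ei]
        lo <- p$offset; hi <- p$offset + w - 1L        # 1-based bp span
        if (lo < 1L || hi > L)
            .stopf("site on edge %d (offset %d) exceeds the %d bp duplex",
                   p$edge, p$offset, L)
        # nick coordinates (0-based, between bp c-1 and c): edge ends plus
        # every domain boundary of the plan (nicked on one side or the
        # other), plus edge-strand split points for long edges
        plan <- pl[[as.character(p$edge)]]
        cum <- cumsum(plan)
        nicks <- c(0L, cum)                     # includes L
        if (length(plan) > 3L) {
            starts <- c(0L, cum[-length(cum)])
            for (j in seq(3L, length(plan) - 2L, by = 2L))
                nicks <- c(nicks, starts[j] + plan[j] %/% 2L)
        }
        # site occupies the bp interval [lo-1, hi); clearance in bp from
        # any nick strictly inside or within `clearance` of the span
        bad <- nicks[nicks > lo - 1L - clearance & nicks < hi + clearance]
        if (length(bad))
            .stopf(paste0("site %s on edge %d (offset %d) is within %d bp of",
                          " a nick; move it into a duplexed interior"),
                   p$enzyme, p$edge, p$offset, clearance)
        # fix the motif on the edge strand carrying those duplex coords
        es <- st[st$role == "edge" & !is.na(st$edge) & st$edge == p$edge, ,
                 drop = FALSE]
        dd <- dm[dm$strand %in% es$id, , drop = FALSE]
        hit <- dd[dd$start <= lo - 1L & dd$start + dd$length >= hi, ,
                  drop = FALSE]
        if (!nrow(hit))
            .stopf("site on edge %d spans an edge-strand nick", p$edge)
        prior <- dm[dm$strand == hit$strand[1] & dm$index < hit$index[1], ,
                    drop = FALSE]
        pos <- sum(prior$length) + (lo - 1L - hit$start[1]) + 1L
        fm <- rbind(fm, data.frame(strand = hit$strand[1], position = pos,
                                   motif = site))
    }
    cons@fixedMotifs <- fm
    cons@forbiddenMotifs <- sort(unique(c(
        cons@forbiddenMotifs, enzymes$site[match(unique(placements$enzyme),
                                                 enzymes$name)])))
    design@constraints <- cons
    md <- design@metadata
    md$placements <- placements
    design@metadata <- md
    design
}

#' In-silico restriction digestion of a design
#'
#' Scans every edge duplex of a sequenced design for the recognition
#' sites of a cocktail of enzymes; every duplex occurrence cuts the edge.
#' Cut edges are removed from the cleaved graph (both strands of the
#' duplex are severed) and fragment lengths are computed from the cut
#' offsets for all strands crossing the cut.
#'
#' @param design a \linkS4class{DesignDocument} with sequences generated.
#' @param cocktail character vector of enzyme names.
#' @param enzymes enzyme table (see \code{\link{enzymeTable}}).
#' @return A \linkS4class{DigestResult}.
#' @export
digestDesign <- function(design, cocktail, enzymes = enzymeTable()) {
    if (is.null(design@sequences))
        .stopf("digestion requires generated sequences")
    miss <- setdiff(cocktail, enzymes$name)
    if (length(miss))
        .stopf("enzyme(s) not in the table: %s", paste(miss, collapse = ", "))
    ss <- design@strands
    st <- ss@strands; dm <- ss@domains
    seqs <- as.character(design@sequences)
    names(seqs) <- names(design@sequences)
    e <- graphEdges(design@graph)
    cuts <- data.frame(edge = integer(), enzyme = character(),
                       site_start = integer())
    # duplex sequence of each edge from its edge-strand side (A->B)
    for (k in seq_len(nrow(e))) {
        es <- st[st$role == "edge" & !is.na(st$edge) & st$edge == e$id[k], ,
                 drop = FALSE]
        dd <- dm[dm$strand %in% es$id, , drop = FALSE]
        dd <- dd[order(dd$start), , drop = FALSE]
        duplex <- character(e$length_bp[k])
        for (r in seq_len(nrow(dd))) {
            s_seq <- seqs[st$name[match(dd$strand[r], st$id)]]
            prior <- dm[dm$strand == dd$strand[r] & dm$index < dd$index[r], ,
                        drop = FALSE]
            p0 <- sum(prior$length)
            duplex[dd$start[r] + seq_len(dd$length[r])] <-
                strsplit(substr(s_seq, p0 + 1L, p0 + dd$length[r]), "",
                         fixed = TRUE)[[1]]
        }
        duplex <- paste(duplex, collapse = "")
        for (enz in cocktail) {
            row <- match(enz, enzymes$name)
            site <- enzymes$site[row]
            rc <- .revcomp_chr(site)
            for (pat in unique(c(site, rc))) {
                hits <- gregexpr(pat, duplex, fixed = TRUE)[[1]]
                hits <- hits[hits > 0L]
                for (h in hits)
                    cuts <- rbind(cuts, data.frame(edge = e$id[k],
                                                   enzyme = enz,
                                                   site_start = h))
            }
        }
    }
    cuts <- unique(cuts)
    cutEdges <- unique(cuts$edge)
    cleaved <- if (length(cutEdges))
        .dropEdges(design@graph, cutEdges) else design@graph
    # fragment bookkeeping: strand-level cut positions
    frag <- data.frame(strand = character(), fragment = integer(),
                       length = integer())
    if (nrow(cuts)) {
        strandCuts <- list()
        for (i in seq_len(nrow(cuts))) {
            eid <- cuts$edge[i]
            row <- match(cuts$enzyme[i], enzymes$name)
            w <- nchar(enzymes$site[row])
            topc <- cuts$site_start[i] - 1L + enzymes$cut5[row]  # 0-based coord
            botc <- cuts$site_start[i] - 1L + (w - enzymes$cut5[row])
            dd <- dm[!is.na(dm$edge) & dm$edge == eid & dm$role != "spacer", ,
                     drop = FALSE]
            for (r in seq_len(nrow(dd))) {
                sidx <- dd$strand[r]
                isX <- dd$role[r] == "edge_span"
                cc <- if (isX) topc else botc
                if (cc > dd$start[r] && cc < dd$start[r] + dd$length[r]) {
                    prior <- dm[dm$strand == sidx & dm$index < dd$index[r], ,
                                drop = FALSE]
                    p0 <- sum(prior$length)
                    within <- if (isX) cc - dd$start[r]
                              else (dd$start[r] + dd$length[r]) - cc
                    pos <- p0 + within      # nt before the cut
                    keynm <- st$name[match(sidx, st$id)]
                    strandCuts[[keynm]] <- c(strandCuts[[keynm]], pos)
                }
            }
        }
        for (nmx in sort(names(strandCuts))) {
            L <- st$length[match(nmx, st$name)]
            cps <- sort(unique(c(0L, strandCuts[[nmx]], L)))
            lens <- diff(cps)
            frag <- rbind(frag, data.frame(strand = nmx,
                                           fragment = seq_along(lens),
                                           length = lens))
        }
    }
    rownames(cuts) <- NULL
    new("DigestResult", cleavedGraph = cleaved, cuts = cuts,
        fragments = frag)
}

# remove edges by id without degree revalidation (digestion may orphan
# vertices; the cleaved graph is a result, not a design)
.dropEdges <- function(graph, edgeIds) {
    e <- graph@edges[!graph@edges$id %in% edgeIds, , drop = FALSE]
    faces <- Filter(function(f) {
        nxt <- c(f[-1], f[1])
        key <- paste(pmin(f, nxt), pmax(f, nxt))
        all(key %in% paste(e$v1, e$v2))
    }, graph@faces)
    md <- graph@metadata
    md$digested <- TRUE
    out <- new("WireframeGraph", vertices = graph@vertices, edges = e,
               faces = faces, metadata = md)
    out
}

setMethod("show", "DigestResult", function(object) {
    cat(sprintf("DigestResult: %d cut(s) on %d edge(s); cleaved graph has %d edges\n",
                nrow(object@cuts), length(unique(object@cuts$edge)),
                nEdges(object@cleavedGraph)))
    invisible(NULL)
})

#' @rdname strandset-accessors
#' @param object a \linkS4class{DigestResult}.
#' @export
cutEdges <- function(object) unique(object@cuts$edge)

# average residue masses (Da) for a synthetic oligo with 5'-OH/3'-OH ends
.BASE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
.WATER_MASS <- 18.02

#' Design statistics
#'
#' Strand count, total nucleotides, estimated molecular weight, and the
#' degree and edge-length spectra. MW sums average per-residue masses
#' (A 313.21, C 289.18, G 329.21, T 304.20 Da) plus 18.02 Da per strand
#' (5'-OH/3'-OH convention for unphosphorylated synthetic oligos); when
#' sequences are absent the mean residue mass is used.
#'
#' @param design a \linkS4class{DesignDocument}.
#' @return A \linkS4class{DesignStats}.
#' @examples
#' d <- designWireframe(makePolyhedron("tetrahedron", 32))
#' computeStats(d)    # 16 strands, 384 nt, ~119 kDa
#' @export
computeStats <- function(design) {
    st <- design@strands@strands
    totalNt <- sum(st$length)
    if (!is.null(design@sequences)) {
        comp <- Biostrings::alphabetFrequency(design@sequences)[,
            c("A", "C", "G", "T"), drop = FALSE]
        mw <- sum(colSums(comp) * .BASE_MASS[colnames(comp)]) +
            nrow(st) * .WATER_MASS
    } else {
        mw <- totalNt * mean(.BASE_MASS) + nrow(st) * .WATER_MASS
    }
    new("DesignStats", strandCount = nrow(st), totalNt = as.integer(totalNt),
        molecularWeight = mw,
        degreeHistogram = table(vertexDegrees(design@graph)),
        edgeLengthHistogram = table(graphEdges(design@graph)$length_bp))
}

setMethod("show", "DesignStats", function(object) {
    cat(sprintf("DesignStats: %d strands, %d nt, MW %.3g Da (%.2g kDa)\n",
                object@strandCount, object@totalNt, object@molecularWeight,
                object@molecularWeight / 1e3))
    cat("  arms:", paste(sprintf("%s-arm x%d", names(object@degreeHistogram),
                                 as.integer(object@degreeHistogram)),
                         collapse = ", "), "\n")
    cat("  edge lengths (bp):",
        paste(sprintf("%s x%d", names(object@edgeLengthHistogram),
                      as.integer(object@edgeLengthHistogram)),
              collapse = ", "), "\n")
    invisible(NULL)
})
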