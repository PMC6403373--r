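#' Assemble a complete wireframe design from a graph
#'
#' Convenience pipeline: validates the graph, plans every edge under the
#' segmentation scheme, assigns junction spacers and builds the strand
#' diagram.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param scheme a \linkS4class{SegmentationScheme} (default the typical
#'   11-bp root / 10-bp stem arrangement).
#' @param policy a \linkS4class{SpacerPolicy}.
#' @param constraints optional \linkS4class{SeqConstraints} stored for
#'   later sequence generation.
#' @param warn passed to \code{\link{planEdges}}.
#' @return A \linkS4class{DesignDocument} (without sequences).
#' @examples
#' d <- designWireframe(makePolyhedron("icosahedron", 32))
#' computeStats(d)
#' @export
designWireframe <- function(graph, scheme = segmentationScheme(11, 10),
                            policy = spacerPolicy(), constraints = NULL,
                            warn = TRUE) {
    rep <- validateGraph(graph, minDomainBp = scheme@minDomainBp)
    if (any(rep$severity == "error"))
        .stopf("graph fails validation: %s",
               paste(rep$message[rep$severity == "error"], collapse = "; "))
    plans <- planEdges(graph, scheme, warn = warn)
    spacers <- assignSpacers(graph, policy)
    strands <- buildStrands(graph, plans, spacers)
    new("DesignDocument", graph = graph, plans = plans, spacers = spacers,
        strands = strands, sequences = NULL, constraints = constraints,
        metadata = list(
            tool = "wireframeDNA",
            version = as.character(utils::packageVersion("wireframeDNA")),
            shape = graph@metadata$shape,
            scheme = c(root = scheme@rootBp, stem = scheme@stemBp)))
}

#' Generate sequences for a whole design
#'
#' Runs \code{\link{generateSequences}} on the design's strand set with
#' the design's stored constraints (or the given ones) and returns the
#' design with the \code{sequences} slot filled.
#'
#' @param design a \linkS4class{DesignDocument}.
#' @param constraints a \linkS4class{SeqConstraints}; defaults to the
#'   constraints stored in the design, or \code{seqConstraints()}.
#' @param quiet passed to \code{\link{generateSequences}}.
#' @return The design with sequences.
#' @export
sequenceDesign <- function(design, constraints = NULL, quiet = TRUE) {
    if (is.null(constraints)) constraints <- design@constraints
    if (is.null(constraints)) constraints <- seqConstraints()
    design@sequences <- generateSequences(design@strands, constraints,
                                          quiet = quiet)
    design@constraints <- constraints
    design@metadata$seed <- constraints@seed
    design
}

#' DesignDocument accessors
#'
#' @param x a \linkS4class{DesignDocument}.
#' @return \code{designGraph} the \linkS4class{WireframeGraph},
#'   \code{designStrands} the \linkS4class{StrandSet},
#'   \code{strandSequences} the \code{DNAStringSet} (or NULL),
#'   \code{designConstraints} the stored \linkS4class{SeqConstraints}
#'   (or NULL).
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
designGraph <- function(x) x@graph

#' @rdname design-accessors
#' @export
designStrands <- function(x) x@strands

#' @rdname design-accessors
#' @export
strandSequences <- function(x) x@sequences

#' @rdname design-accessors
#' @export
designConstraints <- function(x) x@constraints

setMethod("show", "DesignDocument", function(object) {
    g <- object@graph
    cat(sprintf("DesignDocument '%s': %d vertices, %d edges, %d strands%s\n",
                object@metadata$shape, nVertices(g), nEdges(g),
                nStrands(object@strands),
                if (is.null(object@sequences)) " (no sequences)"
                else " (sequences generated)"))
    invisible(NULL)
})
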