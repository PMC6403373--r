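#' Write a design document to the versioned design XML
#'
#' The design XML carries the graph, segmentation plans, spacer map,
#' strand layout with the segment pairing map, generation constraints
#' and (when present) sequences. Element ordering is deterministic (by
#' id), so identical designs serialize byte-identically. The schema is
#' documented in \code{inst/schema/design-xml.md}.
#'
#' @param doc a \linkS4class{DesignDocument}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDesignXML <- function(doc, path) {
    root <- xml2::xml_new_root("wireframeDesign", version = "1.0",
                               tool = "wireframeDNA")
    md <- xml2::xml_add_child(root, "metadata")
    for (k in c("shape", "version", "seed")) {
        v <- doc@metadata[[k]]
        if (!is.null(v)) xml2::xml_set_attr(md, k, as.character(v))
    }
    sc <- doc@plans@scheme
    xml2::xml_add_child(md, "scheme", root_bp = sc@rootBp, stem_bp = sc@stemBp,
                        min_domain_bp = sc@minDomainBp,
                        preferred_min_bp = sc@preferredMinBp)

    g <- doc@graph
    gx <- xml2::xml_add_child(root, "graph")
    fmt <- function(x) sprintf("%.9g", x)
    v <- g@vertices
    for (r in seq_len(nrow(v)))
        xml2::xml_add_child(gx, "vertex", id = v$id[r], x = fmt(v$x[r]),
                            y = fmt(v$y[r]), z = fmt(v$z[r]))
    e <- g@edges
    for (r in seq_len(nrow(e)))
        xml2::xml_add_child(gx, "edge", id = e$id[r], v1 = e$v1[r],
                            v2 = e$v2[r], length_bp = e$length_bp[r],
                            role = e$role[r])
    for (f in g@faces)
        xml2::xml_add_child(gx, "face", vertices = paste(f, collapse = " "))

    px <- xml2::xml_add_child(root, "plans")
    pl <- doc@plans@plans
    for (eid in names(pl))
        xml2::xml_add_child(px, "plan", edge = eid,
                            domains = paste(pl[[eid]], collapse = " "))

    sx <- xml2::xml_add_child(root, "spacers")
    for (vid in names(doc@spacers))
        xml2::xml_add_child(sx, "spacer", vertex = vid,
                            nt = doc@spacers[[vid]])

    ss <- doc@strands
    stx <- xml2::xml_add_child(root, "strands")
    seqs <- if (!is.null(doc@sequences)) {
        x <- as.character(doc@sequences); names(x) <- names(doc@sequences); x
    } else NULL
    st <- ss@strands; dm <- ss@domains
    for (r in seq_len(nrow(st))) {
        at <- list(id = st$id[r], name = st$name[r], role = st$role[r],
                   length = st$length[r])
        if (!is.na(st$vertex[r])) at$vertex <- st$vertex[r]
        if (!is.na(st$edge[r])) at$edge <- st$edge[r]
        if (!is.null(seqs)) at$sequence <- unname(seqs[st$name[r]])
        node <- do.call(xml2::xml_add_child,
                        c(list(stx, "strand"), lapply(at, as.character)))
        dd <- dm[dm$strand == st$id[r], , drop = FALSE]
        dd <- dd[order(dd$index), , drop = FALSE]
        for (q in seq_len(nrow(dd))) {
            da <- list(id = dd$id[q], index = dd$index[q],
                       length = dd$length[q], role = dd$role[q])
            if (!is.na(dd$partner[q])) da$partner <- dd$partner[q]
            if (!is.na(dd$edge[q])) da$edge <- dd$edge[q]
            if (!is.na(dd$start[q])) da$start <- dd$start[q]
            do.call(xml2::xml_add_child,
                    c(list(node, "domain"), lapply(da, as.character)))
        }
    }
    mods <- ss@modifications
    if (nrow(mods)) {
        mx <- xml2::xml_add_child(root, "modifications")
        for (r in seq_len(nrow(mods)))
            xml2::xml_add_child(mx, "modification", strand = mods$strand[r],
                                position = mods$position[r],
                                label = mods$label[r])
    }
    cons <- doc@constraints
    if (!is.null(cons)) {
        cx <- xml2::xml_add_child(root, "constraints", k = cons@k,
                                  max_run = cons@maxRun, seed = cons@seed,
                                  max_restarts = cons@maxRestarts,
                                  backtrack_window = cons@backtrackWindow,
                                  spacer_strict = tolower(cons@spacerStrict))
        fm <- cons@fixedMotifs
        for (r in seq_len(nrow(fm)))
            xml2::xml_add_child(cx, "fixedMotif", strand = fm$strand[r],
                                position = fm$position[r], motif = fm$motif[r])
        for (m in cons@forbiddenMotifs)
            xml2::xml_add_child(cx, "forbiddenMotif", motif = m)
    }
    xml2::write_xml(root, path)
    invisible(path)
}

#' Read a design document from design XML
#'
#' @param path a file written by \code{\link{writeDesignXML}}.
#' @return A \linkS4class{DesignDocument}; \code{read(write(doc))} equals
#'   \code{doc}.
#' @export
readDesignXML <- function(path) {
    x <- xml2::read_xml(path)
    if (xml2::xml_name(x) != "wireframeDesign")
        .stopf("not a wireframeDesign XML file: %s", path)
    attrs <- function(nodes, name) xml2::xml_attr(nodes, name)
    gx <- xml2::xml_find_first(x, "./graph")
    vn <- xml2::xml_find_all(gx, "./vertex")
    vertices <- data.frame(id = as.integer(attrs(vn, "id")),
                           x = as.numeric(attrs(vn, "x")),
                           y = as.numeric(attrs(vn, "y")),
                           z = as.numeric(attrs(vn, "z")))
    en <- xml2::xml_find_all(gx, "./edge")
    edges <- data.frame(id = as.integer(attrs(en, "id")),
                        v1 = as.integer(attrs(en, "v1")),
                        v2 = as.integer(attrs(en, "v2")),
                        length_bp = as.integer(attrs(en, "length_bp")),
                        role = attrs(en, "role"))
    fn <- xml2::xml_find_all(gx, "./face")
    faces <- lapply(attrs(fn, "vertices"), function(s)
        as.integer(strsplit(s, " ", fixed = TRUE)[[1]]))
    md <- xml2::xml_find_first(x, "./metadata")
    shape <- xml2::xml_attr(md, "shape")
    graph <- new("WireframeGraph", vertices = vertices,
                 edges = edges, faces = faces,
                 metadata = list(shape = shape))
    validObject(graph)

    scn <- xml2::xml_find_first(md, "./scheme")
    scheme <- segmentationScheme(
        as.integer(xml2::xml_attr(scn, "root_bp")),
        as.integer(xml2::xml_attr(scn, "stem_bp")),
        as.integer(xml2::xml_attr(scn, "min_domain_bp")),
        as.integer(xml2::xml_attr(scn, "preferred_min_bp")))
    pn <- xml2::xml_find_all(x, "./plans/plan")
    plans <- lapply(attrs(pn, "domains"), function(s)
        as.integer(strsplit(s, " ", fixed = TRUE)[[1]]))
    names(plans) <- attrs(pn, "edge")
    planset <- new("EdgePlanSet", plans = plans, scheme = scheme)

    sn <- xml2::xml_find_all(x, "./spacers/spacer")
    spacers <- as.integer(attrs(sn, "nt"))
    names(spacers) <- attrs(sn, "vertex")

    stn <- xml2::xml_find_all(x, "./strands/strand")
    strands <- data.frame(id = as.integer(attrs(stn, "id")),
                          name = attrs(stn, "name"),
                          role = attrs(stn, "role"),
                          vertex = as.integer(attrs(stn, "vertex")),
                          edge = as.integer(attrs(stn, "edge")),
                          length = as.integer(attrs(stn, "length")))
    dn <- xml2::xml_find_all(x, "./strands/strand/domain")
    parent_id <- vapply(dn, function(n)
        as.integer(xml2::xml_attr(xml2::xml_parent(n), "id")), integer(1))
    domains <- data.frame(id = as.integer(attrs(dn, "id")),
                          strand = parent_id,
                          index = as.integer(attrs(dn, "index")),
                          length = as.integer(attrs(dn, "length")),
                          role = attrs(dn, "role"),
                          partner = as.integer(attrs(dn, "partner")),
                          edge = as.integer(attrs(dn, "edge")),
                          start = as.integer(attrs(dn, "start")))
    domains <- domains[order(domains$id), , drop = FALSE]
    rownames(domains) <- NULL
    mn <- xml2::xml_find_all(x, "./modifications/modification")
    mods <- data.frame(strand = as.integer(attrs(mn, "strand")),
                       position = as.integer(attrs(mn, "position")),
                       label = attrs(mn, "label"))
    ss <- new("StrandSet", strands = strands, domains = domains,
              graph = graph, plans = planset, spacers = spacers,
              modifications = mods)
    validObject(ss)

    cx <- xml2::xml_find_first(x, "./constraints")
    cons <- NULL
    if (!inherits(cx, "xml_missing")) {
        fmn <- xml2::xml_find_all(cx, "./fixedMotif")
        fm <- data.frame(strand = as.integer(attrs(fmn, "strand")),
                         position = as.integer(attrs(fmn, "position")),
                         motif = attrs(fmn, "motif"))
        cons <- seqConstraints(
            k = as.integer(xml2::xml_attr(cx, "k")),
            maxRun = as.integer(xml2::xml_attr(cx, "max_run")),
            fixedMotifs = fm,
            forbiddenMotifs = attrs(
                xml2::xml_find_all(cx, "./forbiddenMotif"), "motif"),
            seed = as.integer(xml2::xml_attr(cx, "seed")),
            maxRestarts = as.integer(xml2::xml_attr(cx, "max_restarts")),
            backtrackWindow = as.integer(xml2::xml_attr(cx, "backtrack_window")),
            spacerStrict = xml2::xml_attr(cx, "spacer_strict") == "true")
    }
    seqs <- NULL
    sq <- attrs(stn, "sequence")
    if (!all(is.na(sq))) {
        seqs <- Biostrings::DNAStringSet(sq)
        names(seqs) <- strands$name
    }
    meta <- list(tool = "wireframeDNA",
                 version = xml2::xml_attr(md, "version"),
                 shape = shape,
                 scheme = c(root = scheme@rootBp, stem = scheme@stemBp))
    sd <- xml2::xml_attr(md, "seed")
    if (!is.na(sd)) meta$seed <- as.integer(sd)
    new("DesignDocument", graph = graph, plans = planset, spacers = spacers,
        strands = ss, sequences = seqs, constraints = cons, metadata = meta)
}

#' Write / read a wireframe graph as JSON
#'
#' A lightweight interchange format for user-supplied graphs: vertices
#' with nm coordinates, edges with bp lengths and roles, optional faces.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param path file path.
#' @return \code{writeGraphJSON} returns \code{path} invisibly;
#'   \code{readGraphJSON} returns the \linkS4class{WireframeGraph}.
#' @name graph-json
NULL

#' @rdname graph-json
#' @export
writeGraphJSON <- function(graph, path) {
    obj <- list(schema = "wireframeDNA-graph-1",
                shape = graph@metadata$shape,
                vertices = graph@vertices,
                edges = graph@edges,
                faces = lapply(graph@faces, identity))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname graph-json
#' @export
readGraphJSON <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    faces <- if (length(obj$faces)) lapply(obj$faces, as.integer) else list()
    g <- new("WireframeGraph",
             vertices = as.data.frame(obj$vertices),
             edges = as.data.frame(obj$edges),
             faces = .canonicalizeFaces(faces),
             metadata = list(shape = obj$shape))
    validObject(g)
    g
}

#' Export strands for synthesis
#'
#' FASTA records are named by strand name (via
#' \code{Biostrings::writeXStringSet}); CSV has columns \code{name},
#' \code{sequence}, \code{length_nt}, \code{role}, \code{modifications}.
#' Ordering follows strand ids, so output is stable across runs.
#'
#' @param doc a \linkS4class{DesignDocument} with sequences.
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
exportStrands <- function(doc, path, format = c("fasta", "csv")) {
    format <- match.arg(format)
    if (is.null(doc@sequences))
        .stopf("no sequences in the design; run sequenceDesign() first")
    st <- doc@strands@strands
    seqs <- doc@sequences[st$name]
    if (format == "fasta") {
        Biostrings::writeXStringSet(seqs, filepath = path)
    } else {
        mods <- doc@strands@modifications
        modcol <- vapply(st$id, function(sid) {
            mm <- mods[mods$strand == sid, , drop = FALSE]
            if (!nrow(mm)) return("")
            paste(sprintf("%s@%d", mm$label, mm$position), collapse = ";")
        }, character(1))
        df <- data.frame(name = st$name,
                         sequence = as.character(seqs),
                         length_nt = st$length,
                         role = st$role,
                         modifications = modcol)
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' Export the wireframe mesh as a Wavefront OBJ file
#'
#' Vertices in nm; edges as OBJ line elements, faces as polygon faces.
#' Visualization-only.
#'
#' @param graph a \linkS4class{WireframeGraph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportOBJ <- function(graph, path) {
    v <- graph@vertices
    idx <- match(v$id, v$id)
    lines <- c("# wireframeDNA mesh (nm)",
               sprintf("v %.6f %.6f %.6f", v$x, v$y, v$z))
    remap <- seq_len(nrow(v)); names(remap) <- v$id
    e <- graph@edges
    if (nrow(e))
        lines <- c(lines, sprintf("l %d %d", remap[as.character(e$v1)],
                                  remap[as.character(e$v2)]))
    for (f in graph@faces)
        lines <- c(lines, paste("f", paste(remap[as.character(f)],
                                           collapse = " ")))
    writeLines(lines, path)
    invisible(path)
}
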