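#' Generate a wireframe tube, donut or bent tube
#'
#' A tube is a triangulated cylindrical mesh of 6-arm vertices:
#' \code{rings} rings of \code{circumference} vertices, joined by
#' circumferential, axial and diagonal edges. \code{"donut"} closes the
#' long axis into a torus. \code{"bent"} places the rings on a circular
#' arc of \code{bendAngleDeg}; the length of each longitudinal
#' (axial/diagonal) edge is scaled by the ratio of its local radius to
#' the centerline radius - shorter on the concave (inner) side, longer
#' on the convex (outer) side - then rounded to full turns.
#' Reinforcement struts are simple duplex chords across the lumen in the
#' bend plane, placed in evenly spaced rings.
#'
#' @param circumference vertices per ring (>= 3).
#' @param rings number of vertex rings (>= 2 for straight/bent, >= 3 for
#'   donut).
#' @param edgeBp base edge length in bp.
#' @param mode \code{"straight"}, \code{"donut"} or \code{"bent"}.
#' @param bendAngleDeg bend angle in degrees (bent mode; 0 < angle <= 180).
#' @param struts number of reinforcement struts (>= 0).
#' @param minDomainBp feasibility floor: a bend requiring a longitudinal
#'   edge shorter than \code{2 * minDomainBp} is an error.
#' @return A \linkS4class{WireframeGraph} (faces are not populated for
#'   tubes; the mesh is already triangulated).
#' @examples
#' makeTube(8, 6, 32)                       # straight tube, all edges 32 bp
#' @export
makeTube <- function(circumference, rings, edgeBp = 32L,
                     mode = c("straight", "donut", "bent"),
                     bendAngleDeg = NA_real_, struts = 0L,
                     minDomainBp = 6L) {
    mode <- match.arg(mode)
    if (!.is_count(circumference, 3L)) .stopf("circumference must be >= 3")
    if (!.is_count(rings, 2L)) .stopf("rings must be >= 2")
    if (mode == "donut" && rings < 3L) .stopf("a donut needs >= 3 rings")
    if (!.is_count(struts, 0L)) .stopf("struts must be >= 0")
    if (mode == "bent") {
        if (!is.finite(bendAngleDeg) || bendAngleDeg <= 0 || bendAngleDeg > 180)
            .stopf("bent mode requires 0 < bendAngleDeg <= 180")
    }
    n <- as.integer(circumference); m <- as.integer(rings)
    h <- edgeBp * .BP_NM                   # axial step, nm
    rho <- n * edgeBp * .BP_NM / (2 * pi)  # tube radius, nm
    phi <- 2 * pi * (seq_len(n) - 1L) / n  # phi = 0 faces the convex side

    closed <- mode == "donut"
    ngap <- if (closed) m else m - 1L
    if (mode == "straight") {
        Rc <- Inf
        theta <- 0
    } else if (mode == "bent") {
        theta <- bendAngleDeg * pi / 180
        Rc <- ngap * h / theta
    } else {
        theta <- 2 * pi
        Rc <- ngap * h / theta
    }

    vid <- function(r, i) r * n + i + 1L   # r in 0..m-1, i in 0..n-1
    v <- NULL
    for (r in 0:(m - 1L)) {
        if (mode == "straight") {
            cx <- 0; cz <- r * h
            ax <- c(1, 0, 0); az <- c(0, 0, 1)  # unused
            px <- rho * cos(phi); py <- rho * sin(phi)
            v <- rbind(v, data.frame(id = vid(r, 0:(n - 1L)),
                                     x = px, y = py, z = cz))
        } else {
            a <- r * theta / ngap
            # centerline in the xz-plane; phi = 0 points away from the
            # bend centre (convex side)
            ctr <- c(Rc * sin(a), 0, -Rc * cos(a) + Rc)
            u_r <- c(sin(a), 0, -cos(a))   # outward radial direction
            u_y <- c(0, 1, 0)
            px <- ctr[1] + rho * (cos(phi) * u_r[1]) + rho * sin(phi) * u_y[1]
            py <- ctr[2] + rho * cos(phi) * u_r[2] + rho * sin(phi) * u_y[2]
            pz <- ctr[3] + rho * cos(phi) * u_r[3] + rho * sin(phi) * u_y[3]
            v <- rbind(v, data.frame(id = vid(r, 0:(n - 1L)), x = px, y = py,
                                     z = pz))
        }
    }

    # local-radius scale factor for longitudinal edges at ring position i
    lscale <- function(i1, i2) {
        if (mode == "straight") return(1)
        r1 <- Rc + rho * cos(phi[i1 + 1L]); r2 <- Rc + rho * cos(phi[i2 + 1L])
        (r1 + r2) / (2 * Rc)
    }
    e <- NULL
    addE <- function(e, a, b, bp, role = "frame")
        rbind(e, data.frame(v1 = a, v2 = b, length_bp = bp, role = role))
    for (r in 0:(m - 1L)) {
        for (i in 0:(n - 1L)) {
            ip1 <- (i + 1L) %% n
            e <- addE(e, vid(r, i), vid(r, ip1), edgeBp)        # circumferential
            if (r < m - 1L || closed) {
                r2 <- (r + 1L) %% m
                sc_a <- lscale(i, i)
                sc_d <- lscale(i, ip1)
                bp_a <- if (mode == "straight") edgeBp else
                    quantizeFullTurns(max(edgeBp * sc_a, 5.25))
                bp_d <- if (mode == "straight") edgeBp else
                    quantizeFullTurns(max(edgeBp * sc_d, 5.25))
                if (mode != "straight" &&
                    min(bp_a, bp_d) < 2L * minDomainBp)
                    .stopf(paste0("bend requires a longitudinal edge of %d bp,",
                                  " below the 2 x minDomainBp floor (%d bp);",
                                  " use more rings or a smaller circumference"),
                           min(bp_a, bp_d), 2L * minDomainBp)
                e <- addE(e, vid(r, i), vid(r2, i), bp_a)       # axial
                e <- addE(e, vid(r, i), vid(r2, ip1), bp_d)     # diagonal
            }
        }
    }

    # struts: chords across the lumen in the bend plane, evenly spaced rings
    if (struts > 0L) {
        if (n < 4L) .stopf("struts need circumference >= 4")
        srings <- unique(round(seq(0L, m - 1L, length.out = struts)))
        k <- 0L; ridx <- srings
        while (length(ridx) < struts) {     # top up if rounding collapsed
            cand <- setdiff(0:(m - 1L), ridx)
            ridx <- sort(c(ridx, cand[seq_len(struts - length(ridx))]))
        }
        iin <- as.integer(round(n / 2))     # phi ~ pi: concave side
        iout <- 0L                          # phi = 0: convex side
        strut_bp <- quantizeFullTurns(2 * rho / .BP_NM)
        for (r in ridx[seq_len(struts)])
            e <- addE(e, vid(r, iout), vid(r, iin), strut_bp, role = "strut")
    }

    g <- wireframeGraph(v, e,
        metadata = list(shape = paste0(mode, "_tube"), mode = mode,
                        circumference = n, rings = m, edge_bp = edgeBp,
                        bend_angle_deg = bendAngleDeg, struts = struts))
    validObject(g)
    g
}
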