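#' Create sequence-generation constraints
#'
#' The generator draws free bases uniformly one by one (5'->3', strand by
#' strand), forces every partnered base to the Watson-Crick complement of
#' its partner, and enforces: no homopolymer run longer than
#' \code{maxRun}; no (k+1)-mer occurring at two locations not related by
#' designed complementarity (identical or reverse-complement occurrences
#' both count); no forbidden motif outside its fixed placements. On a
#' violation the most recent free base is redrawn without replacement;
#' exhausted positions trigger chronological backtracking up to
#' \code{backtrackWindow} free positions, then a restart with a fresh
#' random stream.
#'
#' @param k repeat limit, 7 or 8 (default 8: no 9-mer repeats).
#' @param maxRun maximum homopolymer run (default 3).
#' @param fixedMotifs data.frame(strand, position, motif): bases forced
#'   verbatim; \code{strand} may be a strand id or name; \code{position}
#'   is 1-based within the strand.
#' @param forbiddenMotifs character vector of motifs excluded outside
#'   fixed placements (occurrences on either duplex side count).
#' @param seed integer RNG seed (Mersenne-Twister, locally scoped).
#' @param maxRestarts restart budget (default 20).
#' @param backtrackWindow free positions a backtrack may unwind
#'   (default 16).
#' @param spacerStrict if TRUE (default) spacer Ts participate in run and
#'   k-mer scans; FALSE reproduces the looser convention of appending
#'   spacers after sequence assignment.
#' @return A \linkS4class{SeqConstraints}.
#' @export
seqConstraints <- function(k = 8L, maxRun = 3L,
                           fixedMotifs = data.frame(strand = integer(),
                                                    position = integer(),
                                                    motif = character()),
                           forbiddenMotifs = character(), seed = 1L,
                           maxRestarts = 20L, backtrackWindow = 16L,
                           spacerStrict = TRUE) {
    x <- new("SeqConstraints", k = as.integer(k), maxRun = as.integer(maxRun),
             fixedMotifs = as.data.frame(fixedMotifs),
             forbiddenMotifs = toupper(forbiddenMotifs),
             seed = as.integer(seed), maxRestarts = as.integer(maxRestarts),
             backtrackWindow = as.integer(backtrackWindow),
             spacerStrict = isTRUE(spacerStrict))
    validObject(x)
    x
}

# Flatten a StrandSet into base-level arrays: global positions are
# concatenated strand sequences (strands in id order, 5'->3'). Returns
# strand offsets, the base-level partner involution and the spacer mask.
# This is the data contract of the layout, shared by the generator and
# the verifier (the scanning logic is not shared).
.basePairingMap <- function(strandset) {
    s <- strandset@strands[order(strandset@strands$id), , drop = FALSE]
    d <- strandset@domains
    offset <- c(0L, cumsum(s$length))
    names(offset) <- c(as.character(s$id), "end")
    N <- sum(s$length)
    partner <- integer(N)
    spacer <- logical(N)
    d <- d[order(d$strand, d$index), , drop = FALSE]
    # map domain id -> global 0-based start position
    gstart <- integer(max(d$id))
    pos <- 0L; cur <- -1L
    for (r in seq_len(nrow(d))) {
        if (d$strand[r] != cur) {
            cur <- d$strand[r]
            pos <- offset[[as.character(cur)]]
        }
        gstart[d$id[r]] <- pos
        pos <- pos + d$length[r]
    }
    for (r in seq_len(nrow(d))) {
        if (d$role[r] == "spacer") {
            spacer[gstart[d$id[r]] + seq_len(d$length[r])] <- TRUE
        } else if (!is.na(d$partner[r])) {
            len <- d$length[r]
            a <- gstart[d$id[r]]; b <- gstart[d$partner[r]]
            partner[a + seq_len(len)] <- b + rev(seq_len(len))
        }
    }
    list(strands = s, offset = offset[-length(offset)], N = N,
         partner = partner, spacer = spacer,
         strand_of = rep(s$id, s$length),
         pos_in_strand = unlist(lapply(s$length, seq_len), use.names = FALSE))
}

#' Populate a strand set with nucleotide sequences
#'
#' @param strandset a \linkS4class{StrandSet}.
#' @param constraints a \linkS4class{SeqConstraints}.
#' @param quiet suppress the progress message.
#' @return A \code{DNAStringSet} named by strand name (the sequence
#'   assignment).
#' @examples
#' g <- makePolyhedron("tetrahedron", 32)
#' ss <- buildStrands(g, planEdges(g, segmentationScheme(11, 10)))
#' seqs <- generateSequences(ss, seqConstraints(seed = 7))
#' @export
generateSequences <- function(strandset, constraints = seqConstraints(),
                              quiet = TRUE) {
    bp <- .basePairingMap(strandset)
    N <- bp$N
    K <- constraints@k                 # windows have K + 1 bases
    W <- K + 1L
    maxRun <- constraints@maxRun
    strict <- constraints@spacerStrict
    partner <- bp$partner
    pis <- bp$pos_in_strand
    sof <- bp$strand_of

    # fixed bases: spacer Ts plus fixed motifs (complements propagated)
    fixed <- integer(N)
    fixed[bp$spacer] <- 4L             # T
    fm <- constraints@fixedMotifs
    if (nrow(fm)) {
        sid <- fm$strand
        if (is.character(sid)) {
            sid <- strandset@strands$id[match(sid, strandset@strands$name)]
            if (anyNA(sid)) .stopf("fixed motif on unknown strand name")
        }
        for (r in seq_len(nrow(fm))) {
            off <- bp$offset[[as.character(sid[r])]]
            mv <- .seq_to_int(toupper(fm$motif[r]))
            idx <- off + fm$position[r] - 1L + seq_along(mv)
            if (max(idx) > N || any(sof[idx] != sid[r]))
                .stopf("fixed motif outside strand bounds")
            for (t in seq_along(mv)) {
                g <- idx[t]
                if (fixed[g] && fixed[g] != mv[t])
                    .stopf("conflicting fixed bases at strand %s position %d",
                           sid[r], fm$position[r] + t - 1L)
                fixed[g] <- mv[t]
                pg <- partner[g]
                if (pg > 0L) {
                    cv <- .comp_int(mv[t])
                    if (fixed[pg] && fixed[pg] != cv)
                        .stopf("fixed motif conflicts with a partner constraint")
                    fixed[pg] <- cv
                }
            }
        }
    }
    forb <- lapply(constraints@forbiddenMotifs, .seq_to_int)
    forb <- c(forb, lapply(constraints@forbiddenMotifs,
                           function(m) .comp_int(rev(.seq_to_int(m)))))
    if (length(forb)) forb <- unique(forb)

    # strand extent of every position (windows never span strands)
    sstart <- integer(N); send <- integer(N)
    {
        off <- bp$offset; lens <- bp$strands$length
        for (r in seq_along(lens)) {
            idx <- off[[r]] + seq_len(lens[r])
            sstart[idx] <- off[[r]] + 1L
            send[idx] <- off[[r]] + lens[r]
        }
    }

    result <- .with_seed(constraints@seed, {
        restarts <- 0L
        last_violation <- "none"
        cp <- utf8ToInt("ACGT")     # fast window keys via intToUtf8

        repeat {
            bases <- fixed            # spacers and fixed motifs pre-placed
            reg <- new.env(parent = emptyenv())
            registered <- character(N)   # window key registered at end pos
            rlist <- vector("list", N)   # window ends registered per placement
            cand <- vector("list", N)
            attempts <- 0L
            attempt_cap <- 60L * N + 1000L
            reshuffles <- 0L
            episode_work <- 0L
            hw <- 0L
            conflict <- integer(0)
            instack <- logical(N)
            failed <- FALSE

            wkey <- function(e) intToUtf8(cp[bases[(e - K):e]])
            wrckey <- function(e) intToUtf8(cp[5L - bases[e:(e - K)]])

            # register the (k+1)-window ending at e; FALSE on an
            # unrelated duplicate (identical or reverse-complement)
            regWindow <- function(e) {
                w <- wkey(e)
                occ <- c(reg[[w]], reg[[wrckey(e)]])
                if (length(occ)) {
                    pw <- rev(partner[(e - K):e])
                    for (q in occ) {
                        if (!identical(pw, (q - K):q)) {
                            last_violation <<- "repeating segment"
                            conflict <<- c((e - K):e, (q - K):q)
                            return(FALSE)
                        }
                    }
                }
                reg[[w]] <- c(reg[[w]], e)
                registered[e] <<- w
                TRUE
            }
            unregWindow <- function(e) {
                ky <- registered[e]
                if (nzchar(ky)) {
                    v <- reg[[ky]]
                    v <- v[v != e]
                    if (length(v)) reg[[ky]] <- v else rm(list = ky, envir = reg)
                    registered[e] <<- ""
                }
            }
            # constraint scan around a newly set position x:
            # maximal homopolymer run through x, forbidden motifs
            # containing x, and every (k+1)-window containing x that is
            # now complete. Newly registered ends accumulate in `newe`.
            newe <- integer(0)
            scanAt <- function(x) {
                v <- bases[x]
                l <- x
                while (l > sstart[x] && bases[l - 1L] == v) l <- l - 1L
                r <- x
                while (r < send[x] && bases[r + 1L] == v) r <- r + 1L
                if (r - l + 1L > maxRun &&
                    (strict || !any(bp$spacer[l:r]))) {
                    last_violation <<- "homopolymer run"
                    conflict <<- l:r
                    return(FALSE)
                }
                for (mv in forb) {
                    lm <- length(mv)
                    for (s0 in max(sstart[x], x - lm + 1L):
                               min(x, send[x] - lm + 1L)) {
                        sl <- bases[s0:(s0 + lm - 1L)]
                        if (all(sl == mv) &&
                            !all(fixed[s0:(s0 + lm - 1L)] > 0L)) {
                            last_violation <<- "forbidden motif"
                            conflict <<- s0:(s0 + lm - 1L)
                            return(FALSE)
                        }
                    }
                }
                for (e in max(x, sstart[x] + K):min(x + K, send[x])) {
                    if (nzchar(registered[e])) next
                    win <- bases[(e - K):e]
                    if (any(win == 0L)) next
                    if (!strict && any(bp$spacer[(e - K):e])) next
                    if (!regWindow(e)) return(FALSE)
                    newe <<- c(newe, e)
                }
                TRUE
            }
            place <- function(i, v) {
                bases[i] <<- v
                p <- partner[i]
                if (p > 0L) bases[p] <<- .comp_int(v)
                newe <<- integer(0)
                ok <- scanAt(i) && (p == 0L || scanAt(p))
                if (!ok) {
                    for (e in newe) unregWindow(e)
                    bases[i] <<- 0L
                    if (p > 0L) bases[p] <<- 0L
                }
                ok
            }
            undo <- function(i) {
                for (e in rlist[[i]]) unregWindow(e)
                rlist[i] <<- list(NULL)
                bases[i] <<- 0L
                p <- partner[i]
                if (p > 0L) bases[p] <<- 0L
            }

            # windows fully determined by fixed bases (inside spacers and
            # fixed-motif placements) are registered up front
            ok0 <- TRUE
            for (x in which(fixed > 0L)) {
                newe <- integer(0)
                if (!scanAt(x)) { ok0 <- FALSE; break }
            }
            if (!ok0)
                .stopf("fixed bases alone violate the rules (%s)",
                       last_violation)

            stack <- integer(0)      # placed free positions, in order
            i <- 1L
            while (i <= N) {
                if (bases[i] > 0L) { i <- i + 1L; next }
                if (is.null(cand[[i]])) cand[[i]] <- sample(4L)
                placed <- FALSE
                while (length(cand[[i]])) {
                    attempts <- attempts + 1L
                    if (i <= hw) episode_work <- episode_work + 1L
                    if (attempts > attempt_cap) break
                    if (place(i, cand[[i]][1L])) {
                        rlist[[i]] <- newe
                        stack <- c(stack, i)
                        placed <- TRUE
                        break
                    }
                    cand[[i]] <- cand[[i]][-1L]
                }
                if (attempts > attempt_cap) { failed <- TRUE; break }
                if (placed) {
                    instack[i] <- TRUE
                    if (i > hw) { hw <- i; episode_work <- 0L }
                    i <- i + 1L
                    next
                }
                # backtrack chronologically over placed free positions;
                # when the local window has been churned too long, jump
                # to the most recent free variable of the last conflict
                # that lies beyond the local window (typically a junction
                # base controlling a forced root region)
                cand[i] <- list(NULL)
                if (episode_work > 3000L) {
                    episode_work <- 0L
                    reshuffles <- reshuffles + 1L
                    if (reshuffles > 500L) { failed <- TRUE; break }
                    tg <- unique(c(conflict, partner[conflict]))
                    tg <- tg[tg > 0L]
                    tg <- tg[instack[tg]]
                    sp <- match(tg, stack)
                    keep <- sp <= length(stack) - constraints@backtrackWindow
                    jt <- if (any(keep)) tg[which.max(sp * keep)]
                          else if (length(tg)) tg[which.min(sp)]
                          else NA_integer_
                    if (!is.na(jt)) {
                        while (length(stack)) {
                            j <- stack[length(stack)]
                            stack <- stack[-length(stack)]
                            instack[j] <- FALSE
                            undo(j)
                            if (j == jt) break
                        }
                        if (length(cand[[jt]]) > 1L) {
                            cand[[jt]] <- cand[[jt]][-1L]
                        } else cand[jt] <- list(NULL)
                        i <- jt
                        next
                    }
                }
                depth <- 0L
                repeat {
                    if (!length(stack)) { failed <- TRUE; break }
                    j <- stack[length(stack)]
                    stack <- stack[-length(stack)]
                    instack[j] <- FALSE
                    undo(j)
                    depth <- depth + 1L
                    if (depth > constraints@backtrackWindow) {
                        # spent the window: re-randomize it and go on
                        reshuffles <- reshuffles + 1L
                        if (reshuffles > 1000L) { failed <- TRUE; break }
                        cand[j] <- list(NULL)
                        i <- j
                        break
                    }
                    if (length(cand[[j]]) > 1L) {
                        cand[[j]] <- cand[[j]][-1L]
                        i <- j
                        break
                    }
                    cand[j] <- list(NULL)
                }
                if (failed) break
            }
            if (!failed) break
            restarts <- restarts + 1L
            if (restarts > constraints@maxRestarts)
                .stopf(paste0("sequence generation failed after %d restarts; ",
                              "binding constraint: %s (consider k = 8 or a ",
                              "smaller design)"),
                       restarts - 1L, last_violation)
            if (!quiet) message("seqgen: restart ", restarts)
        }
        bases
    })

    s <- bp$strands
    seqs <- vapply(seq_len(nrow(s)), function(r) {
        idx <- bp$offset[[as.character(s$id[r])]] + seq_len(s$length[r])
        paste(.BASES[result[idx]], collapse = "")
    }, character(1))
    names(seqs) <- s$name
    Biostrings::DNAStringSet(seqs)
}

#' Feasibility estimate for the repeat-segment rule
#'
#' Counts the (k+1)-base windows the design will consume against the
#' 4^(k+1) possible words. Because every used window also excludes its
#' reverse complement, the usable space is half that. Random sequential
#' generation saturates well below full occupancy; occupancies above 0.9
#' are classified infeasible and above \code{warnRatio} a warning is
#' attached.
#'
#' @param strandset a \linkS4class{StrandSet}.
#' @param k repeat limit (window length is k+1).
#' @param warnRatio occupancy above which a warning is attached
#'   (default 0.5).
#' @return List with \code{windowsNeeded}, \code{windowsAvailable}
#'   (4^(k+1)/2 after reverse-complement exclusion), \code{occupancy}
#'   and \code{feasible}.
#' @export
kmerCapacityCheck <- function(strandset, k = 8L, warnRatio = 0.5) {
    lens <- strandset@strands$length
    needed <- sum(pmax(0L, lens - as.integer(k)))
    avail <- 4^(k + 1) / 2
    occ <- needed / avail
    feasible <- occ < 0.9
    if (!feasible)
        warning(sprintf(
            "k = %d infeasible for this design: occupancy %.2f (>= 0.9)",
            k, occ), call. = FALSE)
    else if (occ > warnRatio)
        warning(sprintf("k = %d occupancy %.2f above %.2f: generation may be slow",
                        k, occ, warnRatio), call. = FALSE)
    list(windowsNeeded = needed, windowsAvailable = avail,
         occupancy = occ, feasible = feasible)
}
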