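#' Independently verify a sequence assignment
#'
#' Re-scans an assignment against the design rules with logic independent
#' of the generator: complementarity is checked domain-by-domain with
#' \code{Biostrings::reverseComplement}, homopolymer runs with run-length
#' encoding, the repeat-segment rule by brute-force enumeration of all
#' (k+1)-windows grouped by canonical (min of window and reverse
#' complement) form, and motif placements by exact string search. Only
#' the layout's base-level pairing map - the design contract - is shared
#' with the generator.
#'
#' @param strandset a \linkS4class{StrandSet}.
#' @param assignment a named \code{DNAStringSet} or character vector
#'   covering every strand.
#' @param constraints the \linkS4class{SeqConstraints} the assignment
#'   should satisfy.
#' @return data.frame report with columns \code{type}, \code{strand},
#'   \code{position}, \code{detail}; zero rows iff all rules hold.
#' @export
verifySequences <- function(strandset, assignment,
                            constraints = seqConstraints()) {
    s <- strandset@strands[order(strandset@strands$id), , drop = FALSE]
    nm <- names(assignment)
    seqs <- as.character(assignment)
    names(seqs) <- nm
    if (is.null(names(seqs))) .stopf("assignment must be named by strand name")
    miss <- setdiff(s$name, names(seqs))
    if (length(miss))
        .stopf("assignment missing strand(s): %s", paste(miss, collapse = ", "))
    seqs <- seqs[s$name]
    if (!all(nchar(seqs) == s$length))
        .stopf("assignment lengths do not match the strand layout")

    rep <- list()
    addv <- function(type, strand, position, detail)
        rep[[length(rep) + 1L]] <<- data.frame(type = type, strand = strand,
                                               position = position,
                                               detail = detail)
    bp <- .basePairingMap(strandset)
    big <- paste(seqs, collapse = "")        # global coordinates match bp
    bigv <- strsplit(big, "", fixed = TRUE)[[1]]

    # complementarity: each partnered base must complement its partner
    has <- which(bp$partner > 0L)
    pv <- bp$partner[has]
    compl <- chartr("ACGT", "TGCA", big)
    complv <- strsplit(compl, "", fixed = TRUE)[[1]]
    bad <- has[bigv[has] != complv[pv]]
    for (g in bad)
        addv("complementarity", s$name[match(bp$strand_of[g], s$id)],
             bp$pos_in_strand[g], "base does not complement its partner")

    # spacers must be T
    spc <- which(bp$spacer)
    badT <- spc[bigv[spc] != "T"]
    for (g in badT)
        addv("spacer", s$name[match(bp$strand_of[g], s$id)],
             bp$pos_in_strand[g], "spacer base is not T")

    # homopolymer runs per strand
    for (r in seq_len(nrow(s))) {
        rl <- rle(strsplit(seqs[r], "", fixed = TRUE)[[1]])
        ends <- cumsum(rl$lengths)
        for (j in which(rl$lengths > constraints@maxRun)) {
            if (!constraints@spacerStrict) {
                gidx <- bp$offset[[as.character(s$id[r])]] +
                    (ends[j] - rl$lengths[j] + 1L):ends[j]
                if (any(bp$spacer[gidx])) next
            }
            addv("run", s$name[r], ends[j],
                 sprintf("homopolymer %s x %d", rl$values[j], rl$lengths[j]))
        }
    }

    # repeat-segment rule: brute-force window enumeration
    W <- constraints@k + 1L
    winpos <- integer(0); winstr <- character(0)
    for (r in seq_len(nrow(s))) {
        n <- s$length[r]
        if (n < W) next
        st <- seq_len(n - W + 1L)
        ws <- substring(seqs[r], st, st + W - 1L)
        gend <- bp$offset[[as.character(s$id[r])]] + st + W - 1L
        keep <- rep(TRUE, length(ws))
        if (!constraints@spacerStrict)
            keep <- vapply(seq_along(st), function(t)
                !any(bp$spacer[(gend[t] - W + 1L):gend[t]]), logical(1))
        winpos <- c(winpos, gend[keep]); winstr <- c(winstr, ws[keep])
    }
    rcstr <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(winstr)))
    canon <- ifelse(winstr <= rcstr, winstr, rcstr)
    grp <- split(seq_along(winpos), canon)
    for (g in grp) {
        if (length(g) < 2L) next
        for (a in seq_along(g)) for (b in seq_along(g)) {
            if (a >= b) next
            i <- winpos[g[a]]; q <- winpos[g[b]]
            related <- identical(rev(bp$partner[(i - W + 1L):i]),
                                 (q - W + 1L):q)
            if (!related)
                addv("repeat", s$name[match(bp$strand_of[i], s$id)],
                     bp$pos_in_strand[i],
                     sprintf("window repeats at %s:%d",
                             s$name[match(bp$strand_of[q], s$id)],
                             bp$pos_in_strand[q]))
        }
    }

    # fixed motifs verbatim; forbidden motifs absent outside fixed bases
    fixedMask <- bp$spacer
    fm <- constraints@fixedMotifs
    if (nrow(fm)) {
        sid <- fm$strand
        if (is.character(sid)) sid <- s$id[match(sid, s$name)]
        for (r in seq_len(nrow(fm))) {
            off <- bp$offset[[as.character(sid[r])]]
            mseq <- toupper(fm$motif[r])
            idx <- off + fm$position[r] - 1L + seq_len(nchar(mseq))
            fixedMask[idx] <- TRUE
            pg <- bp$partner[idx]
            fixedMask[pg[pg > 0L]] <- TRUE
            have <- substr(seqs[match(sid[r], s$id)], fm$position[r],
                           fm$position[r] + nchar(mseq) - 1L)
            if (have != mseq)
                addv("fixed_motif", s$name[match(sid[r], s$id)],
                     fm$position[r],
                     sprintf("expected %s, found %s", mseq, have))
        }
    }
    for (m in unique(constraints@forbiddenMotifs)) {
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
        for (pat in unique(c(m, rc))) {
            for (r in seq_len(nrow(s))) {
                hits <- gregexpr(pat, seqs[r], fixed = TRUE)[[1]]
                hits <- hits[hits > 0L]
                for (h in hits) {
                    gidx <- bp$offset[[as.character(s$id[r])]] +
                        h:(h + nchar(pat) - 1L)
                    if (!all(fixedMask[gidx]))
                        addv("forbidden_motif", s$name[r], h,
                             sprintf("motif %s outside designed placements", pat))
                }
            }
        }
    }

    # all strand sequences pairwise distinct
    dup <- which(duplicated(seqs))
    for (r in dup)
        addv("duplicate_strand", s$name[r], 1L,
             "identical sequence to another strand")

    if (!length(rep))
        return(data.frame(type = character(), strand = character(),
                          position = integer(), detail = character()))
    out <- do.call(rbind, rep)
    rownames(out) <- NULL
    out
}
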