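test_that("generation is deterministic in the seed", {
    ss <- icosaStrands()
    a <- generateSequences(ss, seqConstraints(seed = 11))
    b <- generateSequences(ss, seqConstraints(seed = 11))
    expect_identical(as.character(a), as.character(b))
    c <- generateSequences(ss, seqConstraints(seed = 12))
    expect_false(identical(as.character(a), as.character(c)))
})

test_that("partnered domains are exact reverse complements", {
    ss <- icosaStrands()
    seqs <- fixture("icosa_seqs", function()
        generateSequences(icosaStrands(), seqConstraints(seed = 11)))
    st <- strandTable(ss); d <- domainTable(ss)
    sq <- as.character(seqs); names(sq) <- names(seqs)
    d2 <- d[order(d$strand, d$index), ]
    d2$from <- stats::ave(d2$length, d2$strand, FUN = function(l)
        cumsum(c(0L, l[-length(l)])) + 1L)
    for (r in which(!is.na(d2$partner) & d2$id < d2$partner)) {
        q <- d2[match(d2$partner[r], d2$id), ]
        s1 <- substr(sq[st$name[match(d2$strand[r], st$id)]],
                     d2$from[r], d2$from[r] + d2$length[r] - 1L)
        s2 <- substr(sq[st$name[match(q$strand, st$id)]],
                     q$from, q$from + q$length - 1L)
        expect_identical(
            unname(s2),
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s1))))
    }
})

test_that("no strand carries four identical consecutive bases or a long repeat", {
    seqs <- fixture("icosa_seqs", function()
        generateSequences(icosaStrands(), seqConstraints(seed = 11)))
    sq <- as.character(seqs)
    expect_false(any(grepl("AAAA|CCCC|GGGG|TTTT", sq)))
    rep <- verifySequences(icosaStrands(), seqs, seqConstraints(seed = 11))
    expect_identical(nrow(rep), 0L)
    # all strands pairwise distinct
    expect_false(any(duplicated(sq)))
})

test_that("spacer bases are T and participate in the scans by default", {
    seqs <- fixture("icosa_seqs", function()
        generateSequences(icosaStrands(), seqConstraints(seed = 11)))
    d <- domainTable(icosaStrands())
    st <- strandTable(icosaStrands())
    sq <- as.character(seqs); names(sq) <- names(seqs)
    jid <- st$id[st$role == "junction"][1]
    dd <- d[d$strand == jid, ]; dd <- dd[order(dd$index), ]
    ends <- cumsum(dd$length)
    for (k in which(dd$role == "spacer")) {
        spc <- substr(sq[st$name[match(jid, st$id)]],
                      ends[k] - dd$length[k] + 1L, ends[k])
        expect_identical(unname(spc), strrep("T", dd$length[k]))
    }
})

test_that("the verifier flags hand-made violations", {
    ss <- singleEdgeStrands()
    cons <- seqConstraints(seed = 3)
    seqs <- generateSequences(ss, cons)
    sq <- as.character(seqs); names(sq) <- names(seqs)

    # a single broken base pair
    bad <- sq
    pos <- 5L
    cur <- substr(bad[["edge_E1"]], pos, pos)
    substr(bad[["edge_E1"]], pos, pos) <- if (cur == "A") "C" else "A"
    rep <- verifySequences(ss, bad, cons)
    expect_true("complementarity" %in% rep$type)

    # a duplicated 9-mer placed consistently with the pairing map:
    # copy stem bases from elsewhere on the edge strand and update the
    # stem strand to its reverse complement
    bad2 <- sq
    donor <- substr(bad2[["edge_E1"]], 2, 10)
    substr(bad2[["edge_E1"]], 13, 21) <- donor
    stem <- substr(bad2[["edge_E1"]], 12, 21)
    bad2[["edge_S1"]] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(stem)))
    rep2 <- verifySequences(ss, bad2, cons)
    expect_true("repeat" %in% rep2$type)
    expect_false("complementarity" %in% rep2$type)
})

test_that("fixed motifs are honoured and forbidden motifs excluded", {
    ss <- singleEdgeStrands()
    cons <- seqConstraints(
        seed = 9,
        fixedMotifs = data.frame(strand = "edge_E1", position = 14L,
                                 motif = "GGATCC"),
        forbiddenMotifs = "GGATCC")
    seqs <- generateSequences(ss, cons)
    sq <- as.character(seqs); names(sq) <- names(seqs)
    expect_identical(substr(sq[["edge_E1"]], 14, 19), "GGATCC")
    # no other duplex occurrence on any strand
    occ <- sum(vapply(sq, function(s)
        length(gregexpr("GGATCC", s, fixed = TRUE)[[1]][
            gregexpr("GGATCC", s, fixed = TRUE)[[1]] > 0]), integer(1)))
    # exactly the designed site and its complement image (the stem strand
    # carries the reverse complement, which for a palindrome is the motif)
    expect_identical(occ, 2L)
    expect_identical(nrow(verifySequences(ss, seqs, cons)), 0L)
})

test_that("impossible constraints fail loudly, naming the binding rule", {
    ss <- singleEdgeStrands()
    cons <- seqConstraints(seed = 1, forbiddenMotifs = c("A", "C", "G", "T"),
                           maxRestarts = 2)
    expect_error(generateSequences(ss, cons), "forbidden motif")
})

test_that("k-mer capacity accounting matches strand arithmetic", {
    ss <- icosaStrands()
    cc <- kmerCapacityCheck(ss, 8)
    lens <- strandTable(ss)$length
    expect_identical(cc$windowsNeeded, sum(pmax(0L, lens - 8L)))
    expect_identical(cc$windowsAvailable, 4^9 / 2)
    expect_true(cc$feasible)
    # an empty strand set needs nothing
    es <- ss
    es@strands <- ss@strands[0, ]; es@domains <- ss@domains[0, ]
    expect_identical(suppressWarnings(kmerCapacityCheck(es, 8))$windowsNeeded,
                     0L)
})

test_that("k = 7 saturates for the largest array while k = 8 is feasible", {
    ss <- grid884Strands()
    expect_warning(c7 <- kmerCapacityCheck(ss, 7), "infeasible")
    expect_false(c7$feasible)
    c8 <- kmerCapacityCheck(ss, 8)
    expect_true(c8$feasible)
    expect_lt(c8$occupancy, 0.5)
})

test_that("lax spacer mode ignores windows and runs that touch spacers", {
    ss <- icosaStrands()
    cons <- seqConstraints(seed = 21, spacerStrict = FALSE)
    seqs <- generateSequences(ss, cons)
    expect_identical(nrow(verifySequences(ss, seqs, cons)), 0L)
})
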