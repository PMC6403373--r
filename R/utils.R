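# Internal helpers shared across modules.

# B-form rise per base pair, nm.
.BP_NM <- 0.34

.BASES <- c("A", "C", "G", "T")

# integer base codes 1..4 = A,C,G,T; complement is 5 - code
.comp_int <- function(v) 5L - v

.seq_to_int <- function(s) {
    m <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES)
    if (anyNA(m)) stop("sequence contains non-ACGT characters: ", s)
    m
}

.int_to_seq <- function(v) paste(.BASES[v], collapse = "")

# reverse complement of a plain character string (generator-side helper;
# the independent verifier uses Biostrings::reverseComplement instead)
.revcomp_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
}

.is_count <- function(x, min = 1L) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic rounding of coordinates for vertex deduplication keys
.coord_key <- function(x, y, z = 0) {
    sprintf("%.6f_%.6f_%.6f", round(x, 6) + 0, round(y, 6) + 0, round(z, 6) + 0)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    force(code)
}
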