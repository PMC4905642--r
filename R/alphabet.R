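# Internal sequence encoding shared by the search engine.
# DNA codes: A=0 C=1 G=2 T=3, everything else (incl. N) = 4; code 4 never
# seeds and always scores as a mismatch, so N never counts as a match.

.DNA_BASES <- c("A", "C", "G", "T")

.dna_lookup <- local({
    lk <- rep(4L, 256L)
    lk[utf8ToInt("A") + 1L] <- 0L
    lk[utf8ToInt("C") + 1L] <- 1L
    lk[utf8ToInt("G") + 1L] <- 2L
    lk[utf8ToInt("T") + 1L] <- 3L
    lk[utf8ToInt("a") + 1L] <- 0L
    lk[utf8ToInt("c") + 1L] <- 1L
    lk[utf8ToInt("g") + 1L] <- 2L
    lk[utf8ToInt("t") + 1L] <- 3L
    lk
})

encode_dna <- function(x) {
    .dna_lookup[utf8ToInt(x) + 1L]
}

decode_dna <- function(codes) {
    intToUtf8(utf8ToInt("ACGTN")[codes + 1L])
}

# scoring matrix used throughout nucleotide search: match +1, mismatch -2,
# N scores -2 against everything including itself
.dna_score_matrix <- function(match = 1L, mismatch = -2L) {
    m <- matrix(mismatch, 5L, 5L)
    diag(m)[1:4] <- match
    m
}

# protein alphabet: 20 standard residues seed; B/Z/X/* score but never seed
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")

.aa_lookup <- local({
    lk <- rep(22L, 256L) # unknown -> X
    for (i in seq_along(.AA_ALPHABET)) {
        lk[utf8ToInt(.AA_ALPHABET[i]) + 1L] <- i - 1L
        lo <- tolower(.AA_ALPHABET[i])
        if (lo != .AA_ALPHABET[i]) lk[utf8ToInt(lo) + 1L] <- i - 1L
    }
    lk
})

encode_aa <- function(x) {
    .aa_lookup[utf8ToInt(x) + 1L]
}

.aa_score_matrix <- function() {
    b62 <- get_blosum62()
    m <- matrix(0L, 24L, 24L)
    for (i in 1:24) {
        for (j in 1:24) {
            m[i, j] <- as.integer(b62[.AA_ALPHABET[i], .AA_ALPHABET[j]])
        }
    }
    m
}

get_blosum62 <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
}

revcomp <- function(x) {
    vapply(x, function(s) {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
}

translate_frame <- function(x, frame) {
    # frame in 1:3 (forward) or -1:-3 (reverse-complement)
    s <- if (frame < 0) revcomp(x) else x
    off <- abs(frame) - 1L
    n <- nchar(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    sub <- substr(s, off + 1L, off + n)
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "solve"))
}
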