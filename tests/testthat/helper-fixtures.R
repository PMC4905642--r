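# Shared fixtures. Everything is generated in code; the small simulation is
# cached per test run because several files exercise it.

rdna <- function(n, gc = 0.5) tescape:::random_dna(n, gc)

# a reduced configuration for module-level tests (fast to simulate)
small_config <- function(seed = 101, ...) {
    sim_config(
        genome_length = 1.2e6,
        n_chromosomes = 2L,
        families = list(
            list(name = "GypA", label = "LTR/Gypsy", ltr_len = 300L,
                 internal_len = 2500L, tsd_len = 5L, n_full = 8L,
                 n_fragments = 12L, n_solo = 4L),
            list(name = "CopA", label = "LTR/Copia", ltr_len = 250L,
                 internal_len = 2000L, tsd_len = 5L, n_full = 6L,
                 n_fragments = 8L, n_solo = 3L),
            list(name = "HelA", label = "Helitron", ltr_len = 0L,
                 internal_len = 1500L, tsd_len = 0L, n_full = 4L,
                 n_fragments = 5L, n_solo = 0L)),
        n_clusters = 2L,
        cluster_span = 80000,
        scenario_plant = c(up = 15L, down = 15L, both = 15L),
        seed = seed,
        ...)
}

.fixture_env <- new.env()

small_sim <- function() {
    if (is.null(.fixture_env$sim)) {
        sim <- simulate_genome(small_config())
        sim <- simulate_haplotypes(sim, seed = 102)
        .fixture_env$sim <- sim
    }
    .fixture_env$sim
}

# Smith-Waterman oracle: Biostrings exact local alignment with the same
# scoring as the package's seed-and-extend engine
sw_oracle <- function(query, target) {
    pa <- Biostrings::pairwiseAlignment(
        query, target, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2, baseOnly = FALSE, type = "DNA"),
        gapOpening = 5, gapExtension = 2)
    sub <- Biostrings::subject(pa)
    list(score = Biostrings::score(pa),
         tstart = Biostrings::start(sub) - 1L,
         tend = Biostrings::end(sub))
}

# brute-force hypergeometric upper tail via binomial coefficients
hyper_tail_oracle <- function(k, K, n, N) {
    kk <- k:min(n, K)
    kk <- kk[kk >= max(0, n - (N - K))]
    if (length(kk) == 0) return(0)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force BH significance: largest i with p_(i) <= i*q/m
bh_flags_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * q / m)
    flags <- rep(FALSE, m)
    if (length(ok) > 0) flags[o[seq_len(max(ok))]] <- TRUE
    flags
}

# exact two-sided MWW p-value by enumerating all labelings
mww_enum_oracle <- function(x, y) {
    n1 <- length(x)
    pool <- c(x, y)
    n <- length(pool)
    r <- rank(pool)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(idx) {
        sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * (n - n1) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# solo-LTR landscape: full elements and lone LTRs on one chromosome
make_solo_fixture <- function(n_full = 6, n_solo = 5, seed = 36) {
    set.seed(seed)
    ltr <- rdna(400)
    internal <- rdna(2500)
    chunks <- character(0)
    rows <- list()
    pos <- 0
    add <- function(piece) {
        chunks <<- c(chunks, piece)
        start <- pos
        pos <<- pos + nchar(piece)
        c(start, pos)
    }
    add(rdna(8000))
    for (i in seq_len(n_full)) {
        el <- paste0(mutate_sequence(ltr, 0.01), internal,
                     mutate_sequence(ltr, 0.01))
        span <- add(el)
        rows[[length(rows) + 1]] <- data.frame(
            kind = "full", family = "FamA", chrom = "chr1",
            start = span[1], end = span[2], strand = "+")
        add(rdna(12000))
    }
    for (i in seq_len(n_solo)) {
        span <- add(mutate_sequence(ltr, 0.02))
        rows[[length(rows) + 1]] <- data.frame(
            kind = "solo", family = "FamA", chrom = "chr1",
            start = span[1], end = span[2], strand = "+")
        add(rdna(12000))
    }
    list(genome = setNames(paste(chunks, collapse = ""), "chr1"),
         truth = do.call(rbind, rows))
}
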