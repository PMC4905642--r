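# LTR pair detection, K2P distance (with an independent oracle), insertion
# ages, cohort dating recovery, solo-LTR scanning and divergence times.

test_that("LTR pairs are located exactly on planted termini", {
    set.seed(31)
    ltr <- rdna(300)
    internal <- rdna(2000)
    ann <- detect_ltr_pair(paste0(ltr, internal, ltr))
    expect_equal(ann$left, c(0, 300))
    expect_equal(ann$right, c(2300, 2600))
    expect_equal(ann$identity, 1)
    # diverged termini still detected with identity near 0.9
    el <- paste0(mutate_sequence(ltr, 0.055), internal,
                 mutate_sequence(ltr, 0.055))
    ann2 <- detect_ltr_pair(el)
    expect_false(is.null(ann2))
    expect_gt(ann2$identity, 0.85)
    expect_lt(ann2$identity, 0.97)
    # no terminal repeats -> nothing
    expect_null(detect_ltr_pair(rdna(3000)))
    # too short to hold two LTRs
    expect_null(detect_ltr_pair(rdna(150)))
})

test_that("K2P distance matches the closed form and flags saturation", {
    k0 <- k2p_distance("ACGTACGT", "ACGTACGT")
    expect_equal(c(k0$P, k0$Q, k0$K), c(0, 0, 0))
    # 1000 columns with 100 transitions and 50 transversions
    a <- strrep("A", 1000)
    b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
    k <- k2p_distance(a, b)
    expect_equal(k$P, 0.1)
    expect_equal(k$Q, 0.05)
    expect_equal(k$K, 0.170181, tolerance = 1e-6 / 0.170181)
    # gap and N columns are excluded from the denominator
    kg <- k2p_distance(paste0("--N", a), paste0("AC-", b))
    expect_equal(kg$n_sites, 1000)
    expect_equal(kg$K, k$K)
    # 4-mer with 2 transitions + 2 transversions: P = Q = 0.5, saturated
    expect_error(k2p_distance("ACGT", "GTAC"), class = "tescape_saturation")
    expect_error(k2p_distance("----", "----"), "no comparable")
})

test_that("K2P agrees with an independent distance implementation", {
    skip_if_not_installed("ape")
    set.seed(32)
    for (rep in 1:10) {
        a <- rdna(800)
        b <- mutate_sequence(a, runif(1, 0.01, 0.4))
        mine <- k2p_distance(a, b)$K
        m <- rbind(strsplit(tolower(a), "")[[1]],
                   strsplit(tolower(b), "")[[1]])
        ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
        expect_equal(mine, ref, tolerance = 1e-12)
    }
})

test_that("insertion age follows the molecular clock", {
    expect_equal(insertion_age(0), 0)
    expect_equal(insertion_age(0.170181, 1.05e-9), 8.1038571e7,
                 tolerance = 1e-6)
    expect_equal(insertion_age(0.00021), 1e5)
    # linear in K, inverse in rate
    set.seed(33)
    for (i in 1:10) {
        K <- runif(1, 0, 1)
        mu <- runif(1, 1e-10, 1e-8)
        expect_equal(insertion_age(2 * K, mu), 2 * insertion_age(K, mu))
        expect_equal(insertion_age(K, 2 * mu), insertion_age(K, mu) / 2)
    }
    expect_equal(insertion_age(0.2, divisor = 1), 2 * insertion_age(0.2))
})

make_cohort <- function(ages_my, ltr_len = 500, internal_len = 1000,
                        mu = 1.05e-9) {
    genome <- character(0)
    rows <- list()
    for (i in seq_along(ages_my)) {
        ltr <- rdna(ltr_len)
        k <- mu * ages_my[i] * 1e6
        el <- paste0(mutate_sequence(ltr, k), rdna(internal_len),
                     mutate_sequence(ltr, k))
        genome[sprintf("el%03d", i)] <- el
        rows[[i]] <- data.frame(copy_id = sprintf("c%03d", i),
                                family = "FamA",
                                chrom = sprintf("el%03d", i),
                                start = 0, end = nchar(el), strand = "+")
    }
    list(genome = genome, copies = do.call(rbind, rows))
}

test_that("a 5 My cohort dates to 5 My on average; 0 My dates to 0", {
    set.seed(34)
    fx <- make_cohort(rep(5, 50))
    d <- date_all_elements(fx$copies, fx$genome)
    expect_equal(nrow(d$ages), 50)
    expect_equal(d$n_saturated + d$n_without_ltr, 0)
    expect_lt(abs(mean(d$ages$age_my) - 5) / 5, 0.15)
    fx0 <- make_cohort(rep(0, 20))
    d0 <- date_all_elements(fx0$copies, fx0$genome)
    expect_true(all(d0$ages$age_my == 0))
})

test_that("a mixed 0/5/20 My cohort separates into its modes", {
    set.seed(35)
    truth <- rep(c(0, 5, 20), each = 25)
    fx <- make_cohort(truth)
    d <- date_all_elements(fx$copies, fx$genome)
    est <- d$ages$age_my[order(as.integer(sub("c", "", d$ages$element)))]
    expect_lt(mean(abs(est[truth == 0])), 0.5)
    expect_lt(abs(mean(est[truth == 5]) - 5) / 5, 0.2)
    expect_lt(abs(mean(est[truth == 20]) - 20) / 20, 0.2)
})

test_that("solo-LTR scan attains perfect precision and recall on plants", {
    fx <- make_solo_fixture()
    elements <- fx$truth[fx$truth$kind == "full", ]
    solos <- solo_ltr_scan(fx$genome, elements)
    truth_solos <- fx$truth[fx$truth$kind == "solo", ]
    expect_equal(nrow(solos), nrow(truth_solos))
    for (i in seq_len(nrow(truth_solos))) {
        hit <- any(solos$start < truth_solos$end[i] &
                   solos$end > truth_solos$start[i])
        expect_true(hit)
    }
    # genome without LTR families -> empty
    none <- solo_ltr_scan(setNames(rdna(20000), "chr1"), elements[0, ])
    expect_equal(nrow(none), 0)
})

test_that("an LTR flanked by internal sequence is rejected as solo", {
    set.seed(37)
    ltr <- rdna(400)
    internal <- rdna(2500)
    el <- paste0(ltr, internal, ltr)
    # lone LTR whose flank holds internal sequence 2 kb away
    genome <- paste0(rdna(6000), el, rdna(10000),
                     ltr, rdna(2000), substr(internal, 1, 1200),
                     rdna(10000),
                     ltr,                       # genuine solo
                     rdna(8000))
    g <- setNames(genome, "chr1")
    elements <- data.frame(kind = "full", family = "FamA", chrom = "chr1",
                           start = 6000, end = 6000 + nchar(el),
                           strand = "+")
    solos <- solo_ltr_scan(g, elements)
    expect_equal(nrow(solos), 1)
    true_solo_start <- 6000 + nchar(el) + 10000 + 400 + 2000 + 1200 + 10000
    expect_lt(abs(solos$start - true_solo_start), 20)
})

test_that("divergence times invert the planted distance", {
    set.seed(38)
    expect_equal(divergence_time("ACGTACGTACGT", "ACGTACGTACGT"), 0)
    a <- rdna(2000)
    b <- mutate_sequence(a, 0.21)
    t <- divergence_time(a, b)
    expect_lt(abs(t - 1e8) / 1e8, 0.15)
    # unrelated random pairs sit at the K2P saturation boundary: either a
    # saturation condition is raised or the distance is absurdly large
    deep <- tryCatch(divergence_time(rdna(500), rdna(500)),
                     tescape_saturation = function(e) Inf)
    expect_gt(deep, 2e8)
})
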