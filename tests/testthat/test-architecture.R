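# Hypergeometric windows, FDR, cluster merging, the distance randomisation
# test and Fisher category enrichment.

test_that("hypergeometric tail matches exact enumeration", {
    expect_equal(hypergeometric_tail(0, 5, 4, 10), 1)
    expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210)
    expect_equal(hypergeometric_tail(5, 8, 5, 20), 56 / 15504)
    expect_error(hypergeometric_tail(5, 3, 4, 10), "inconsistent")
    # spot enumeration over a grid (the full N <= 30 sweep is in the
    # acceptance suite)
    set.seed(41)
    for (i in 1:50) {
        N <- sample(2:30, 1)
        K <- sample(0:N, 1)
        n <- sample(0:N, 1)
        k <- sample(max(0, n - (N - K)):min(n, K), 1)
        expect_equal(hypergeometric_tail(k, K, n, N),
                     hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
    }
})

test_that("hypergeometric tail is monotone decreasing in k", {
    for (k in 1:8) {
        expect_lt(hypergeometric_tail(k, 10, 8, 40),
                  hypergeometric_tail(k - 1, 10, 8, 40))
    }
})

test_that("BH adjustment reproduces the hand-computed example", {
    adj <- fdr_adjust(c(0.001, 0.01, 0.03, 0.04))
    expect_equal(adj$q_value, c(0.004, 0.02, 0.04, 0.04))
    expect_true(all(adj$significant))
    all1 <- fdr_adjust(rep(1, 5))
    expect_true(all(all1$q_value == 1))
    expect_false(any(all1$significant))
    single <- fdr_adjust(0.04)
    expect_equal(single$q_value, 0.04)
    expect_true(single$significant)
    expect_equal(nrow(fdr_adjust(numeric(0))), 0)
    expect_error(fdr_adjust(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("BH flags match the brute-force step-up rule", {
    set.seed(42)
    for (i in 1:20) {
        p <- runif(sample(3:40, 1))^sample(1:3, 1)
        adj <- fdr_adjust(p, 0.05)
        expect_identical(adj$significant, bh_flags_oracle(p, 0.05))
    }
})

test_that("windows count features by midpoint and respect the floor", {
    chrom_lengths <- c(chr1 = 500000)
    set.seed(43)
    # uniform features: no enrichment
    n <- 300
    feats <- data.frame(chrom = "chr1",
                        start = sort(sample(0:499000, n)),
                        end = NA, is_te = runif(n) < 0.2)
    feats$end <- feats$start + 500
    ws <- scan_windows(feats, chrom_lengths)
    expect_true(all(ws$n_te <= ws$n_features))
    expect_true(all(ws$n_features >= 10))
    # a window with < 10 features is absent
    sparse <- feats[1:9, ]
    ws9 <- scan_windows(sparse, chrom_lengths, width = 500000)
    expect_equal(nrow(ws9), 0)
    # chromosome shorter than the window: single whole-chromosome window
    ws1 <- scan_windows(feats, c(chr1 = 500000), width = 1e6)
    expect_equal(nrow(ws1), 1)
    expect_equal(ws1$n_features, n)
})

test_that("a planted dense region is overwhelmingly significant", {
    # 100 kb region holding 30 of the genome's 60 TEs among 40 features
    set.seed(44)
    chrom_lengths <- c(chr1 = 2e6)
    inside_te <- sort(sample(500000:599000, 30))
    inside_gene <- sort(sample(500000:599000, 10))
    outside_te <- sort(sample(c(0:490000, 610000:1990000), 30))
    outside_gene <- sort(sample(c(0:490000, 610000:1990000), 400))
    feats <- data.frame(
        chrom = "chr1",
        start = c(inside_te, inside_gene, outside_te, outside_gene),
        is_te = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 30, 400)))
    feats$end <- feats$start + 200
    ws <- scan_windows(feats, chrom_lengths)
    hot <- ws[ws$start <= 500000 & ws$end >= 600000, ]
    expect_gte(nrow(hot), 1)
    expect_true(all(hot$p_hyper < 1e-8))
    expect_true(any(ws$significant))
})

test_that("significant windows merge into cluster regions with summaries", {
    ws <- data.frame(chrom = "chr1",
                     start = c(0, 10000, 50000, 200000),
                     end = c(100000, 110000, 150000, 300000),
                     n_features = 20, n_te = 10, p_hyper = 1e-9,
                     q_value = 1e-8,
                     significant = c(TRUE, TRUE, TRUE, FALSE))
    te <- data.frame(chrom = "chr1", start = c(5000, 250000),
                     end = c(6000, 251000))
    genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(70000, 400000), end = c(72000, 402000))
    m <- merge_significant_windows(ws, te, genes)
    expect_equal(nrow(m$clusters), 1)
    expect_equal(m$clusters$start, 0)
    expect_equal(m$clusters$end, 150000)
    expect_equal(m$summary$frac_te_in_clusters, 0.5)
    expect_equal(m$summary$n_genes_in_clusters, 1)
    none <- merge_significant_windows(ws[ws$significant == FALSE, ], te,
                                      genes)
    expect_equal(nrow(none$clusters), 0)
    expect_equal(none$summary$frac_te_in_clusters, 0)
})

test_that("clustered TEs reject the random-placement null decisively", {
    set.seed(45)
    chrom_lengths <- c(chr1 = 1e6, chr2 = 1e6)
    # clustered: all TEs inside two 20 kb islands
    cl <- data.frame(
        chrom = rep(c("chr1", "chr2"), each = 50),
        start = c(sort(sample(100000:120000, 50)),
                  sort(sample(700000:720000, 50))))
    cl$end <- cl$start + 100
    res <- inter_element_distance_test(cl, chrom_lengths, seed = 46)
    expect_lt(res$p, 1e-6)
    expect_error(inter_element_distance_test(cl, chrom_lengths,
                                             n_random = 1, seed = 1),
                 "n_random")
})

test_that("the distance test never exceeds its nominal size", {
    # inter-event gaps within one sample are negatively correlated, so the
    # rank test is conservative under the uniform null; size is controlled
    # (never anti-conservative), which is what FDR downstream relies on
    set.seed(47)
    chrom_lengths <- c(chr1 = 1e6)
    rejections <- vapply(1:150, function(i) {
        te <- data.frame(chrom = "chr1",
                         start = sort(sample(0:999000, 80)))
        te$end <- te$start + 100
        inter_element_distance_test(te, chrom_lengths, seed = 1000 + i)$p <
            0.05
    }, logical(1))
    expect_lt(mean(rejections), 0.07)
})

test_that("category enrichment reduces to Fisher's exact test", {
    genes <- sprintf("g%03d", 1:110)
    clusters <- genes[1:10]
    cat_even <- c(genes[1:3], genes[11:40])   # 3/10 in, 30/100 out
    expect_equal(category_enrichment(clusters, genes, cat_even), 1)
    expect_equal(category_enrichment(clusters, genes, character(0)), 1)
    # perfectly confounded 10x10 table
    genes20 <- sprintf("g%02d", 1:20)
    p <- category_enrichment(genes20[1:10], genes20, genes20[1:10])
    expect_equal(p, fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value)
    expect_lt(p, 2e-5)
})
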