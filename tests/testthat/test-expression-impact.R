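# Scenario assignment, the rank test, scenario-versus-control reports,
# ortholog on/off tables and per-family TE expression.

test_that("any base-pair overlap makes a gene TE-associated", {
    genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(1000, 5000), end = c(2000, 6000),
                        strand = "+")
    te <- data.frame(chrom = "chr1", start = 1999, end = 2500)
    parts <- classify_te_associated(genes, te)
    expect_identical(parts$te_associated$gene_id, "g1")
    # 1 bp away: not associated
    te2 <- data.frame(chrom = "chr1", start = 2000, end = 2500)
    parts2 <- classify_te_associated(genes, te2)
    expect_equal(nrow(parts2$te_associated), 0)
    none <- classify_te_associated(genes, te[0, ])
    expect_equal(nrow(none$non_te), 2)
})

test_that("scenario assignment is strand-aware with edge-to-edge distance", {
    te <- data.frame(chrom = "chr1", start = 9100, end = 9600)
    plus <- data.frame(gene_id = "g", chrom = "chr1", start = 10000,
                       end = 12000, strand = "+")
    a <- assign_scenarios(plus, te)
    expect_identical(a$scenario, "UP")
    expect_equal(a$dist_up, 400)
    # the same geometry on a minus-strand gene flips to DOWN
    minus <- plus
    minus$strand <- "-"
    am <- assign_scenarios(minus, te)
    expect_identical(am$scenario, "DOWN")
    expect_equal(am$dist_down, 400)
    # TEs on both sides within the window
    te2 <- rbind(te, data.frame(chrom = "chr1", start = 12300, end = 12800))
    ab <- assign_scenarios(plus, te2)
    expect_identical(ab$scenario, "BOTH")
    # beyond 1 kb on both sides: control
    far <- data.frame(chrom = "chr1", start = 5000, end = 8000)
    ac <- assign_scenarios(plus, far)
    expect_identical(ac$scenario, "CONTROL")
    # book-ended TE: distance 0
    te0 <- data.frame(chrom = "chr1", start = 9000, end = 10000)
    a0 <- assign_scenarios(plus, te0)
    expect_equal(a0$dist_up, 0)
})

test_that("the scenario partition is exhaustive and mutually exclusive", {
    sim <- small_sim()
    p <- scenario_partition(sim$genes, sim$te_truth[c("chrom", "start",
                                                      "end")],
                            chrom_lengths = sim$chrom_lengths)
    expect_equal(nrow(p), nrow(sim$genes))
    expect_equal(anyDuplicated(p$gene_id), 0)
    counts <- table(factor(p$scenario, levels = tescape:::SCENARIOS))
    expect_equal(sum(counts), nrow(sim$genes))
    # matches the generator's independent truth labels
    truth <- sim$scenario_truth
    expect_identical(p$scenario[match(truth$gene_id, p$gene_id)],
                     truth$scenario)
})

test_that("scenario assignment is invariant under genome reflection", {
    sim <- small_sim()
    te <- sim$te_truth[c("chrom", "start", "end")]
    genes <- sim$genes
    p1 <- assign_scenarios(genes, te)
    # mirror every coordinate and flip strands
    L <- sim$chrom_lengths
    te2 <- data.frame(chrom = te$chrom,
                      start = L[te$chrom] - te$end,
                      end = L[te$chrom] - te$start)
    genes2 <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                         start = L[genes$chrom] - genes$end,
                         end = L[genes$chrom] - genes$start,
                         strand = ifelse(genes$strand == "+", "-", "+"))
    p2 <- assign_scenarios(genes2, te2)
    expect_identical(p1$scenario, p2$scenario)
    expect_equal(p1$dist_up, p2$dist_up)
    expect_equal(p1$dist_down, p2$dist_down)
})

test_that("the rank test reproduces exact enumeration and handles ties", {
    r <- mww_test(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$p, 0.1)
    expect_identical(r$method, "exact")
    same <- mww_test(c(2, 2, 2), c(2, 2, 2))
    expect_equal(same$p, 1)
    x <- c(1.2, 3.4, 0.5, 2.2)
    expect_equal(mww_test(x, x)$p, 1)
    # exact branch equals full labeling enumeration
    set.seed(61)
    for (i in 1:10) {
        n1 <- sample(2:6, 1)
        n2 <- sample(2:6, 1)
        x <- rnorm(n1)
        y <- rnorm(n2, 0.5)
        expect_equal(mww_test(x, y)$p, mww_enum_oracle(x, y),
                     tolerance = 1e-10)
    }
    # normal branch close to exact for tie-free n1 = n2 = 10
    for (i in 1:5) {
        x <- rnorm(10)
        y <- rnorm(10, 0.3)
        approx <- mww_test(x, y, exact_max_n = 0)$p
        exact <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
        expect_lt(abs(approx - exact), 0.01)
    }
})

test_that("the rank test holds its size on same-distribution samples", {
    set.seed(62)
    rej <- vapply(1:400, function(i) {
        mww_test(rnorm(100), rnorm(100))$p < 0.05
    }, logical(1))
    expect_gt(mean(rej), 0.02)
    expect_lt(mean(rej), 0.09)
})

make_report_fixture <- function(n_scen = 120, n_ctrl = 400, repress = 0.1,
                                seed = 63) {
    set.seed(seed)
    scens <- sample(rep(c("UP", "DOWN", "BOTH", "CONTROL"),
                        c(n_scen, n_scen, n_scen, n_ctrl)))
    n <- length(scens)
    genes <- data.frame(gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                        start = seq(0, by = 3000, length.out = n))
    genes$end <- genes$start + 1500
    genes$strand <- "+"
    base <- rlnorm(n, 1.5, 1)
    value <- base * ifelse(scens == "CONTROL", 1, repress)
    assignments <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                              start = genes$start, end = genes$end,
                              strand = "+", scenario = scens,
                              dist_up = NA, dist_down = NA, edge = FALSE)
    list(assignments = assignments,
         expr = setNames(value, genes$gene_id))
}

test_that("planted repression is detected in every scenario", {
    fx <- make_report_fixture(repress = 0.1)
    rep <- scenario_report(fx$assignments, fx$expr)
    tested <- rep[rep$scenario != "CONTROL", ]
    expect_true(all(tested$p < 0.05))
    expect_true(all(tested$median <
                    rep$median[rep$scenario == "CONTROL"]))
})

test_that("without an effect the scenarios match the control", {
    set.seed(64)
    ps <- replicate(20, {
        fx <- make_report_fixture(repress = 1, seed = sample.int(1e6, 1))
        rep <- scenario_report(fx$assignments, fx$expr)
        min(rep$p[rep$scenario != "CONTROL"], na.rm = TRUE)
    })
    # with 3 tests per run, expect few runs with any p < 0.05
    expect_gte(mean(ps >= 0.05), 0.7)
})

test_that("a planted cluster-wide effect shows in the control-control test", {
    fx <- make_report_fixture(repress = 0.1)
    # put the first third of all genes inside a cluster and halve them
    clusters <- data.frame(chrom = "chr1", start = 0,
                           end = fx$assignments$end[
                               floor(nrow(fx$assignments) / 3)])
    inside <- fx$assignments$start < clusters$end
    expr2 <- fx$expr
    expr2[inside] <- expr2[inside] * 0.3
    rep <- scenario_report(fx$assignments, expr2, clusters = clusters)
    cc <- rep[rep$stratum == "inside-vs-outside", ]
    expect_equal(nrow(cc), 1)
    expect_lt(cc$p, 0.05)
    expect_true(all(c("inside", "outside") %in% rep$stratum))
})

test_that("ortholog on/off and fold tables follow their thresholds", {
    pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                        gene_b = c("b1", "b2", "b3", "b4"),
                        family = "Gypsy_3", carrier = "A")
    expr_a <- setNames(c(0, 2, 0, 4), c("a1", "a2", "a3", "a4"))
    expr_b <- setNames(c(31.61, 9, 0, 30), c("b1", "b2", "b3", "b4"))
    res <- ortholog_onoff(pairs, expr_a, expr_b)
    # silent TE allele with active TE-free allele
    expect_identical(res$onoff$gene_a, "a1")
    expect_equal(res$onoff$te_free_rpkm, 31.61)
    # 9/2 = 4.5 < 5 excluded; 30/4 = 7.5 included
    expect_identical(res$fold$gene_a, "a4")
    # (0, 0) in neither table
    expect_false("a3" %in% c(res$onoff$gene_a, res$fold$gene_a))
    # sorted by TE-free expression descending
    res2 <- ortholog_onoff(rbind(pairs, pairs[1, ]), expr_a,
                           setNames(c(31.61, 9, 0, 30), names(expr_b)))
    expect_true(!is.unsorted(rev(res2$onoff$te_free_rpkm)))
})

test_that("family expression normalises to copy number", {
    te_expr <- data.frame(
        copy_id = sprintf("c%d", 1:14),
        family = rep(c("A", "B"), c(10, 4)),
        rpkm = c(rep(2, 10), rep(0, 4)))
    fe <- family_expression(te_expr)
    a <- fe$families[fe$families$family == "A", ]
    expect_equal(a$per_copy, 2)
    expect_equal(a$per_copy_log2, 1)
    b <- fe$families[fe$families$family == "B", ]
    expect_true(b$silent)
    expect_equal(fe$frac_families_expressed, 0.5)
    expect_equal(fe$frac_copies_expressed, 10 / 14)
})

test_that("planted expressed-family fractions are recovered", {
    set.seed(65)
    n_fam <- 40
    expressed <- runif(n_fam) < 0.6
    rows <- lapply(seq_len(n_fam), function(f) {
        n_copies <- sample(3:12, 1)
        vals <- rep(0, n_copies)
        if (expressed[f]) vals[sample(n_copies, 1)] <- rlnorm(1, 1, 1)
        data.frame(copy_id = sprintf("f%02d_c%d", f, seq_len(n_copies)),
                   family = sprintf("f%02d", f), rpkm = vals)
    })
    fe <- family_expression(do.call(rbind, rows))
    expect_lt(abs(fe$frac_families_expressed - mean(expressed)), 0.05)
})
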