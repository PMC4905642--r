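# Library construction: de-duplication, the length/copy/homology filter,
# centroid clustering, classification, annotation, defragmentation and
# genome-fraction arithmetic.

test_that("deduplication keeps the longer of near-identical pairs", {
    a <- rdna(800)
    cand <- data.frame(id = c("x", "y"), seq = c(a, a))
    expect_equal(nrow(deduplicate_candidates(cand)), 1)
    # contained exact substring: full identity but 50% coverage -> both kept
    half <- substr(a, 1, 400)
    cand2 <- data.frame(id = c("long", "short"), seq = c(a, half))
    expect_equal(nrow(deduplicate_candidates(cand2)), 2)
    expect_equal(nrow(deduplicate_candidates(cand[0, ])), 0)
    # near-duplicate at 98% identity passes a 0.95 cutoff
    b <- mutate_sequence(a, 0.02, seed = 21)
    cand3 <- data.frame(id = c("x", "y"), seq = c(a, b))
    expect_equal(nrow(deduplicate_candidates(cand3, identity_cutoff = 0.95)), 1)
})

make_filter_fixture <- function(seed = 22) {
    set.seed(seed)
    short_many <- rdna(350)   # fails length despite many copies
    long_many <- rdna(500)    # passes by copy count
    long_pep <- rdna(500)     # passes by peptide homology only
    genome <- paste0(
        rdna(2000),
        paste(vapply(1:10, function(i) paste0(short_many, rdna(300)),
                     character(1)), collapse = ""),
        paste(vapply(1:6, function(i) paste0(long_many, rdna(400)),
                     character(1)), collapse = ""),
        paste0(long_pep, rdna(500), long_pep),
        rdna(2000))
    pep <- paste(sample(tescape:::.AA_ALPHABET[1:20], 80, replace = TRUE),
                 collapse = "")
    codons <- Biostrings::GENETIC_CODE
    backtrans <- vapply(strsplit(pep, "")[[1]], function(aa) {
        names(codons)[codons == aa][1]
    }, character(1))
    long_pep_sub <- paste0(substr(long_pep, 1, 200),
                           paste(backtrans, collapse = ""),
                           substr(long_pep, 201, 260))
    genome <- paste0(genome, long_pep_sub, rdna(1000))
    list(genome = setNames(genome, "chr1"),
         panel = data.frame(id = "gypsy_pol", seq = pep,
                            label = "LTR/Gypsy"),
         candidates = data.frame(
             id = c("short_many", "long_many", "long_pep_only"),
             seq = c(short_many, long_many, long_pep_sub)))
}

test_that("the candidate filter applies length AND (copies OR homology)", {
    fx <- make_filter_fixture()
    res <- filter_ltr_candidates(fx$candidates, fx$genome, fx$panel)
    rep <- res$report
    expect_false(rep$kept[rep$id == "short_many"])  # 350 bp, any copies
    expect_true(rep$copies[rep$id == "short_many"] > 5)
    expect_true(rep$kept[rep$id == "long_many"])    # > 5 genomic copies
    expect_true(rep$kept[rep$id == "long_pep_only"]) # peptide rescue
    expect_lte(rep$copies[rep$id == "long_pep_only"], 5)
    expect_identical(rep$best_peptide_hit[rep$id == "long_pep_only"],
                     "gypsy_pol")
})

test_that("filtering is monotone in genome copy number", {
    fx <- make_filter_fixture()
    cand <- fx$candidates[fx$candidates$id == "long_many", ]
    more <- paste0(fx$genome, paste(rep(paste0(cand$seq, rdna(200)), 4),
                                    collapse = ""))
    before <- filter_ltr_candidates(cand, fx$genome, fx$panel)$report
    after <- filter_ltr_candidates(cand, setNames(more, "chr1"),
                                   fx$panel)$report
    expect_gte(after$copies, before$copies)
    expect_true(after$kept)
})

test_that("greedy centroid clustering follows the identity threshold", {
    set.seed(23)
    a <- rdna(600)
    near <- mutate_sequence(a, 0.11)  # ~85% matching columns
    far <- rdna(600)
    f1 <- cluster_library(data.frame(id = c("a", "b"), seq = c(a, near)))
    expect_equal(nrow(f1), 1)
    expect_equal(f1$n_members, 2L)
    f2 <- cluster_library(data.frame(id = c("a", "b"), seq = c(a, far)))
    expect_equal(nrow(f2), 2)
    # exact duplicates: single cluster, centroid = first by tie-break (id)
    f3 <- cluster_library(data.frame(id = c("z2", "z1"), seq = c(a, a)))
    expect_equal(nrow(f3), 1)
    expect_identical(f3$name, "z1")
    # degenerate thresholds
    expect_equal(nrow(cluster_library(
        data.frame(id = c("a", "b", "c"), seq = c(a, near, far)),
        identity = 0)), 1)
    expect_equal(nrow(cluster_library(
        data.frame(id = c("a", "b", "c"), seq = c(a, near, far)),
        identity = 1)), 3)
})

test_that("classification labels by best panel hit, unknown otherwise", {
    set.seed(24)
    pep <- paste(sample(tescape:::.AA_ALPHABET[1:20], 90, replace = TRUE),
                 collapse = "")
    codons <- Biostrings::GENETIC_CODE
    nt <- paste(vapply(strsplit(pep, "")[[1]], function(aa) {
        names(codons)[codons == aa][1]
    }, character(1)), collapse = "")
    panel <- data.frame(id = c("gypsy_pol", "copia_pol"),
                        seq = c(pep, paste(rev(strsplit(pep, "")[[1]]),
                                           collapse = "")),
                        label = c("LTR/Gypsy", "LTR/Copia"))
    consensus <- paste0(rdna(400), nt, rdna(400))
    cl <- classify_family(consensus, panel)
    expect_identical(cl$label, "LTR/Gypsy")
    expect_identical(cl$te_class, "I")
    expect_false(cl$excluded)
    # a shuffled sequence has no credible hit
    cl2 <- classify_family(rdna(1200), panel)
    expect_identical(cl2$label, "unknown")
    expect_true(cl2$excluded)
})

make_annotation_fixture <- function(seed = 25) {
    set.seed(seed)
    cons <- rdna(2000)
    copy1 <- mutate_sequence(cons, 0.02)
    frag_a <- substr(mutate_sequence(cons, 0.03), 1, 700)    # consensus 0-700
    frag_b <- substr(mutate_sequence(cons, 0.03), 801, 2000) # consensus 800-2000
    genome <- paste0(rdna(1500), copy1, rdna(1500),
                     frag_a, rdna(200), frag_b,   # one fragmented copy
                     rdna(1500))
    fams <- data.frame(name = "FamA", consensus = cons,
                       consensus_length = 2000L, label = "LTR/Gypsy",
                       te_class = "I", excluded = FALSE)
    list(genome = setNames(genome, "chr1"), fams = fams,
         spans = list(copy1 = c(1500, 3500),
                      frag_a = c(5000, 5700),
                      frag_b = c(5900, 7100)))
}

test_that("annotation recovers planted copies; TE-free genomes give none", {
    fx <- make_annotation_fixture()
    ann <- annotate_genome(fx$genome, fx$fams)
    expect_equal(nrow(ann), 3)
    expect_lte(abs(ann$start[1] - 1500), 10)
    expect_lte(abs(ann$end[1] - 3500), 10)
    none <- annotate_genome(setNames(rdna(5000), "chr1"), fx$fams)
    expect_equal(nrow(none), 0)
})

test_that("defragmentation joins collinear fragments within the gap", {
    fx <- make_annotation_fixture()
    ann <- annotate_genome(fx$genome, fx$fams)
    copies <- defragment_hits(ann, fx$fams)
    expect_equal(nrow(copies), 2)
    joined <- copies[copies$n_fragments == 2, ]
    expect_equal(nrow(joined), 1)
    # reconstructed length is the fragment sum, not the genomic span
    expect_lt(abs(joined$reconstructed_length - 1900), 40)
    expect_true(joined$full_length)   # 1900/2000 >= 0.9
    single <- copies[copies$n_fragments == 1, ]
    expect_true(single$full_length)
    # same fragments placed 10 kb apart stay separate copies
    far <- ann
    far$start[far$start > 5800] <- far$start[far$start > 5800] + 10000
    far$end[far$end > 5800] <- far$end[far$end > 5800] + 10000
    copies_far <- defragment_hits(far, fx$fams, max_gap = 5000)
    expect_equal(nrow(copies_far), 3)
})

test_that("defragmentation conserves masked base pairs", {
    fx <- make_annotation_fixture()
    ann <- annotate_genome(fx$genome, fx$fams)
    copies <- defragment_hits(ann, fx$fams)
    expect_equal(sum(copies$reconstructed_length), sum(ann$end - ann$start))
})

test_that("genome fraction table uses per-family kb and cross-family union", {
    copies <- data.frame(
        copy_id = c("a1", "b1"), family = c("A", "B"),
        chrom = "chr1", start = c(0, 31000), end = c(62000, 93000),
        strand = "+", n_fragments = 1L,
        reconstructed_length = c(62000, 62000), full_length = TRUE)
    frac <- genome_te_fraction(copies, c(chr1 = 1e6))
    expect_equal(frac$table$pct[frac$table$family == "A"], 6.2)
    expect_equal(frac$table$pct[frac$table$family == "B"], 6.2)
    # overlapping families: totals use the union
    expect_equal(frac$totals$pct, 9.3)
    expect_lte(frac$totals$pct, 100)
    empty <- genome_te_fraction(copies[0, ], c(chr1 = 1e6))
    expect_equal(empty$totals$pct, 0)
})

test_that("read-survey TE content recovers a 5% planted mixture", {
    set.seed(26)
    fam_seqs <- setNames(vapply(c(5000, 4000, 3000, 2500), rdna,
                                character(1)),
                         c("F1", "F2", "F3", "F4"))
    families <- data.frame(name = names(fam_seqs),
                           consensus = unname(fam_seqs),
                           consensus_length = nchar(fam_seqs))
    n <- 5000
    is_te <- runif(n) < 0.05
    # skewed family abundances, as in real repeat landscapes
    fam_of <- sample(names(fam_seqs), n, replace = TRUE,
                     prob = c(0.55, 0.25, 0.13, 0.07))
    reads <- vapply(seq_len(n), function(i) {
        len <- sample(150:450, 1)
        if (is_te[i]) {
            cons <- fam_seqs[[fam_of[i]]]
            off <- sample(nchar(cons) - len, 1)
            mutate_sequence(substr(cons, off + 1, off + len), 0.01)
        } else rdna(len)
    }, character(1))
    names(reads) <- sprintf("r%05d", seq_len(n))
    est <- estimate_te_content_from_reads(
        reads, families, n_subsamples = 2, coverage_target = 0.45,
        genome_length = sum(nchar(reads)), seed = 27)
    p <- mean(is_te)
    ci <- 2.58 * sqrt(p * (1 - p) / (n / 2))
    expect_true(all(abs(est$fractions - p) < ci + 0.01))
    expect_gt(est$r_squared, 0.9)
})

test_that("read survey saturates at pure-TE and pure-background input", {
    set.seed(28)
    cons <- rdna(3000)
    families <- data.frame(name = "F1", consensus = cons,
                           consensus_length = 3000L)
    te_reads <- setNames(vapply(1:50, function(i) {
        off <- sample(2700, 1)
        substr(cons, off + 1, off + 300)
    }, character(1)), sprintf("t%d", 1:50))
    bg_reads <- setNames(vapply(1:50, function(i) rdna(300), character(1)),
                         sprintf("b%d", 1:50))
    hi <- estimate_te_content_from_reads(te_reads, families, seed = 1)
    expect_gt(mean(hi$fractions), 0.97)
    lo <- estimate_te_content_from_reads(bg_reads, families, seed = 1)
    expect_lt(mean(lo$fractions), 0.01)
    expect_warning(
        estimate_te_content_from_reads(bg_reads, families,
                                       coverage_target = 10,
                                       genome_length = 1e6, seed = 1),
        "coverage")
})
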