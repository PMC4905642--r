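# Non-random TE placement and TE-cluster discovery: inter-element distance
# randomisation test, hypergeometric sliding windows (100 kb / 10 kb shift /
# >= 10 features), Benjamini-Hochberg FDR at 5%, and merging of significant
# windows into cluster regions.

#' Rank test of inter-TE distances against random placement
#'
#' Observed inter-element start-to-start distances (per chromosome, sorted
#' starts) are compared with those of uniformly placed random elements on
#' the same chromosome partition using a two-sided
#' Mann-Whitney-Wilcoxon test.
#'
#' @param te_intervals data.frame with `chrom`, `start`, `end`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_random number of random elements; defaults to the observed TE
#'   count.
#' @param seed RNG seed.
#' @return list with `u`, `p`, `n_obs_gaps`, `n_random_gaps`.
#' @export
inter_element_distance_test <- function(te_intervals, chrom_lengths,
                                        n_random = NULL, seed) {
    stopifnot(nrow(te_intervals) >= 2L)
    if (is.null(n_random)) n_random <- nrow(te_intervals)
    if (n_random < 2L) stop("n_random must be >= 2")
    set.seed(seed)
    gaps_of <- function(chrom, pos) {
        unlist(lapply(split(pos, chrom), function(p) {
            if (length(p) < 2L) return(numeric(0))
            diff(sort(p))
        }), use.names = FALSE)
    }
    obs <- gaps_of(te_intervals$chrom, te_intervals$start)
    rchrom <- sample(names(chrom_lengths), n_random, replace = TRUE,
                     prob = chrom_lengths / sum(chrom_lengths))
    rpos <- floor(runif(n_random) * chrom_lengths[rchrom])
    rnd <- gaps_of(rchrom, rpos)
    if (length(obs) == 0L || length(rnd) == 0L) {
        stop("not enough inter-element gaps to test")
    }
    if (identical(sort(obs), sort(rnd))) {
        return(list(u = length(obs) * length(rnd) / 2, p = 1,
                    n_obs_gaps = length(obs), n_random_gaps = length(rnd)))
    }
    wt <- wilcox.test(obs, rnd, exact = FALSE, correct = TRUE)
    list(u = unname(wt$statistic), p = wt$p.value,
         n_obs_gaps = length(obs), n_random_gaps = length(rnd))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the probability of drawing at
#' least `k` special items in `n` draws without replacement from `N` items
#' of which `K` are special. Computed in log space via [stats::phyper()].
#'
#' @param k observed count of special items in the sample.
#' @param K total special items in the population.
#' @param n sample size.
#' @param N population size.
#' @return The upper-tail probability.
#' @examples
#' hypergeometric_tail(4, 5, 4, 10) # 5/210
#' @export
hypergeometric_tail <- function(k, K, n, N) {
    if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0)) {
        stop("inconsistent hypergeometric counts")
    }
    exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric sliding-window scan for TE enrichment
#'
#' Features (genes and TEs merged) are assigned to windows by midpoint;
#' windows with fewer than `min_features` features are skipped; each
#' remaining window is tested for TE enrichment against the genome-wide
#' feature composition.
#'
#' @param features data.frame with `chrom`, `start`, `end` and a logical
#'   `is_te` column.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width window width, bp (default 100 kb).
#' @param shift window shift, bp (default 10 kb).
#' @param min_features minimum features per tested window (default 10).
#' @param q_threshold FDR level for the significance flag (default 0.05).
#' @return data.frame of window statistics: `chrom`, `start`, `end`,
#'   `n_features`, `n_te`, `p_hyper`, `q_value`, `significant`.
#' @export
scan_windows <- function(features, chrom_lengths, width = 100000L,
                         shift = 10000L, min_features = 10L,
                         q_threshold = 0.05) {
    stopifnot("is_te" %in% names(features))
    N <- nrow(features)
    K <- sum(features$is_te)
    mids <- interval_midpoint(features$start, features$end)
    out <- list()
    for (ch in names(chrom_lengths)) {
        L <- chrom_lengths[[ch]]
        sel <- features$chrom == ch
        m_all <- sort(mids[sel])
        m_te <- sort(mids[sel & features$is_te])
        starts <- if (L <= width) 0 else seq(0, L - width, by = shift)
        ends <- pmin(starts + width, L)
        nf <- findInterval(ends - 0.5, m_all) -
            findInterval(starts - 0.5, m_all)
        nt <- findInterval(ends - 0.5, m_te) -
            findInterval(starts - 0.5, m_te)
        keep <- nf >= min_features
        if (!any(keep)) next
        out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                                end = ends[keep], n_features = nf[keep],
                                n_te = nt[keep], stringsAsFactors = FALSE)
    }
    if (length(out) == 0L) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), n_features = integer(),
                          n_te = integer(), p_hyper = numeric(),
                          q_value = numeric(), significant = logical()))
    }
    ws <- do.call(rbind, out)
    rownames(ws) <- NULL
    ws$p_hyper <- hypergeometric_tail(ws$n_te, K, ws$n_features, N)
    adj <- fdr_adjust(ws$p_hyper, q_threshold)
    ws$q_value <- adj$q_value
    ws$significant <- adj$significant
    ws
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q_threshold significance level on the adjusted values.
#' @return data.frame with `p_value`, `q_value`, `significant`.
#' @export
fdr_adjust <- function(p_values, q_threshold = 0.05) {
    if (length(p_values) == 0L) {
        return(data.frame(p_value = numeric(), q_value = numeric(),
                          significant = logical()))
    }
    if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
    q <- p.adjust(p_values, method = "BH")
    data.frame(p_value = p_values, q_value = q,
               significant = q <= q_threshold)
}

#' Merge significant windows into TE cluster regions
#'
#' @param window_stats data.frame from [scan_windows()].
#' @param te_intervals data.frame of TE copies (`chrom`, `start`, `end`).
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @return list with `clusters` (merged regions), `te_in_cluster` and
#'   `gene_in_cluster` (logical vectors by midpoint containment) and a
#'   `summary` (fraction of TEs in clusters, genes inside clusters).
#' @export
merge_significant_windows <- function(window_stats, te_intervals, genes) {
    sig <- window_stats[window_stats$significant, , drop = FALSE]
    clusters <- do.call(rbind, lapply(split(sig, sig$chrom), function(w) {
        m <- merge_intervals(w$start, w$end)
        data.frame(chrom = w$chrom[1], start = m$start, end = m$end,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(clusters) || nrow(clusters) == 0L) {
        clusters <- data.frame(chrom = character(), start = integer(),
                               end = integer())
    }
    rownames(clusters) <- NULL
    clusters$cluster_id <- if (nrow(clusters) > 0) {
        sprintf("cluster_%d", seq_len(nrow(clusters)))
    } else character(0)
    in_cluster <- function(df) {
        if (nrow(df) == 0L) return(logical(0))
        mids <- interval_midpoint(df$start, df$end)
        vapply(seq_len(nrow(df)), function(i) {
            cc <- clusters[clusters$chrom == df$chrom[i], , drop = FALSE]
            any(mids[i] >= cc$start & mids[i] < cc$end)
        }, logical(1))
    }
    te_in <- in_cluster(te_intervals)
    gene_in <- in_cluster(genes)
    list(clusters = clusters, te_in_cluster = te_in,
         gene_in_cluster = gene_in,
         summary = data.frame(
             n_clusters = nrow(clusters),
             frac_te_in_clusters = if (length(te_in)) mean(te_in) else 0,
             n_genes_in_clusters = sum(gene_in),
             n_genes_total = length(gene_in)))
}

#' Fisher test for category enrichment inside clusters
#'
#' @param genes_in_clusters ids of genes inside cluster regions.
#' @param genes_total ids of all genes.
#' @param category_members ids of genes in the category of interest.
#' @return Two-sided Fisher exact p-value for the 2x2 table
#'   (in/out cluster x in/out category); a zero-margin table gives p = 1.
#' @export
category_enrichment <- function(genes_in_clusters, genes_total,
                                category_members) {
    inc <- genes_total %in% genes_in_clusters
    cat_ <- genes_total %in% category_members
    tab <- matrix(c(sum(inc & cat_), sum(inc & !cat_),
                    sum(!inc & cat_), sum(!inc & !cat_)), 2, 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
}
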