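# TE neighbourhood scenarios and their effect on gene expression.
# Genes overlapping any TE are "TE-associated" and removed from the
# analysis universe; each remaining gene is classified by its nearest TE
# within 1 kb upstream (scenario UP), downstream (DOWN) or on both sides
# (BOTH, "captured"); everything else is the subtraction-defined CONTROL.
# Upstream/downstream are strand-aware; distances are edge-to-edge.

SCENARIOS <- c("TE_ASSOCIATED", "UP", "DOWN", "BOTH", "CONTROL")

#' Split genes into TE-associated and non-TE sets
#'
#' Any base-pair overlap between the gene body and any TE copy makes a gene
#' TE-associated; the partition is exhaustive.
#'
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param te_copies data.frame of TE copies (`chrom`, `start`, `end`).
#' @return list with `te_associated` and `non_te` gene data.frames.
#' @export
classify_te_associated <- function(genes, te_copies) {
    assoc <- rep(FALSE, nrow(genes))
    for (ch in unique(genes$chrom)) {
        gi <- which(genes$chrom == ch)
        tt <- te_copies[te_copies$chrom == ch, , drop = FALSE]
        if (nrow(tt) == 0L) next
        assoc[gi] <- vapply(gi, function(i) {
            any(tt$start < genes$end[i] & tt$end > genes$start[i])
        }, logical(1))
    }
    list(te_associated = genes[assoc, , drop = FALSE],
         non_te = genes[!assoc, , drop = FALSE])
}

#' Assign TE-neighbourhood scenarios to non-TE genes
#'
#' @param non_te_genes data.frame of genes not overlapping any TE
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param te_copies data.frame of TE copies.
#' @param window maximum edge-to-edge distance, bp (default 1000).
#' @param strand_aware if `TRUE` (default) upstream means 5' of the gene
#'   start codon; `FALSE` gives the left/right (coordinate) reading for
#'   sensitivity analysis.
#' @param chrom_lengths optional; genes within `window` of a contig edge
#'   are flagged `edge = TRUE` (kept, not dropped).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `scenario` (`UP`, `DOWN`, `BOTH`, `CONTROL`), `dist_up`, `dist_down`
#'   (bp or `NA`), `edge`.
#' @export
assign_scenarios <- function(non_te_genes, te_copies, window = 1000L,
                             strand_aware = TRUE, chrom_lengths = NULL) {
    g <- non_te_genes
    n <- nrow(g)
    left_d <- rep(NA_real_, n)
    right_d <- rep(NA_real_, n)
    for (ch in unique(g$chrom)) {
        gi <- which(g$chrom == ch)
        tt <- te_copies[te_copies$chrom == ch, , drop = FALSE]
        if (nrow(tt) == 0L) next
        ends <- sort(tt$end)
        starts <- sort(tt$start)
        # nearest TE ending at or before the gene start
        k <- findInterval(g$start[gi], ends)
        left_d[gi] <- ifelse(k >= 1, g$start[gi] - ends[pmax(k, 1L)], NA)
        # nearest TE starting at or after the gene end
        k2 <- findInterval(g$end[gi] - 0.5, starts) + 1L
        right_d[gi] <- ifelse(k2 <= length(starts),
                              starts[pmin(k2, length(starts))] - g$end[gi],
                              NA)
    }
    if (strand_aware) {
        minus <- g$strand == "-"
        up <- ifelse(minus, right_d, left_d)
        down <- ifelse(minus, left_d, right_d)
    } else {
        up <- left_d
        down <- right_d
    }
    has_up <- !is.na(up) & up <= window
    has_down <- !is.na(down) & down <= window
    scenario <- ifelse(has_up & has_down, "BOTH",
                ifelse(has_up, "UP",
                ifelse(has_down, "DOWN", "CONTROL")))
    edge <- rep(FALSE, n)
    if (!is.null(chrom_lengths)) {
        edge <- g$start < window |
            g$end > chrom_lengths[g$chrom] - window
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, strand = g$strand, scenario = scenario,
               dist_up = ifelse(has_up, up, NA),
               dist_down = ifelse(has_down, down, NA),
               edge = edge, stringsAsFactors = FALSE)
}

#' Full scenario partition of a gene set
#'
#' Convenience wrapper: [classify_te_associated()] then
#' [assign_scenarios()], returning one row per input gene so that the
#' partition property (mutually exclusive, exhaustive) holds by
#' construction and is asserted.
#'
#' @inheritParams assign_scenarios
#' @param genes all gene models.
#' @return data.frame as [assign_scenarios()] plus `TE_ASSOCIATED` rows.
#' @export
scenario_partition <- function(genes, te_copies, window = 1000L,
                               strand_aware = TRUE, chrom_lengths = NULL) {
    parts <- classify_te_associated(genes, te_copies)
    out <- assign_scenarios(parts$non_te, te_copies, window, strand_aware,
                            chrom_lengths)
    if (nrow(parts$te_associated) > 0) {
        ta <- parts$te_associated
        out <- rbind(out, data.frame(
            gene_id = ta$gene_id, chrom = ta$chrom, start = ta$start,
            end = ta$end, strand = ta$strand, scenario = "TE_ASSOCIATED",
            dist_up = NA_real_, dist_down = NA_real_, edge = FALSE,
            stringsAsFactors = FALSE))
    }
    stopifnot(nrow(out) == nrow(genes),
              !anyDuplicated(out$gene_id),
              all(out$scenario %in% SCENARIOS))
    rownames(out) <- NULL
    out
}

#' Mann-Whitney-Wilcoxon rank test
#'
#' Exact enumeration when the samples are small (`n1 + n2 <= exact_max_n`)
#' and tie-free; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Two groups with all values identical
#' give p = 1.
#'
#' @param x,y numeric samples.
#' @param exact_max_n size limit for the exact branch (default 16).
#' @return list with `u`, `n1`, `n2`, `p` and `method`.
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))$p # 0.1
#' @export
mww_test <- function(x, y, exact_max_n = 16L) {
    n1 <- length(x)
    n2 <- length(y)
    stopifnot(n1 >= 1L, n2 >= 1L)
    if (length(unique(c(x, y))) == 1L) {
        return(list(u = n1 * n2 / 2, n1 = n1, n2 = n2, p = 1,
                    method = "degenerate"))
    }
    ties <- anyDuplicated(c(x, y)) > 0L
    if (n1 + n2 <= exact_max_n && !ties) {
        wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
        method <- "exact"
    } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE))
        method <- "normal-approx"
    }
    list(u = unname(wt$statistic), n1 = n1, n2 = n2,
         p = min(1, wt$p.value), method = method)
}

#' Scenario-versus-control expression report
#'
#' Each scenario's expression distribution is tested against the
#' subtraction-defined control of its stratum with [mww_test()]. When
#' cluster regions are supplied the report is duplicated for genes inside
#' and outside TE clusters, and the inside-control versus outside-control
#' comparison is appended.
#'
#' @param assignments data.frame from [scenario_partition()] (or
#'   [assign_scenarios()]).
#' @param expression expression table (`feature_id`, `rpkm`) or a named
#'   numeric vector of per-gene values.
#' @param clusters optional cluster regions data.frame (`chrom`, `start`,
#'   `end`) from [merge_significant_windows()].
#' @param exclude_edge drop genes flagged `edge = TRUE` (default FALSE).
#' @return data.frame with one row per stratum x group: `stratum`,
#'   `scenario`, `n`, `median`, `q1`, `q3`, `u`, `p` (`NA` for the control
#'   rows and empty groups).
#' @export
scenario_report <- function(assignments, expression, clusters = NULL,
                            exclude_edge = FALSE) {
    expr <- as_expression_vector(expression)
    a <- assignments[assignments$scenario != "TE_ASSOCIATED", , drop = FALSE]
    if (exclude_edge && "edge" %in% names(a)) {
        a <- a[!a$edge, , drop = FALSE]
    }
    a$value <- unname(expr[a$gene_id])
    a <- a[!is.na(a$value), , drop = FALSE]
    if (is.null(clusters)) {
        a$stratum <- "all"
    } else {
        mids <- interval_midpoint(a$start, a$end)
        a$stratum <- vapply(seq_len(nrow(a)), function(i) {
            cc <- clusters[clusters$chrom == a$chrom[i], , drop = FALSE]
            if (any(mids[i] >= cc$start & mids[i] < cc$end)) "inside"
            else "outside"
        }, character(1))
    }
    rows <- list()
    for (st in unique(a$stratum)) {
        sa <- a[a$stratum == st, , drop = FALSE]
        ctrl <- sa$value[sa$scenario == "CONTROL"]
        for (sc in c("CONTROL", "UP", "DOWN", "BOTH")) {
            v <- sa$value[sa$scenario == sc]
            if (length(v) == 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    stratum = st, scenario = sc, n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_, u = NA_real_, p = NA_real_)
                next
            }
            test <- if (sc != "CONTROL" && length(ctrl) > 0) {
                mww_test(v, ctrl)
            } else NULL
            rows[[length(rows) + 1L]] <- data.frame(
                stratum = st, scenario = sc, n = length(v),
                median = median(v), q1 = unname(quantile(v, 0.25)),
                q3 = unname(quantile(v, 0.75)),
                u = if (is.null(test)) NA_real_ else test$u,
                p = if (is.null(test)) NA_real_ else test$p)
        }
    }
    out <- do.call(rbind, rows)
    if (!is.null(clusters) &&
        all(c("inside", "outside") %in% unique(a$stratum))) {
        ci <- a$value[a$stratum == "inside" & a$scenario == "CONTROL"]
        co <- a$value[a$stratum == "outside" & a$scenario == "CONTROL"]
        if (length(ci) > 0 && length(co) > 0) {
            test <- mww_test(ci, co)
            out <- rbind(out, data.frame(
                stratum = "inside-vs-outside", scenario = "CONTROL",
                n = length(ci) + length(co), median = median(ci),
                q1 = NA_real_, q3 = NA_real_, u = test$u, p = test$p))
        }
    }
    rownames(out) <- NULL
    out
}

as_expression_vector <- function(expression) {
    if (is.data.frame(expression)) {
        setNames(expression$rpkm, expression$feature_id)
    } else {
        expression
    }
}

#' On/off and strong-fold repression tables for ortholog pairs
#'
#' @param pairs data.frame from [polymorphic_neighbors()] (`gene_a`,
#'   `gene_b`, `family`, `carrier`).
#' @param expr_a,expr_b expression tables (or named vectors) for the two
#'   haplotypes.
#' @param fold_threshold minimum TE-free / TE-allele expression ratio for
#'   the fold table (default 5).
#' @return list with `onoff` (TE allele silent, TE-free allele active) and
#'   `fold` (TE-free at least `fold_threshold`-fold higher, TE allele > 0),
#'   both sorted by TE-free expression, descending.
#' @export
ortholog_onoff <- function(pairs, expr_a, expr_b, fold_threshold = 5) {
    ea <- as_expression_vector(expr_a)
    eb <- as_expression_vector(expr_b)
    te_val <- ifelse(pairs$carrier == "A", ea[pairs$gene_a], eb[pairs$gene_b])
    free_val <- ifelse(pairs$carrier == "A", eb[pairs$gene_b], ea[pairs$gene_a])
    tab <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      family = pairs$family, carrier = pairs$carrier,
                      te_allele_rpkm = unname(te_val),
                      te_free_rpkm = unname(free_val),
                      stringsAsFactors = FALSE)
    tab <- tab[!is.na(tab$te_allele_rpkm) & !is.na(tab$te_free_rpkm), ,
               drop = FALSE]
    onoff <- tab[tab$te_allele_rpkm == 0 & tab$te_free_rpkm > 0, ,
                 drop = FALSE]
    fold <- tab[tab$te_allele_rpkm > 0 &
                tab$te_free_rpkm / tab$te_allele_rpkm >= fold_threshold, ,
                drop = FALSE]
    onoff <- onoff[order(-onoff$te_free_rpkm), , drop = FALSE]
    fold <- fold[order(-fold$te_free_rpkm), , drop = FALSE]
    rownames(onoff) <- rownames(fold) <- NULL
    list(onoff = onoff, fold = fold)
}

#' Per-family TE expression summary
#'
#' Family expression is the summed copy expression normalised to copy
#' number. For display, zero per-copy values map to a configurable log2
#' floor; statistics always use the raw values.
#'
#' @param te_expr data.frame of per-copy expression with columns
#'   `copy_id`, `family`, `rpkm`.
#' @param log2_floor value substituted for log2(0); default half the
#'   smallest positive per-copy value.
#' @return list with `families` (per family: copy count, summed and
#'   per-copy expression, log2, `silent` flag), `frac_families_expressed`
#'   (families with at least one expressed copy) and
#'   `frac_copies_expressed` (copies with value > 0).
#' @export
family_expression <- function(te_expr, log2_floor = NULL) {
    stopifnot(all(c("copy_id", "family", "rpkm") %in% names(te_expr)))
    per <- lapply(split(te_expr, te_expr$family), function(d) {
        data.frame(family = d$family[1], n_copies = nrow(d),
                   total_rpkm = sum(d$rpkm),
                   per_copy = sum(d$rpkm) / nrow(d),
                   n_expressed_copies = sum(d$rpkm > 0))
    })
    fam <- do.call(rbind, per)
    rownames(fam) <- NULL
    pos <- fam$per_copy[fam$per_copy > 0]
    if (is.null(log2_floor)) {
        log2_floor <- if (length(pos) > 0) log2(min(pos) / 2) else 0
    }
    fam$per_copy_log2 <- ifelse(fam$per_copy > 0, log2(fam$per_copy),
                                log2_floor)
    fam$silent <- fam$n_expressed_copies == 0L
    list(families = fam,
         frac_families_expressed = mean(!fam$silent),
         frac_copies_expressed = mean(te_expr$rpkm > 0))
}
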