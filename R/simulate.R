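# Synthetic genome generator with full ground truth. Emulates a compact
# fungal genome: dense gene models (~1.14 kb mean intergenic distance),
# planted LTR-retrotransposon families whose paired LTRs diverge according
# to chosen insertion ages, truncated fragments, solo-LTRs, TE-dense
# clusters, a second haplotype with polymorphic insertions, and expression
# tables with scenario-dependent repression.
#
# Insertion points are chosen in the background coordinate space and
# applied jointly, so planted elements never nest and every final
# coordinate is exact by construction.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package's tests run under:
#' a 5 Mb, two-chromosome genome at the gene density of an oyster-mushroom
#' assembly, three Class I LTR families plus one Class II family, an
#' amplification burst with 33% of insertions at 0 My and about two thirds
#' within the last 5 My, three TE-dense clusters holding 58% of the
#' non-scenario insertions, 50% polymorphic insertions, 7.7% heterozygous
#' genes, and repression of scenario genes with probability 0.5 by a
#' factor 0.1 (0.02 for captured genes).
#'
#' @param genome_length total assembly length, bp.
#' @param n_chromosomes number of chromosomes (equal lengths).
#' @param gc GC fraction of the background.
#' @param gene_length_mean,gene_length_sd gene length distribution, bp.
#' @param intergenic_mean mean intergenic distance, bp (default 1140).
#' @param families list of family specs (`name`, `label`, `ltr_len`,
#'   `internal_len`, `tsd_len`, `n_full`, `n_fragments`, `n_solo`).
#' @param age_p0,age_p_recent,age_recent_range,age_old_range insertion-age
#'   mixture: probability of age exactly 0, probability of a recent age
#'   drawn uniformly from `age_recent_range` (My), remainder from
#'   `age_old_range`.
#' @param n_clusters,cluster_span,cluster_te_fraction TE-dense clusters:
#'   count, span (bp) and the fraction of non-scenario insertions placed
#'   inside them.
#' @param scenario_plant named vector: TE fragments planted within 1 kb
#'   `up`stream, `down`stream or on `both` sides of that many genes.
#' @param p_te_intergenic probability that a non-cluster insertion point
#'   falls in intergenic space (the remainder may hit gene bodies, yielding
#'   TE-associated genes).
#' @param fragment_len_range planted fragment lengths, bp.
#' @param polymorphic_fraction fraction of TE insertions absent from
#'   haplotype B.
#' @param gene_het_fraction fraction of gene loci absent from haplotype B.
#' @param expr_meanlog,expr_sdlog log-normal baseline RPKM parameters.
#' @param repress_prob probability that an UP/DOWN scenario gene is
#'   repressed.
#' @param repress_factor,capture_factor repression factors for UP/DOWN and
#'   BOTH (captured) genes.
#' @param cluster_factor multiplicative expression factor for all genes
#'   inside TE clusters (1 = off).
#' @param depth library size used when drawing Poisson counts.
#' @param te_family_silent,te_copy_expressed fraction of TE families with
#'   no expressed copy; probability that a copy of an expressed family is
#'   itself expressed.
#' @param expr_dispersion `NULL` for Poisson counts, or a negative-binomial
#'   size parameter for overdispersed counts.
#' @param mu substitution rate, per site per year.
#' @param ts_tv transition/transversion ratio used when planting
#'   divergence.
#' @param seed RNG seed (mandatory).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 5e6,
                       n_chromosomes = 2L,
                       gc = 0.5,
                       gene_length_mean = 1500,
                       gene_length_sd = 300,
                       intergenic_mean = 1140,
                       families = default_families(),
                       age_p0 = 0.33,
                       age_p_recent = 0.31,
                       age_recent_range = c(0.5, 5),
                       age_old_range = c(5, 20),
                       n_clusters = 3L,
                       cluster_span = 150000,
                       cluster_te_fraction = 0.58,
                       scenario_plant = c(up = 60L, down = 60L, both = 60L),
                       p_te_intergenic = 0.92,
                       fragment_len_range = c(300, 900),
                       polymorphic_fraction = 0.5,
                       gene_het_fraction = 0.077,
                       expr_meanlog = 1.5,
                       expr_sdlog = 1.2,
                       repress_prob = 0.5,
                       repress_factor = 0.1,
                       capture_factor = 0.02,
                       cluster_factor = 1,
                       depth = 5e6,
                       te_family_silent = 0.4,
                       te_copy_expressed = 0.25,
                       expr_dispersion = NULL,
                       mu = FUNGAL_SUBSTITUTION_RATE,
                       ts_tv = 2,
                       seed) {
    if (missing(seed)) stop("a seed is mandatory")
    cfg <- as.list(environment())
    stopifnot(cfg$gc > 0, cfg$gc < 1,
              cfg$polymorphic_fraction >= 0, cfg$polymorphic_fraction <= 1,
              cfg$repress_prob >= 0, cfg$repress_prob <= 1)
    structure(cfg, class = "sim_config")
}

#' Default planted TE family specifications
#' @return list of family spec lists.
#' @export
default_families <- function() {
    list(
        list(name = "Gypsy_1", label = "LTR/Gypsy", ltr_len = 400L,
             internal_len = 4200L, tsd_len = 5L, n_full = 14L,
             n_fragments = 40L, n_solo = 6L),
        list(name = "Gypsy_2", label = "LTR/Gypsy", ltr_len = 350L,
             internal_len = 3800L, tsd_len = 5L, n_full = 10L,
             n_fragments = 30L, n_solo = 5L),
        list(name = "Copia_1", label = "LTR/Copia", ltr_len = 250L,
             internal_len = 3500L, tsd_len = 5L, n_full = 8L,
             n_fragments = 25L, n_solo = 4L),
        list(name = "HELPO1", label = "Helitron", ltr_len = 0L,
             internal_len = 3000L, tsd_len = 0L, n_full = 6L,
             n_fragments = 15L, n_solo = 0L)
    )
}

random_dna <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

#' Mutate a sequence to a target K2P distance
#'
#' Per-site substitutions are drawn so that the expected K2P distance of
#' the result to the original equals `target_K`, with transitions and
#' transversions in the given ratio. The per-site substitution probability
#' is obtained by numerically inverting the K2P formula.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param target_K target K2P distance, substitutions/site.
#' @param ts_tv_ratio transition/transversion ratio (`Inf` = transitions
#'   only).
#' @param seed optional RNG seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, target_K, ts_tv_ratio = 2, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(target_K >= 0)
    if (target_K == 0) return(seq)
    r <- ts_tv_ratio
    if (is.infinite(r)) {
        kfun <- function(d) -0.5 * log(1 - 2 * d)
        dmax <- 0.5
    } else {
        kfun <- function(d) {
            P <- d * r / (r + 1)
            Q <- d / (r + 1)
            -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
        }
        dmax <- min((r + 1) / (2 * r + 1), (r + 1) / 2)
    }
    upper <- dmax * (1 - 1e-9)
    if (target_K >= 1 || target_K >= kfun(upper)) {
        stop("target_K too large: substitution process saturates")
    }
    d <- uniroot(function(x) kfun(x) - target_K, c(0, upper),
                 tol = 1e-12)$root
    codes <- encode_dna(seq)
    eligible <- codes < 4L
    hit <- runif(length(codes)) < d & eligible
    idx <- which(hit)
    if (length(idx) > 0) {
        is_ts <- if (is.infinite(r)) rep(TRUE, length(idx)) else
            runif(length(idx)) < r / (r + 1)
        new_codes <- codes[idx]
        new_codes[is_ts] <- (codes[idx][is_ts] + 2L) %% 4L
        ntv <- sum(!is_ts)
        if (ntv > 0) {
            new_codes[!is_ts] <- (codes[idx][!is_ts] + 1L +
                                  2L * rbinom(ntv, 1L, 0.5)) %% 4L
        }
        codes[idx] <- new_codes
    }
    decode_dna(codes)
}

# draw an insertion age (My) from the configured burst mixture
draw_age <- function(n, cfg) {
    u <- runif(n)
    age <- numeric(n)
    recent <- u >= cfg$age_p0 & u < cfg$age_p0 + cfg$age_p_recent
    old <- u >= cfg$age_p0 + cfg$age_p_recent
    age[recent] <- runif(sum(recent), cfg$age_recent_range[1],
                         cfg$age_recent_range[2])
    age[old] <- runif(sum(old), cfg$age_old_range[1], cfg$age_old_range[2])
    age
}

# approximate dinucleotide shuffle used for decoy candidates
dinuc_shuffle <- function(seq) {
    n <- nchar(seq)
    n2 <- n - n %% 2L
    pairs <- substring(seq, seq(1, n2, by = 2), seq(2, n2, by = 2))
    paste0(paste(sample(pairs), collapse = ""),
           if (n > n2) substr(seq, n, n) else "")
}

#' Simulate a genome with planted TE landscape and full ground truth
#'
#' @param config a [sim_config()].
#' @return list of class `"te_simulation"`: `genome` (named character),
#'   `chrom_lengths`, `genes`, `te_truth` (planted copies with family,
#'   kind, age, cluster membership), `clusters`, `families`, `candidates`
#'   (true consensus set plus shuffled decoys), `scenario_truth` (per-gene
#'   neighbourhood class derived from the final geometry) and `config`.
#' @export
simulate_genome <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    cfg <- config
    set.seed(cfg$seed)
    L <- floor(cfg$genome_length / cfg$n_chromosomes)
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    chrom_lengths <- setNames(rep(L, cfg$n_chromosomes), chroms)
    background <- setNames(
        vapply(chroms, function(ch) random_dna(L, cfg$gc), character(1)),
        chroms)

    # gene models in background coordinates
    genes <- do.call(rbind, lapply(chroms, function(ch) {
        n_est <- ceiling(L / (cfg$intergenic_mean + cfg$gene_length_mean) * 1.6)
        gaps <- pmax(50, round(rexp(n_est, 1 / cfg$intergenic_mean)))
        lens <- pmax(300, round(rnorm(n_est, cfg$gene_length_mean,
                                      cfg$gene_length_sd)))
        ends <- cumsum(gaps + lens)
        starts <- ends - lens
        keep <- ends < L - 1000
        data.frame(gene_id = sprintf("%s_g%04d", ch, seq_len(sum(keep))),
                   chrom = ch, start = starts[keep], end = ends[keep],
                   strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                   stringsAsFactors = FALSE)
    }))

    # family consensi
    empty_families <- data.frame(
        name = character(), label = character(), ltr_len = integer(),
        internal_len = integer(), tsd_len = integer(), ltr = character(),
        internal = character(), consensus = character(),
        consensus_length = integer())
    families <- do.call(rbind, lapply(cfg$families, function(f) {
        ltr <- if (f$ltr_len > 0) random_dna(f$ltr_len, cfg$gc) else ""
        internal <- random_dna(f$internal_len, cfg$gc)
        consensus <- paste0(ltr, internal, ltr)
        data.frame(name = f$name, label = f$label, ltr_len = f$ltr_len,
                   internal_len = f$internal_len, tsd_len = f$tsd_len,
                   ltr = ltr, internal = internal, consensus = consensus,
                   consensus_length = nchar(consensus),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(families)) families <- empty_families

    # cluster regions (background coordinates)
    clusters0 <- NULL
    if (cfg$n_clusters > 0) {
        picks <- list()
        tries <- 0
        while (length(picks) < cfg$n_clusters && tries < 1000) {
            tries <- tries + 1
            ch <- sample(chroms, 1)
            s <- floor(runif(1, 0.05 * L, 0.95 * L - cfg$cluster_span))
            ok <- TRUE
            for (p in picks) {
                if (p$chrom == ch &&
                    overlap_with_set(s - 20000, s + cfg$cluster_span + 20000,
                                     p$start, p$end) > 0) ok <- FALSE
            }
            if (ok) picks[[length(picks) + 1L]] <-
                list(chrom = ch, start = s, end = s + cfg$cluster_span)
        }
        clusters0 <- data.frame(
            chrom = vapply(picks, `[[`, character(1), "chrom"),
            start = vapply(picks, `[[`, numeric(1), "start"),
            end = vapply(picks, `[[`, numeric(1), "end"),
            stringsAsFactors = FALSE)
    }

    # --- choose scenario genes and their planted fragments -----------------
    protect <- data.frame(chrom = character(), start = numeric(),
                          end = numeric())
    insertions <- list()   # each: chrom, point, elem (5'->3' on +), meta
    add_insertion <- function(chrom, point, elem_seq, strand, family,
                              kind, age_my, tsd_len, scenario_plant) {
        ins <- if (strand == "-") revcomp(elem_seq) else elem_seq
        insertions[[length(insertions) + 1L]] <<- list(
            chrom = chrom, point = point, elem = ins, strand = strand,
            family = family, kind = kind, age_my = age_my,
            tsd_len = tsd_len, scenario_plant = scenario_plant)
    }
    make_fragment <- function(fam_row) {
        full_len <- fam_row$consensus_length
        flen <- round(runif(1, cfg$fragment_len_range[1],
                            min(cfg$fragment_len_range[2], full_len - 1)))
        off <- floor(runif(1, 0, full_len - flen))
        frag <- substr(fam_row$consensus, off + 1, off + flen)
        mutate_sequence(frag, runif(1, 0, 0.05), cfg$ts_tv)
    }
    scn_counts <- cfg$scenario_plant
    scn_gene_idx <- integer(0)
    if (sum(scn_counts) > 0) {
        cand_idx <- sample(seq_len(nrow(genes)))
        chosen <- integer(0)
        need <- sum(scn_counts)
        for (i in cand_idx) {
            if (length(chosen) >= need) break
            ok <- TRUE
            for (j in chosen) {
                if (genes$chrom[j] == genes$chrom[i] &&
                    abs(genes$start[j] - genes$start[i]) < 6000) {
                    ok <- FALSE
                    break
                }
            }
            if (ok) chosen <- c(chosen, i)
        }
        if (length(chosen) < need) {
            stop(sprintf("genome too small to plant %d scenario genes", need))
        }
        scn_gene_idx <- chosen
        sides <- rep(names(scn_counts), scn_counts)
        fam_ltr <- families[families$ltr_len > 0, , drop = FALSE]
        for (m in seq_along(sides)) {
            gi <- chosen[m]
            side <- sides[m]
            ch <- genes$chrom[gi]
            s <- genes$start[gi]
            e <- genes$end[gi]
            minus <- genes$strand[gi] == "-"
            plant_side <- function(where) { # "left"/"right" in coordinates
                gap <- sample(150:800, 1)
                fam_row <- fam_ltr[sample(nrow(fam_ltr), 1), , drop = FALSE]
                frag <- make_fragment(fam_row)
                point <- if (where == "left") s - gap else e + gap
                if (point < fam_row$tsd_len || point > L - 1000) return(FALSE)
                add_insertion(ch, point - fam_row$tsd_len, frag,
                              sample(c("+", "-"), 1), fam_row$name,
                              "fragment", NA_real_, fam_row$tsd_len, TRUE)
                TRUE
            }
            do_up <- side %in% c("up", "both")
            do_down <- side %in% c("down", "both")
            if (do_up) plant_side(if (minus) "right" else "left")
            if (do_down) plant_side(if (minus) "left" else "right")
            protect <- rbind(protect, data.frame(
                chrom = ch, start = s - 2000, end = e + 2000))
        }
    }

    # --- full elements, fragments and solo-LTRs ----------------------------
    intergenic <- do.call(rbind, lapply(chroms, function(ch) {
        gg <- genes[genes$chrom == ch, , drop = FALSE]
        bounds <- c(0, as.vector(rbind(gg$start, gg$end)), L)
        s <- bounds[seq(1, length(bounds) - 1, by = 2)]
        e <- bounds[seq(2, length(bounds), by = 2)]
        data.frame(chrom = ch, start = s, end = e)[e - s > 100, ]
    }))
    used_points <- new.env()
    pick_point <- function() {
        for (try in 1:200) {
            in_cluster <- !is.null(clusters0) &&
                runif(1) < cfg$cluster_te_fraction
            if (in_cluster) {
                ci <- sample(nrow(clusters0), 1)
                ch <- clusters0$chrom[ci]
                ig <- intergenic[intergenic$chrom == ch &
                                 intergenic$end > clusters0$start[ci] &
                                 intergenic$start < clusters0$end[ci], ,
                                 drop = FALSE]
                ig$start <- pmax(ig$start, clusters0$start[ci])
                ig$end <- pmin(ig$end, clusters0$end[ci])
                ig <- ig[ig$end - ig$start > 50, , drop = FALSE]
                if (nrow(ig) > 0 && runif(1) < cfg$p_te_intergenic) {
                    gi <- sample(nrow(ig), 1, prob = ig$end - ig$start)
                    p <- floor(runif(1, ig$start[gi] + 10, ig$end[gi] - 10))
                } else {
                    p <- floor(runif(1, clusters0$start[ci],
                                     clusters0$end[ci]))
                }
            } else if (runif(1) < cfg$p_te_intergenic) {
                gi <- sample(nrow(intergenic), 1,
                             prob = intergenic$end - intergenic$start)
                ch <- intergenic$chrom[gi]
                p <- floor(runif(1, intergenic$start[gi] + 10,
                                 intergenic$end[gi] - 10))
            } else {
                ch <- sample(chroms, 1)
                p <- floor(runif(1, 1000, L - 1000))
            }
            pr <- protect[protect$chrom == ch, , drop = FALSE]
            if (nrow(pr) > 0 && overlap_with_set(p, p + 1, pr$start, pr$end) > 0)
                next
            key <- paste(ch, p)
            if (!is.null(used_points[[key]])) next
            used_points[[key]] <- TRUE
            return(list(chrom = ch, point = p))
        }
        stop("could not place insertion point; genome too crowded")
    }
    for (fi in seq_len(nrow(families))) {
        fam <- families[fi, ]
        spec <- cfg$families[[fi]]
        is_ltr <- fam$ltr_len > 0
        # full-length copies
        ages <- draw_age(spec$n_full, cfg)
        for (ai in seq_len(spec$n_full)) {
            k_branch <- cfg$mu * ages[ai] * 1e6
            elem <- if (is_ltr) {
                paste0(mutate_sequence(fam$ltr, k_branch, cfg$ts_tv),
                       mutate_sequence(fam$internal, k_branch, cfg$ts_tv),
                       mutate_sequence(fam$ltr, k_branch, cfg$ts_tv))
            } else {
                mutate_sequence(fam$consensus, k_branch, cfg$ts_tv)
            }
            pp <- pick_point()
            add_insertion(pp$chrom, pp$point, elem, sample(c("+", "-"), 1),
                          fam$name, "full", ages[ai], fam$tsd_len, FALSE)
        }
        # truncated fragments
        for (ai in seq_len(spec$n_fragments)) {
            pp <- pick_point()
            add_insertion(pp$chrom, pp$point, make_fragment(fam),
                          sample(c("+", "-"), 1), fam$name, "fragment",
                          NA_real_, fam$tsd_len, FALSE)
        }
        # solo-LTRs
        if (is_ltr && spec$n_solo > 0) {
            for (ai in seq_len(spec$n_solo)) {
                k <- cfg$mu * runif(1, 0, 15) * 1e6
                pp <- pick_point()
                add_insertion(pp$chrom, pp$point,
                              mutate_sequence(fam$ltr, k, cfg$ts_tv),
                              sample(c("+", "-"), 1), fam$name, "solo",
                              NA_real_, fam$tsd_len, FALSE)
            }
        }
    }

    # --- apply insertions --------------------------------------------------
    genome <- background
    te_rows <- list()
    shift_tables <- list()
    for (ch in chroms) {
        ins <- insertions[vapply(insertions, function(x) x$chrom == ch,
                                 logical(1))]
        if (length(ins) == 0L) {
            shift_tables[[ch]] <- list(points = numeric(0), cum = numeric(0))
            next
        }
        bg <- background[[ch]]
        offsets <- vapply(ins, function(x) x$point + x$tsd_len, numeric(1))
        ins <- ins[order(offsets)]
        offsets <- sort(offsets)
        strings <- vapply(ins, function(x) {
            tsd <- if (x$tsd_len > 0)
                substr(bg, x$point + 1, x$point + x$tsd_len) else ""
            paste0(x$elem, tsd)
        }, character(1))
        lens <- nchar(strings)
        cum <- cumsum(lens)
        shift_before <- c(0, cum[-length(cum)])
        pieces_bg <- substring(bg, c(0, offsets) + 1, c(offsets, nchar(bg)))
        assembled <- character(2 * length(ins) + 1)
        assembled[seq(1, length(assembled), by = 2)] <- pieces_bg
        assembled[seq(2, length(assembled), by = 2)] <- strings
        genome[[ch]] <- paste(assembled, collapse = "")
        elem_lens <- vapply(ins, function(x) nchar(x$elem), numeric(1))
        starts <- offsets + shift_before
        te_rows[[ch]] <- data.frame(
            family = vapply(ins, function(x) x$family, character(1)),
            kind = vapply(ins, function(x) x$kind, character(1)),
            chrom = ch, start = starts, end = starts + elem_lens,
            strand = vapply(ins, function(x) x$strand, character(1)),
            age_my = vapply(ins, function(x) x$age_my, numeric(1)),
            tsd_len = vapply(ins, function(x) x$tsd_len, numeric(1)),
            scenario_plant = vapply(ins, function(x) x$scenario_plant,
                                    logical(1)),
            stringsAsFactors = FALSE)
        shift_tables[[ch]] <- list(points = offsets, cum = cum)
    }
    te_truth <- do.call(rbind, te_rows)
    if (is.null(te_truth)) {
        te_truth <- data.frame(family = character(), kind = character(),
                               chrom = character(), start = numeric(),
                               end = numeric(), strand = character(),
                               age_my = numeric(), tsd_len = numeric(),
                               scenario_plant = logical())
    }
    te_truth$te_id <- sprintf("te_%04d", seq_len(nrow(te_truth)))
    te_truth$full_length <- te_truth$kind == "full"
    rownames(te_truth) <- NULL

    shift_coord <- function(ch, x, inclusive = TRUE) {
        st <- shift_tables[[ch]]
        if (length(st$points) == 0L) return(x)
        k <- findInterval(if (inclusive) x else x - 0.5, st$points)
        x + ifelse(k > 0, st$cum[pmax(k, 1L)], 0)
    }
    for (ch in chroms) {
        gi <- genes$chrom == ch
        genes$start[gi] <- shift_coord(ch, genes$start[gi], TRUE)
        genes$end[gi] <- shift_coord(ch, genes$end[gi], FALSE)
    }
    chrom_lengths <- setNames(nchar(genome), chroms)
    clusters <- clusters0
    if (!is.null(clusters)) {
        for (i in seq_len(nrow(clusters))) {
            ch <- clusters$chrom[i]
            clusters$start[i] <- shift_coord(ch, clusters$start[i], TRUE)
            clusters$end[i] <- shift_coord(ch, clusters$end[i], FALSE)
        }
    } else {
        clusters <- data.frame(chrom = character(), start = numeric(),
                               end = numeric())
    }

    te_truth$in_cluster <- vapply(seq_len(nrow(te_truth)), function(i) {
        cc <- clusters[clusters$chrom == te_truth$chrom[i], , drop = FALSE]
        mid <- interval_midpoint(te_truth$start[i], te_truth$end[i])
        any(mid >= cc$start & mid < cc$end)
    }, logical(1))

    scenario_truth <- derive_scenarios_from_truth(genes, te_truth, clusters)

    candidates <- setNames(families$consensus, families$name)
    decoys <- setNames(vapply(families$consensus, dinuc_shuffle, character(1)),
                       sprintf("decoy_%d", seq_len(nrow(families))))
    structure(list(genome = genome, chrom_lengths = chrom_lengths,
                   genes = genes, te_truth = te_truth, clusters = clusters,
                   families = families,
                   candidates = c(candidates, decoys),
                   scenario_truth = scenario_truth, config = cfg),
              class = "te_simulation")
}

# independent (loop-based) derivation of per-gene neighbourhood classes
# from the final planted geometry; deliberately not assign_scenarios()
derive_scenarios_from_truth <- function(genes, te_truth, clusters) {
    n <- nrow(genes)
    scenario <- character(n)
    in_cluster <- logical(n)
    for (i in seq_len(n)) {
        tt <- te_truth[te_truth$chrom == genes$chrom[i], , drop = FALSE]
        s <- genes$start[i]
        e <- genes$end[i]
        if (nrow(tt) > 0 && any(tt$start < e & tt$end > s)) {
            scenario[i] <- "TE_ASSOCIATED"
        } else {
            dl <- if (any(tt$end <= s)) s - max(tt$end[tt$end <= s]) else Inf
            dr <- if (any(tt$start >= e)) min(tt$start[tt$start >= e]) - e
                  else Inf
            if (genes$strand[i] == "-") { tmp <- dl; dl <- dr; dr <- tmp }
            up <- dl <= 1000
            down <- dr <= 1000
            scenario[i] <- if (up && down) "BOTH" else if (up) "UP"
                else if (down) "DOWN" else "CONTROL"
        }
        cc <- clusters[clusters$chrom == genes$chrom[i], , drop = FALSE]
        mid <- interval_midpoint(s, e)
        in_cluster[i] <- any(mid >= cc$start & mid < cc$end)
    }
    data.frame(gene_id = genes$gene_id, scenario = scenario,
               in_cluster = in_cluster, stringsAsFactors = FALSE)
}

#' Derive haplotype B by excising polymorphic insertions
#'
#' A seeded random subset of planted TE copies (and a small fraction of
#' gene loci) is excised from haplotype B; the alignment block map between
#' the haplotypes is the complement of the excised spans and is exact by
#' construction.
#'
#' @param sim a `"te_simulation"` from [simulate_genome()].
#' @param polymorphic_fraction per-copy probability of absence from B
#'   (default from the config).
#' @param gene_het_fraction per-gene probability of absence from B.
#' @param seed RNG seed.
#' @return `sim` extended with `genome_b`, `blocks`, a `present_in_b`
#'   column on `te_truth` and `gene_present_in_b`.
#' @export
simulate_haplotypes <- function(sim, polymorphic_fraction = NULL,
                                gene_het_fraction = NULL, seed) {
    stopifnot(inherits(sim, "te_simulation"))
    set.seed(seed)
    if (is.null(polymorphic_fraction)) {
        polymorphic_fraction <- sim$config$polymorphic_fraction
    }
    if (is.null(gene_het_fraction)) {
        gene_het_fraction <- sim$config$gene_het_fraction
    }
    te <- sim$te_truth
    absent_te <- rbinom(nrow(te), 1, polymorphic_fraction) == 1
    # heterozygous genes are drawn among genes free of TE overlap so that
    # gene excisions never disturb TE locus coverage
    overlaps_te <- vapply(seq_len(nrow(sim$genes)), function(i) {
        tt <- te[te$chrom == sim$genes$chrom[i], , drop = FALSE]
        nrow(tt) > 0 && any(tt$start < sim$genes$end[i] &
                            tt$end > sim$genes$start[i])
    }, logical(1))
    absent_gene <- rbinom(nrow(sim$genes), 1, gene_het_fraction) == 1 &
        !overlaps_te
    cut_list <- rbind(
        if (any(absent_te)) data.frame(
            chrom = te$chrom[absent_te], start = te$start[absent_te],
            end = pmin(te$end[absent_te] + te$tsd_len[absent_te],
                       sim$chrom_lengths[te$chrom[absent_te]])),
        if (any(absent_gene)) data.frame(
            chrom = sim$genes$chrom[absent_gene],
            start = sim$genes$start[absent_gene],
            end = sim$genes$end[absent_gene]))
    genome_b <- sim$genome
    blocks <- list()
    for (ch in names(sim$genome)) {
        L <- sim$chrom_lengths[[ch]]
        cuts <- if (!is.null(cut_list)) {
            cl <- cut_list[cut_list$chrom == ch, , drop = FALSE]
            merge_intervals(cl$start, cl$end)
        } else data.frame(start = numeric(0), end = numeric(0))
        keep_s <- c(0, cuts$end)
        keep_e <- c(cuts$start, L)
        w <- keep_e - keep_s
        pos <- w > 0
        keep_s <- keep_s[pos]
        keep_e <- keep_e[pos]
        pieces <- substring(sim$genome[[ch]], keep_s + 1, keep_e)
        genome_b[[ch]] <- paste(pieces, collapse = "")
        other_start <- cumsum(c(0, head(keep_e - keep_s, -1)))
        blocks[[ch]] <- data.frame(
            ref_chrom = ch, ref_start = keep_s, ref_end = keep_e,
            other_chrom = paste0(ch, "_B"), other_start = other_start,
            other_end = other_start + (keep_e - keep_s),
            stringsAsFactors = FALSE)
    }
    names(genome_b) <- paste0(names(sim$genome), "_B")
    sim$genome_b <- genome_b
    sim$blocks <- do.call(rbind, blocks)
    rownames(sim$blocks) <- NULL
    sim$te_truth$present_in_b <- !absent_te
    sim$gene_present_in_b <- setNames(!absent_gene, sim$genes$gene_id)
    sim
}

#' Simulate expression with scenario-dependent repression
#'
#' Baseline per-gene RPKM is log-normal and shared between haplotypes;
#' genes in the UP/DOWN scenarios of a haplotype are repressed with the
#' configured probability, captured (BOTH) genes always and more strongly;
#' an optional cluster-wide factor multiplies every in-cluster gene.
#' Counts are Poisson (or negative-binomial) draws from the expected
#' coverage, and the reported RPKM is recomputed from the drawn counts.
#'
#' @param sim a `"te_simulation"`, optionally after
#'   [simulate_haplotypes()] (then a B-side table is returned too).
#' @param seed RNG seed.
#' @return list with `expr_a` (genes + TE copies), `expr_b` (genes present
#'   in haplotype B; `NULL` without haplotypes) and `truth` (baselines and
#'   per-haplotype repression flags).
#' @export
simulate_expression <- function(sim, seed) {
    stopifnot(inherits(sim, "te_simulation"))
    set.seed(seed)
    cfg <- sim$config
    genes <- sim$genes
    n <- nrow(genes)
    baseline <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    scn_a <- sim$scenario_truth
    in_cluster <- scn_a$in_cluster
    factor_for <- function(scenario, repressed) {
        ifelse(scenario == "BOTH", cfg$capture_factor,
        ifelse(scenario %in% c("UP", "DOWN") & repressed,
               cfg$repress_factor, 1))
    }
    draw_counts <- function(expected, lens) {
        lambda <- expected * lens * cfg$depth / 1e9
        if (is.null(cfg$expr_dispersion)) {
            rpois(length(lambda), lambda)
        } else {
            stats::rnbinom(length(lambda), size = cfg$expr_dispersion,
                           mu = lambda)
        }
    }
    make_table <- function(scenarios, present) {
        repressed <- rbinom(n, 1, cfg$repress_prob) == 1
        fac <- factor_for(scenarios, repressed)
        fac <- fac * ifelse(in_cluster, cfg$cluster_factor, 1)
        expected <- baseline * fac
        lens <- genes$end - genes$start
        counts <- draw_counts(expected, lens)
        counts[!present] <- NA
        df <- data.frame(feature_id = genes$gene_id, count = counts,
                         rpkm = rpkm(ifelse(is.na(counts), 0, counts),
                                     lens, cfg$depth),
                         stringsAsFactors = FALSE)
        df$rpkm[is.na(counts)] <- NA
        list(table = df, repressed = repressed & scenarios %in%
                 c("UP", "DOWN"))
    }
    a <- make_table(scn_a$scenario, rep(TRUE, n))
    # TE copy expression
    te <- sim$te_truth
    fam_names <- unique(te$family)
    fam_silent <- setNames(rbinom(length(fam_names), 1,
                                  cfg$te_family_silent) == 1, fam_names)
    copy_expressed <- !fam_silent[te$family] &
        rbinom(nrow(te), 1, cfg$te_copy_expressed) == 1
    te_lens <- te$end - te$start
    te_expected <- ifelse(copy_expressed,
                          rlnorm(nrow(te), cfg$expr_meanlog - 1,
                                 cfg$expr_sdlog), 0)
    te_counts <- draw_counts(te_expected, te_lens)
    te_tab <- data.frame(feature_id = te$te_id, count = te_counts,
                         rpkm = rpkm(te_counts, te_lens, cfg$depth),
                         stringsAsFactors = FALSE)
    expr_a <- rbind(a$table, te_tab)
    expr_b <- NULL
    repressed_b <- NULL
    scn_b <- NULL
    if (!is.null(sim$genome_b)) {
        te_b <- te[te$present_in_b, , drop = FALSE]
        scn_b <- derive_scenarios_from_truth(genes, te_b, sim$clusters)
        present_b <- unname(sim$gene_present_in_b[genes$gene_id])
        b <- make_table(scn_b$scenario, present_b)
        expr_b <- b$table
        repressed_b <- b$repressed
    }
    list(expr_a = expr_a, expr_b = expr_b,
         truth = list(baseline = setNames(baseline, genes$gene_id),
                      repressed_a = setNames(a$repressed, genes$gene_id),
                      repressed_b = if (!is.null(repressed_b))
                          setNames(repressed_b, genes$gene_id),
                      scenario_b = scn_b,
                      te_copy_expressed = setNames(copy_expressed, te$te_id)))
}

#' Write a simulation to disk in standard formats
#'
#' Emits `genomeA.fa`, `te.gff3`, `genes.gff3`, `candidates.fa` and, when
#' present, `genomeB.fa` and `blocks.tsv`.
#'
#' @param sim a `"te_simulation"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sequences(sim$genome, file.path(dir, "genomeA.fa"))
    write_sequences(sim$candidates, file.path(dir, "candidates.fa"))
    te <- sim$te_truth
    te_feat <- data.frame(chrom = te$chrom, source = "tescape_sim",
                          type = "dispersed_repeat", start = te$start,
                          end = te$end, score = ".", strand = te$strand,
                          stringsAsFactors = FALSE)
    te_feat$attributes <- I(lapply(seq_len(nrow(te)), function(i) {
        c(ID = te$te_id[i], Target = te$family[i], kind = te$kind[i])
    }))
    write_features(te_feat, file.path(dir, "te.gff3"), "gff3")
    g <- sim$genes
    g_feat <- data.frame(chrom = g$chrom, source = "tescape_sim",
                         type = "gene", start = g$start, end = g$end,
                         score = ".", strand = g$strand,
                         stringsAsFactors = FALSE)
    g_feat$attributes <- I(lapply(g$gene_id, function(id) c(ID = id)))
    write_features(g_feat, file.path(dir, "genes.gff3"), "gff3")
    if (!is.null(sim$genome_b)) {
        write_sequences(sim$genome_b, file.path(dir, "genomeB.fa"))
        utils::write.table(sim$blocks, file.path(dir, "blocks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
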