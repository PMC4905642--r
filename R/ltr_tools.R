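# LTR pair detection, Kimura two-parameter dating of LTR-retrotransposon
# insertions, solo-LTR discovery and generic pairwise divergence times.
#
# Dating model: the two LTRs of an element are identical at insertion and
# accumulate substitutions independently afterwards, so the K2P distance
# between them is 2*mu*T and the insertion age is T = K / (2*mu). The
# divisor is exposed for sensitivity analysis.

#' Fungal per-site substitution rate (substitutions/site/year)
#' @export
FUNGAL_SUBSTITUTION_RATE <- 1.05e-9

#' Detect the LTR pair of a reconstructed element
#'
#' The best local alignment between the two termini of the copy, anchored
#' within `end_anchor` bp of each end, defines the pair.
#'
#' @param copy_sequence element sequence, 5'->3' (character scalar).
#' @param min_ltr_len,max_ltr_len accepted LTR length range, bp.
#' @param min_identity minimum identity of the terminal repeat alignment.
#' @param end_anchor maximum distance of the alignment from each terminus.
#' @return list with `left`, `right` (0-based half-open spans in copy
#'   coordinates), `internal` span and `identity`; `NULL` when no pair
#'   qualifies.
#' @export
detect_ltr_pair <- function(copy_sequence, min_ltr_len = 100L,
                            max_ltr_len = 2000L, min_identity = 0.7,
                            end_anchor = 50L) {
    s <- as.character(copy_sequence)[1]
    L <- nchar(s)
    if (L <= 2L * min_ltr_len) return(NULL)
    w <- min(max_ltr_len + end_anchor, floor(L / 2))
    head_seq <- substr(s, 1L, w)
    tail_seq <- substr(s, L - w + 1L, L)
    al <- align_pair(head_seq, tail_seq, type = "local")
    left <- al$a_span                       # on head = copy coords
    right <- al$b_span + (L - w)            # shift tail window
    len_l <- left[2] - left[1]
    len_r <- right[2] - right[1]
    if (min(len_l, len_r) < min_ltr_len) return(NULL)
    if (al$identity < min_identity) return(NULL)
    if (left[1] > end_anchor) return(NULL)
    if (right[2] < L - end_anchor) return(NULL)
    if (max(len_l, len_r) > 1.15 * min(len_l, len_r)) return(NULL)
    list(left = left, right = right,
         internal = c(left[2], right[1]),
         identity = al$identity)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap or N are excluded from the denominator.
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion fraction.
#'
#' @param aligned_a,aligned_b aligned sequences of equal length (gaps as
#'   `-`).
#' @return list with `P`, `Q`, `K` and `n_sites` (ungapped columns).
#'   Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise a condition
#'   of class `"tescape_saturation"`.
#' @examples
#' k2p_distance("ACGT", "ACGT") # K = 0
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
    a <- toupper(as.character(aligned_a)[1])
    b <- toupper(as.character(aligned_b)[1])
    if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    ok <- ca %in% .DNA_BASES & cb %in% .DNA_BASES
    ca <- ca[ok]
    cb <- cb[ok]
    n <- length(ca)
    if (n == 0L) stop("no comparable (ungapped, unambiguous) columns")
    diff <- ca != cb
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    transition <- diff & (purine[ca] == purine[cb])
    P <- sum(transition) / n
    Q <- sum(diff & !transition) / n
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) {
        stop(structure(class = c("tescape_saturation", "error", "condition"),
                       list(message = sprintf(
                           "K2P distance undefined (saturated): P=%.3f Q=%.3f",
                           P, Q), call = sys.call(-1))))
    }
    K <- -0.5 * log(w1) - 0.25 * log(w2)
    list(P = P, Q = Q, K = K, n_sites = n)
}

#' Insertion age from LTR divergence
#'
#' @param K K2P distance between the two LTRs (substitutions/site).
#' @param rate per-site substitution rate per year.
#' @param divisor 2 under independent divergence of both LTRs (default);
#'   1 would interpret `K` as one-branch divergence.
#' @return Age in years, `T = K / (divisor * rate)`.
#' @examples
#' insertion_age(0.170181) / 1e6 # ~81 My
#' @export
insertion_age <- function(K, rate = FUNGAL_SUBSTITUTION_RATE, divisor = 2) {
    stopifnot(all(K >= 0), rate > 0)
    K / (divisor * rate)
}

#' Date all intact LTR-retrotransposon copies
#'
#' For each copy the LTR pair is located, the two LTRs are globally aligned
#' and their K2P distance converted to an insertion age. Saturated pairs
#' are reported with `NA` age and counted, not silently dropped.
#'
#' @param copies data.frame of copies (`copy_id`, `family`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param genome named character vector of assembly sequences.
#' @param rate substitution rate per site per year.
#' @param min_family_n families with more than this many dated copies get
#'   their own histogram row; the rest are pooled as `"Other"`.
#' @param bin_width_my histogram bin width in My.
#' @param ... passed to [detect_ltr_pair()].
#' @return list with `ages` (per element: P, Q, K, age_years, age_my),
#'   `histogram` (family x age-bin counts), `n_saturated` and
#'   `n_without_ltr`.
#' @export
date_all_elements <- function(copies, genome,
                              rate = FUNGAL_SUBSTITUTION_RATE,
                              min_family_n = 5L, bin_width_my = 1, ...) {
    rows <- list()
    n_saturated <- 0L
    n_without <- 0L
    for (i in seq_len(nrow(copies))) {
        seq_i <- substr(genome[[copies$chrom[i]]], copies$start[i] + 1L,
                        copies$end[i])
        if (copies$strand[i] == "-") seq_i <- revcomp(seq_i)
        ann <- detect_ltr_pair(seq_i, ...)
        if (is.null(ann)) {
            n_without <- n_without + 1L
            next
        }
        lseq <- substr(seq_i, ann$left[1] + 1L, ann$left[2])
        rseq <- substr(seq_i, ann$right[1] + 1L, ann$right[2])
        al <- align_pair(lseq, rseq, type = "global")
        k2p <- tryCatch(k2p_distance(al$aligned_a, al$aligned_b),
                        tescape_saturation = function(e) NULL)
        if (is.null(k2p)) {
            n_saturated <- n_saturated + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                element = copies$copy_id[i], family = copies$family[i],
                chrom = copies$chrom[i], start = copies$start[i],
                end = copies$end[i], P = NA_real_, Q = NA_real_,
                K = NA_real_, age_years = NA_real_, age_my = NA_real_)
            next
        }
        age <- insertion_age(k2p$K, rate)
        rows[[length(rows) + 1L]] <- data.frame(
            element = copies$copy_id[i], family = copies$family[i],
            chrom = copies$chrom[i], start = copies$start[i],
            end = copies$end[i], P = k2p$P, Q = k2p$Q, K = k2p$K,
            age_years = age, age_my = age / 1e6)
    }
    ages <- if (length(rows) > 0) do.call(rbind, rows) else
        data.frame(element = character(), family = character(),
                   chrom = character(), start = integer(), end = integer(),
                   P = numeric(), Q = numeric(), K = numeric(),
                   age_years = numeric(), age_my = numeric())
    dated <- ages[!is.na(ages$age_my), , drop = FALSE]
    hist <- NULL
    if (nrow(dated) > 0) {
        fam_n <- table(dated$family)
        fam_lab <- ifelse(fam_n[dated$family] > min_family_n,
                          dated$family, "Other")
        bins <- floor(dated$age_my / bin_width_my) * bin_width_my
        hist <- as.matrix(table(fam_lab, factor(bins,
            levels = sort(unique(bins)))))
    }
    list(ages = ages, histogram = hist, n_saturated = n_saturated,
         n_without_ltr = n_without)
}

#' Scan a genome for solo-LTRs
#'
#' The left LTR of a representative autonomous copy of each family is
#' searched genome-wide; for each hit both flanks are screened for that
#' family's internal sequence, and hits with no internal match on either
#' flank and no overlap with an annotated element are reported as
#' solo-LTRs.
#'
#' @param genome named character vector of assembly sequences.
#' @param elements data.frame of annotated element copies (`family`,
#'   `chrom`, `start`, `end`, `strand`); the first copy per family whose
#'   sequence yields an LTR pair serves as the representative.
#' @param flank flank length screened on each side, bp (default 5000).
#' @param max_evalue LTR hit significance cutoff (default 1e-15).
#' @param min_identity minimum identity of LTR hits.
#' @param internal_min_length minimum internal-sequence match that
#'   disqualifies a hit from being solo.
#' @param ... passed to [detect_ltr_pair()].
#' @return data.frame of solo-LTRs: `chrom`, `start`, `end`, `strand`,
#'   `family`, `flank_screened`.
#' @export
solo_ltr_scan <- function(genome, elements, flank = 5000L,
                          max_evalue = 1e-15, min_identity = 0.8,
                          internal_min_length = 100L, ...) {
    fams <- unique(elements$family)
    if (length(fams) == 0L) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          family = character(), flank_screened = integer()))
    }
    idx <- build_index(genome)
    solos <- list()
    for (fam in fams) {
        fe <- elements[elements$family == fam, , drop = FALSE]
        rep_ann <- NULL
        rep_seq <- NULL
        for (i in seq_len(nrow(fe))) {
            s <- substr(genome[[fe$chrom[i]]], fe$start[i] + 1L, fe$end[i])
            if (fe$strand[i] == "-") s <- revcomp(s)
            ann <- detect_ltr_pair(s, ...)
            if (!is.null(ann)) {
                rep_ann <- ann
                rep_seq <- s
                break
            }
        }
        if (is.null(rep_ann)) next
        ltr <- substr(rep_seq, rep_ann$left[1] + 1L, rep_ann$left[2])
        internal <- substr(rep_seq, rep_ann$internal[1] + 1L,
                           rep_ann$internal[2])
        hits <- local_search(idx, setNames(ltr, paste0(fam, "_LTR")),
                             min_identity = min_identity,
                             min_length = max(50L, floor(0.5 * nchar(ltr))),
                             max_evalue = max_evalue)
        for (j in seq_len(nrow(hits))) {
            chrom <- hits$target[j]
            s <- hits$tstart[j]
            e <- hits$tend[j]
            fe_all <- elements[elements$chrom == chrom, , drop = FALSE]
            if (overlap_with_set(s, e, fe_all$start, fe_all$end) > 0) next
            L <- nchar(genome[[chrom]])
            lf <- substr(genome[[chrom]], max(0L, s - flank) + 1L, s)
            rf <- substr(genome[[chrom]], e + 1L, min(L, e + flank))
            flanks <- c(left = lf, right = rf)
            flanks <- flanks[nchar(flanks) >= 50L]
            has_internal <- FALSE
            if (length(flanks) > 0) {
                fidx <- build_index(flanks)
                ih <- local_search(fidx, setNames(internal,
                                                  paste0(fam, "_internal")),
                                   min_identity = min_identity,
                                   min_length = internal_min_length,
                                   max_evalue = max_evalue)
                has_internal <- nrow(ih) > 0
            }
            if (!has_internal) {
                solos[[length(solos) + 1L]] <- data.frame(
                    chrom = chrom, start = s, end = e,
                    strand = hits$strand[j], family = fam,
                    flank_screened = flank, score = hits$score[j],
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(solos) == 0L) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          family = character(), flank_screened = integer()))
    }
    out <- do.call(rbind, solos)
    # one call per locus: best score wins, ties by family name
    out <- out[order(out$chrom, out$start, -out$score, out$family), ,
               drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    if (nrow(out) > 1) {
        for (i in seq(2, nrow(out))) {
            prev <- which(keep[seq_len(i - 1)])
            prev <- prev[out$chrom[prev] == out$chrom[i]]
            if (length(prev) > 0 &&
                overlap_with_set(out$start[i], out$end[i],
                                 out$start[prev], out$end[prev]) > 0) {
                keep[i] <- FALSE
            }
        }
    }
    out <- out[keep, c("chrom", "start", "end", "strand", "family",
                       "flank_screened")]
    rownames(out) <- NULL
    out
}

#' Divergence time between two sequences
#'
#' Global alignment followed by K2P distance and the molecular clock
#' `T = K / (divisor * rate)`.
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @inheritParams insertion_age
#' @return Divergence time in years.
#' @export
divergence_time <- function(seq_a, seq_b, rate = FUNGAL_SUBSTITUTION_RATE,
                            divisor = 2) {
    al <- align_pair(seq_a, seq_b, type = "global")
    k2p <- k2p_distance(al$aligned_a, al$aligned_b)
    insertion_age(k2p$K, rate, divisor)
}
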