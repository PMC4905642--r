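# TE consensus library construction: de-duplication, the length/copy/homology
# filter for structural LTR candidates, greedy 80%-identity centroid
# clustering, classification against labelled panels, genome annotation,
# fragment defragmentation and genome-fraction summaries.

.nt_submat <- function() {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                             baseOnly = FALSE, type = "DNA")
}

# pairwise alignment wrapper; identity = matching columns / alignment length
align_pair <- function(a, b, type = "global") {
    pa <- Biostrings::pairwiseAlignment(a, b, type = type,
                                        substitutionMatrix = .nt_submat(),
                                        gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(pa)
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    list(identity = Biostrings::nmatch(pa) / max(1L, alen),
         score = Biostrings::score(pa),
         alen = alen,
         a_span = c(Biostrings::start(pat) - 1L, Biostrings::end(pat)),
         b_span = c(Biostrings::start(sub) - 1L, Biostrings::end(sub)),
         aligned_a = as.character(Biostrings::alignedPattern(pa)),
         aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

#' Remove duplicate repeat candidates
#'
#' Two candidates are duplicates when a local alignment reaches the identity
#' cutoff over at least 95% of both sequences; only the longer is kept.
#' A contained exact substring (full identity but partial coverage of the
#' longer sequence) is not a duplicate.
#'
#' @param candidates data.frame with columns `id`, `seq` (and optionally
#'   `source`), or a named character vector.
#' @param identity_cutoff fraction; default 1.0 (exact duplicates).
#' @param min_coverage mutual-coverage floor (default 0.95).
#' @return The de-duplicated candidates, original order preserved.
#' @export
deduplicate_candidates <- function(candidates, identity_cutoff = 1.0,
                                   min_coverage = 0.95) {
    cand <- as_candidates(candidates)
    n <- nrow(cand)
    if (n <= 1L) return(cand)
    drop <- rep(FALSE, n)
    len <- nchar(cand$seq)
    for (i in seq_len(n - 1L)) {
        if (drop[i]) next
        for (j in seq((i + 1L), n)) {
            if (drop[j]) next
            al <- align_pair(cand$seq[i], cand$seq[j], type = "local")
            cov_i <- (al$a_span[2] - al$a_span[1]) / len[i]
            cov_j <- (al$b_span[2] - al$b_span[1]) / len[j]
            if (al$identity >= identity_cutoff && cov_i >= min_coverage &&
                cov_j >= min_coverage) {
                if (len[i] >= len[j]) drop[j] <- TRUE else drop[i] <- TRUE
            }
            if (drop[i]) break
        }
    }
    out <- cand[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
}

as_candidates <- function(x) {
    if (is.data.frame(x)) {
        stopifnot(all(c("id", "seq") %in% names(x)))
        if (!"source" %in% names(x)) x$source <- rep("denovo", nrow(x))
        x[c("id", "seq", "source")]
    } else {
        data.frame(id = names(x), seq = unname(as.character(x)),
                   source = "denovo", stringsAsFactors = FALSE)
    }
}

#' Filter structural LTR-retrotransposon candidates
#'
#' Keeps a candidate iff it is longer than `min_length` bp AND it either
#' has more than `min_copies` genomic copies (hits at the nucleotide
#' significance cutoff covering at least half the candidate) or yields a
#' significant translated hit to the LTR-retrotransposon peptide panel.
#'
#' @param candidates candidates (data.frame `id`/`seq` or named vector).
#' @param genome named character vector of assembly sequences.
#' @param peptide_panel data.frame `id`, `seq`, `label` of reference TE
#'   peptides (or named vector).
#' @param min_length length floor, bp (candidates must exceed it).
#' @param min_copies copy-count floor (candidates must exceed it).
#' @param nt_evalue,pep_evalue significance cutoffs for the nucleotide and
#'   translated searches.
#' @param copy_coverage fraction of the candidate a genomic hit must cover
#'   to count as a copy.
#' @return list with `kept` (filtered candidates) and `report`
#'   (per-candidate length, copy count, best peptide hit, decision).
#' @export
filter_ltr_candidates <- function(candidates, genome, peptide_panel,
                                  min_length = 400L, min_copies = 5L,
                                  nt_evalue = 1e-15, pep_evalue = 1e-5,
                                  copy_coverage = 0.5) {
    cand <- as_candidates(candidates)
    idx <- if (length(genome) > 0) build_index(genome) else NULL
    n <- nrow(cand)
    len <- nchar(cand$seq)
    copies <- integer(n)
    best_pep <- character(n)
    for (i in seq_len(n)) {
        if (!is.null(idx)) {
            h <- local_search(idx, cand$seq[i], min_identity = 0,
                              min_length = 50L, max_evalue = nt_evalue,
                              query_id = cand$id[i])
            copies[i] <- sum((h$qend - h$qstart) >= copy_coverage * len[i])
        }
        ph <- translated_search(setNames(cand$seq[i], cand$id[i]),
                                peptide_panel, max_evalue = pep_evalue)
        best_pep[i] <- if (nrow(ph) > 0) ph$target[1] else NA_character_
    }
    kept <- len > min_length & (copies > min_copies | !is.na(best_pep))
    report <- data.frame(id = cand$id, length = len, copies = copies,
                         best_peptide_hit = best_pep, kept = kept,
                         stringsAsFactors = FALSE)
    list(kept = cand[kept, , drop = FALSE], report = report)
}

#' Greedy centroid clustering of a candidate library
#'
#' Candidates are sorted by decreasing length (ties by id) and each either
#' joins the first existing centroid whose global-alignment identity
#' reaches the threshold, or founds a new cluster. The cluster consensus is
#' the centroid sequence itself, which keeps the stage deterministic.
#'
#' @param candidates candidates (data.frame `id`/`seq` or named vector).
#' @param identity clustering identity threshold (default 0.8).
#' @return data.frame of families: `name`, `consensus`, `consensus_length`,
#'   `n_members`, plus a `members` list-column; classification columns
#'   (`label`, `te_class`, `excluded`) are initialised for
#'   [classify_family()].
#' @export
cluster_library <- function(candidates, identity = 0.8) {
    cand <- as_candidates(candidates)
    if (nrow(cand) == 0L) stop("no candidates to cluster")
    o <- order(-nchar(cand$seq), cand$id)
    cand <- cand[o, , drop = FALSE]
    centroids <- integer(0)
    membership <- integer(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        placed <- FALSE
        for (ci in seq_along(centroids)) {
            al <- align_pair(cand$seq[i], cand$seq[centroids[ci]],
                             type = "global")
            if (al$identity >= identity) {
                membership[i] <- ci
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            centroids <- c(centroids, i)
            membership[i] <- length(centroids)
        }
    }
    fam <- data.frame(name = cand$id[centroids],
                      consensus = cand$seq[centroids],
                      consensus_length = nchar(cand$seq[centroids]),
                      n_members = as.integer(table(factor(membership,
                          levels = seq_along(centroids)))),
                      label = NA_character_, te_class = NA_character_,
                      excluded = FALSE, stringsAsFactors = FALSE)
    fam$members <- I(split(cand$id, membership))
    rownames(fam) <- NULL
    fam
}

#' Classify a family consensus against reference panels
#'
#' The label of the best translated (peptide) hit wins; if no peptide hit,
#' the best nucleotide hit; if neither, the family is labelled `"unknown"`
#' and flagged as excluded from downstream analyses.
#'
#' @param consensus consensus sequence (character scalar, optionally named).
#' @param peptide_panel data.frame `id`, `seq`, `label` of TE peptides.
#' @param nucleotide_panel optional data.frame `id`, `seq`, `label` of TE
#'   nucleotide references.
#' @param pep_evalue,nt_evalue significance cutoffs.
#' @return list with `label`, `te_class` (`"I"`, `"II"` or `NA`) and
#'   `excluded`.
#' @export
classify_family <- function(consensus, peptide_panel, nucleotide_panel = NULL,
                            pep_evalue = 1e-5, nt_evalue = 1e-15) {
    h <- translated_search(consensus, peptide_panel, max_evalue = pep_evalue)
    label <- NA_character_
    if (nrow(h) > 0) {
        lab <- panel_labels(peptide_panel)[h$target]
        # tie-break: higher score, then lexicographic label
        o <- order(-h$score, lab)
        label <- unname(lab[o[1]])
    } else if (!is.null(nucleotide_panel)) {
        pan <- as_candidates(nucleotide_panel)
        idx <- build_index(setNames(pan$seq, pan$id))
        nh <- local_search(idx, consensus, min_identity = 0,
                           min_length = 50L, max_evalue = nt_evalue)
        if (nrow(nh) > 0) {
            label <- unname(panel_labels(nucleotide_panel)[nh$target[1]])
        }
    }
    if (is.na(label)) {
        list(label = "unknown", te_class = NA_character_, excluded = TRUE)
    } else {
        list(label = label, te_class = te_class_of(label), excluded = FALSE)
    }
}

panel_labels <- function(panel) {
    if (is.data.frame(panel) && "label" %in% names(panel)) {
        setNames(panel$label, panel$id)
    } else {
        ids <- if (is.data.frame(panel)) panel$id else names(panel)
        setNames(ids, ids)
    }
}

te_class_of <- function(label) {
    class_i <- c("LTR", "DIRS", "LINE", "SINE", "PLE")
    class_ii <- c("TIR", "Helitron", "Crypton", "Maverick", "MITE")
    top <- sub("/.*$", "", label)
    if (top %in% class_i) "I" else if (top %in% class_ii) "II" else NA_character_
}

#' Classify every family in a clustered library
#'
#' Applies [classify_family()] to each cluster consensus and names families
#' `<Superfamily>_<n>` in cluster order within each label.
#'
#' @inheritParams classify_family
#' @param families data.frame from [cluster_library()].
#' @return `families` with `label`, `te_class`, `excluded` filled in and
#'   `name` rewritten to the `Superfamily_n` convention.
#' @export
classify_library <- function(families, peptide_panel, nucleotide_panel = NULL,
                             pep_evalue = 1e-5, nt_evalue = 1e-15) {
    if (is.null(families$centroid)) families$centroid <- families$name
    for (i in seq_len(nrow(families))) {
        cl <- classify_family(setNames(families$consensus[i], families$name[i]),
                              peptide_panel, nucleotide_panel,
                              pep_evalue, nt_evalue)
        families$label[i] <- cl$label
        families$te_class[i] <- cl$te_class
        families$excluded[i] <- cl$excluded
    }
    base <- sub("^.*/", "", families$label)
    idx <- stats::ave(seq_len(nrow(families)), base, FUN = seq_along)
    families$name <- ifelse(families$label == "unknown",
                            paste0("unknown_", idx),
                            paste0(base, "_", idx))
    families
}

#' Annotate a genome with a TE library
#'
#' Every family consensus is searched against the genome; overlapping hits
#' from different families at one locus are resolved to the best-scoring
#' family (lower-scoring hits are trimmed at the edges or dropped when more
#' than half covered).
#'
#' @param genome named character vector of assembly sequences.
#' @param families data.frame from [cluster_library()] /
#'   [classify_library()]; families flagged `excluded` are skipped.
#' @param min_identity minimum hit identity (default 0.7).
#' @param min_length minimum hit length, bp.
#' @param max_evalue significance cutoff.
#' @return data.frame of raw TE hits: `family`, `chrom`, `start`, `end`,
#'   `strand`, `qstart`, `qend` (consensus coordinates), `identity`,
#'   `score`, `evalue`, sorted by position.
#' @export
annotate_genome <- function(genome, families, min_identity = 0.7,
                            min_length = 80L, max_evalue = 1e-15) {
    stopifnot(nrow(families) > 0)
    use <- families[!families$excluded, , drop = FALSE]
    idx <- build_index(genome)
    hits <- list()
    for (i in seq_len(nrow(use))) {
        h <- local_search(idx, use$consensus[i], min_identity = min_identity,
                          min_length = min_length, max_evalue = max_evalue,
                          query_id = use$name[i])
        if (nrow(h) > 0) hits[[length(hits) + 1L]] <- h
    }
    if (length(hits) == 0L) {
        return(data.frame(family = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), qstart = integer(),
                          qend = integer(), identity = numeric(),
                          score = integer(), evalue = numeric()))
    }
    h <- do.call(rbind, hits)
    h <- resolve_locus_conflicts(h, min_length)
    out <- data.frame(family = h$query, chrom = h$target,
                      start = h$tstart, end = h$tend, strand = h$strand,
                      qstart = h$qstart, qend = h$qend,
                      identity = h$identity, score = h$score,
                      evalue = h$evalue, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Best-score-wins resolution of overlapping hits at a locus. Hits more than
# half covered by better hits are dropped; partial edge overlaps are trimmed
# (consensus coordinates shifted by the trimmed amount, assuming local
# collinearity).
resolve_locus_conflicts <- function(h, min_length) {
    o <- order(-h$score, h$tstart)
    kept <- list()
    keep_rows <- logical(nrow(h))
    for (i in o) {
        ch <- h$target[i]
        ks <- kept[[ch]]
        s <- h$tstart[i]
        e <- h$tend[i]
        if (!is.null(ks) && nrow(ks) > 0) {
            ov <- overlap_with_set(s, e, ks$s, ks$e)
            if (ov > 0.5 * (e - s)) next
            # trim leading/trailing overlap
            lead <- ks[ks$s <= s & ks$e > s, , drop = FALSE]
            if (nrow(lead) > 0) {
                trim <- max(lead$e) - s
                s <- s + trim
                if (h$strand[i] == "+") h$qstart[i] <- h$qstart[i] + trim
                else h$qend[i] <- h$qend[i] - trim
            }
            trail <- ks[ks$s < e & ks$e >= e, , drop = FALSE]
            if (nrow(trail) > 0) {
                trim <- e - min(trail$s)
                e <- e - trim
                if (h$strand[i] == "+") h$qend[i] <- h$qend[i] - trim
                else h$qstart[i] <- h$qstart[i] + trim
            }
            if (e - s < min_length) next
        }
        h$tstart[i] <- s
        h$tend[i] <- e
        keep_rows[i] <- TRUE
        kept[[ch]] <- rbind(ks, data.frame(s = s, e = e))
    }
    h[keep_rows, , drop = FALSE]
}

#' Reconstruct TE copies from fragmented hits
#'
#' Same-family, same-strand hits that are collinear in consensus
#' coordinates and within `max_gap` bp on the genome are joined into one
#' copy. The reconstructed length is the summed fragment length, and a copy
#' is full-length when it reaches 90% of its family consensus.
#'
#' @param hits data.frame from [annotate_genome()].
#' @param consensus_lengths named vector of family consensus lengths (or a
#'   families data.frame).
#' @param max_gap maximum genomic gap joined, bp (default 5000).
#' @param full_length_frac consensus-coverage threshold for the full-length
#'   flag (default 0.9).
#' @param qtol tolerated overlap in consensus coordinates when chaining, bp.
#' @return data.frame of copies: `copy_id`, `family`, `chrom`, `start`,
#'   `end`, `strand`, `n_fragments`, `reconstructed_length`, `full_length`,
#'   with a `fragments` list-column of per-fragment intervals.
#' @export
defragment_hits <- function(hits, consensus_lengths, max_gap = 5000L,
                            full_length_frac = 0.9, qtol = 20L) {
    if (is.data.frame(consensus_lengths)) {
        consensus_lengths <- setNames(consensus_lengths$consensus_length,
                                      consensus_lengths$name)
    }
    if (nrow(hits) == 0L) {
        return(data.frame(copy_id = character(), family = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_fragments = integer(),
                          reconstructed_length = integer(),
                          full_length = logical()))
    }
    hits <- hits[order(hits$family, hits$chrom, hits$strand, hits$start), ,
                 drop = FALSE]
    key <- paste(hits$family, hits$chrom, hits$strand, sep = "\r")
    copies <- list()
    for (g in split(seq_len(nrow(hits)), key)) {
        current <- g[1]
        chain <- list(g[1])
        if (length(g) > 1) {
            for (i in g[-1]) {
                last <- chain[[length(chain)]]
                last_i <- last[length(last)]
                gap <- hits$start[i] - hits$end[last_i]
                collinear <- if (hits$strand[i] == "+") {
                    hits$qstart[i] >= hits$qend[last_i] - qtol
                } else {
                    hits$qend[i] <= hits$qstart[last_i] + qtol
                }
                if (gap <= max_gap && gap >= 0 && collinear) {
                    chain[[length(chain)]] <- c(last, i)
                } else {
                    chain[[length(chain) + 1L]] <- i
                }
            }
        }
        for (cc in chain) copies[[length(copies) + 1L]] <- cc
    }
    fam <- vapply(copies, function(cc) hits$family[cc[1]], character(1))
    chrom <- vapply(copies, function(cc) hits$chrom[cc[1]], character(1))
    strand <- vapply(copies, function(cc) hits$strand[cc[1]], character(1))
    start <- vapply(copies, function(cc) min(hits$start[cc]), numeric(1))
    end <- vapply(copies, function(cc) max(hits$end[cc]), numeric(1))
    recon <- vapply(copies, function(cc) sum(hits$end[cc] - hits$start[cc]),
                    numeric(1))
    out <- data.frame(copy_id = sprintf("%s_copy%d", fam,
                                        stats::ave(seq_along(fam), fam,
                                                   FUN = seq_along)),
                      family = fam, chrom = chrom, start = start, end = end,
                      strand = strand,
                      n_fragments = lengths(copies),
                      reconstructed_length = recon,
                      full_length = recon >= full_length_frac *
                          consensus_lengths[fam],
                      stringsAsFactors = FALSE)
    out$fragments <- I(lapply(copies, function(cc) {
        data.frame(start = hits$start[cc], end = hits$end[cc],
                   qstart = hits$qstart[cc], qend = hits$qend[cc])
    }))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-family genome occupancy table
#'
#' @param copies data.frame from [defragment_hits()].
#' @param genome named character vector of assembly sequences (or named
#'   vector of chromosome lengths).
#' @return list with `table` (per family: copies, full-length copies,
#'   fragments, kb, percent of genome) and `totals`; the genome-total
#'   percentage uses the cross-family union so overlapping annotation never
#'   pushes it past 100%.
#' @export
genome_te_fraction <- function(copies, genome) {
    glen <- if (is.numeric(genome)) sum(genome) else sum(nchar(genome))
    if (nrow(copies) == 0L) {
        return(list(table = data.frame(family = character(), copies = integer(),
                                       full_length = integer(),
                                       fragments = integer(), kb = numeric(),
                                       pct = numeric()),
                    totals = data.frame(copies = 0L, full_length = 0L,
                                        fragments = 0L, kb = 0, pct = 0)))
    }
    per <- lapply(split(copies, copies$family), function(cc) {
        kb <- sum(vapply(split(cc, cc$chrom), function(x) {
            interval_union_length(x$start, x$end)
        }, numeric(1))) / 1000
        data.frame(family = cc$family[1], copies = nrow(cc),
                   full_length = sum(cc$full_length),
                   fragments = sum(cc$n_fragments),
                   kb = kb, pct = 100 * kb * 1000 / glen)
    })
    tab <- do.call(rbind, per)
    rownames(tab) <- NULL
    union_kb <- sum(vapply(split(copies, copies$chrom), function(x) {
        interval_union_length(x$start, x$end)
    }, numeric(1))) / 1000
    totals <- data.frame(copies = nrow(copies),
                         full_length = sum(copies$full_length),
                         fragments = sum(copies$n_fragments),
                         kb = union_kb, pct = 100 * union_kb * 1000 / glen)
    list(table = tab, totals = totals)
}

#' Estimate TE content from unassembled reads
#'
#' Reads are subsampled to a coverage target, repeat-masked with the
#' library, and the masked fraction reported per subsample together with
#' the between-subsample correlation of per-family masked amounts.
#'
#' @param reads named character vector of read sequences.
#' @param families families data.frame (or named consensus vector).
#' @param n_subsamples number of independent subsamples (default 2).
#' @param coverage_target subsample size as a multiple of `genome_length`;
#'   `NULL` uses all reads in every subsample.
#' @param genome_length assembly length used to interpret
#'   `coverage_target`.
#' @param seed RNG seed for the subsampling.
#' @param min_length,max_evalue,min_identity masking hit thresholds; reads
#'   are short, so the length floor is lower than for assemblies.
#' @return list with `fractions` (per subsample), `per_family` (matrix of
#'   masked nt, family x subsample) and `r_squared` (Pearson between the
#'   first two subsamples; `NA` if fewer than two).
#' @export
estimate_te_content_from_reads <- function(reads, families, n_subsamples = 2L,
                                           coverage_target = NULL,
                                           genome_length = NULL, seed,
                                           min_length = 30L,
                                           max_evalue = 1e-10,
                                           min_identity = 0.8) {
    stopifnot(length(reads) >= 1L)
    set.seed(seed)
    if (is.data.frame(families)) {
        lib <- setNames(families$consensus, families$name)
    } else {
        lib <- families
    }
    idx <- build_index(lib)
    fam_names <- names(lib)
    read_len <- nchar(reads)
    pick_subsample <- function() {
        if (is.null(coverage_target) || is.null(genome_length)) {
            return(seq_along(reads))
        }
        target_nt <- coverage_target * genome_length
        o <- sample(seq_along(reads))
        cum <- cumsum(read_len[o])
        if (cum[length(cum)] < target_nt) {
            warning("coverage target exceeds available reads; using all")
            return(o)
        }
        o[seq_len(which(cum >= target_nt)[1])]
    }
    fractions <- numeric(n_subsamples)
    per_family <- matrix(0, nrow = length(fam_names), ncol = n_subsamples,
                         dimnames = list(fam_names, NULL))
    warned <- FALSE
    for (s in seq_len(n_subsamples)) {
        sel <- withCallingHandlers(
            pick_subsample(),
            warning = function(w) {
                if (warned) invokeRestart("muffleWarning")
                warned <<- TRUE
            })
        masked <- 0
        for (i in sel) {
            h <- local_search(idx, reads[i], min_identity = min_identity,
                              min_length = min_length,
                              max_evalue = max_evalue)
            if (nrow(h) == 0L) next
            m <- merge_intervals(h$qstart, h$qend)
            masked <- masked + sum(m$end - m$start)
            for (f in unique(h$target)) {
                hh <- h[h$target == f, , drop = FALSE]
                per_family[f, s] <- per_family[f, s] +
                    interval_union_length(hh$qstart, hh$qend)
            }
        }
        fractions[s] <- masked / sum(read_len[sel])
    }
    r2 <- if (n_subsamples >= 2L &&
              isTRUE(stats::sd(per_family[, 1]) > 0) &&
              isTRUE(stats::sd(per_family[, 2]) > 0)) {
        cor(per_family[, 1], per_family[, 2])^2
    } else NA_real_
    list(fractions = fractions, per_family = per_family, r_squared = r2)
}
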