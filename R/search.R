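# Seed-and-extend local similarity search: the package's stand-in for a
# BLAST-like engine at desk scale. Scoring: match +1, mismatch -2, gap open
# -5, gap extend -2 (nucleotide); BLOSUM62 with gap 11/1-style penalties is
# deliberately NOT used -- the protein path reuses BLOSUM62 with the same
# affine penalties for simplicity, stated in the docs.

# classical ungapped Karlin-Altschul constants for the +1/-2 scoring
.NT_LAMBDA <- 1.28
.NT_K <- 0.46
# classical ungapped BLOSUM62 constants
.AA_LAMBDA <- 0.3176
.AA_K <- 0.134

#' Build a k-mer index over a set of target sequences
#'
#' The index stores every k-mer position of every target; queries are later
#' searched in forward and reverse-complement orientation against it, so
#' both strands are covered implicitly.
#'
#' @param targets named character vector of nucleotide (or peptide)
#'   sequences; ids must be unique.
#' @param k seed length; 8--32 for nucleotides (default 11), 3--6 for
#'   peptides (default 4).
#' @param alphabet `"nt"` or `"aa"`.
#' @return An object of class `"search_index"`.
#' @export
build_index <- function(targets, k = 11L, alphabet = c("nt", "aa")) {
    alphabet <- match.arg(alphabet)
    if (length(targets) > 0 && is.null(names(targets))) {
        stop("targets must be named")
    }
    if (anyDuplicated(names(targets))) {
        stop("duplicate target ids: ",
             paste(unique(names(targets)[duplicated(names(targets))]),
                   collapse = ", "))
    }
    if (alphabet == "nt") {
        if (k < 8L || k > 32L) stop("k must be in [8, 32] for nucleotides")
        enc <- lapply(targets, encode_dna)
        seed_asz <- 4L
    } else {
        if (k < 3L || k > 6L) stop("k must be in [3, 6] for peptides")
        enc <- lapply(targets, encode_aa)
        seed_asz <- 20L
    }
    short <- vapply(enc, length, integer(1)) < k
    if (any(short)) {
        warning("skipping ", sum(short), " target(s) shorter than k")
        enc <- enc[!short]
        targets <- targets[!short]
    }
    ptr <- cpp_build_index(unname(enc), as.integer(k), seed_asz)
    structure(list(ptr = ptr, k = as.integer(k), alphabet = alphabet,
                   target_ids = names(targets),
                   target_lengths = setNames(nchar(targets), names(targets)),
                   n_positions = cpp_index_n_positions(ptr)),
              class = "search_index")
}

#' @export
print.search_index <- function(x, ...) {
    cat(sprintf("search_index: %d %s target(s), %s bp, k = %d, %d seed positions\n",
                length(x$target_ids), x$alphabet,
                format(sum(x$target_lengths), big.mark = ","), x$k,
                x$n_positions))
    invisible(x)
}

# bit score and expected-hit statistic for a raw score
evalue_like <- function(score, m, n, lambda, K) {
    bit <- (lambda * score - log(K)) / log(2)
    as.numeric(m) * as.numeric(n) * 2^(-bit)
}

empty_hits <- function() {
    data.frame(query = character(), target = character(),
               qstart = integer(), qend = integer(),
               tstart = integer(), tend = integer(),
               strand = character(), length = integer(),
               identity = numeric(), score = integer(),
               evalue = numeric(), stringsAsFactors = FALSE)
}

#' Search a query sequence against an index
#'
#' Exact k-mer seeds are chained and extended by a banded affine-gap local
#' alignment (match +1, mismatch -2, gap open -5, gap extend -2).
#' Overlapping hits to the same target and strand are merged keeping the
#' best score. Hits are filtered by identity, target-span length and the
#' expected-hit statistic, and sorted by descending score (ties: leftmost
#' target start, then + strand).
#'
#' @param index a `"search_index"` from [build_index()].
#' @param query a single sequence (character scalar, optionally named).
#' @param min_identity minimum fraction of matching columns.
#' @param min_length minimum hit length on the target, bp.
#' @param max_evalue expected-hit cutoff (default `1e-15`, the package's
#'   nucleotide significance default).
#' @param query_id id used in the output (default the name of `query`).
#' @param band,margin,chain_gap engine tuning: band half-width of the
#'   alignment around the seed diagonals, window margin beyond the outermost
#'   seeds, and the maximum seed gap bridged within one chain.
#' @param both_strands search the reverse complement as well (nucleotide
#'   indexes only).
#' @return data.frame of hits: `query`, `target`, `qstart`, `qend`,
#'   `tstart`, `tend` (target coordinates, 0-based half-open, forward
#'   strand), `strand`, `length`, `identity`, `score`, `evalue`.
#' @export
local_search <- function(index, query, min_identity = 0.5, min_length = 50L,
                         max_evalue = 1e-15, query_id = NULL,
                         band = 32L, margin = 100L, chain_gap = 200L,
                         both_strands = TRUE) {
    stopifnot(inherits(index, "search_index"))
    if (is.null(query_id)) {
        query_id <- if (!is.null(names(query))) names(query)[1] else "query"
    }
    query <- toupper(as.character(query)[1])
    if (is.na(query) || nchar(query) < index$k ||
        length(index$target_ids) == 0L) {
        return(empty_hits())
    }
    nt <- index$alphabet == "nt"
    smat <- if (nt) .dna_score_matrix() else .aa_score_matrix()
    lambda <- if (nt) .NT_LAMBDA else .AA_LAMBDA
    K <- if (nt) .NT_K else .AA_K
    qlen <- nchar(query)
    run <- function(q, strand) {
        enc <- if (nt) encode_dna(q) else encode_aa(q)
        h <- cpp_search(index$ptr, enc, smat, 5L, 2L, as.integer(band),
                        as.integer(margin), as.integer(chain_gap), 1L, 200L)
        if (nrow(h) == 0L) return(NULL)
        if (strand == "-") {
            qs <- qlen - h$qend
            qe <- qlen - h$qstart
            h$qstart <- qs
            h$qend <- qe
        }
        h$strand <- strand
        h
    }
    hits <- run(query, "+")
    if (both_strands && nt) {
        hits <- rbind(hits, run(revcomp(query), "-"))
    }
    if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
    n_total <- sum(index$target_lengths)
    out <- data.frame(query = query_id,
                      target = index$target_ids[hits$tid],
                      qstart = hits$qstart, qend = hits$qend,
                      tstart = hits$tstart, tend = hits$tend,
                      strand = hits$strand,
                      length = hits$tend - hits$tstart,
                      identity = hits$matches / pmax(1L, hits$alnlen),
                      score = hits$score,
                      evalue = evalue_like(hits$score, qlen, n_total,
                                           lambda, K),
                      stringsAsFactors = FALSE)
    out <- merge_strand_hits(out)
    out <- out[out$identity >= min_identity & out$length >= min_length &
               out$evalue <= max_evalue, , drop = FALSE]
    out <- out[order(-out$score, out$target, out$tstart,
                     match(out$strand, c("+", "-"))), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# merge overlapping hits per (target, strand), keeping the best score
merge_strand_hits <- function(hits) {
    if (nrow(hits) <= 1L) return(hits)
    keep <- rep(TRUE, nrow(hits))
    o <- order(-hits$score, hits$tstart)
    for (g in split(o, paste(hits$target[o], hits$strand[o]))) {
        kept_s <- numeric(0)
        kept_e <- numeric(0)
        for (i in g) {
            ov <- overlap_with_set(hits$tstart[i], hits$tend[i], kept_s, kept_e)
            if (ov > 0.5 * (hits$tend[i] - hits$tstart[i])) {
                keep[i] <- FALSE
            } else {
                kept_s <- c(kept_s, hits$tstart[i])
                kept_e <- c(kept_e, hits$tend[i])
            }
        }
    }
    hits[keep, , drop = FALSE]
}

#' Translated search of a nucleotide query against a peptide panel
#'
#' All six reading frames are translated (stop codons break the frame into
#' segments) and searched against the panel with BLOSUM62 scoring. The best
#' hit per panel entry is retained.
#'
#' @param query nucleotide sequence (character scalar, optionally named).
#' @param peptide_panel named character vector of peptide sequences, or a
#'   data.frame with columns `id`, `seq` (and optionally `label`).
#' @param max_evalue expected-hit cutoff (default `1e-5`, the package's
#'   peptide significance default).
#' @param k peptide seed length (default 4).
#' @return data.frame of hits with nucleotide query coordinates and a
#'   `frame` column; `target` is the panel entry id.
#' @export
translated_search <- function(query, peptide_panel, max_evalue = 1e-5,
                              k = 4L) {
    if (is.data.frame(peptide_panel)) {
        panel <- setNames(peptide_panel$seq, peptide_panel$id)
    } else {
        panel <- peptide_panel
    }
    if (length(panel) == 0L) stop("peptide panel is empty")
    query_id <- if (!is.null(names(query))) names(query)[1] else "query"
    query <- toupper(as.character(query)[1])
    if (nchar(query) < 3L * k) return(empty_hits())
    idx <- build_index(panel, k = k, alphabet = "aa")
    all_hits <- list()
    for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
        pep <- translate_frame(query, frame)
        if (!nzchar(pep)) next
        segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
        off <- 0L
        for (seg in segs) {
            if (nchar(seg) >= k) {
                h <- local_search(idx, seg, min_identity = 0,
                                  min_length = k, max_evalue = Inf,
                                  query_id = query_id, both_strands = FALSE)
                if (nrow(h) > 0L) {
                    # peptide coords -> nucleotide coords on the query
                    aa_s <- off + h$qstart
                    aa_e <- off + h$qend
                    if (frame > 0) {
                        h$qstart <- (frame - 1L) + 3L * aa_s
                        h$qend <- (frame - 1L) + 3L * aa_e
                        h$strand <- "+"
                    } else {
                        nt_s <- (-frame - 1L) + 3L * aa_s
                        nt_e <- (-frame - 1L) + 3L * aa_e
                        h$qstart <- nchar(query) - nt_e
                        h$qend <- nchar(query) - nt_s
                        h$strand <- "-"
                    }
                    h$frame <- frame
                    h$evalue <- evalue_like(h$score, nchar(pep),
                                            sum(nchar(panel)),
                                            .AA_LAMBDA, .AA_K)
                    all_hits[[length(all_hits) + 1L]] <- h
                }
            }
            off <- off + nchar(seg) + 1L
        }
    }
    if (length(all_hits) == 0L) {
        out <- empty_hits()
        out$frame <- integer(0)
        return(out)
    }
    hits <- do.call(rbind, all_hits)
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    # best hit per panel entry
    hits <- hits[order(-hits$score, hits$target), , drop = FALSE]
    hits <- hits[!duplicated(hits$target), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Mask hit-covered regions of a sequence
#'
#' @param sequence a single sequence (character scalar, optionally named).
#' @param hits data.frame of hits on this sequence; intervals are taken
#'   from columns `tstart`/`tend` if present, else `start`/`end`.
#' @param hard if `TRUE` (default) covered positions become `N`; otherwise
#'   they are lowercased (soft masking).
#' @return list with `sequence` (masked) and `masked_fraction`
#'   (union length / sequence length).
#' @export
mask_regions <- function(sequence, hits, hard = TRUE) {
    s <- as.character(sequence)[1]
    L <- nchar(s)
    if (is.null(hits) || nrow(hits) == 0L) {
        return(list(sequence = s, masked_fraction = 0))
    }
    st <- if ("tstart" %in% names(hits)) hits$tstart else hits$start
    en <- if ("tend" %in% names(hits)) hits$tend else hits$end
    if (any(st < 0) || any(en > L)) stop("hit interval out of sequence bounds")
    m <- merge_intervals(st, en)
    r <- charToRaw(s)
    for (i in seq_len(nrow(m))) {
        span <- (m$start[i] + 1L):m$end[i]
        if (hard) {
            r[span] <- charToRaw("N")
        } else {
            r[span] <- as.raw(bitwOr(as.integer(r[span]), 0x20L))
        }
    }
    list(sequence = rawToChar(r),
         masked_fraction = sum(m$end - m$start) / L)
}
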