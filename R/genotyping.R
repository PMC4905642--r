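# Genotyping of TE and gene loci between two haplotypes from a
# whole-genome-alignment block map. A locus is homozygous when alignment
# blocks cover at least 80% of it, heterozygous when the other allele is
# absent (zero coverage), and ambiguous in between; ambiguous calls are
# excluded from summary percentages (configurable).

#' Read a whole-genome-alignment block map
#'
#' Tab-separated with header columns `ref_chrom`, `ref_start`, `ref_end`,
#' `other_chrom`, `other_start`, `other_end` (0-based half-open).
#'
#' @param path input TSV.
#' @return data.frame of alignment blocks.
#' @export
read_alignment_blocks <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("ref_chrom", "ref_start", "ref_end",
              "other_chrom", "other_start", "other_end")
    if (!all(need %in% names(df))) {
        stop("block map must have columns: ", paste(need, collapse = ", "))
    }
    if (any(df$ref_end <= df$ref_start)) stop("non-positive block on reference")
    df[need]
}

#' Alignment coverage of one locus
#'
#' @param locus_start,locus_end locus span (0-based half-open).
#' @param block_starts,block_ends reference spans of the alignment blocks
#'   on the locus chromosome (non-overlapping).
#' @return Fraction of the locus covered by blocks, in \[0, 1\].
#' @export
locus_coverage <- function(locus_start, locus_end, block_starts, block_ends) {
    len <- locus_end - locus_start
    if (len <= 0) stop("zero-length locus")
    overlap_with_set(locus_start, locus_end, block_starts, block_ends) / len
}

#' Genotype call from alignment coverage
#'
#' @param coverage_fraction coverage of the locus by alignment blocks.
#' @param homozygous_threshold coverage at or above which the locus is
#'   called homozygous (default 0.8, inclusive).
#' @return `"homozygous"`, `"heterozygous"` (coverage exactly 0) or
#'   `"ambiguous"`.
#' @export
genotype_locus <- function(coverage_fraction, homozygous_threshold = 0.8) {
    stopifnot(all(coverage_fraction >= 0), all(coverage_fraction <= 1))
    ifelse(coverage_fraction >= homozygous_threshold, "homozygous",
           ifelse(coverage_fraction == 0, "heterozygous", "ambiguous"))
}

#' Genotype all TE and gene loci
#'
#' @param te_loci data.frame of TE loci (`chrom`, `start`, `end`, plus any
#'   id/family columns, carried through).
#' @param gene_loci data.frame of gene loci (same shape).
#' @param blocks alignment block map (see [read_alignment_blocks()]).
#' @param homozygous_threshold see [genotype_locus()].
#' @return list with `calls` (per-locus coverage and state, TE and gene
#'   loci concatenated with a `locus_type` column) and `summary`
#'   (percent heterozygous among genes and among TEs, ambiguous calls
#'   excluded from the denominators).
#' @export
genotype_all <- function(te_loci, gene_loci, blocks,
                         homozygous_threshold = 0.8) {
    bl <- split(blocks, blocks$ref_chrom)
    call_set <- function(loci, type) {
        if (is.null(loci) || nrow(loci) == 0L) return(NULL)
        cov <- vapply(seq_len(nrow(loci)), function(i) {
            b <- bl[[loci$chrom[i]]]
            if (is.null(b)) return(0)
            locus_coverage(loci$start[i], loci$end[i],
                           b$ref_start, b$ref_end)
        }, numeric(1))
        loci$locus_type <- type
        loci$coverage <- cov
        loci$state <- genotype_locus(cov, homozygous_threshold)
        loci
    }
    te_calls <- call_set(te_loci, "te")
    gene_calls <- call_set(gene_loci, "gene")
    all_names <- union(names(te_calls), names(gene_calls))
    pad <- function(df) {
        if (is.null(df)) return(NULL)
        for (nm in setdiff(all_names, names(df))) df[[nm]] <- NA
        df[all_names]
    }
    calls <- rbind(pad(te_calls), pad(gene_calls))
    if (is.null(calls)) stop("no loci to genotype")
    pct_het <- function(type) {
        st <- calls$state[calls$locus_type == type & calls$state != "ambiguous"]
        if (length(st) == 0L) return(NA_real_)
        100 * mean(st == "heterozygous")
    }
    list(calls = calls,
         summary = data.frame(
             pct_het_genes = pct_het("gene"),
             pct_het_te = pct_het("te"),
             n_ambiguous = sum(calls$state == "ambiguous")))
}

#' Ortholog pairs with a polymorphic TE insertion nearby
#'
#' Reports ortholog pairs for which a heterozygous (carrier-only) TE lies
#' within `window` bp of, or overlaps, the reference allele of the gene.
#'
#' @param calls calls data.frame from [genotype_all()] (reference-based);
#'   TE rows must carry a `family` column.
#' @param genes data.frame of reference gene models (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param ortholog_map data.frame with columns `gene_a` (reference id) and
#'   `gene_b` (other-haplotype id).
#' @param window maximum edge-to-edge distance, bp (default 1000).
#' @param carrier label for the haplotype carrying the TE (default `"A"`,
#'   the reference).
#' @return data.frame with `gene_a`, `gene_b`, `family`, `carrier`,
#'   `distance`.
#' @export
polymorphic_neighbors <- function(calls, genes, ortholog_map,
                                  window = 1000L, carrier = "A") {
    het_te <- calls[calls$locus_type == "te" &
                    calls$state == "heterozygous", , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(genes))) {
        tt <- het_te[het_te$chrom == genes$chrom[i], , drop = FALSE]
        if (nrow(tt) == 0L) next
        d <- pmax(0, pmax(tt$start - genes$end[i],
                          genes$start[i] - tt$end))
        near <- which(d <= window)
        if (length(near) == 0L) next
        j <- near[which.min(d[near])]
        gb <- ortholog_map$gene_b[ortholog_map$gene_a == genes$gene_id[i]]
        if (length(gb) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
            gene_a = genes$gene_id[i], gene_b = gb[1],
            family = if ("family" %in% names(tt)) tt$family[j] else NA_character_,
            carrier = carrier, distance = d[j], stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
        return(data.frame(gene_a = character(), gene_b = character(),
                          family = character(), carrier = character(),
                          distance = numeric()))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
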