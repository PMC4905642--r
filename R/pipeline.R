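# End-to-end orchestration: simulate -> build library -> annotate ->
# defragment -> date -> solo-LTRs -> clusters -> genotype -> expression
# impact. Used by the smoke tests and the reproducibility script; each
# stage is also callable on its own.

#' Run the full TE analysis pipeline on a simulation
#'
#' @param sim a `"te_simulation"`, after [simulate_haplotypes()] if
#'   genotyping stages are wanted.
#' @param expr result of [simulate_expression()] (optional; expression
#'   stages are skipped without it).
#' @param peptide_panel reference TE peptide panel for classification;
#'   defaults to panels derived from the simulation's family consensi (see
#'   [sim_peptide_panel()]).
#' @param max_evalue,min_identity annotation thresholds.
#' @param fdr cluster FDR level.
#' @param seed seed for the randomisation test.
#' @return list with each stage's output: `families`, `annotation`,
#'   `copies`, `te_fraction`, `dating`, `solo_ltrs`, `window_stats`,
#'   `clusters`, `distance_test`, `genotypes`, `neighbors`, `scenarios`,
#'   `report`, `onoff`.
#' @export
te_pipeline <- function(sim, expr = NULL, peptide_panel = NULL,
                        max_evalue = 1e-15, min_identity = 0.7,
                        fdr = 0.05, seed = 1L) {
    stopifnot(inherits(sim, "te_simulation"))
    if (is.null(peptide_panel)) peptide_panel <- sim_peptide_panel(sim)

    filt <- filter_ltr_candidates(sim$candidates, sim$genome, peptide_panel)
    fams <- cluster_library(filt$kept)
    fams <- classify_library(fams, peptide_panel)

    ann <- annotate_genome(sim$genome, fams, min_identity = min_identity,
                           max_evalue = max_evalue)
    copies <- defragment_hits(ann, fams)
    frac <- genome_te_fraction(copies, sim$genome)

    dating <- date_all_elements(copies[copies$full_length, , drop = FALSE],
                                sim$genome)
    solos <- solo_ltr_scan(sim$genome,
                           copies[copies$full_length, , drop = FALSE])

    feats <- rbind(
        data.frame(chrom = sim$genes$chrom, start = sim$genes$start,
                   end = sim$genes$end, is_te = FALSE),
        data.frame(chrom = copies$chrom, start = copies$start,
                   end = copies$end, is_te = TRUE))
    ws <- scan_windows(feats, sim$chrom_lengths, q_threshold = fdr)
    cl <- merge_significant_windows(ws, copies, sim$genes)
    dist_test <- if (nrow(copies) >= 2) {
        inter_element_distance_test(copies, sim$chrom_lengths, seed = seed)
    } else NULL

    genotypes <- NULL
    neighbors <- NULL
    if (!is.null(sim$blocks)) {
        te_loci <- copies[c("copy_id", "family", "chrom", "start", "end")]
        gene_loci <- data.frame(gene_id = sim$genes$gene_id,
                                chrom = sim$genes$chrom,
                                start = sim$genes$start,
                                end = sim$genes$end)
        genotypes <- genotype_all(te_loci, gene_loci, sim$blocks)
        calls <- genotypes$calls
        ortho <- data.frame(gene_a = sim$genes$gene_id,
                            gene_b = sim$genes$gene_id)
        neighbors <- polymorphic_neighbors(calls, sim$genes, ortho)
    }

    scenarios <- scenario_partition(sim$genes, copies,
                                    chrom_lengths = sim$chrom_lengths)
    report <- NULL
    onoff <- NULL
    if (!is.null(expr)) {
        report <- scenario_report(scenarios, expr$expr_a,
                                  clusters = cl$clusters)
        if (!is.null(expr$expr_b) && !is.null(neighbors) &&
            nrow(neighbors) > 0) {
            onoff <- ortholog_onoff(neighbors, expr$expr_a, expr$expr_b)
        }
    }

    list(filter_report = filt$report, families = fams, annotation = ann,
         copies = copies, te_fraction = frac, dating = dating,
         solo_ltrs = solos, window_stats = ws, clusters = cl,
         distance_test = dist_test, genotypes = genotypes,
         neighbors = neighbors, scenarios = scenarios, report = report,
         onoff = onoff)
}

#' Peptide and nucleotide panels derived from a simulation
#'
#' Builds a labelled peptide panel by translating the internal region of
#' each simulated LTR family (longest open segment of frame +1), mimicking
#' a reference TE protein database for classification tests. The panel is
#' synthetic: it derives from the simulation's own consensi, not from any
#' curated database.
#'
#' @param sim a `"te_simulation"`.
#' @return data.frame with `id`, `seq`, `label`.
#' @export
sim_peptide_panel <- function(sim) {
    rows <- lapply(seq_len(nrow(sim$families)), function(i) {
        fam <- sim$families[i, ]
        pep <- translate_frame(fam$internal, 1L)
        segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
        segs <- segs[order(-nchar(segs))]
        if (length(segs) == 0L || nchar(segs[1]) < 30L) return(NULL)
        data.frame(id = paste0(fam$name, "_pol"),
                   seq = segs[1], label = fam$label,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
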