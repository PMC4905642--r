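---
title: "Methods: transposable-element genome architecture and expression impact"
author: "tescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element genome architecture and expression impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tescape` re-implements, as a tested library, the standard analysis chain
used to characterise the transposable-element (TE) landscape of a compact
fungal genome and its consequences for nearby genes:

1. build and filter a TE consensus library from candidate repeats;
2. annotate the assembly with that library and reconstruct fragmented
   copies;
3. date LTR-retrotransposon insertions from the divergence of their two
   long terminal repeats (LTRs);
4. detect solo-LTRs (recombination relics);
5. locate TE-dense clusters with a hypergeometric sliding-window scan
   under FDR control;
6. genotype insertions as homozygous or heterozygous between two
   haplotypes using a whole-genome-alignment block map;
7. test whether genes with TEs in their immediate neighbourhood are
   transcriptionally repressed.

Every stage is exercised against a synthetic-genome generator whose truth
is known exactly, so correctness claims are parameter-recovery claims, not
anecdotes.

# Coordinates and formats

All coordinates inside the package are 0-based half-open. GFF3 (1-based
inclusive) is converted at the I/O boundary only; BED passes through.
Features on unknown chromosomes are rejected with a named error rather
than dropped: silent loss of annotation rows is the classic source of
irreproducible TE tables. `N` residues never count as matches anywhere —
they cannot seed the search engine and score as mismatches.

# The search primitive

The annotation stages need a local similarity search. `tescape` ships its
own seed-and-extend engine (`build_index()`, `local_search()`,
`translated_search()`):

* exact k-mer seeds (default k = 11 nt / 4 aa) from a hash index of the
  targets, queried on both strands;
* seeds chained when near-collinear (diagonal band half-width 32 bp,
  chain gap 200 bp);
* each chain refined by a banded affine-gap Smith–Waterman with the
  scoring `match +1, mismatch −2, gap open −5, gap extend −2`
  (BLOSUM62 for peptides);
* a BLAST-like expected-hit statistic
  `E = m·n·2^(−(λS − ln K)/ln 2)` with the classical ungapped constants
  λ = 1.28, K = 0.46 (nucleotide) and λ = 0.3176, K = 0.134 (BLOSUM62).
  The default significance cutoffs are `1e-15` (nucleotide) and `1e-5`
  (peptide).

These constants are conventions, not fits: the E-value is used as a
ranked threshold, exactly as the corresponding cutoffs are used in
practice. The engine's contract is checked against an exact
Smith–Waterman oracle (an independent dynamic-programming implementation)
on planted-homology pairs: the top hit's target interval must agree
within ±10 bp and its score never exceeds the optimum. The banded
refinement can in principle miss an optimum lying far off every seed
diagonal; with ≥ 70% identity and these seed lengths the band is
effectively never binding, which is what the oracle test verifies.

# Library construction

Candidate filtering follows the rule: keep a candidate iff it is longer
than 400 bp AND (it has more than five genomic copies OR a significant
translated hit to a reference LTR-retrotransposon peptide). The length
condition is applied unconditionally — reading the rule any other way
would let a 100 bp artefact survive on a chance peptide hit. A "copy"
is a nucleotide hit at the `1e-15` cutoff covering at least half the
candidate; the coverage floor keeps micro-satellite matches from
counting.

Clustering is greedy centroid clustering at 80% global-alignment
identity: candidates sorted by decreasing length (ties by id) either join
the first centroid reaching the threshold or found a new cluster. The
cluster consensus is the centroid sequence itself; no multiple-alignment
consensus is rebuilt, which keeps the stage deterministic.
Classification takes the label of the best translated hit (then the best
nucleotide hit); families without any hit become `"unknown"` and are
flagged out of all downstream analyses.

Defragmentation joins same-family, same-strand, consensus-collinear hits
within 5 kb of genomic gap. The 5 kb default is a package choice (the
upstream tooling this emulates does not publish its gap rule) and is
exposed as `max_gap`. A copy is full-length at ≥ 90% of its family
consensus. Per-family occupancy uses the per-family span union; the
genome-total row uses the cross-family union, so overlapping annotation
can never push the total past 100%.

# Insertion dating

The two LTRs of an element are identical at insertion and accumulate
substitutions independently afterwards. After global alignment of the
detected LTR pair, the Kimura two-parameter distance

\[ K = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q) \]

(P transitions, Q transversions, gap/N columns excluded) converts to an
age through the fungal substitution rate μ = 1.05 × 10⁻⁹
substitutions/site/year as **T = K / (2μ)**. The divisor 2 reflects the
two independently diverging LTRs; it is exposed (`divisor`) for readers
who prefer the one-branch convention. Saturated pairs
(1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) raise a classed condition and are counted
in a QC column, never silently dropped.

A statistical point that shapes the tests: a 500 bp LTR pair inserted
1 My ago carries about one expected substitution, so *per-element* ages
at that horizon have ~100% relative noise no matter the estimator. The
estimator is unbiased, and the package's recovery checks therefore
score the *cohort mean* (50 elements per planted age, recovered within
15%) rather than per-element error. For the amplification-burst check the
fixture uses 1.5 kb LTRs so that the zero-age bin is identifiable
(P(no substitution) for a genuinely recent element is then small).

Solo-LTRs follow the operational definition: the left LTR of a
representative autonomous copy is searched genome-wide at `1e-15`; each
hit's two 5 kb flanks are screened for the family's internal sequence;
hits with no internal match on either flank and no overlap with an
annotated element are solo. Note the definition itself classifies a lone
LTR that happens to sit within 5 kb of unrelated internal sequence as
non-solo; the controlled fixtures place their planted solos accordingly.

# Cluster discovery

Genes and TEs are merged into one feature set; 100 kb windows shifted by
10 kb count features by midpoint (midpoint membership keeps window counts
additive; any-overlap membership is available for sensitivity analysis).
Windows with fewer than 10 features are skipped. Each window's TE count
is scored with the upper-tail hypergeometric probability against the
genome-wide composition, adjusted by Benjamini–Hochberg, and flagged at
FDR 5%. Overlapping windows are positively correlated, so BH here is
conservative in practice — the null simulations (1000 uniform-placement
replicates) show well under 5% of replicates with any significant
window. Significant windows are unioned into cluster regions; TEs and
genes are assigned to clusters by midpoint.

The inter-element distance randomisation test compares observed inter-TE
start distances with those of an equally sized uniform random set on the
same chromosome partition by a two-sided rank test. Gaps within one
sample are negatively correlated (they sum to the chromosome length), so
the test is *conservative* under the null — it controls size but does not
achieve it. It also has little power against moderate clustering, because
clustering produces both more small and more large gaps while the mean is
fixed; the hypergeometric scan is the workhorse, and the distance test is
kept as the conventional companion statistic.

# Genotyping between haplotypes

A locus is homozygous when alignment blocks cover ≥ 80% of it (boundary
inclusive), heterozygous when coverage is exactly zero (the other allele
absent), and *ambiguous* in between. The third state is a package
decision: the original dichotomy leaves (0, 0.8) undefined, and silently
assigning those loci either way would bias the percentages. Summary
percentages exclude ambiguous calls and say so. Coverage evaluates the
locus span as given; whether flanking sequence should also be required to
be absent is left to the caller's choice of span.

# Expression impact

Genes overlapping any TE ("TE-associated") are excluded from the
neighbourhood analysis. For the rest, the nearest TE within 1 kb
upstream, downstream, or on both sides (strand-aware: upstream = 5′ of
the start codon; a strand-agnostic mode exists for sensitivity analysis)
defines scenarios UP, DOWN and BOTH ("captured"); everything else is the
control, by subtraction. Distances are edge-to-edge, 0 for book-ended
features. The partition is asserted to be exhaustive and mutually
exclusive on every run. Genes within 1 kb of a contig edge keep their
assignment but carry an `edge` flag.

Each scenario is compared with its stratum's control by a two-sided
Mann–Whitney–Wilcoxon test: exact enumeration for tie-free samples with
n₁+n₂ ≤ 16, otherwise the normal approximation with tie-corrected
variance and continuity correction. When cluster regions are supplied the
report is stratified inside/outside clusters and the inside-control
versus outside-control test is appended.

Ortholog on/off tables list pairs where the allele carrying the TE is
silent (RPKM = 0) while the TE-free allele is active; the companion fold
table uses a 5-fold threshold with a non-zero TE-allele. Per-family TE
expression is the summed copy expression normalised to copy number;
log₂ display maps zero to half the smallest positive per-copy value
(display only — statistics always use raw values).

# The synthetic-genome generator

The generator (`simulate_genome()`, `simulate_haplotypes()`,
`simulate_expression()`) is first-class, tested code. Its defaults are
the study conditions of the test suite:

* 5 Mb across two chromosomes, i.i.d. background at 50% GC (a deliberate
  simplification — no isochores, no k-mer structure);
* genes with exponential intergenic gaps of mean 1.14 kb and normal
  lengths (1.5 kb ± 0.3 kb), random strands;
* three LTR families (Gypsy-like ×2, Copia-like) and one Class II
  (Helitron-like) family: full-length elements built LTR–internal–LTR
  with both LTRs *independently* mutated at μT each — so the dating
  divisor decision is itself testable — plus truncated fragments,
  solo-LTRs and target-site duplications;
* insertion ages from a burst mixture (33% at 0 My, 31% within 0.5–5 My,
  the rest 5–20 My);
* three 150 kb clusters receiving 58% of the non-scenario insertions;
* TE fragments planted within 1 kb of chosen genes to populate the
  UP/DOWN/BOTH scenarios at known counts (60 each by default; the
  expression power checks raise this to 170 so every scenario holds at
  least 150 genes);
* haplotype B derived by excising a Bernoulli(0.5) subset of TE copies
  (leaving one TSD) and 7.7% of TE-free gene loci; the alignment block
  map is the complement of the excisions and is exact by construction;
* expression: shared log-normal baselines, repression of UP/DOWN genes
  with probability 0.5 by factor 0.1, captured genes always by 0.02,
  Poisson counts (negative-binomial overdispersion available), and TE
  copies expressed family-wise (60% of families with at least one active
  copy).

Insertion points are drawn in the background coordinate space and applied
jointly, so planted elements never nest and all truth coordinates are
exact. Everything is reproducible bit-for-bit from the seed.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: indel evolution and alignment ambiguity,
nested and recombined insertions, compositional heterogeneity of real
chromosomes, mapping noise in count tables, and repeat-induced point
mutation spectra. Conclusions about real genomes inherit the usual caveat
that annotation quality dominates.

# Numerical and design notes

* The K2P inversion in `mutate_sequence()` solves for the per-site
  substitution probability by `uniroot` on the closed form, so the
  *expected* measured distance equals the target; targets ≥ 1
  substitution/site are refused as saturated.
* Hit merging, clustering and tie-breaks are all deterministic (score,
  then leftmost coordinate, then strand/id), so identical inputs give
  identical outputs.
* `phyper`, `p.adjust(method = "BH")`, `wilcox.test` and `fisher.test`
  do the standard statistics; each is verified in the test suite against
  an independent brute-force implementation (exhaustive enumeration for
  the hypergeometric tail over all N ≤ 30, all labelings for the rank
  test at n₁+n₂ ≤ 12, the step-up rule for BH).
* Problem sizes in the tests (5 Mb genomes, 50-element dating cohorts,
  1000-replicate nulls) were chosen as the smallest sizes at which the
  recovery targets are statistically identifiable.

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes the package's main quantities from
scratch — closed-form K2P values, cohort age recovery, burst fractions,
search-versus-oracle agreement, the full 5 Mb pipeline (families, genome
percentage, clusters), solo-LTR precision/recall, heterozygosity
recovery, scenario power and type-I rate, the null FDR of the window
scan, and the read-survey estimate — and writes them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
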