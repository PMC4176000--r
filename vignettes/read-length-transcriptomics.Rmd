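---
title: "Read-length effects in RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-length effects in RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longrna)
```

# Scope

`longrna` implements the analysis layer of a read-length comparison for bulk
RNA-seq: given two libraries of the same transcriptome sequenced at
different read lengths, it quantifies how read length changes (i) the
mergeability of overlapping read pairs, (ii) RNA/DNA genotype concordance,
(iii) the assignability of fragments to genes and mRNA isoforms, (iv) the
detectability of allele-specific expression (ASE) and allele-specific
alternative splicing (ASAS), and (v) what each observation costs. Running
external aligners or inference-based abundance estimators is out of scope;
their outputs (alignments, id-to-value tables) are inputs here. A
self-contained simulator plus an exhaustive toy aligner make every stage
testable without any download.

# The statistical models

## Overlap merging

A cDNA fragment shorter than the read length is sequenced past its 3' end
into the ligated adapter, so the adapter's start position inside the read
*is* the fragment length. `merge_pair()` locates the adapter independently
in both mates and requires the two implied fragment lengths to agree; the
mates are then collapsed into a single fragment-length read. Rules, in
order: fragments shorter than 20 bases are discarded; mates disagreeing on
more than 10 overlapping bases are discarded; disagreeing bases are
resolved toward the higher base quality, with mate 1 winning ties and the
merged quality being the per-position maximum. Pairs in which the adapter
is absent, found in only one mate, or found at inconsistent positions stay
paired. At a per-base error rate $e$, two independent reads of the same
base disagree with probability $2e(1-e) + \tfrac{2}{3}e^2$ (either mate
errs alone, or both err to different bases); the observed disagreement rate
over overlapping bases is reported and converges to this value on
simulated data.

Adapter matching tolerates 0 mismatches over the full 13-mer. At the read
end, where only a prefix of the adapter is visible, a 6+ base prefix may
mismatch once and a 5-base prefix must match exactly; shorter prefixes are
uninformative (a 1–2 base "match" occurs by chance in most reads), so
fragments within 4 bases of the read length are undetectable and their
pairs are kept. These tolerances are a design choice; the merge thresholds
(20 bases, 10 disagreements, 13-base adapter) are fixed by the procedure
being implemented.

## Genotype concordance

At a genotyped SNP with depth $n_i$, let $x_i$ count the reads whose base
matches neither genotype allele (allelic imbalance is therefore *not*
penalized). Under a no-mismapping null, $x_i \sim \mathrm{Binomial}(n_i,
\varepsilon)$ with $\varepsilon$ the per-base sequencing error rate, and
the *discordance p-value* is the upper tail $P(X \ge x_i)$. $\varepsilon$
is estimated per dataset as total mismatches over total aligned bases at
the analyzed sites. Sites need depth $\ge 10$; two libraries are compared
per depth bin (10–99, 100–499, 500–999, $\ge$1000, each library binned by
its own depth) with a one-sided Wilcoxon rank-sum test of whether the
first library's p-values are stochastically larger (more concordant).
Genotyped indels are summarized by the modal observed indel size among
spanning reads, with ties broken toward the smaller magnitude and flagged.

## Feature assignment

Each reference base carries the set of features containing it — genes
(genic footprint) or isoforms (exonic bases). A fragment's *consistent
features* are the intersection of the nonempty per-base sets over all
bases covered by either mate; ignoring empty sets lets alignments overhang
unannotated sequence without destroying the assignment. At isoform level,
every splice junction implied by the alignment must additionally occur in
the isoform's intron chain; a junction matching no candidate empties the
set. A singleton set is an unambiguous assignment. The per-fragment
*effective alignment length* is the number of distinct reference bases
covered, which is the natural stratifier for read-length effects within a
library.

Transcript abundance is estimated without inference: count fragments
unambiguous to a transcript and divide by the transcript's *unique bases*
(exonic bases belonging to no sibling isoform; transcripts with fewer than
10 are excluded, and the analysis set is protein-coding genes with
multiple isoforms). Uniqueness is scoped within the gene — cross-gene
ambiguity is already handled by unambiguous gene assignment. External
estimators are evaluated by Spearman correlation against these unique-base
abundances over genes below a sweep of ambiguity-rate thresholds, with a
seeded bootstrap over genes for the difference between two estimators.

Mappability enters as a per-gene length-weighted mean of an interval
score track (uncovered bases score 0). Genes observed in both libraries
and at least 500 bases long are split into five near-equal groups by mean
score; per group we report the fraction of genes with a higher read
proportion in the long-read library.

## Allele-specific analysis

A fragment is assigned to the maternal or paternal haplotype only if every
phased heterozygous site it covers carries that haplotype's allele; a
mixture or a non-allelic base is conflicting. For alignments covering $L$
bases, the assignable fraction under a Poisson het-site model is
$p(L) = 1 - e^{-\lambda L}$; `fit_poisson_model()` obtains $\lambda$ by
maximizing the Bernoulli likelihood of the per-fragment assignment
indicators (one-dimensional optimization on $\log\lambda$, tolerance
$10^{-8}$, boundary fits flagged), and the fitted curve extrapolates to
read lengths beyond those observed. At the package default
$\lambda = -\ln(0.75)/1000 \approx 2.9\times10^{-4}$ per base, a quarter
of 1,000-base alignments cover a heterozygous site.

Gene-level ASE is a two-sided exact binomial test of the maternal count
against $p = 0.5$ (two-sided because imbalance in either direction is of
interest), requiring 20 haplotype-assigned fragments. ASAS tests each
*exon block* — the atomic intervals obtained by cutting the gene's exonic
union at every isoform's exon boundaries — with a 1-df Pearson chi-square
(no continuity correction) on the 2×2 table of haplotype × block overlap,
requiring 40 assigned fragments per gene; tables with an expected count
below 5 are flagged but tested, and zero-margin tables are skipped. All
blocks of all testable genes enter a single Benjamini–Hochberg pool at
FDR 0.10; `bh_fdr()` is the standard step-up procedure.

Reference-allele mapping bias is diagnosed by the *mapping retention
rate*: every assigned fragment has its het-site alleles swapped to the
other haplotype (`allele_flip()`, an involution) and is realigned;
retention means every mate maps uniquely back to the identical start and
block structure. Genes below rate 0.9 are untestable. HLA-named genes are
excluded by default (`^HLA-` pattern) as hyper-polymorphic genotype risks.
Enrichment of significant genes in an annotated set (e.g. genes with a
heterozygous known-eQTL site) uses the upper-tail hypergeometric.

## Costs and matched comparisons

`cost_per_million_bases()` is price divided by sequenced megabases,
reported at three decimals; the per-read cost ratio and the cost-matched
fraction (cheaper price over dearer price) follow directly. Subsampling
supports read-, base- and cost-matched designs without replacement; in
base-matched mode accumulation stops at the first pair crossing the
target (overshoot at most one pair — a documented choice, since either
convention is defensible). Replicates (default 3) derive their seeds from
the master seed. `truncate_reads()` builds the in-silico short-read
library from long reads; `truncate_fragments()` applies the same cut to
true alignments so downstream stages can run without re-alignment.
Library-preparation cost is excluded by default, with a constant available.

# The simulator

`sim_config()` fixes the study conditions: a single-chromosome genome laid
out as gene loci with 3–6 exons of 80–300 bases and 60–200 base introns; a
configurable fraction of genes duplicated elsewhere with per-base
divergence (annotated as pseudogenes — the low-mappability regime);
heterozygous SNVs placed as a Poisson process (default rate the
quarter-at-1kb regime above); log-normal expression with pseudogene mass
pinned to 5%; fragment lengths from a truncated normal (default mean 180,
sd 60 — mostly below a 262-base read, mostly above 75, matching the
TruSeq-style libraries being modeled); strand-specific pairs with mate 1
transcript-sense; adapter read-through for short fragments (default
adapter the 13-base Illumina TruSeq read-through prefix, since only the
adapter's length is fixed by the procedure); uniform substitution errors;
constant Q37 qualities with an optional linear decay. Every stage re-seeds
from the master seed plus a fixed offset, so identical configurations give
byte-identical output. Truth tables record each fragment's gene,
transcript, haplotype and alignment, and the generator emits standard
formats (FASTA/GTF/VCF/FASTQ/SAM) through thin writers with matching
readers.

The toy aligner does exhaustive substring search with a mismatch budget
(default 4) over both genome strands and all spliced transcript
sequences, collapsing hits with identical genomic blocks; it exists to
close the loop for retention-rate simulations and truth recovery, not to
model any particular mapper's heuristics.

What the simulator does *not* model: PCR duplicates, GC and
transcript-position bias, quality-dependent or indel errors, intergenic
transcription, overlapping genes on the same strand, and fragmentation
chemistry (real fragment-length distributions are set empirically, not
derived). Passing tests on this generator therefore demonstrate
correctness of the statistical machinery and the direction of read-length
effects under idealized noise — not calibrated performance on real
libraries, where mapping artifacts and coverage biases are stronger and
correlated.

# Numerical and design notes

* Coordinates are 1-based inclusive everywhere (the IRanges/GTF/VCF
  convention); emitted files need no shifting.
* Pairs failing the 10-disagreement cap are *discarded* (with the
  too-short fragments), not kept as pairs: the bipartition counts only
  add up under that reading, and `MergeOutcome` has a dedicated
  `discarded_mismatch` status.
* Fragments are the counting unit throughout: a site covered by both
  mates contributes one base call (mate 1's), and a fragment counts once
  per gene in ASE/ASAS tables; a fragment overlapping an exon block with
  either mate counts as overlapping.
* Disagreement positions with equal qualities take mate 1's base; the
  merged quality is the per-position maximum.
* Wilcoxon comparisons use `stats::wilcox.test` (exact for small
  untied samples, midrank/normal otherwise).
* The per-base feature intersection is computed on interval matrices
  (a fragment's candidate features are found by one batched overlap
  query); a literal per-base oracle in the test suite certifies
  equivalence.
* Strand is ignored during feature assignment (the data being modeled are
  strand-specific, but assignment is defined on coverage); junction
  matching is exact interval identity.
* `retention_rate` demands identical start *and* block structure; "same
  location" is otherwise ambiguous for spliced alignments.
* Test and acceptance problem sizes — tens of genes, $10^3$–$10^4$
  fragments, 20–100 replicates — are chosen so that binomial/Poisson
  sampling error is several times smaller than the tolerances being
  asserted while the whole suite stays interactive; the acceptance script
  prints the `n` it used alongside every number.

# Known limitations

Haplotype assignment treats phased sites as ground truth; genotype error
is only addressed via the HLA name filter and the retention diagnostic.
The unique-base abundance estimator is unbiased only under uniform
coverage of the unique region, and fragment-length edge effects at
unique-region boundaries are not corrected. The toy aligner's exhaustive
search is exact but quadratic, so retention analyses are practical only at
simulator scale; with real data, plug in any aligner honoring the
`f(read) -> hit` contract.
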