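#' Simulation configuration for the diploid transcriptome generator
#'
#' Bundles every tunable of the synthetic-data generator: genome layout,
#' gene/isoform structure, heterozygous-site density, fragment-length law,
#' read length, sequencing error, adapter read-through, expression and
#' allelic-imbalance specs. All generator functions re-seed R's RNG from
#' `seed` (plus a fixed per-stage offset), so an identical config yields
#' byte-identical genomes, annotations, site lists and libraries.
#'
#' @param genome_length target minimum genome length in bases; the layout of
#'   gene loci is padded with random intergenic sequence up to this length
#'   (the genome may exceed it if the loci themselves need more room).
#' @param n_genes number of primary (protein-coding) gene loci.
#' @param isoforms_per_gene length-2 integer range; the isoform count of each
#'   gene is drawn uniformly from it.
#' @param duplicate_locus_fraction fraction of genes that also get a diverged
#'   second copy elsewhere in the genome, annotated as a pseudogene. Models
#'   the low-mappability regime (gene families, processed pseudogenes).
#' @param duplicate_divergence per-base substitution rate between a duplicated
#'   locus and its parent, in `[0, 1]`.
#' @param het_density expected heterozygous SNVs per base. Placement is a
#'   Poisson process, the model under which the fraction of alignments of
#'   length L covering at least one het site is `1 - exp(-het_density * L)`.
#'   The default corresponds to the regime where roughly a quarter of
#'   1,000-base alignments contain a het site (`-log(0.75)/1000`).
#' @param fragment_length list with `mean`, `sd`, `min`: cDNA fragment lengths
#'   are drawn from a normal distribution truncated below at `min` (redrawn
#'   until above the floor) and rounded to integer.
#' @param read_length sequenced bases per mate (>= 20).
#' @param error_rate per-base substitution error rate in `[0, 1]`.
#' @param adapter adapter sequence read through when the fragment is shorter
#'   than the read length; at least 13 bases. Default is the Illumina TruSeq
#'   read-through prefix.
#' @param expression either the string `"lognormal"` (per-gene weights drawn
#'   log-normal, meanlog 0 / sdlog 1, at simulation time) or a numeric vector
#'   of per-gene weights named by gene id.
#' @param pseudogene_expression_fraction when `expression = "lognormal"` and
#'   pseudogenes exist, their total expression weight is rescaled to this
#'   fraction of the library.
#' @param allelic_ratio per-gene maternal read fraction in `[0, 1]`; a scalar
#'   is recycled to all genes, or a named vector per gene id.
#' @param isoform_usage `NULL` for uniform isoform usage on both haplotypes,
#'   or a named list (by gene id) of 2-row matrices (rows maternal, paternal;
#'   columns the gene's transcripts in annotation order) of usage weights.
#'   Haplotype-specific weights are how allele-specific splicing is planted.
#' @param n_fragments number of cDNA fragments to draw for a library.
#' @param n_exons,exon_length,intron_length length-2 ranges controlling gene
#'   structure (uniform draws).
#' @param intergenic_gap bases of random sequence between consecutive loci.
#' @param quality list with `profile` (`"constant"` or `"decay"`) and `q`
#'   (Phred score; under `"decay"` the score falls linearly to `q - 20` at
#'   the read end, floored at 2).
#' @param seed integer master seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 1e5,
                       n_genes = 20,
                       isoforms_per_gene = c(1L, 3L),
                       duplicate_locus_fraction = 0.1,
                       duplicate_divergence = 0.01,
                       het_density = -log(0.75) / 1000,
                       fragment_length = list(mean = 180, sd = 60, min = 1),
                       read_length = 262L,
                       error_rate = 0.005,
                       adapter = "AGATCGGAAGAGC",
                       expression = "lognormal",
                       pseudogene_expression_fraction = 0.05,
                       allelic_ratio = 0.5,
                       isoform_usage = NULL,
                       n_fragments = 2000L,
                       n_exons = c(3L, 6L),
                       exon_length = c(80L, 300L),
                       intron_length = c(60L, 200L),
                       intergenic_gap = 150L,
                       quality = list(profile = "constant", q = 37L),
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    duplicate_locus_fraction = duplicate_locus_fraction,
    duplicate_divergence = duplicate_divergence,
    het_density = het_density,
    fragment_length = fragment_length,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    adapter = toupper(adapter),
    expression = expression,
    pseudogene_expression_fraction = pseudogene_expression_fraction,
    allelic_ratio = allelic_ratio,
    isoform_usage = isoform_usage,
    n_fragments = as.integer(n_fragments),
    n_exons = as.integer(n_exons),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    intergenic_gap = as.integer(intergenic_gap),
    quality = quality,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0,
    cfg$n_genes >= 1,
    length(cfg$isoforms_per_gene) == 2, all(cfg$isoforms_per_gene >= 1),
    cfg$read_length >= 20,
    cfg$fragment_length$min >= 1,
    nchar(cfg$adapter) >= 13,
    cfg$n_fragments >= 0,
    is.finite(cfg$seed)
  )
  rates <- c(
    duplicate_locus_fraction = cfg$duplicate_locus_fraction,
    duplicate_divergence = cfg$duplicate_divergence,
    error_rate = cfg$error_rate,
    pseudogene_expression_fraction = cfg$pseudogene_expression_fraction
  )
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  }
  if (cfg$het_density < 0) stop("het_density must be >= 0")
  ar <- cfg$allelic_ratio
  if (any(ar < 0 | ar > 1)) stop("allelic_ratio must lie in [0, 1]")
  if (!grepl("^[ACGT]+$", cfg$adapter)) stop("adapter must be over {A,C,G,T}")
  invisible(cfg)
}

# Re-seed the RNG deterministically for one generator stage. Offsets keep the
# stages independent of each other and of the caller's RNG state.
seed_stage <- function(cfg, offset) {
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      sprintf("dup %.0f%%,", 100 * x$duplicate_locus_fraction),
      sprintf("het %.2e/bp,", x$het_density),
      sprintf("frag N(%g, %g) >= %g,", x$fragment_length$mean,
              x$fragment_length$sd, x$fragment_length$min),
      sprintf("2 x %d bp reads, err %.3g, seed %d\n",
              x$read_length, x$error_rate, x$seed))
  invisible(x)
}
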