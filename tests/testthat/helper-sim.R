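# Shared fixtures, all built in code.

# A small simulated world: genome, annotation, phased sites.
sim_world <- function(seed = 1, n_genes = 10, genome_length = 4e4,
                      het_density = 2e-3, error_rate = 0,
                      duplicate_locus_fraction = 0, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    genome_length = genome_length,
                    het_density = het_density, error_rate = error_rate,
                    duplicate_locus_fraction = duplicate_locus_fraction, ...)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(genome, cfg)
  sites <- generate_diplotype(genome, cfg)
  list(cfg = cfg, genome = genome, ann = ann, sites = sites)
}

# Hand-built single-mate fragment from blocks and calls.
frag <- function(id, blocks, calls, strand = "+", chrom = "chr1",
                 quals = NULL, indels = NULL) {
  if (is.null(quals)) quals <- strrep("F", nchar(calls))
  aligned_fragment(id, chrom, strand,
                   list(list(blocks = blocks, calls = calls, quals = quals)),
                   indels = indels)
}

blk <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Hand-built annotation from an exon table; one chromosome.
mk_annotation <- function(exon_list, biotype = NULL, strand = NULL) {
  # exon_list: named list gene -> named list transcript -> blk() matrix
  genes <- transcripts <- exons <- list()
  for (g in names(exon_list)) {
    all_ex <- do.call(rbind, exon_list[[g]])
    genes[[g]] <- data.frame(
      gene_id = g, gene_name = g,
      biotype = if (is.null(biotype)) "protein_coding" else biotype[[g]],
      chrom = "chr1",
      strand = if (is.null(strand)) "+" else strand[[g]],
      start = min(all_ex[, 1]), end = max(all_ex[, 2]),
      stringsAsFactors = FALSE)
    for (t in names(exon_list[[g]])) {
      m <- exon_list[[g]][[t]]
      transcripts[[t]] <- data.frame(transcript_id = t, gene_id = g,
                                     stringsAsFactors = FALSE)
      exons[[t]] <- data.frame(transcript_id = t, chrom = "chr1",
                               start = m[, 1], end = m[, 2],
                               stringsAsFactors = FALSE)
    }
  }
  tx_annotation(do.call(rbind, genes), do.call(rbind, transcripts),
                do.call(rbind, exons))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent per-base brute-force feature assignment oracle: literal
# per-base set construction and intersection over nonempty sets, plus the
# junction filter at isoform level. Used to validate consistent_features().
brute_force_features <- function(fragment, annotation, level) {
  pos <- sort(unique(unlist(lapply(fragment$mates, function(m)
    unlist(mapply(seq.int, m$blocks[, 1], m$blocks[, 2], SIMPLIFY = FALSE))))))
  feature_set_at <- function(p) {
    if (level == "gene") {
      g <- annotation$genes
      g$gene_id[g$chrom == fragment$chrom & g$start <= p & g$end >= p]
    } else {
      e <- annotation$exons
      unique(e$transcript_id[e$chrom == fragment$chrom &
                               e$start <= p & e$end >= p])
    }
  }
  sets <- lapply(pos, feature_set_at)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) return(character(0))
  feats <- Reduce(intersect, sets)
  if (level == "isoform" && length(feats)) {
    jx <- longrna:::fragment_junctions(fragment)
    if (nrow(jx)) {
      ok <- vapply(feats, function(tid) {
        ex <- annotation$exons[annotation$exons$transcript_id == tid, ]
        ex <- ex[order(ex$start), ]
        if (nrow(ex) < 2) return(FALSE)
        introns <- cbind(head(ex$end, -1) + 1L, ex$start[-1] - 1L)
        all(apply(jx, 1, function(j)
          any(introns[, 1] == j["start"] & introns[, 2] == j["end"])))
      }, TRUE)
      feats <- feats[ok]
    }
  }
  sort(feats)
}
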