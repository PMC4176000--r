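#' Generate a toy reference genome
#'
#' Lays out `n_genes` gene loci on a single chromosome (`chr1`), separated by
#' random intergenic sequence, and appends, for `duplicate_locus_fraction` of
#' the genes, a second copy of the locus with per-base divergence
#' `duplicate_divergence`. Duplicated copies create the pseudogene-like,
#' low-mappability regime in which short reads multimap.
#'
#' The locus layout (including each gene's canonical exon structure) is stored
#' in the returned object's metadata and consumed by [generate_annotation()],
#' so genome and annotation are always consistent.
#'
#' @param config a [sim_config()].
#' @return a [Biostrings::DNAStringSet] of length 1 named `chr1`, with the
#'   simulation plan in `S4Vectors::metadata()$sim_plan`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  seed_stage(config, 0L)
  plan <- plan_loci(config)
  total_len <- max(config$genome_length, plan$loci$end[nrow(plan$loci)] +
                     config$intergenic_gap)
  bases <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)

  # overwrite duplicate loci with diverged copies of their parents
  dup <- plan$loci[plan$loci$is_duplicate, , drop = FALSE]
  for (i in seq_len(nrow(dup))) {
    par <- plan$loci[plan$loci$locus_id == dup$parent[i], ]
    copy <- bases[par$start:par$end]
    d <- config$duplicate_divergence
    if (d > 0) {
      hit <- which(stats::runif(length(copy)) < d)
      if (length(hit)) copy[hit] <- vapply(copy[hit], other_base, "")
    }
    bases[dup$start[i]:dup$end[i]] <- copy
  }

  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chr1"
  S4Vectors::metadata(genome)$sim_plan <- plan
  genome
}

# Draw one locus layout per gene: exon/intron lengths and locus spans, plus
# duplicate placements. Exon layouts are relative 1-based coordinates.
plan_loci <- function(config) {
  n_dup <- round(config$duplicate_locus_fraction * config$n_genes)
  layouts <- vector("list", config$n_genes)
  spans <- integer(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample_range(config$n_exons)
    ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1) {
      sample(config$intron_length[1]:config$intron_length[2], n_ex - 1,
             replace = TRUE)
    } else integer(0)
    starts <- cumsum(c(1L, utils::head(ex_len, -1) + in_len))
    layouts[[g]] <- cbind(start = starts, end = starts + ex_len - 1L)
    spans[g] <- starts[n_ex] + ex_len[n_ex] - 1L
  }
  dup_parent <- if (n_dup > 0) seq_len(n_dup) else integer(0)
  all_spans <- c(spans, spans[dup_parent])
  gap <- config$intergenic_gap
  locus_start <- gap + cumsum(c(0L, utils::head(all_spans + gap, -1))) + 1L
  n_all <- config$n_genes + n_dup
  loci <- data.frame(
    locus_id = sprintf("L%03d", seq_len(n_all)),
    start = locus_start,
    end = locus_start + all_spans - 1L,
    is_duplicate = c(rep(FALSE, config$n_genes), rep(TRUE, n_dup)),
    parent = c(rep(NA_character_, config$n_genes),
               sprintf("L%03d", dup_parent)),
    stringsAsFactors = FALSE
  )
  list(loci = loci, exon_layout = layouts)
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Generate a multi-isoform annotation over a simulated genome
#'
#' Builds the gene models planned by [generate_genome()]. Every gene gets its
#' canonical transcript (all exons); additional isoforms (count drawn from
#' `isoforms_per_gene`) are derived by skipping an internal exon or, for
#' short genes, shifting the first exon's boundary, so that isoforms of a
#' gene always share at least one exon and differ in at least one exon or
#' boundary. Duplicated loci are annotated as single-transcript genes with
#' biotype `pseudogene`.
#'
#' @param genome output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return a `tx_annotation` object; see [tx_annotation()].
#' @export
generate_annotation <- function(genome, config) {
  plan <- S4Vectors::metadata(genome)$sim_plan
  if (is.null(plan)) stop("genome lacks a simulation plan; use generate_genome()")
  seed_stage(config, 1L)
  loci <- plan$loci
  genes <- transcripts <- exons <- list()
  for (i in seq_len(nrow(loci))) {
    lo <- loci[i, ]
    layout <- if (lo$is_duplicate) {
      plan$exon_layout[[match(lo$parent, loci$locus_id)]]
    } else {
      plan$exon_layout[[i]]
    }
    ex <- layout + lo$start - 1L  # absolute coordinates
    strand <- sample(c("+", "-"), 1L)
    if (lo$is_duplicate) {
      gid <- sub("^L", "PG", lo$locus_id)
      biotype <- "pseudogene"
      iso <- list(seq_len(nrow(ex)))  # single transcript, full structure
      bshift <- NULL
    } else {
      gid <- sub("^L", "G", lo$locus_id)
      biotype <- "protein_coding"
      n_iso <- sample_range(config$isoforms_per_gene)
      iso <- list(seq_len(nrow(ex)))
      bshift <- vector("list", n_iso)
      if (n_iso > 1) {
        internal <- setdiff(seq_len(nrow(ex)), c(1L, nrow(ex)))
        for (k in 2:n_iso) {
          if (length(internal) >= 1) {
            skip <- internal[1L + (k - 2L) %% length(internal)]
            iso[[k]] <- setdiff(seq_len(nrow(ex)), skip)
          } else {
            # too few exons to skip: alternative boundary on the first exon
            iso[[k]] <- seq_len(nrow(ex))
            bshift[[k]] <- min(40L * (k - 1L), ex[1, 2] - ex[1, 1] - 10L)
          }
        }
      }
    }
    for (k in seq_along(iso)) {
      tid <- sprintf("%s.t%d", gid, k)
      exk <- ex[iso[[k]], , drop = FALSE]
      if (!is.null(bshift) && length(bshift) >= k && !is.null(bshift[[k]])) {
        exk[1, 1] <- exk[1, 1] + bshift[[k]]
      }
      transcripts[[tid]] <- data.frame(transcript_id = tid, gene_id = gid,
                                       stringsAsFactors = FALSE)
      exons[[tid]] <- data.frame(transcript_id = tid, chrom = "chr1",
                                 start = exk[, 1], end = exk[, 2],
                                 stringsAsFactors = FALSE)
    }
    genes[[gid]] <- data.frame(
      gene_id = gid, gene_name = gid, biotype = biotype, chrom = "chr1",
      strand = strand, start = lo$start, end = lo$end,
      stringsAsFactors = FALSE
    )
  }
  tx_annotation(
    genes = do.call(rbind, genes),
    transcripts = do.call(rbind, transcripts),
    exons = do.call(rbind, exons)
  )
}

#' Transcript annotation container
#'
#' A light container for genes -> transcripts -> exons, the in-memory
#' equivalent of a GTF. Coordinates are 1-based inclusive throughout (the
#' IRanges/GTF convention).
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`; exons of a transcript must be disjoint.
#' @return object of class `tx_annotation`.
#' @export
tx_annotation <- function(genes, transcripts, exons) {
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- NULL
  ann <- structure(list(genes = genes, transcripts = transcripts,
                        exons = exons), class = "tx_annotation")
  for (tid in transcripts$transcript_id) {
    ex <- exons[exons$transcript_id == tid, ]
    ir <- IRanges::IRanges(ex$start, ex$end)
    if (length(IRanges::reduce(ir)) != length(ir)) {
      stop("exons of ", tid, " overlap")
    }
  }
  ann
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

# exon rows of one transcript, sorted by genomic start
exons_of <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown transcript: ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

transcripts_of <- function(ann, gene_id) {
  ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
}

gene_of_transcript <- function(ann, transcript_id) {
  ann$transcripts$gene_id[match(transcript_id, ann$transcripts$transcript_id)]
}

strand_of_gene <- function(ann, gene_id) {
  ann$genes$strand[match(gene_id, ann$genes$gene_id)]
}

# Genomic positions of a transcript's bases in transcript (5'->3') order.
# For minus-strand genes the positions descend and the transcript base is the
# complement of the plus-strand genome base.
tx_pos_map <- function(ann, transcript_id) {
  ex <- exons_of(ann, transcript_id)
  pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE),
                use.names = FALSE)
  strand <- strand_of_gene(ann, gene_of_transcript(ann, transcript_id))
  if (strand == "-") rev(pos) else pos
}

# introns of a transcript as an IRanges (gaps between consecutive exons)
tx_introns <- function(ann, transcript_id) {
  ex <- exons_of(ann, transcript_id)
  if (nrow(ex) < 2) return(IRanges::IRanges())
  IRanges::IRanges(utils::head(ex$end, -1) + 1L, ex$start[-1] - 1L)
}

# plus-strand genome bases at positions (character vector)
genome_base_at <- function(genome, chrom, pos) {
  s <- genome[[chrom]]
  strsplit(as.character(Biostrings::extractAt(
    s, IRanges::IRanges(min(pos), max(pos))))[[1]], "")[[1]][pos - min(pos) + 1]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# byte-level reverse complement; hot path, so no DNAString round trip
revcomp <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}

# Haplotype-resolved transcript sequence (5'->3'). `sites` alleles are
# plus-strand bases; substitution happens on the plus strand before any
# reverse complement for minus-strand genes.
haplotype_tx_seq <- function(genome, ann, sites, transcript_id,
                             haplotype = c("maternal", "paternal")) {
  haplotype <- match.arg(haplotype)
  ex <- exons_of(ann, transcript_id)
  pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE),
                use.names = FALSE)  # ascending genomic order
  base <- strsplit(as.character(unlist(
    Biostrings::extractAt(genome[[ex$chrom[1]]],
                          IRanges::IRanges(ex$start, ex$end)))), "")
  base <- unlist(base, use.names = FALSE)
  if (!is.null(sites) && nrow(sites) > 0) {
    hit <- match(sites$pos, pos)
    keep <- !is.na(hit)
    base[hit[keep]] <- sites[[haplotype]][keep]
  }
  strand <- strand_of_gene(ann, gene_of_transcript(ann, transcript_id))
  seq <- paste(base, collapse = "")
  if (strand == "-") revcomp(seq) else seq
}

#' Generate phased heterozygous sites over a genome
#'
#' Places heterozygous SNVs by a homogeneous Poisson process at rate
#' `het_density` per base: the site count is Poisson, positions uniform
#' without replacement. Each site's alternate allele differs from the
#' reference; the alternate is assigned to the maternal or the paternal
#' haplotype with equal probability.
#'
#' @param genome a [generate_genome()] result (or any named DNAStringSet).
#' @param config a [sim_config()].
#' @return data.frame of class `phased_sites` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `maternal`, `paternal` (plus-strand bases).
#' @export
generate_diplotype <- function(genome, config) {
  stopifnot(config$het_density >= 0)
  seed_stage(config, 2L)
  L <- Biostrings::width(genome)[1]
  n <- stats::rpois(1, config$het_density * L)
  n <- min(n, L)
  if (n == 0) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), maternal = character(),
                      paternal = character(), stringsAsFactors = FALSE)
    class(out) <- c("phased_sites", "data.frame")
    return(out)
  }
  pos <- sort(sample.int(L, n))
  ref <- genome_base_at(genome, names(genome)[1], pos)
  alt <- vapply(ref, other_base, "")
  alt_is_maternal <- stats::runif(n) < 0.5
  out <- data.frame(
    chrom = names(genome)[1], pos = pos, ref = ref, alt = alt,
    maternal = ifelse(alt_is_maternal, alt, ref),
    paternal = ifelse(alt_is_maternal, ref, alt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("phased_sites", "data.frame")
  out
}
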