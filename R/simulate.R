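#' Simulate a strand-specific paired-end RNA-seq library
#'
#' Draws cDNA fragments from haplotype-resolved transcript sequences
#' according to per-gene expression weights, per-gene allelic ratios and
#' (optionally haplotype-specific) isoform-usage weights, then sequences
#' both mates. The protocol is strand-specific: mate 1 reads the transcript
#' sense strand. When the fragment is shorter than the read length, each
#' mate reads through the fragment end into the adapter (adapter bases
#' appended, then random padding) — the structure that overlap merging
#' detects. Substitution errors are applied to every sequenced base at
#' `error_rate`.
#'
#' Fragment lengths come from a normal distribution truncated below at the
#' configured minimum and are capped at the transcript length. Draws landing
#' on a transcript shorter than the minimum fragment length are logged as
#' failures and emit no read, so requested fragments = emitted reads +
#' failures.
#'
#' @param genome a [generate_genome()] result.
#' @param annotation the matching [generate_annotation()] result.
#' @param sites phased heterozygous sites from [generate_diplotype()] (may
#'   have zero rows).
#' @param config the [sim_config()].
#' @return a list of class `sim_library`:
#'   \describe{
#'     \item{reads}{`read_library` data.frame (`id`, `seq1`, `qual1`,
#'       `seq2`, `qual2`).}
#'     \item{fragments}{[fragment_set()] of true alignments, error-applied
#'       base calls included.}
#'     \item{truth}{per-read truth table (`id`, `gene_id`, `transcript_id`,
#'       `haplotype`, `strand`, `tx_start`, `frag_len`), the gene-level
#'       expression/allelic-ratio tables actually used, and the failure
#'       count.}
#'   }
#' @export
simulate_library <- function(genome, annotation, sites, config) {
  validate_sim_config(config)
  seed_stage(config, 3L)
  n <- config$n_fragments
  genes <- annotation$genes
  w <- expression_weights(config, genes)
  ar <- allelic_ratios(config, genes$gene_id)

  pick_gene <- sample(genes$gene_id, n, replace = TRUE, prob = w)
  pick_hap <- ifelse(stats::runif(n) < unname(ar[pick_gene]),
                     "maternal", "paternal")

  rl <- config$read_length
  adapter <- config$adapter
  qual_m <- quality_string(config, rl)
  site_pos <- if (nrow(sites)) sites$pos else integer(0)

  hap_cache <- new.env(parent = emptyenv())
  pmap_cache <- new.env(parent = emptyenv())
  reads <- vector("list", n)
  frags <- vector("list", n)
  truth <- vector("list", n)
  failures <- 0L

  for (i in seq_len(n)) {
    g <- pick_gene[i]
    hap <- pick_hap[i]
    tx <- pick_transcript(config, annotation, g, hap)
    key <- paste0(tx, "|", hap)
    if (is.null(hap_cache[[key]])) {
      hap_cache[[key]] <- haplotype_tx_seq(genome, annotation, sites, tx, hap)
      pmap_cache[[tx]] <- tx_pos_map(annotation, tx)
    }
    hapseq <- hap_cache[[key]]
    pmap <- pmap_cache[[tx]]
    txlen <- nchar(hapseq)
    if (txlen < config$fragment_length$min) {
      failures <- failures + 1L
      next
    }
    fl <- draw_fragment_length(config)
    fl <- min(fl, txlen)
    s <- if (txlen == fl) 1L else sample.int(txlen - fl + 1L, 1L)
    frag_seq <- substr(hapseq, s, s + fl - 1L)

    m1 <- read_through(frag_seq, rl, adapter)
    m2 <- read_through(revcomp(frag_seq), rl, adapter)
    m1 <- apply_errors(m1, config$error_rate)
    m2 <- apply_errors(m2, config$error_rate)

    id <- sprintf("frag%06d", i)
    strand <- strand_of_gene(annotation, g)
    k <- min(rl, fl)
    mate1 <- truth_mate(substr(m1, 1L, k), substr(qual_m, 1L, k),
                        pmap, s, s + k - 1L, strand)
    mate2 <- truth_mate(revcomp(substr(m2, 1L, k)),
                        reverse_chars(substr(qual_m, 1L, k)),
                        pmap, s + fl - k, s + fl - 1L, strand)
    reads[[i]] <- c(id = id, seq1 = m1, qual1 = qual_m, seq2 = m2,
                    qual2 = qual_m)
    frags[[i]] <- aligned_fragment(id, "chr1", strand, list(mate1, mate2))
    truth[[i]] <- c(id = id, gene_id = g, transcript_id = tx,
                    haplotype = hap, strand = strand, tx_start = s,
                    frag_len = fl)
  }

  emitted <- !vapply(reads, is.null, TRUE)
  reads_df <- as.data.frame(do.call(rbind, reads[emitted]),
                            stringsAsFactors = FALSE)
  class(reads_df) <- c("read_library", "data.frame")
  attr(reads_df, "read_length") <- rl
  truth_df <- as.data.frame(do.call(rbind, truth[emitted]),
                            stringsAsFactors = FALSE)
  truth_df$tx_start <- as.integer(truth_df$tx_start)
  truth_df$frag_len <- as.integer(truth_df$frag_len)
  rownames(truth_df) <- NULL
  structure(list(
    reads = reads_df,
    fragments = fragment_set(frags[emitted]),
    truth = list(
      reads = truth_df,
      gene_expression = data.frame(gene_id = genes$gene_id, weight = w / sum(w)),
      allelic_ratio = data.frame(gene_id = names(ar), maternal_fraction = ar,
                                 row.names = NULL),
      failures = failures
    )
  ), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", nrow(x$reads), "read pairs,", x$truth$failures,
      "failed draws\n")
  invisible(x)
}

expression_weights <- function(config, genes) {
  if (is.numeric(config$expression)) {
    w <- config$expression[genes$gene_id]
    w[is.na(w)] <- 0
    if (all(w == 0)) stop("expression weights name no annotated gene")
    return(unname(w))
  }
  if (!identical(config$expression, "lognormal")) {
    stop("expression must be 'lognormal' or a named numeric vector")
  }
  w <- stats::rlnorm(nrow(genes))
  pg <- genes$biotype == "pseudogene"
  pef <- config$pseudogene_expression_fraction
  if (any(pg) && any(!pg) && pef >= 0) {
    w[pg] <- w[pg] / sum(w[pg]) * pef
    w[!pg] <- w[!pg] / sum(w[!pg]) * (1 - pef)
  }
  w
}

allelic_ratios <- function(config, gene_ids) {
  ar <- config$allelic_ratio
  if (length(ar) == 1 && is.null(names(ar))) {
    ar <- stats::setNames(rep(ar, length(gene_ids)), gene_ids)
  } else {
    full <- stats::setNames(rep(0.5, length(gene_ids)), gene_ids)
    full[intersect(names(ar), gene_ids)] <- ar[intersect(names(ar), gene_ids)]
    ar <- full
  }
  ar
}

pick_transcript <- function(config, annotation, gene_id, haplotype) {
  txs <- transcripts_of(annotation, gene_id)
  if (length(txs) == 1) return(txs)
  usage <- config$isoform_usage[[gene_id]]
  w <- if (is.null(usage)) rep(1, length(txs))
       else usage[if (haplotype == "maternal") 1 else 2, ]
  sample(txs, 1L, prob = w)
}

draw_fragment_length <- function(config) {
  fl <- config$fragment_length
  repeat {
    x <- round(stats::rnorm(1, fl$mean, fl$sd))
    if (x >= fl$min) return(as.integer(x))
  }
}

# fragment sequence, then adapter, then random padding, cut to read length
read_through <- function(frag_seq, read_length, adapter) {
  fl <- nchar(frag_seq)
  if (fl >= read_length) return(substr(frag_seq, 1L, read_length))
  s <- paste0(frag_seq, adapter)
  pad <- read_length - nchar(s)
  if (pad > 0) {
    s <- paste0(s, paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                         collapse = ""))
  }
  substr(s, 1L, read_length)
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[hit] <- vapply(ch[hit], other_base, "")
  paste(ch, collapse = "")
}

quality_string <- function(config, read_length) {
  q <- config$quality$q
  if (identical(config$quality$profile, "decay")) {
    qs <- round(seq(q, max(2, q - 20), length.out = read_length))
    intToUtf8(qs + 33L)
  } else {
    strrep(intToUtf8(q + 33L), read_length)
  }
}

reverse_chars <- function(s) {
  intToUtf8(rev(utf8ToInt(s)))
}

# Build one truth mate covering transcript positions t1..t2. `seq` holds the
# transcript-sense bases over t1..t2 ascending (for mate 2 the caller has
# already re-oriented the raw read). Converts to plus-strand calls in
# ascending genomic order and splits into blocks at intron jumps.
truth_mate <- function(seq, quals, pmap, t1, t2, strand) {
  gpos <- pmap[t1:t2]
  if (strand == "-") {
    # genomic order is the reverse of transcript order; complement bases
    gpos <- rev(gpos)
    seq <- revcomp(seq)
    quals <- reverse_chars(quals)
  }
  brk <- which(diff(gpos) != 1L)
  starts <- gpos[c(1L, brk + 1L)]
  ends <- gpos[c(brk, length(gpos))]
  list(blocks = cbind(start = starts, end = ends), calls = seq, quals = quals)
}
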