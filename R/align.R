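#' Exhaustive toy aligner
#'
#' Aligns a single read by exhaustive substring search with at most
#' `max_mismatch` substitutions against (i) the genome on both strands and
#' (ii) every annotated spliced transcript sequence on both strands
#' (transcript hits are mapped back to genomic blocks, which is how the
#' aligner places reads across splice junctions). Hits with identical
#' genomic block structure are collapsed. A unique hit at the minimal
#' mismatch count is `mapped`; two or more equally good hits are
#' `multimapped`; no hit is `unmapped`.
#'
#' This is a reference aligner for testing and for the mapping-retention
#' simulation, not a production mapper: cost is linear in genome and
#' transcriptome size per read.
#'
#' @param read nucleotide string.
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotation optional [tx_annotation()]; when supplied, spliced
#'   transcript sequences are searched too.
#' @param max_mismatch maximum substitutions per alignment (default 4).
#' @return a list with `status` (`mapped`/`multimapped`/`unmapped`) and, when
#'   mapped: `chrom`, `strand` (strand of the alignment), `blocks` (matrix),
#'   `mismatches`.
#' @export
toy_align <- function(read, genome, annotation = NULL, max_mismatch = 4L) {
  idx <- toy_aligner_index(genome, annotation)
  toy_align_indexed(read, idx, max_mismatch)
}

#' Pre-computed index for the toy aligner
#'
#' Builds the spliced transcript sequences and coordinate maps once, so that
#' many reads can be aligned without re-deriving them. [make_toy_aligner()]
#' wraps this into a single-argument aligner function, the contract consumed
#' by [retention_rate()].
#'
#' @inheritParams toy_align
#' @return an opaque index list.
#' @export
toy_aligner_index <- function(genome, annotation = NULL) {
  tx <- list()
  if (!is.null(annotation)) {
    ids <- annotation$transcripts$transcript_id
    tx <- lapply(ids, function(tid) {
      pmap <- tx_pos_map(annotation, tid)
      gid <- gene_of_transcript(annotation, tid)
      strand <- strand_of_gene(annotation, gid)
      chrom <- exons_of(annotation, tid)$chrom[1]
      seq <- haplotype_tx_seq(genome, annotation,
                              sites = NULL, tid, "maternal")
      list(id = tid, chrom = chrom, strand = strand, pmap = pmap, seq = seq)
    })
    names(tx) <- ids
  }
  list(genome = genome, tx = tx)
}

#' @rdname toy_aligner_index
#' @return for `make_toy_aligner()`, a function `f(read)` returning what
#'   [toy_align()] returns.
#' @export
make_toy_aligner <- function(genome, annotation = NULL, max_mismatch = 4L) {
  idx <- toy_aligner_index(genome, annotation)
  function(read) toy_align_indexed(read, idx, max_mismatch)
}

toy_align_indexed <- function(read, idx, max_mismatch = 4L) {
  read <- toupper(read)
  pat_f <- Biostrings::DNAString(read)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()

  add_hit <- function(chrom, strand, blocks, mm) {
    key <- paste(chrom, strand, paste(blocks, collapse = ","))
    old <- hits[[key]]
    if (is.null(old) || old$mismatches > mm) {
      hits[[key]] <<- list(chrom = chrom, strand = strand, blocks = blocks,
                           mismatches = mm)
    }
  }

  for (chrom in names(idx$genome)) {
    subj <- idx$genome[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = IRanges::start(m))
      for (j in seq_along(m)) {
        add_hit(chrom, strand,
                cbind(start = IRanges::start(m)[j], end = IRanges::end(m)[j]),
                mm[j])
      }
    }
  }

  for (t in idx$tx) {
    subj <- Biostrings::DNAString(t$seq)
    if (length(subj) < nchar(read)) next
    for (sense in c(TRUE, FALSE)) {
      pat <- if (sense) pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = IRanges::start(m))
      for (j in seq_along(m)) {
        gpos <- t$pmap[IRanges::start(m)[j]:IRanges::end(m)[j]]
        gpos <- sort(gpos)
        brk <- which(diff(gpos) != 1L)
        blocks <- cbind(start = gpos[c(1L, brk + 1L)],
                        end = gpos[c(brk, length(gpos))])
        # alignment strand on the genome: transcript sense hit on a '-' gene
        # is a '-' genomic alignment
        strand <- if (sense == (t$strand == "+")) "+" else "-"
        add_hit(t$chrom, strand, blocks, mm[j])
      }
    }
  }

  if (length(hits) == 0) return(list(status = "unmapped"))
  mms <- vapply(hits, `[[`, 1, "mismatches")
  best <- hits[mms == min(mms)]
  if (length(best) > 1) {
    return(list(status = "multimapped", n_best = length(best),
                mismatches = min(mms)))
  }
  c(list(status = "mapped"), best[[1]])
}
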