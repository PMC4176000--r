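#' Aligned fragments
#'
#' An `aligned_fragment` represents one sequenced cDNA fragment — a read pair
#' or a merged single-end read — as reference-coordinate alignment blocks
#' plus per-base calls. It is the atomic unit of every downstream stage
#' (concordance, feature assignment, haplotype assignment).
#'
#' Each mate is stored as a block matrix (1-based inclusive reference
#' intervals, ascending) together with `calls`/`quals` strings holding the
#' plus-strand base call and Phred+33 quality for each covered reference
#' position, concatenated block by block in ascending genomic order. Storing
#' calls on the plus strand makes genotype lookups orientation-free; the
#' fragment's `strand` records the transcription strand for read
#' reconstruction. Gaps between consecutive blocks *within* a mate are splice
#' junctions (introns); the unsequenced gap *between* mates of a long
#' fragment is not.
#'
#' @param id fragment name.
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"` (transcript sense of mate 1).
#' @param mates list of 1 or 2 mates, each `list(blocks =` 2-column matrix
#'   `(start, end), calls =, quals =` strings`)`.
#' @param indels optional matrix `(pos, size)` of observed indels (insertion
#'   positive, deletion negative), used by [modal_indel_size()].
#' @return object of class `aligned_fragment`.
#' @export
aligned_fragment <- function(id, chrom, strand, mates, indels = NULL) {
  for (m in mates) {
    stopifnot(is.matrix(m$blocks), ncol(m$blocks) == 2,
              sum(m$blocks[, 2] - m$blocks[, 1] + 1) == nchar(m$calls),
              nchar(m$calls) == nchar(m$quals))
  }
  structure(list(id = id, chrom = chrom, strand = strand, mates = mates,
                 indels = indels),
            class = "aligned_fragment")
}

#' Fragment set
#'
#' A list of [aligned_fragment()]s with pre-computed overlap tables for fast
#' bulk queries.
#'
#' @param fragments list of `aligned_fragment` objects.
#' @return object of class `fragment_set` (a list).
#' @export
fragment_set <- function(fragments) {
  stopifnot(all(vapply(fragments, inherits, TRUE, "aligned_fragment")))
  structure(fragments, class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set of", length(x), "fragments\n")
  invisible(x)
}

#' @export
`[.fragment_set` <- function(x, i) {
  fragment_set(unclass(x)[i])
}

#' Effective alignment length of a fragment
#'
#' The number of distinct reference bases covered by the (possibly
#' overlapping) alignment blocks of both mates.
#'
#' @param frag an [aligned_fragment()].
#' @return integer count of covered reference bases.
#' @export
effective_length <- function(frag) {
  b <- do.call(rbind, lapply(frag$mates, `[[`, "blocks"))
  as.integer(mat_width(mat_reduce(b)))
}

#' @rdname effective_length
#' @param fragments a [fragment_set()].
#' @return for `effective_lengths()`, an integer vector.
#' @export
effective_lengths <- function(fragments) {
  vapply(fragments, effective_length, 1L)
}

# union of both mates' blocks as an IRanges
covered_ranges <- function(frag) {
  b <- do.call(rbind, lapply(frag$mates, `[[`, "blocks"))
  IRanges::reduce(IRanges::IRanges(b[, 1], b[, 2]))
}

# splice junctions (intron intervals) implied by within-mate block gaps
fragment_junctions <- function(frag) {
  out <- lapply(frag$mates, function(m) {
    if (nrow(m$blocks) < 2) return(NULL)
    cbind(start = m$blocks[-nrow(m$blocks), 2] + 1L,
          end = m$blocks[-1, 1] - 1L)
  })
  jx <- do.call(rbind, out)
  if (is.null(jx)) matrix(integer(0), 0, 2,
                          dimnames = list(NULL, c("start", "end")))
  else unique(jx)
}

# Plus-strand base call (and quality) of `frag` at reference position `pos`,
# or NA if not covered. Mate 1 wins where mates overlap.
fragment_base_at <- function(frag, pos, what = c("call", "qual")) {
  what <- match.arg(what)
  for (m in frag$mates) {
    b <- m$blocks
    k <- which(pos >= b[, 1] & pos <= b[, 2])
    if (length(k)) {
      k <- k[1]
      off <- if (k > 1) sum(b[seq_len(k - 1), 2] - b[seq_len(k - 1), 1] + 1) else 0L
      at <- off + pos - b[k, 1] + 1L
      return(substr(if (what == "call") m$calls else m$quals, at, at))
    }
  }
  NA_character_
}

# Long-format block table over a fragment set: one row per (fragment, mate,
# block). `idx` indexes into the fragment set.
blocks_table <- function(fragments) {
  n_b <- vapply(fragments, function(f)
    sum(vapply(f$mates, function(m) nrow(m$blocks), 1L)), 1L)
  idx <- rep(seq_along(fragments), n_b)
  mats <- lapply(fragments, function(f)
    do.call(rbind, lapply(seq_along(f$mates), function(j)
      cbind(mate = j, f$mates[[j]]$blocks))))
  m <- do.call(rbind, mats)
  data.frame(idx = idx, mate = m[, "mate"], start = m[, "start"],
             end = m[, "end"])
}

# For a set of reference positions, find all (fragment, position) pairs where
# the fragment covers the position, with the plus-strand call and quality.
# Each fragment contributes at most one call per position (mate 1 wins).
fragment_calls_at <- function(fragments, pos) {
  if (length(fragments) == 0 || length(pos) == 0) {
    return(data.frame(site = integer(), idx = integer(),
                      call = character(), qual = character()))
  }
  bt <- blocks_table(fragments)
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos),
                                IRanges::IRanges(bt$start, bt$end))
  if (length(hits) == 0) {
    return(data.frame(site = integer(), idx = integer(),
                      call = character(), qual = character()))
  }
  site <- S4Vectors::queryHits(hits)
  frag <- bt$idx[S4Vectors::subjectHits(hits)]
  # one call per (site, fragment); fragment_base_at applies the mate-1 rule
  key <- paste(site, frag)
  keep <- !duplicated(key)
  site <- site[keep]; frag <- frag[keep]
  call <- character(length(site)); qual <- character(length(site))
  for (i in seq_along(site)) {
    call[i] <- fragment_base_at(fragments[[frag[i]]], pos[site[i]], "call")
    qual[i] <- fragment_base_at(fragments[[frag[i]]], pos[site[i]], "qual")
  }
  data.frame(site = site, idx = frag, call = call, qual = qual,
             stringsAsFactors = FALSE)
}

# Reconstruct a mate's read sequence (sequencing orientation) from its
# plus-strand calls. Mate 1 reads in transcript sense; mate 2 antisense.
mate_read_seq <- function(frag, mate) {
  m <- frag$mates[[mate]]
  fwd <- if (mate == 1) frag$strand == "+" else frag$strand == "-"
  if (fwd) m$calls else revcomp(m$calls)
}
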