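#' Locate the adapter read-through position in a read
#'
#' Finds the leftmost position at which the adapter (or, near the read end,
#' its visible prefix) starts. When a cDNA fragment is shorter than the read
#' length the sequencer reads through the fragment into the adapter, so the
#' adapter's start position equals the fragment length.
#'
#' Full-length adapter occurrences are matched with at most
#' `max_adapter_mismatch` substitutions (default 0). At the read end, where
#' fewer than `nchar(adapter)` bases remain, the truncated prefix is matched
#' allowing one substitution if at least 6 bases are visible, or exactly if
#' 5 are; shorter prefixes are considered uninformative and not searched, so
#' fragments within 4 bases of the read length are not detectable.
#'
#' @param sequence read sequence.
#' @param adapter adapter sequence (>= 13 bases).
#' @param max_adapter_mismatch substitutions tolerated for a full-length
#'   adapter match.
#' @return integer: number of read bases preceding the adapter (equivalently
#'   the implied fragment length), or `NA` if the adapter is absent.
#' @export
find_adapter <- function(sequence, adapter, max_adapter_mismatch = 0L) {
  stopifnot(nchar(adapter) >= 13)
  find_adapter_all(sequence, adapter, max_adapter_mismatch)
}

# vectorized over sequences of equal length
find_adapter_all <- function(sequences, adapter, max_adapter_mismatch = 0L) {
  al <- nchar(adapter)
  rl <- unique(nchar(sequences))
  stopifnot(length(rl) == 1)
  subj <- Biostrings::DNAStringSet(sequences)
  pos <- rep(NA_integer_, length(sequences))
  if (rl >= al) {
    m <- Biostrings::vmatchPattern(adapter, subj,
                                   max.mismatch = max_adapter_mismatch)
    st <- as.list(IRanges::start(m))
    has <- lengths(st) > 0
    pos[has] <- vapply(st[has], min, 1L) - 1L
  }
  # truncated prefix at the read end: offsets leaving 5..(al-1) visible bases
  lo <- max(rl - al + 2L, 1L)
  hi <- rl - 4L
  if (hi >= lo) {
    seq_chars <- strsplit(sequences, "")
    ad_chars <- strsplit(adapter, "")[[1]]
    for (start in lo:hi) {
      vis <- rl - start + 1L
      allowed <- if (vis >= 6L) 1L else 0L
      cand <- which(is.na(pos) | pos > start - 1L)
      if (!length(cand)) next
      for (i in cand) {
        mm <- sum(seq_chars[[i]][start:rl] != ad_chars[seq_len(vis)])
        if (mm <= allowed && (is.na(pos[i]) || start - 1L < pos[i])) {
          pos[i] <- start - 1L
        }
      }
      # once set, earlier full matches already beat later truncated ones
    }
  }
  pos
}

#' Merge one read pair whose fragment is shorter than the read length
#'
#' Locates the adapter independently in each mate (mate 2 in its own
#' orientation); concordant positions imply the fragment length. Mate 2 is
#' reverse-complemented and compared with mate 1 over the fragment.
#' Disagreeing bases are resolved in favour of the higher quality score
#' (mate 1 wins ties); the merged quality is the per-position maximum.
#'
#' Outcomes follow the library bipartition rules: fragments shorter than
#' `min_fragment` (default 20) are discarded; pairs disagreeing on more than
#' `max_disagreements` (default 10) bases are discarded; pairs in which the
#' adapter is absent, found in only one mate, or found at different
#' positions are kept as pairs.
#'
#' @param seq1,qual1,seq2,qual2 mate sequences and Phred+33 quality strings.
#' @param adapter adapter sequence.
#' @param min_fragment minimum fragment length to keep a merged read.
#' @param max_disagreements maximum tolerated disagreeing bases.
#' @param max_adapter_mismatch passed to [find_adapter()].
#' @return list with `status` (`merged`, `kept_pair`, `discarded_short`,
#'   `discarded_mismatch`), `fragment_length`, `n_disagreements`, `reason`
#'   (for kept pairs), and for merged reads `merged_seq` / `merged_qual`.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, adapter,
                       min_fragment = 20L, max_disagreements = 10L,
                       max_adapter_mismatch = 0L) {
  p1 <- find_adapter(seq1, adapter, max_adapter_mismatch)
  p2 <- find_adapter(seq2, adapter, max_adapter_mismatch)
  merge_pair_at(seq1, qual1, seq2, qual2, p1, p2, min_fragment,
                max_disagreements)
}

merge_pair_at <- function(seq1, qual1, seq2, qual2, p1, p2,
                          min_fragment = 20L, max_disagreements = 10L) {
  if (is.na(p1) && is.na(p2)) {
    return(list(status = "kept_pair", reason = "no_adapter",
                fragment_length = NA_integer_, n_disagreements = NA_integer_))
  }
  if (is.na(p1) || is.na(p2)) {
    return(list(status = "kept_pair", reason = "adapter_one_mate",
                fragment_length = NA_integer_, n_disagreements = NA_integer_))
  }
  if (p1 != p2) {
    return(list(status = "kept_pair", reason = "position_disagree",
                fragment_length = NA_integer_, n_disagreements = NA_integer_))
  }
  f <- p1
  if (f < min_fragment) {
    return(list(status = "discarded_short", fragment_length = f,
                n_disagreements = NA_integer_))
  }
  b1 <- utf8ToInt(substr(seq1, 1L, f))
  b2 <- utf8ToInt(revcomp(substr(seq2, 1L, f)))
  q1 <- utf8ToInt(substr(qual1, 1L, f))
  q2 <- rev(utf8ToInt(substr(qual2, 1L, f)))
  dis <- which(b1 != b2)
  if (length(dis) > max_disagreements) {
    return(list(status = "discarded_mismatch", fragment_length = f,
                n_disagreements = length(dis), n_overlap = f))
  }
  take2 <- dis[q2[dis] > q1[dis]]  # mate 1 wins ties
  merged <- b1
  merged[take2] <- b2[take2]
  list(status = "merged",
       merged_seq = intToUtf8(merged),
       merged_qual = intToUtf8(pmax(q1, q2)),
       fragment_length = f, n_disagreements = length(dis), n_overlap = f)
}

#' Bipartition a paired-end library by overlap merging
#'
#' Applies [merge_pair()] to every pair: pairs whose fragment is shorter
#' than the read length are collapsed into single-end reads, the rest remain
#' paired, and too-short or too-discordant fragments are discarded. Counts
#' are conserved: merged + kept + discarded = input pairs.
#'
#' @param pairs a `read_library` data.frame (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @inheritParams merge_pair
#' @return list of class `merge_partition`: `single_end` (data.frame `id`,
#'   `seq`, `qual`, `fragment_length`, `n_disagreements`), `paired_end`
#'   (subset of the input pairs with a `reason` column), `discarded`
#'   (data.frame `id`, `status`, `fragment_length`), and `stats` (one-row
#'   data.frame of category counts plus the observed disagreement rate over
#'   overlapping bases).
#' @export
partition_library <- function(pairs, adapter, min_fragment = 20L,
                              max_disagreements = 10L,
                              max_adapter_mismatch = 0L) {
  n <- nrow(pairs)
  if (is.null(n) || n == 0) {
    return(empty_partition())
  }
  p1 <- find_adapter_all(pairs$seq1, adapter, max_adapter_mismatch)
  p2 <- find_adapter_all(pairs$seq2, adapter, max_adapter_mismatch)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- merge_pair_at(pairs$seq1[i], pairs$qual1[i], pairs$seq2[i],
                              pairs$qual2[i], p1[i], p2[i], min_fragment,
                              max_disagreements)
  }
  status <- vapply(out, `[[`, "", "status")
  n_dis <- vapply(out, function(x) {
    if (is.null(x$n_disagreements)) NA_integer_ else as.integer(x$n_disagreements)
  }, 1L)
  n_ovl <- vapply(out, function(x) {
    if (is.null(x$n_overlap)) NA_integer_ else as.integer(x$n_overlap)
  }, 1L)
  flen <- vapply(out, function(x) as.integer(x$fragment_length), 1L)

  is_m <- status == "merged"
  single_end <- data.frame(
    id = pairs$id[is_m],
    seq = vapply(out[is_m], `[[`, "", "merged_seq"),
    qual = vapply(out[is_m], `[[`, "", "merged_qual"),
    fragment_length = flen[is_m],
    n_disagreements = n_dis[is_m],
    stringsAsFactors = FALSE
  )
  is_k <- status == "kept_pair"
  paired_end <- pairs[is_k, , drop = FALSE]
  paired_end$reason <- vapply(out[is_k], `[[`, "", "reason")
  is_d <- startsWith(status, "discarded")
  discarded <- data.frame(id = pairs$id[is_d], status = status[is_d],
                          fragment_length = flen[is_d],
                          stringsAsFactors = FALSE)
  overlap_bases <- sum(n_ovl, na.rm = TRUE)
  stats <- data.frame(
    n_pairs = n,
    n_merged = sum(is_m),
    n_kept_pairs = sum(is_k),
    n_discarded_short = sum(status == "discarded_short"),
    n_discarded_mismatch = sum(status == "discarded_mismatch"),
    overlap_bases = overlap_bases,
    disagreement_rate = if (overlap_bases > 0)
      sum(n_dis, na.rm = TRUE) / overlap_bases else NA_real_
  )
  structure(list(single_end = single_end, paired_end = paired_end,
                 discarded = discarded, stats = stats),
            class = "merge_partition")
}

empty_partition <- function() {
  structure(list(
    single_end = data.frame(id = character(), seq = character(),
                            qual = character(), fragment_length = integer(),
                            n_disagreements = integer()),
    paired_end = data.frame(id = character(), seq1 = character(),
                            qual1 = character(), seq2 = character(),
                            qual2 = character(), reason = character()),
    discarded = data.frame(id = character(), status = character(),
                           fragment_length = integer()),
    stats = data.frame(n_pairs = 0L, n_merged = 0L, n_kept_pairs = 0L,
                       n_discarded_short = 0L, n_discarded_mismatch = 0L,
                       overlap_bases = 0L, disagreement_rate = NA_real_)
  ), class = "merge_partition")
}

#' @export
print.merge_partition <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "merge_partition: %d pairs -> %d merged, %d kept, %d discarded (%d short, %d discordant)\n",
    s$n_pairs, s$n_merged, s$n_kept_pairs,
    s$n_discarded_short + s$n_discarded_mismatch,
    s$n_discarded_short, s$n_discarded_mismatch))
  if (!is.na(s$disagreement_rate)) {
    cat(sprintf("  disagreement rate over overlapping bases: %.4f%%\n",
                100 * s$disagreement_rate))
  }
  invisible(x)
}
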