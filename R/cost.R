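#' Sequencing-cost specification of a library
#'
#' @param price total sequencing price (currency units) for the library.
#' @param n_pairs number of read pairs produced.
#' @param bases_per_pair sequenced bases per pair (2 x read length).
#' @param library_prep optional fixed library-preparation cost added to
#'   `price` (default 0; sequencing-only comparisons leave it out).
#' @return object of class `library_cost_spec`.
#' @export
library_cost_spec <- function(price, n_pairs, bases_per_pair,
                              library_prep = 0) {
  stopifnot(price > 0, n_pairs > 0, bases_per_pair > 0, library_prep >= 0)
  structure(list(price = price + library_prep, n_pairs = n_pairs,
                 bases_per_pair = bases_per_pair),
            class = "library_cost_spec")
}

#' Cost per million sequenced bases
#'
#' `price / (n_pairs * bases_per_pair / 1e6)`, reported at three decimals.
#'
#' @param spec a [library_cost_spec()].
#' @return cost per megabase, rounded to 3 decimals.
#' @export
cost_per_million_bases <- function(spec) {
  mb <- spec$n_pairs * spec$bases_per_pair / 1e6
  if (mb <= 0) stop("zero sequenced bases")
  round(spec$price / mb, 3)
}

#' Per-read cost ratio between two libraries
#'
#' How many of library B's read pairs cost the same as one of library A's:
#' `(priceA / n_pairsA) / (priceB / n_pairsB)`.
#'
#' @param specA,specB [library_cost_spec()]s.
#' @return the ratio.
#' @export
per_read_cost_ratio <- function(specA, specB) {
  (specA$price / specA$n_pairs) / (specB$price / specB$n_pairs)
}

#' Fraction of the dearer library matching the cheaper library's cost
#'
#' @param specA the more expensive library.
#' @param specB the cheaper library.
#' @return `priceB / priceA`, the fraction of library A's reads whose cost
#'   equals all of library B.
#' @export
cost_matched_fraction <- function(specA, specB) {
  f <- specB$price / specA$price
  if (f > 1) stop("specA must be the more expensive library")
  f
}

#' Subsample a read library
#'
#' Draws read pairs without replacement to match a target number of reads
#' (`by_reads`), a target number of raw sequenced bases (`by_bases`;
#' accumulation stops at the first pair crossing the target, overshooting
#' by at most one pair), or a cost-matched fraction of pairs (`by_cost`).
#' Replicate draws use seeds derived deterministically from the master seed.
#'
#' @param library a `read_library` data.frame.
#' @param mode one of `by_reads`, `by_bases`, `by_cost`.
#' @param target pairs (`by_reads`), bases (`by_bases`) or a fraction in
#'   (0, 1] (`by_cost`).
#' @param n_replicates number of independent subsamples (default 3).
#' @param seed master seed.
#' @return list of `read_library` data.frames, one per replicate.
#' @export
subsample_library <- function(library, mode = c("by_reads", "by_bases",
                                                "by_cost"),
                              target, n_replicates = 3L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(target > 0)
  n <- nrow(library)
  bases <- nchar(library$seq1) + nchar(library$seq2)
  if (mode == "by_reads" && target > n) stop("target exceeds library size")
  if (mode == "by_bases" && target > sum(bases)) {
    stop("target exceeds library bases")
  }
  if (mode == "by_cost" && target > 1) stop("by_cost target is a fraction")
  lapply(seq_len(n_replicates), function(r) {
    set.seed((seed + r) %% .Machine$integer.max)
    ord <- sample.int(n)
    take <- switch(mode,
      by_reads = ord[seq_len(target)],
      by_cost = ord[seq_len(round(target * n))],
      by_bases = {
        cum <- cumsum(bases[ord])
        ord[seq_len(which(cum >= target)[1])]
      })
    out <- library[take, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(library)
    attr(out, "read_length") <- attr(library, "read_length")
    out
  })
}

#' Truncate every read of a library to a shorter length
#'
#' Keeps each mate's first `new_length` bases and qualities — the in-silico
#' short-read library used for read-length comparisons on identical
#' fragments.
#'
#' @param library a `read_library` data.frame.
#' @param new_length target read length (at most the current length).
#' @return the truncated `read_library`.
#' @export
truncate_reads <- function(library, new_length) {
  rl <- unique(nchar(library$seq1))
  if (any(new_length > rl)) stop("new_length exceeds read length")
  library$seq1 <- substr(library$seq1, 1L, new_length)
  library$seq2 <- substr(library$seq2, 1L, new_length)
  library$qual1 <- substr(library$qual1, 1L, new_length)
  library$qual2 <- substr(library$qual2, 1L, new_length)
  attr(library, "read_length") <- as.integer(new_length)
  library
}

#' Truncate true alignments to a shorter read length
#'
#' Companion to [truncate_reads()] for truth [fragment_set()]s: each mate's
#' alignment is cut to its first `new_length` sequenced bases (mate 1 from
#' the fragment 5' end, mate 2 from the 3' end), so downstream analyses can
#' run on the truncated library without re-alignment.
#'
#' @param fragments a [fragment_set()] of true alignments.
#' @param new_length target read length.
#' @return a [fragment_set()].
#' @export
truncate_fragments <- function(fragments, new_length) {
  out <- lapply(fragments, function(f) {
    f$mates <- lapply(seq_along(f$mates), function(j) {
      truncate_mate(f$mates[[j]], new_length,
                    from_right = xor(j == 2, f$strand == "-"))
    })
    f
  })
  fragment_set(out)
}

# keep `len` covered bases from the left (from_right = FALSE) or right end
# of a mate's plus-strand block/call representation
truncate_mate <- function(m, len, from_right) {
  w <- m$blocks[, 2] - m$blocks[, 1] + 1L
  total <- sum(w)
  if (total <= len) return(m)
  if (!from_right) {
    cw <- cumsum(w)
    k <- which(cw >= len)[1]
    blocks <- m$blocks[seq_len(k), , drop = FALSE]
    blocks[k, 2] <- blocks[k, 1] + (len - c(0, cw)[k] - 1L)
    list(blocks = blocks, calls = substr(m$calls, 1L, len),
         quals = substr(m$quals, 1L, len))
  } else {
    rw <- rev(cumsum(rev(w)))
    k <- max(which(rw >= len))
    blocks <- m$blocks[k:nrow(m$blocks), , drop = FALSE]
    drop_left <- rw[k] - len
    blocks[1, 1] <- blocks[1, 1] + drop_left
    list(blocks = blocks,
         calls = substr(m$calls, total - len + 1L, total),
         quals = substr(m$quals, total - len + 1L, total))
  }
}
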