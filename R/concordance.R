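#' Per-site mismatch counts against known genotypes
#'
#' For each genotyped SNP site covered by at least `min_depth` fragments,
#' counts the depth `n` (fragments contributing a base at the site; a
#' fragment counts once even if both mates cover it) and the mismatches `x`
#' (fragments whose base at the site is not one of the genotype's two
#' alleles). A fragment whose alignment gaps over the site contributes no
#' base. Allelic imbalance is not penalized: at a heterozygous site either
#' allele is a match.
#'
#' @param fragments a [fragment_set()] of aligned fragments.
#' @param genotyped_sites data.frame with columns `pos`, `allele1`, `allele2`
#'   (plus-strand bases; homozygous sites have `allele1 == allele2`). A
#'   [generate_diplotype()] result is accepted (its `ref`/`alt` columns are
#'   the alleles).
#' @param min_depth minimum depth for a site to be analyzed (default 10).
#' @return data.frame of class `concordance_sites` with columns `pos`, `n`,
#'   `x`.
#' @export
site_mismatch_counts <- function(fragments, genotyped_sites, min_depth = 10L) {
  gs <- normalize_genotypes(genotyped_sites)
  calls <- fragment_calls_at(fragments, gs$pos)
  if (nrow(calls)) {
    a1 <- gs$allele1[calls$site]
    a2 <- gs$allele2[calls$site]
    mism <- calls$call != a1 & calls$call != a2
    n <- tabulate(calls$site, nbins = nrow(gs))
    x <- tabulate(calls$site[mism], nbins = nrow(gs))
  } else {
    n <- x <- integer(nrow(gs))
  }
  out <- data.frame(pos = gs$pos, n = n, x = x)
  out <- out[out$n >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concordance_sites", "data.frame")
  out
}

normalize_genotypes <- function(sites) {
  if (all(c("allele1", "allele2") %in% names(sites))) {
    data.frame(pos = sites$pos, allele1 = sites$allele1,
               allele2 = sites$allele2, stringsAsFactors = FALSE)
  } else if (all(c("ref", "alt") %in% names(sites))) {
    data.frame(pos = sites$pos, allele1 = sites$ref, allele2 = sites$alt,
               stringsAsFactors = FALSE)
  } else {
    stop("genotyped_sites needs allele1/allele2 (or ref/alt) columns")
  }
}

#' Estimate the per-base sequencing error rate
#'
#' The error rate is the total number of mismatched bases across all
#' analyzed genotyped sites divided by the total number of bases aligned
#' over those sites. Estimated separately per dataset, never pooled across
#' libraries.
#'
#' @param sites a [site_mismatch_counts()] result.
#' @return list of class `error_rate_estimate` with `epsilon`,
#'   `n_mismatches`, `n_aligned_bases`.
#' @export
estimate_error_rate <- function(sites) {
  n_bases <- sum(sites$n)
  if (n_bases < 1) stop("no aligned bases at genotyped sites")
  out <- list(epsilon = sum(sites$x) / n_bases,
              n_mismatches = sum(sites$x), n_aligned_bases = n_bases)
  class(out) <- "error_rate_estimate"
  out
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("per-base error rate: %.3e (%d mismatches / %d aligned bases)\n",
              x$epsilon, x$n_mismatches, x$n_aligned_bases))
  invisible(x)
}

#' Binomial discordance p-value
#'
#' Under the null hypothesis of no mapping error, the mismatch count at a
#' site of depth `n` follows Binomial(`n`, `epsilon`) where `epsilon` is the
#' per-base sequencing error rate. The discordance p-value is the upper-tail
#' probability `P(X >= x)`; sites with `x = 0` get p = 1. Small values flag
#' sites where mismapped reads, not sequencing error, drive the mismatches.
#'
#' @param n depth (vectorized).
#' @param x mismatch count (vectorized).
#' @param epsilon per-base error rate, strictly inside (0, 1).
#' @return numeric p-values in (0, 1].
#' @export
discordance_pvalue <- function(n, x, epsilon) {
  if (length(epsilon) != 1 || epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must be a single value in (0, 1)")
  }
  if (any(x < 0 | x > n)) stop("x must lie in [0, n]")
  ifelse(x == 0, 1, stats::pbinom(x - 1, n, epsilon, lower.tail = FALSE))
}

#' Depth bins used for stratified concordance comparison
#'
#' @param n depth vector.
#' @return factor with levels `10-99`, `100-499`, `500-999`, `>=1000`
#'   (depths below 10 are `NA`; analyzed sites never fall there).
#' @export
depth_bins <- function(n) {
  cut(n, breaks = c(10, 100, 500, 1000, Inf), right = FALSE,
      labels = c("10-99", "100-499", "500-999", ">=1000"))
}

#' Compare two libraries' discordance p-values by depth bin
#'
#' Each library's analyzed sites are stratified by their own read depth into
#' the four standard bins; within each bin a one-sided Wilcoxon rank-sum
#' test asks whether library A's discordance p-values are stochastically
#' larger (i.e. A is more concordant) than library B's. Bins with fewer than
#' two sites in either library are skipped.
#'
#' @param sitesA,sitesB data.frames with columns `n` and `p` (depth and
#'   discordance p-value per site), e.g. [site_mismatch_counts()] output
#'   augmented with [discordance_pvalue()].
#' @param alpha significance level reported alongside (default 0.05).
#' @return data.frame with one row per bin: `bin`, `n_A`, `n_B`, `p_value`,
#'   `significant`, `skipped`.
#' @export
stratify_and_compare <- function(sitesA, sitesB, alpha = 0.05) {
  binA <- depth_bins(sitesA$n)
  binB <- depth_bins(sitesB$n)
  lv <- levels(binA)
  res <- lapply(lv, function(b) {
    pa <- sitesA$p[which(binA == b)]
    pb <- sitesB$p[which(binB == b)]
    if (length(pa) < 2 || length(pb) < 2) {
      return(data.frame(bin = b, n_A = length(pa), n_B = length(pb),
                        p_value = NA_real_, significant = NA, skipped = TRUE))
    }
    p <- suppressWarnings(
      stats::wilcox.test(pa, pb, alternative = "greater")$p.value)
    data.frame(bin = b, n_A = length(pa), n_B = length(pb), p_value = p,
               significant = p < alpha, skipped = FALSE)
  })
  do.call(rbind, res)
}

#' Modal observed indel size per genotyped indel site
#'
#' For each genotyped indel (signed size: insertion positive, deletion
#' negative), tallies the indel sizes reported by fragments spanning the
#' site and reports the most frequent one. Fragments spanning the site
#' without reporting an indel there do not enter the tally; sites with no
#' indel-reporting spanning fragment are omitted. Ties are broken toward
#' the smaller magnitude and flagged.
#'
#' @param fragments a [fragment_set()]; fragments may carry an `indels`
#'   matrix (`pos`, `size`).
#' @param indel_sites data.frame with columns `pos` and `size` (expected
#'   signed size from DNA genotyping).
#' @return data.frame `pos`, `expected_size`, `modal_size`, `n_obs`, `tie`,
#'   `agree`, plus the diagonal agreement fraction as attribute
#'   `"agreement"`.
#' @export
modal_indel_size <- function(fragments, indel_sites) {
  obs <- do.call(rbind, lapply(fragments, function(f) {
    if (is.null(f$indels) || nrow(f$indels) == 0) return(NULL)
    data.frame(pos = f$indels[, "pos"], size = f$indels[, "size"])
  }))
  rows <- lapply(seq_len(nrow(indel_sites)), function(i) {
    p <- indel_sites$pos[i]
    sizes <- if (is.null(obs)) integer(0) else obs$size[obs$pos == p]
    if (length(sizes) == 0) return(NULL)
    tab <- table(sizes)
    top <- as.integer(names(tab)[tab == max(tab)])
    tie <- length(top) > 1
    modal <- top[order(abs(top), top)][1]
    data.frame(pos = p, expected_size = indel_sites$size[i],
               modal_size = modal, n_obs = length(sizes), tie = tie,
               agree = modal == indel_sites$size[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pos = integer(), expected_size = integer(),
                      modal_size = integer(), n_obs = integer(),
                      tie = logical(), agree = logical())
  }
  attr(out, "agreement") <- if (nrow(out)) mean(out$agree) else NA_real_
  out
}
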