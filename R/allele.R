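#' Assign a fragment to its parental haplotype
#'
#' Inspects every phased heterozygous site covered by the fragment: if all
#' covered sites carry the maternal (resp. paternal) allele, the fragment is
#' assigned to that haplotype; a mixture or any non-allelic base is
#' `conflicting`; a fragment covering no het site is `no_site`.
#'
#' @param fragment an [aligned_fragment()].
#' @param sites phased sites ([generate_diplotype()] format: `pos`,
#'   `maternal`, `paternal`).
#' @return one of `"maternal"`, `"paternal"`, `"no_site"`, `"conflicting"`.
#' @export
assign_haplotype <- function(fragment, sites) {
  assign_haplotypes(fragment_set(list(fragment)), sites)
}

#' @rdname assign_haplotype
#' @param fragments a [fragment_set()].
#' @return for `assign_haplotypes()`, a character vector along the set.
#' @export
assign_haplotypes <- function(fragments, sites) {
  out <- rep("no_site", length(fragments))
  if (length(fragments) == 0 || is.null(sites) || nrow(sites) == 0) {
    return(out)
  }
  calls <- fragment_calls_at(fragments, sites$pos)
  if (nrow(calls) == 0) return(out)
  is_m <- calls$call == sites$maternal[calls$site]
  is_p <- calls$call == sites$paternal[calls$site]
  all_m <- tapply(is_m, calls$idx, all)
  all_p <- tapply(is_p, calls$idx, all)
  idx <- as.integer(names(all_m))
  out[idx] <- ifelse(all_m, "maternal",
                     ifelse(all_p, "paternal", "conflicting"))
  out
}

#' Fraction of haplotype-assignable reads, by effective length
#'
#' The proportion of fragments assigned to either parental haplotype,
#' optionally stratified by effective alignment length. Under a Poisson het
#' model with rate `lambda` and error-free reads this fraction is
#' `1 - exp(-lambda * L)` for alignments covering `L` bases.
#'
#' @param fragments a [fragment_set()].
#' @param sites phased sites.
#' @param length_breaks optional numeric breaks for strata; `NULL` pools all.
#' @return data.frame `stratum`, `n`, `mean_length`, `assignable_fraction`
#'   (empty strata are dropped).
#' @export
assignable_fraction <- function(fragments, sites, length_breaks = NULL) {
  hap <- assign_haplotypes(fragments, sites)
  len <- effective_lengths(fragments)
  assigned <- hap %in% c("maternal", "paternal")
  stratum <- if (is.null(length_breaks)) {
    factor(rep("all", length(fragments)))
  } else {
    cut(len, breaks = length_breaks, include.lowest = TRUE)
  }
  keep <- !is.na(stratum)
  res <- lapply(levels(stratum), function(s) {
    i <- which(stratum == s & keep)
    if (!length(i)) return(NULL)
    data.frame(stratum = s, n = length(i), mean_length = mean(len[i]),
               assignable_fraction = mean(assigned[i]))
  })
  do.call(rbind, res)
}

#' Fit the Poisson haplotype-assignment model
#'
#' Models the probability that an alignment covering `L` reference bases
#' contains at least one heterozygous site as `p(L) = 1 - exp(-lambda * L)`,
#' where `lambda` is the het-site rate per base, and fits `lambda` by
#' maximizing the Bernoulli likelihood of the observed per-fragment
#' assignment indicators. The fitted model extrapolates the assignable
#' fraction to arbitrary (longer) read lengths.
#'
#' @param lengths per-fragment effective alignment lengths (positive).
#' @param assigned logical per-fragment indicator of haplotype assignment.
#' @return object of class `poisson_assignment_model`: `lambda`, `n`,
#'   `boundary` flag (all or none assigned), and `predict(L)`.
#' @export
fit_poisson_model <- function(lengths, assigned) {
  stopifnot(length(lengths) == length(assigned), all(lengths > 0))
  if (length(lengths) < 100) stop("need at least 100 fragments to fit")
  y <- as.logical(assigned)
  boundary <- all(y) || !any(y)
  if (boundary) {
    lambda <- if (all(y)) Inf else 0
  } else {
    nll <- function(loglam) {
      lam <- exp(loglam)
      p <- -expm1(-lam * lengths)
      -sum(ifelse(y, log(p), -lam * lengths))
    }
    opt <- stats::optimize(nll, interval = log(c(1e-9, 1)), tol = 1e-8)
    lambda <- exp(opt$minimum)
  }
  structure(list(lambda = lambda, n = length(y), boundary = boundary,
                 predict = function(L) -expm1(-lambda * L)),
            class = "poisson_assignment_model")
}

#' @export
print.poisson_assignment_model <- function(x, ...) {
  cat(sprintf("Poisson assignment model: lambda = %.4g /base (n = %d)%s\n",
              x$lambda, x$n, if (x$boundary) " [boundary fit]" else ""))
  cat(sprintf("  predicted assignable fraction at L = 1000: %.3f\n",
              x$predict(1000)))
  invisible(x)
}

#' Gene-level allele-specific expression test
#'
#' Two-sided exact binomial test of the maternal read count against a
#' balanced (p = 0.5) null. Genes with fewer than `min_total` assigned reads
#' are not testable and return `NA`.
#'
#' @param n_maternal,n_paternal haplotype-assigned read counts (vectorized).
#' @param min_total minimum total reads to test (default 20).
#' @return numeric p-values (`NA` where excluded).
#' @export
ase_test <- function(n_maternal, n_paternal, min_total = 20L) {
  stopifnot(all(n_maternal >= 0), all(n_paternal >= 0))
  mapply(function(m, p) {
    tot <- m + p
    if (tot < min_total || tot == 0) return(NA_real_)
    stats::binom.test(m, tot, p = 0.5)$p.value
  }, n_maternal, n_paternal)
}

#' Per-site allele-specific expression test
#'
#' Two-sided binomial test at p = 0.5 of each heterozygous site's
#' maternal/paternal read counts.
#'
#' @param site_counts data.frame with columns `pos`, `n_maternal`,
#'   `n_paternal`.
#' @param min_total minimum covering reads (default 1).
#' @return the input with a `p_value` column.
#' @export
per_locus_ase_test <- function(site_counts, min_total = 1L) {
  site_counts$p_value <- ase_test(site_counts$n_maternal,
                                  site_counts$n_paternal,
                                  min_total = min_total)
  site_counts
}

#' Haplotype-resolved read counts per heterozygous site
#'
#' @param fragments a [fragment_set()].
#' @param sites phased sites.
#' @return data.frame `pos`, `n_maternal`, `n_paternal` over covered sites;
#'   only fragments assigned to a haplotype contribute.
#' @export
site_haplotype_counts <- function(fragments, sites) {
  hap <- assign_haplotypes(fragments, sites)
  keep <- hap %in% c("maternal", "paternal")
  calls <- fragment_calls_at(fragments[keep], sites$pos)
  if (nrow(calls) == 0) {
    return(data.frame(pos = integer(), n_maternal = integer(),
                      n_paternal = integer()))
  }
  hk <- hap[keep][calls$idx]
  nm <- tabulate(calls$site[hk == "maternal"], nbins = nrow(sites))
  np <- tabulate(calls$site[hk == "paternal"], nbins = nrow(sites))
  any_cov <- nm + np > 0
  data.frame(pos = sites$pos[any_cov], n_maternal = nm[any_cov],
             n_paternal = np[any_cov])
}

#' Exon blocks of a gene
#'
#' Partitions the gene's exonic union into atomic intervals at every exon
#' boundary of every isoform, so that no block contains an internal exon
#' boundary. These blocks are the testing unit of allele-specific
#' alternative splicing.
#'
#' @param gene_id gene id.
#' @param annotation a [tx_annotation()].
#' @return data.frame `gene_id`, `block_id`, `start`, `end`, ordered and
#'   disjoint, covering the exonic union.
#' @export
exon_blocks <- function(gene_id, annotation) {
  tids <- transcripts_of(annotation, gene_id)
  if (length(tids) == 0) stop("unknown gene: ", gene_id)
  ex <- annotation$exons[annotation$exons$transcript_id %in% tids, ]
  blocks <- IRanges::disjoin(IRanges::IRanges(ex$start, ex$end))
  data.frame(gene_id = gene_id, block_id = seq_along(blocks),
             start = IRanges::start(blocks), end = IRanges::end(blocks),
             stringsAsFactors = FALSE)
}

#' Allele-specific alternative-splicing test for one exon block
#'
#' Builds the 2x2 contingency table of the gene's haplotype-assigned
#' fragments — rows maternal/paternal, columns overlap/no-overlap with the
#' block (overlap means either mate covers at least one base) — and applies
#' a Pearson chi-square test with 1 df, no continuity correction. Genes with
#' fewer than `min_total` assigned fragments are not testable; a zero row or
#' column margin leaves the test undefined. Tables with an expected count
#' below 5 are flagged but still tested.
#'
#' @param block one row of [exon_blocks()] output (or any list with `start`,
#'   `end`).
#' @param fragments [fragment_set()] of the gene's fragments.
#' @param haplotypes their [assign_haplotypes()] labels.
#' @param min_total minimum assigned fragments (default 40).
#' @return list: `table` (named counts `a`,`b`,`c`,`d`), `chisq`, `p_value`,
#'   `low_expected`, `status` (`tested`, `too_few`, `zero_margin`).
#' @export
asas_test <- function(block, fragments, haplotypes, min_total = 40L) {
  keep <- haplotypes %in% c("maternal", "paternal")
  frg <- fragments[keep]
  hap <- haplotypes[keep]
  n <- length(frg)
  empty <- list(table = c(a = NA, b = NA, c = NA, d = NA), chisq = NA_real_,
                p_value = NA_real_, low_expected = NA)
  if (n < min_total) return(c(empty, status = "too_few"))
  ov <- vapply(frg, function(f) {
    any(IRanges::overlapsAny(covered_ranges(f),
                             IRanges::IRanges(block$start, block$end)))
  }, TRUE)
  a <- sum(hap == "maternal" & ov)
  b <- sum(hap == "maternal" & !ov)
  cc <- sum(hap == "paternal" & ov)
  d <- sum(hap == "paternal" & !ov)
  tab <- c(a = a, b = b, c = cc, d = d)
  if (any(c(a + b, cc + d, a + cc, b + d) == 0)) {
    return(list(table = tab, chisq = NA_real_, p_value = NA_real_,
                low_expected = NA, status = "zero_margin"))
  }
  m <- matrix(as.numeric(c(a, cc, b, d)), 2)  # cross-products overflow int
  chisq <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m), colSums(m))
  expected <- outer(rowSums(m), colSums(m)) / n
  list(table = tab, chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       low_expected = any(expected < 5), status = "tested")
}

#' Scan all exon blocks of all testable genes for ASAS
#'
#' Runs [asas_test()] on every exon block of every gene with at least
#' `min_total` haplotype-assigned fragments. All blocks enter a single
#' multiple-testing pool (see [bh_fdr()]).
#'
#' @param fragments a [fragment_set()].
#' @param gene_ids per-fragment gene labels (e.g. unambiguous gene
#'   assignments; `NA` fragments are ignored).
#' @param sites phased sites.
#' @param annotation a [tx_annotation()].
#' @param min_total minimum assigned fragments per gene (default 40).
#' @param fdr BH false-discovery rate for the `significant` column
#'   (default 0.10).
#' @return data.frame with one row per tested block: `gene_id`, `block_id`,
#'   `start`, `end`, `a`, `b`, `c`, `d`, `chisq`, `p_value`, `low_expected`,
#'   `significant`.
#' @export
asas_scan <- function(fragments, gene_ids, sites, annotation,
                      min_total = 40L, fdr = 0.10) {
  hap <- assign_haplotypes(fragments, sites)
  rows <- list()
  for (g in unique(stats::na.omit(gene_ids))) {
    sel <- which(!is.na(gene_ids) & gene_ids == g)
    hap_g <- hap[sel]
    if (sum(hap_g %in% c("maternal", "paternal")) < min_total) next
    frg <- fragments[sel]
    blocks <- exon_blocks(g, annotation)
    for (i in seq_len(nrow(blocks))) {
      r <- asas_test(blocks[i, ], frg, hap_g, min_total = min_total)
      if (!identical(r$status, "tested")) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, block_id = blocks$block_id[i],
        start = blocks$start[i], end = blocks$end[i],
        a = r$table["a"], b = r$table["b"], c = r$table["c"],
        d = r$table["d"], chisq = r$chisq, p_value = r$p_value,
        low_expected = r$low_expected, row.names = NULL)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), block_id = integer(),
                      start = integer(), end = integer(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      chisq = numeric(), p_value = numeric(),
                      low_expected = logical(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$significant <- bh_fdr(out$p_value, q = fdr)
  out
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard step-up: with `m` p-values sorted ascending, find the largest
#' `k` such that `p_(k) <= k * q / m`; all hypotheses of rank `<= k` are
#' significant.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q target false-discovery rate (default 0.10).
#' @return logical vector (in input order); empty input gives an empty
#'   vector.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  m <- length(p_values)
  if (m == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  sig <- logical(m)
  if (length(ok)) sig[ord[seq_len(max(ok))]] <- TRUE
  sig[is.na(p_values)] <- NA
  sig
}

#' Flip heterozygous-site alleles of a fragment to the other haplotype
#'
#' Replaces the base at every covered heterozygous site with the other
#' haplotype's allele, leaving all other bases unchanged. Applying the flip
#' twice restores the original fragment. A non-allelic base (a sequencing
#' error at a het site) is replaced by the allele opposite the assigned
#' haplotype and flagged; `haplotype` is required in that case.
#'
#' @param fragment an [aligned_fragment()].
#' @param sites phased sites.
#' @param haplotype optional `"maternal"`/`"paternal"` label used only to
#'   resolve non-allelic bases.
#' @return the modified fragment, with attribute `"n_flagged"` counting
#'   non-allelic replacements.
#' @export
allele_flip <- function(fragment, sites, haplotype = NULL) {
  n_flagged <- 0L
  for (j in seq_along(fragment$mates)) {
    m <- fragment$mates[[j]]
    b <- m$blocks
    pos_all <- unlist(mapply(seq.int, b[, 1], b[, 2], SIMPLIFY = FALSE),
                      use.names = FALSE)
    hit <- match(sites$pos, pos_all)
    covered <- which(!is.na(hit))
    if (!length(covered)) next
    ch <- strsplit(m$calls, "")[[1]]
    for (k in covered) {
      at <- hit[k]
      cur <- ch[at]
      if (cur == sites$maternal[k]) {
        ch[at] <- sites$paternal[k]
      } else if (cur == sites$paternal[k]) {
        ch[at] <- sites$maternal[k]
      } else {
        if (is.null(haplotype)) {
          stop("non-allelic base at het site ", sites$pos[k],
               "; supply the assigned haplotype")
        }
        ch[at] <- if (haplotype == "maternal") sites$paternal[k]
                  else sites$maternal[k]
        n_flagged <- n_flagged + 1L
      }
    }
    fragment$mates[[j]]$calls <- paste(ch, collapse = "")
  }
  attr(fragment, "n_flagged") <- n_flagged
  fragment
}

#' Mapping retention rate of a gene
#'
#' The reference-bias diagnostic: every haplotype-assigned fragment of the
#' gene has its heterozygous-site alleles flipped to the other haplotype and
#' is realigned with the supplied aligner; the retention rate is the
#' fraction whose every mate maps uniquely back to the identical start and
#' block structure. Genes with a rate below `min_rate` are marked
#' untestable for allele-specific analysis.
#'
#' @param fragments [fragment_set()] of the gene's fragments.
#' @param haplotypes their [assign_haplotypes()] labels.
#' @param sites phased sites.
#' @param aligner a function `f(read)` with the [toy_align()] contract, e.g.
#'   from [make_toy_aligner()].
#' @param min_rate testability cutoff (default 0.9).
#' @return list of class `retention_result`: `n_flipped`, `n_retained`,
#'   `rate`, `testable`.
#' @export
retention_rate <- function(fragments, haplotypes, sites, aligner,
                           min_rate = 0.9) {
  keep <- which(haplotypes %in% c("maternal", "paternal"))
  if (length(keep) == 0) {
    return(structure(list(n_flipped = 0L, n_retained = 0L, rate = NA_real_,
                          testable = FALSE), class = "retention_result"))
  }
  retained <- vapply(keep, function(i) {
    flipped <- allele_flip(fragments[[i]], sites, haplotypes[i])
    for (j in seq_along(flipped$mates)) {
      hit <- aligner(mate_read_seq(flipped, j))
      if (!identical(hit$status, "mapped")) return(FALSE)
      orig <- fragments[[i]]$mates[[j]]$blocks
      if (!identical(unname(hit$blocks[, 1]), unname(orig[, 1])) ||
          !identical(unname(hit$blocks[, 2]), unname(orig[, 2]))) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  rate <- mean(retained)
  structure(list(n_flipped = length(keep), n_retained = sum(retained),
                 rate = rate, testable = rate >= min_rate),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("mapping retention: %d/%d reads retained (rate %.3f) -> %s\n",
              x$n_retained, x$n_flipped, x$rate,
              if (isTRUE(x$testable)) "testable" else "untestable"))
  invisible(x)
}

#' Gene exclusion filters for allele-specific testing
#'
#' Removes genes matching the HLA (or any supplied) name pattern — a guard
#' against miscalled genotypes in hyper-polymorphic loci — genes with too
#' few haplotype-assigned reads, and genes failing the mapping-retention
#' cutoff.
#'
#' @param gene_stats data.frame with columns `gene_id`, `gene_name`,
#'   `n_assigned`, and optionally `retention_rate`.
#' @param hla_pattern regular expression for name-based exclusion
#'   (default `"^HLA-"`).
#' @param min_reads minimum haplotype-assigned reads (20 for ASE, 40 for
#'   ASAS).
#' @param retention_min minimum mapping retention rate (default 0.9;
#'   ignored if the column is absent).
#' @return the input with logical `testable` and character `reason`
#'   (`NA` when testable).
#' @export
exclusion_filters <- function(gene_stats, hla_pattern = "^HLA-",
                              min_reads = 20L, retention_min = 0.9) {
  reason <- rep(NA_character_, nrow(gene_stats))
  hla <- grepl(hla_pattern, gene_stats$gene_name)
  reason[hla] <- "hla_name"
  few <- is.na(reason) & gene_stats$n_assigned < min_reads
  reason[few] <- "too_few_reads"
  if ("retention_rate" %in% names(gene_stats)) {
    low <- is.na(reason) & (is.na(gene_stats$retention_rate) |
                              gene_stats$retention_rate < retention_min)
    reason[low] <- "low_retention"
  }
  gene_stats$testable <- is.na(reason)
  gene_stats$reason <- reason
  gene_stats
}

#' Hypergeometric enrichment of significant genes in an annotated set
#'
#' Upper-tail hypergeometric probability of drawing at least `k_overlap`
#' annotated genes (e.g. genes with a heterozygous known-eQTL site) among
#' the significant genes, out of `n_tested` tested genes of which
#' `n_annotated` are annotated.
#'
#' @param k_overlap significant genes that are annotated.
#' @param n_annotated annotated genes among those tested.
#' @param n_significant significant genes.
#' @param n_tested all tested genes.
#' @return enrichment p-value `P(X >= k_overlap)`.
#' @export
enrichment_test <- function(k_overlap, n_annotated, n_significant, n_tested) {
  if (k_overlap > min(n_annotated, n_significant) ||
      max(n_annotated, n_significant) > n_tested || k_overlap < 0) {
    stop("inconsistent counts")
  }
  if (k_overlap == 0) return(1)
  stats::phyper(k_overlap - 1, n_annotated, n_tested - n_annotated,
                n_significant, lower.tail = FALSE)
}

#' Gene-level ASE scan
#'
#' Counts maternal and paternal fragments per gene and applies [ase_test()],
#' with BH significance at the requested FDR over testable genes.
#'
#' @param fragments a [fragment_set()].
#' @param gene_ids per-fragment gene labels (`NA` ignored).
#' @param sites phased sites.
#' @param min_total minimum assigned reads per gene (default 20).
#' @param fdr BH false-discovery rate (default 0.10).
#' @return data.frame `gene_id`, `n_maternal`, `n_paternal`,
#'   `maternal_fraction`, `p_value`, `significant` (NA rows are untestable
#'   genes).
#' @export
ase_scan <- function(fragments, gene_ids, sites, min_total = 20L,
                     fdr = 0.10) {
  hap <- assign_haplotypes(fragments, sites)
  keep <- !is.na(gene_ids) & hap %in% c("maternal", "paternal")
  genes <- sort(unique(gene_ids[keep]))
  nm <- vapply(genes, function(g)
    sum(gene_ids[keep] == g & hap[keep] == "maternal"), 1L)
  np <- vapply(genes, function(g)
    sum(gene_ids[keep] == g & hap[keep] == "paternal"), 1L)
  out <- data.frame(gene_id = genes, n_maternal = nm, n_paternal = np,
                    maternal_fraction = nm / (nm + np),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_value <- ase_test(out$n_maternal, out$n_paternal,
                          min_total = min_total)
  tested <- !is.na(out$p_value)
  out$significant <- NA
  if (any(tested)) out$significant[tested] <- bh_fdr(out$p_value[tested],
                                                     q = fdr)
  out
}
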