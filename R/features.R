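#' Per-base feature index over an annotation
#'
#' Maps reference bases to the features containing them. At `gene` level a
#' feature is a gene and its footprint is the full genic span; at `isoform`
#' level a feature is a transcript and its footprint is its exonic bases.
#' The index also carries each transcript's intron chain for splice-junction
#' consistency filtering.
#'
#' @param annotation a [tx_annotation()].
#' @param level `"gene"` or `"isoform"`.
#' @return object of class `base_index`.
#' @export
build_base_index <- function(annotation, level = c("gene", "isoform")) {
  level <- match.arg(level)
  if (level == "gene") {
    g <- annotation$genes
    tab <- data.frame(feature_id = g$gene_id, chrom = g$chrom,
                      start = g$start, end = g$end, stringsAsFactors = FALSE)
    introns <- NULL
  } else {
    ex <- annotation$exons
    tab <- data.frame(feature_id = ex$transcript_id, chrom = ex$chrom,
                      start = ex$start, end = ex$end, stringsAsFactors = FALSE)
    introns <- lapply(
      stats::setNames(nm = annotation$transcripts$transcript_id),
      function(tid) {
        ir <- tx_introns(annotation, tid)
        cbind(start = IRanges::start(ir), end = IRanges::end(ir))
      })
  }
  # reduced interval matrix per feature (hot path of assignment)
  feat_blocks <- lapply(split(seq_len(nrow(tab)), tab$feature_id), function(i) {
    r <- IRanges::reduce(IRanges::IRanges(tab$start[i], tab$end[i]))
    cbind(start = IRanges::start(r), end = IRanges::end(r))
  })
  feat_chrom <- vapply(split(tab$chrom, tab$feature_id), `[[`, "", 1)
  structure(list(level = level, table = tab,
                 ranges = IRanges::IRanges(tab$start, tab$end),
                 feat_blocks = feat_blocks, feat_chrom = feat_chrom,
                 introns = introns, annotation = annotation),
            class = "base_index")
}

# --- interval arithmetic on 2-column (start, end) matrices -----------------
# Rows are 1-based inclusive intervals; results are sorted and disjoint.
# Used in the per-fragment assignment loop where S4 overhead dominates.

mat_reduce <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  s <- m[, 1]; e <- m[, 2]
  keep_s <- s[1]; out_s <- integer(0); out_e <- integer(0); cur_e <- e[1]
  for (i in seq_len(nrow(m))[-1]) {
    if (s[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, e[i])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
      keep_s <- s[i]; cur_e <- e[i]
    }
  }
  cbind(start = c(out_s, keep_s), end = c(out_e, cur_e))
}

mat_intersect <- function(a, b) {
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- pmax(b[, 1], a[i, 1]); e <- pmin(b[, 2], a[i, 2])
    k <- e >= s
    if (any(k)) out[[i]] <- cbind(start = s[k], end = e[k])
  }
  m <- do.call(rbind, out)
  if (is.null(m)) cbind(start = integer(0), end = integer(0)) else m
}

mat_width <- function(m) if (nrow(m) == 0) 0L else sum(m[, 2] - m[, 1] + 1L)

#' @export
print.base_index <- function(x, ...) {
  cat("base_index (", x$level, " level): ",
      length(unique(x$table$feature_id)), " features, ",
      nrow(x$table), " intervals\n", sep = "")
  invisible(x)
}

# base-level feature sets for one position vector (used by tests as well)
base_feature_sets <- function(index, chrom, pos) {
  keep <- index$table$chrom == chrom
  tab <- index$table[keep, , drop = FALSE]
  rng <- index$ranges[keep]
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), rng)
  split(tab$feature_id[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_along(pos)))
}

#' Consistent features of an aligned fragment
#'
#' Implements per-base feature-set intersection: over the bases covered by
#' the fragment (both mates pooled), take the intersection of all *nonempty*
#' per-base feature sets — bases outside every feature are uninformative and
#' do not empty the intersection, which lets fragments run past annotation
#' edges. At isoform level the result is additionally restricted to isoforms
#' whose intron chain contains every splice junction of the alignment; a
#' junction matching no isoform of the intersected set empties it.
#'
#' An empty result means the fragment is unassigned; a singleton means it is
#' unambiguous.
#'
#' @param fragment an [aligned_fragment()].
#' @param index a [build_base_index()] result.
#' @return list with `features` (character vector, possibly empty) and
#'   `unambiguous` (exactly one feature).
#' @export
consistent_features <- function(fragment, index) {
  cov <- covered_ranges(fragment)
  keep <- index$table$chrom == fragment$chrom
  hits <- IRanges::findOverlaps(cov, index$ranges[keep])
  cand <- unique(index$table$feature_id[keep][S4Vectors::subjectHits(hits)])
  covm <- cbind(start = IRanges::start(cov), end = IRanges::end(cov))
  feats <- consistent_features_impl(covm, fragment_junctions(fragment),
                                    cand, index)
  list(features = feats, unambiguous = length(feats) == 1)
}

# shared core: per-base set intersection over nonempty sets, then junction
# filtering at isoform level. `covm` is the fragment's reduced coverage.
consistent_features_impl <- function(covm, jx, cand, index) {
  if (length(cand) == 0) return(character(0))
  inter <- lapply(cand, function(f)
    mat_reduce(mat_intersect(covm, index$feat_blocks[[f]])))
  explained_w <- mat_width(mat_reduce(do.call(rbind, inter)))
  ok <- vapply(inter, function(m) as.numeric(mat_width(m)), 0) == explained_w
  feats <- cand[ok]
  if (index$level == "isoform" && length(feats) && nrow(jx)) {
    feats <- feats[vapply(feats, function(f) {
      intr <- index$introns[[f]]
      all(vapply(seq_len(nrow(jx)), function(r)
        any(intr[, "start"] == jx[r, "start"] &
              intr[, "end"] == jx[r, "end"]), TRUE))
    }, TRUE)]
  }
  feats
}

#' Assign every fragment of a set to its consistent features
#'
#' @param fragments a [fragment_set()].
#' @param index a [build_base_index()] result.
#' @return data.frame of class `feature_assignments` with one row per
#'   fragment: `id`, `n_features`, `unambiguous`, `feature` (the single
#'   feature or `NA`), `effective_length`, and list-column `features`.
#' @export
assign_fragments <- function(fragments, index) {
  # one batched overlap query for candidate features, then the shared core
  covs <- lapply(fragments, function(f) {
    mat_reduce(do.call(rbind, lapply(f$mates, `[[`, "blocks")))
  })
  n_per <- vapply(covs, nrow, 1L)
  frag_of <- rep(seq_along(fragments), n_per)
  allcov <- do.call(rbind, covs)
  chroms <- vapply(fragments, `[[`, "", "chrom")
  cand <- vector("list", length(fragments))
  for (ch in unique(chroms)) {
    keep <- index$table$chrom == ch
    rows <- which(chroms[frag_of] == ch)
    if (!length(rows)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(allcov[rows, 1], allcov[rows, 2]),
      index$ranges[keep])
    fid <- frag_of[rows][S4Vectors::queryHits(hits)]
    feat <- index$table$feature_id[keep][S4Vectors::subjectHits(hits)]
    sp <- split(feat, fid)
    cand[as.integer(names(sp))] <- lapply(sp, unique)
  }
  feats <- lapply(seq_along(fragments), function(i) {
    consistent_features_impl(covs[[i]], fragment_junctions(fragments[[i]]),
                             if (is.null(cand[[i]])) character(0) else cand[[i]],
                             index)
  })
  n_feat <- lengths(feats)
  out <- data.frame(
    id = vapply(fragments, `[[`, "", "id"),
    n_features = n_feat,
    unambiguous = n_feat == 1L,
    feature = ifelse(n_feat == 1L, vapply(feats, function(f)
      if (length(f) == 1) f else NA_character_, ""), NA_character_),
    effective_length = effective_lengths(fragments),
    stringsAsFactors = FALSE
  )
  out$features <- feats
  attr(out, "level") <- index$level
  class(out) <- c("feature_assignments", "data.frame")
  out
}

#' Cumulative distribution of the number of consistent features
#'
#' Among fragments assigned to at least one feature, tabulates the number of
#' consistent features per fragment, optionally stratified by effective
#' alignment length, and reports the cumulative distribution. The fraction
#' at count 1 is the unambiguous assignment rate.
#'
#' @param assignments an [assign_fragments()] result.
#' @param length_breaks optional numeric breaks for effective-length strata;
#'   `NULL` pools everything into one stratum.
#' @return data.frame `stratum`, `n_features`, `count`, `cum_fraction`, with
#'   the per-stratum unambiguous rate in attribute `"unambiguous_rate"`.
#' @export
consistency_distribution <- function(assignments, length_breaks = NULL) {
  a <- assignments[assignments$n_features >= 1L, , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned fragments")
  stratum <- if (is.null(length_breaks)) {
    factor(rep("all", nrow(a)))
  } else {
    cut(a$effective_length, breaks = length_breaks, include.lowest = TRUE)
  }
  pieces <- lapply(levels(stratum), function(s) {
    k <- a$n_features[stratum == s]
    if (!length(k)) return(NULL)
    tab <- table(k)
    data.frame(stratum = s, n_features = as.integer(names(tab)),
               count = as.integer(tab),
               cum_fraction = cumsum(as.integer(tab)) / length(k))
  })
  out <- do.call(rbind, pieces)
  ur <- vapply(levels(stratum), function(s) {
    k <- a$n_features[stratum == s]
    if (!length(k)) NA_real_ else mean(k == 1L)
  }, 1)
  attr(out, "unambiguous_rate") <-
    data.frame(stratum = levels(stratum), rate = unname(ur))
  out
}

#' Per-gene fraction of unambiguous reads
#'
#' @param assignments gene-level [assign_fragments()] output.
#' @param min_fraction genes with a read fraction at or below this are
#'   flagged unobserved (default `1e-6`).
#' @return data.frame `gene_id`, `n_reads`, `fraction`, `observed`; fractions
#'   sum to 1 over genes with reads.
#' @export
gene_read_fractions <- function(assignments, min_fraction = 1e-6) {
  u <- assignments[assignments$unambiguous, , drop = FALSE]
  if (nrow(u) == 0) stop("no unambiguous assignments")
  tab <- table(u$feature)
  out <- data.frame(gene_id = names(tab), n_reads = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_reads / sum(out$n_reads)
  out$observed <- out$fraction > min_fraction
  rownames(out) <- NULL
  out
}

#' Flag genes with large fold differences between two libraries
#'
#' @param fracA,fracB [gene_read_fractions()] results for the two libraries.
#' @param fold flag threshold (default 10).
#' @return data.frame over genes observed in both libraries: `gene_id`,
#'   `fraction_A`, `fraction_B`, `flag` in `{A-enriched, B-enriched,
#'   neither}`. Genes with zero fraction in both are excluded.
#' @export
fold_change_flags <- function(fracA, fracB, fold = 10) {
  a <- fracA[fracA$observed, c("gene_id", "fraction")]
  b <- fracB[fracB$observed, c("gene_id", "fraction")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_A", "_B"))
  m <- m[m$fraction_A > 0 | m$fraction_B > 0, , drop = FALSE]
  m$flag <- ifelse(m$fraction_A > fold * m$fraction_B, "A-enriched",
                   ifelse(m$fraction_B > fold * m$fraction_A, "B-enriched",
                          "neither"))
  names(m)[2:3] <- c("fraction_A", "fraction_B")
  m
}

#' Length-weighted mean mappability per gene
#'
#' Summarizes an interval mappability track (chrom, start, end, score) as a
#' per-gene mean over the gene's footprint; bases not covered by the track
#' score 0.
#'
#' @param annotation a [tx_annotation()].
#' @param mappability data.frame `chrom`, `start`, `end`, `score` with
#'   1-based inclusive intervals.
#' @return named numeric vector of mean scores, one per gene.
#' @export
gene_mean_mappability <- function(annotation, mappability) {
  g <- annotation$genes
  vapply(seq_len(nrow(g)), function(i) {
    tr <- mappability[mappability$chrom == g$chrom[i], , drop = FALSE]
    if (nrow(tr) == 0) return(0)
    ov_start <- pmax(tr$start, g$start[i])
    ov_end <- pmin(tr$end, g$end[i])
    w <- pmax(0L, ov_end - ov_start + 1L)
    sum(w * tr$score) / (g$end[i] - g$start[i] + 1L)
  }, 1)
}

#' Mappability-stratified comparison of two libraries' gene fractions
#'
#' Genes observed in both libraries and at least `min_length` long are
#' sorted by mean mappability and split into `n_groups` near-equal groups
#' (sizes differ by at most one); per group the fraction of genes with a
#' higher read proportion in library A is reported. If longer reads rescue
#' poorly mappable loci, the lowest-score group shows the largest fraction.
#'
#' @param fracA,fracB [gene_read_fractions()] results.
#' @param annotation a [tx_annotation()].
#' @param mappability interval track; see [gene_mean_mappability()].
#' @param n_groups number of mappability groups (default 5).
#' @param min_length minimum gene span in bases (default 500).
#' @param biotype optional biotype restriction (e.g. `"protein_coding"`).
#' @return data.frame `group` (1 = lowest mappability), `n_genes`,
#'   `mean_score`, `frac_A_higher`.
#' @export
mappability_stratify <- function(fracA, fracB, annotation, mappability,
                                 n_groups = 5L, min_length = 500L,
                                 biotype = NULL) {
  g <- annotation$genes
  score <- gene_mean_mappability(annotation, mappability)
  names(score) <- g$gene_id
  m <- merge(fracA[fracA$observed, c("gene_id", "fraction")],
             fracB[fracB$observed, c("gene_id", "fraction")],
             by = "gene_id", suffixes = c("_A", "_B"))
  span <- g$end - g$start + 1L
  keep <- m$gene_id %in% g$gene_id[span >= min_length]
  if (!is.null(biotype)) {
    keep <- keep & m$gene_id %in% g$gene_id[g$biotype %in% biotype]
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < n_groups) stop("fewer eligible genes than groups")
  m$score <- score[m$gene_id]
  m <- m[order(m$score), , drop = FALSE]
  sizes <- diff(round(seq(0, nrow(m), length.out = n_groups + 1)))
  m$group <- rep(seq_len(n_groups), sizes)
  out <- lapply(split(m, m$group), function(d) {
    data.frame(group = d$group[1], n_genes = nrow(d),
               mean_score = mean(d$score),
               frac_A_higher = mean(d$fraction_A > d$fraction_B))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read fraction per gene biotype
#'
#' @param assignments gene-level [assign_fragments()] output.
#' @param annotation a [tx_annotation()].
#' @return data.frame `biotype`, `n_reads`, `fraction` (fractions sum to 1
#'   over unambiguously assigned reads).
#' @export
biotype_breakdown <- function(assignments, annotation) {
  u <- assignments[assignments$unambiguous, , drop = FALSE]
  bt <- annotation$genes$biotype[match(u$feature, annotation$genes$gene_id)]
  tab <- table(bt)
  data.frame(biotype = names(tab), n_reads = as.integer(tab),
             fraction = as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bases unique to a transcript within its gene
#'
#' The number of exonic bases belonging to the transcript and to no other
#' transcript of the same gene — the denominator of unique-base transcript
#' quantification. Uniqueness is scoped within the gene; cross-gene
#' ambiguity is handled by unambiguous gene assignment upstream.
#'
#' @param transcript_id transcript id.
#' @param annotation a [tx_annotation()].
#' @return integer base count.
#' @export
unique_bases <- function(transcript_id, annotation) {
  gid <- gene_of_transcript(annotation, transcript_id)
  if (is.na(gid)) stop("unknown transcript: ", transcript_id)
  ex <- exons_of(annotation, transcript_id)
  own <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
  sibs <- setdiff(transcripts_of(annotation, gid), transcript_id)
  if (length(sibs) == 0) return(sum(IRanges::width(own)))
  sx <- annotation$exons[annotation$exons$transcript_id %in% sibs, ]
  other <- IRanges::reduce(IRanges::IRanges(sx$start, sx$end))
  sum(IRanges::width(IRanges::setdiff(own, other)))
}

#' Unique-base-normalized transcript abundance
#'
#' Counts fragments unambiguously consistent with a single transcript and
#' divides by the transcript's unique base count, correcting for the fact
#' that only the unique portion of a transcript can produce unambiguous
#' reads. Restricted to protein-coding genes with multiple isoforms;
#' transcripts with fewer than `min_unique` unique bases are excluded.
#'
#' @param assignments isoform-level [assign_fragments()] output.
#' @param annotation a [tx_annotation()].
#' @param min_unique minimum unique bases (default 10).
#' @return data.frame `transcript_id`, `gene_id`, `n_unambiguous`,
#'   `unique_bases`, `abundance`.
#' @export
transcript_abundance <- function(assignments, annotation, min_unique = 10L) {
  tx <- annotation$transcripts
  n_iso <- table(tx$gene_id)
  eligible_genes <- annotation$genes$gene_id[
    annotation$genes$biotype == "protein_coding" &
      annotation$genes$gene_id %in% names(n_iso)[n_iso >= 2]]
  tids <- tx$transcript_id[tx$gene_id %in% eligible_genes]
  if (length(tids) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      n_unambiguous = integer(), unique_bases = integer(),
                      abundance = numeric()))
  }
  u <- assignments[assignments$unambiguous, , drop = FALSE]
  counts <- table(factor(u$feature, levels = tids))
  ub <- vapply(tids, unique_bases, 1L, annotation = annotation)
  out <- data.frame(
    transcript_id = tids,
    gene_id = tx$gene_id[match(tids, tx$transcript_id)],
    n_unambiguous = as.integer(counts),
    unique_bases = ub,
    stringsAsFactors = FALSE
  )
  out <- out[out$unique_bases >= min_unique, , drop = FALSE]
  out$abundance <- out$n_unambiguous / out$unique_bases
  rownames(out) <- NULL
  out
}

#' Per-gene isoform-ambiguity rate
#'
#' Fraction of a gene's reads consistent with more than one isoform, among
#' reads whose consistent isoforms all belong to that gene. Genes with no
#' such reads are skipped.
#'
#' @param assignments isoform-level [assign_fragments()] output.
#' @param annotation a [tx_annotation()].
#' @return data.frame `gene_id`, `n_reads`, `ambiguity_rate`.
#' @export
ambiguity_rate <- function(assignments, annotation) {
  tx2g <- stats::setNames(annotation$transcripts$gene_id,
                          annotation$transcripts$transcript_id)
  a <- assignments[assignments$n_features >= 1L, , drop = FALSE]
  gene <- vapply(a$features, function(f) {
    gs <- unique(tx2g[f])
    if (length(gs) == 1) gs else NA_character_
  }, "")
  keep <- !is.na(gene)
  ambiguous <- a$n_features[keep] > 1L
  tab <- tapply(ambiguous, gene[keep], mean)
  cnt <- table(gene[keep])
  data.frame(gene_id = names(tab), n_reads = as.integer(cnt[names(tab)]),
             ambiguity_rate = as.numeric(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare external transcript-abundance estimates against unique-base truth
#'
#' Correlates one or two external estimate tables (e.g. FPKM from an
#' inference-based estimator) with internally measured unique-base
#' abundances, over transcripts of genes whose ambiguity rate is below each
#' threshold in a sweep. With two estimators, the difference between their
#' rank correlations on the full eligible set is assessed by a seeded
#' bootstrap over genes.
#'
#' @param external named list of 1 or 2 data.frames (`transcript_id`,
#'   `value`).
#' @param internal a [transcript_abundance()] result.
#' @param ambiguity an [ambiguity_rate()] result.
#' @param thresholds ambiguity thresholds to sweep (default 0.1..1).
#' @param n_boot bootstrap resamples for the correlation-difference test.
#' @param seed seed for the bootstrap.
#' @return list: `curve` (data.frame `threshold`, `estimator`, `n_transcripts`,
#'   `rho`) and, with two estimators, `difference` (`delta_rho`, `p_value`).
#' @export
compare_abundance_estimates <- function(external, internal, ambiguity,
                                        thresholds = seq(0.1, 1, by = 0.1),
                                        n_boot = 10000L, seed = 1L) {
  stopifnot(is.list(external), length(external) %in% c(1L, 2L))
  if (is.null(names(external))) {
    names(external) <- paste0("estimator", seq_along(external))
  }
  rho_at <- function(est, thr) {
    ok_genes <- ambiguity$gene_id[ambiguity$ambiguity_rate < thr]
    d <- internal[internal$gene_id %in% ok_genes, , drop = FALSE]
    m <- merge(d, est, by = "transcript_id")
    if (nrow(m) < 3) return(c(n = nrow(m), rho = NA_real_))
    c(n = nrow(m),
      rho = stats::cor(m$abundance, m$value, method = "spearman"))
  }
  curve <- do.call(rbind, lapply(names(external), function(nm) {
    do.call(rbind, lapply(thresholds, function(t) {
      r <- rho_at(external[[nm]], t)
      data.frame(threshold = t, estimator = nm, n_transcripts = r["n"],
                 rho = r["rho"], row.names = NULL)
    }))
  }))
  out <- list(curve = curve)
  if (length(external) == 2) {
    m <- merge(merge(internal, external[[1]], by = "transcript_id"),
               external[[2]], by = "transcript_id",
               suffixes = c("_1", "_2"))
    genes <- unique(m$gene_id)
    if (length(genes) >= 3) {
      set.seed(seed %% .Machine$integer.max)
      by_gene <- split(seq_len(nrow(m)), m$gene_id)
      delta <- stats::cor(m$abundance, m$value_1, method = "spearman") -
        stats::cor(m$abundance, m$value_2, method = "spearman")
      boot <- replicate(n_boot, {
        rows <- unlist(by_gene[sample(length(by_gene), replace = TRUE)],
                       use.names = FALSE)
        suppressWarnings(
          stats::cor(m$abundance[rows], m$value_1[rows], method = "spearman") -
            stats::cor(m$abundance[rows], m$value_2[rows], method = "spearman"))
      })
      boot <- boot[is.finite(boot)]
      p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
      out$difference <- list(delta_rho = delta, p_value = min(1, p),
                             n_boot = length(boot))
    }
  }
  out
}
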