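SITES2 <- structure(
  data.frame(chrom = "chr1", pos = c(50L, 150L), ref = c("A", "C"),
             alt = c("G", "T"), maternal = c("A", "T"),
             paternal = c("G", "C"), stringsAsFactors = FALSE),
  class = c("phased_sites", "data.frame"))

hap_frag <- function(id, b50 = NULL, b150 = NULL, span = blk(1, 200)) {
  calls <- strrep("C", 200)
  if (!is.null(b50)) substr(calls, 50, 50) <- b50
  if (!is.null(b150)) substr(calls, 150, 150) <- b150
  frag(id, span, substr(calls, span[1, 1], span[1, 2]))
}

test_that("haplotype assignment requires all covered sites to agree", {
  expect_identical(assign_haplotype(hap_frag("a", "A", "T"), SITES2),
                   "maternal")
  expect_identical(assign_haplotype(hap_frag("b", "G", "C"), SITES2),
                   "paternal")
  # one maternal + one paternal allele -> conflicting
  expect_identical(assign_haplotype(hap_frag("c", "A", "C"), SITES2),
                   "conflicting")
  # non-allelic base at a het site -> conflicting
  expect_identical(assign_haplotype(hap_frag("d", "T", "T"), SITES2),
                   "conflicting")
  # single covered site suffices
  expect_identical(assign_haplotype(hap_frag("e", "A", span = blk(1, 100)),
                                    SITES2), "maternal")
  # no het site covered
  expect_identical(assign_haplotype(frag("f", blk(60, 140), strrep("C", 81)),
                                    SITES2), "no_site")
})

test_that("assignable fraction follows the Poisson model and grows with length", {
  lambda <- 1e-3
  w <- sim_world(seed = 61, n_genes = 30, genome_length = 2e5,
                 het_density = lambda, n_fragments = 4000,
                 isoforms_per_gene = c(1L, 1L),
                 fragment_length = list(mean = 260, sd = 120, min = 30))
  lib <- simulate_library(w$genome, w$ann, w$sites, w$cfg)
  out <- assignable_fraction(lib$fragments, w$sites,
                             length_breaks = c(0, 150, 300, 450, Inf))
  expect_true(all(diff(out$assignable_fraction) > 0))
  # error-free reads: assigned exactly when the fragment covers a het site
  all_out <- assignable_fraction(lib$fragments, w$sites)
  calls <- longrna:::fragment_calls_at(lib$fragments, w$sites$pos)
  covers <- seq_along(lib$fragments) %in% calls$idx
  expect_equal(all_out$assignable_fraction, mean(covers))
  # no het sites -> nothing assignable
  expect_equal(assignable_fraction(lib$fragments,
                                   SITES2[0, ])$assignable_fraction, 0)
})

test_that("Poisson model recovers the generating rate and inverts exactly", {
  set.seed(62)
  lambda <- 1e-3
  L <- sample(100:500, 10000, replace = TRUE)
  y <- stats::runif(10000) < -expm1(-lambda * L)
  fit <- fit_poisson_model(L, y)
  expect_false(fit$boundary)
  expect_lt(abs(fit$lambda - lambda) / lambda, 0.1)
  expect_equal(fit$predict(0), 0)
  # closed-form inversion: p(1000) = 0.25 <=> lambda = -log(0.75)/1000
  lam25 <- -log(0.75) / 1000
  y2 <- stats::runif(10000) < -expm1(-lam25 * L)
  fit2 <- fit_poisson_model(L, y2)
  expect_lt(abs(fit2$predict(1000) - 0.25), 0.05)
  # boundary cases flagged
  expect_true(fit_poisson_model(L, rep(TRUE, length(L)))$boundary)
  expect_true(fit_poisson_model(L, rep(FALSE, length(L)))$boundary)
  expect_error(fit_poisson_model(1:10, rep(TRUE, 10)), "100")
})

test_that("ASE binomial test matches closed forms and the count filter", {
  expect_equal(ase_test(10, 10), 1.0)
  expect_equal(ase_test(20, 0), 2 * 0.5^20)
  expect_equal(ase_test(15, 5), 0.041389, tolerance = 1e-4)
  # independent doubled-tail oracle
  expect_equal(ase_test(15, 5), 2 * sum(dbinom(15:20, 20, 0.5)))
  expect_true(is.na(ase_test(10, 9)))   # total 19 < 20
  expect_true(is.na(ase_test(0, 0)))
  expect_equal(ase_test(c(10, 15), c(10, 5)), c(1.0, 2 * pbinom(5, 20, 0.5)))
})

test_that("per-locus ASE test controls its Type-I rate on balanced sites", {
  expect_equal(per_locus_ase_test(
    data.frame(pos = 1L, n_maternal = 5L, n_paternal = 5L))$p_value, 1.0)
  expect_equal(per_locus_ase_test(
    data.frame(pos = 1L, n_maternal = 12L, n_paternal = 0L))$p_value,
    2 * 0.5^12)
  set.seed(63)
  n <- 2000
  m <- stats::rbinom(n, 40, 0.5)
  out <- per_locus_ase_test(data.frame(pos = seq_len(n), n_maternal = m,
                                       n_paternal = 40L - m))
  frac <- mean(out$p_value < 0.05)
  # discrete test is conservative: super-uniform null
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("exon blocks are the boundary-induced partition of the exonic union", {
  one <- mk_annotation(list(G = list(T1 = blk(100, 199, 300, 399))))
  b <- exon_blocks("G", one)
  expect_equal(b$start, c(100, 300))
  expect_equal(b$end, c(199, 399))

  two <- mk_annotation(list(G = list(T1 = blk(100, 199),
                                     T2 = blk(150, 199))))
  b <- exon_blocks("G", two)
  expect_equal(b$start, c(100, 150))
  expect_equal(b$end, c(149, 199))

  # property: no block contains an internal exon boundary of any isoform
  w <- sim_world(seed = 64, n_genes = 8, isoforms_per_gene = c(2L, 3L))
  for (g in w$ann$genes$gene_id) {
    b <- exon_blocks(g, w$ann)
    expect_true(all(b$start <= b$end))
    expect_true(all(b$start[-1] > utils::head(b$end, -1)))  # disjoint, sorted
    ex <- w$ann$exons[w$ann$exons$transcript_id %in% transcripts_of(w$ann, g), ]
    for (i in seq_len(nrow(ex))) {
      inside_start <- b$start < ex$start[i] & ex$start[i] <= b$end
      inside_end <- b$start <= ex$end[i] & ex$end[i] < b$end
      expect_false(any(inside_start | inside_end))
    }
    # blocks cover exactly the exonic union
    expect_equal(sum(b$end - b$start + 1),
                     sum(IRanges::width(IRanges::reduce(
                       IRanges::IRanges(ex$start, ex$end)))))
  }
})

test_that("ASAS chi-square matches the closed form and its guards", {
  mk_hap_frags <- function(n_m_ov, n_m_no, n_p_ov, n_p_no) {
    # block = [100, 200]; overlap fragments cover it, others sit at 300+
    f <- list(); hap <- character(0); i <- 0
    add <- function(n, ov, h) {
      for (k in seq_len(n)) {
        i <<- i + 1
        f[[i]] <<- frag(paste0("f", i),
                        if (ov) blk(120, 180) else blk(300, 360),
                        random_dna(61))
        hap <<- c(hap, h)
      }
    }
    add(n_m_ov, TRUE, "maternal"); add(n_m_no, FALSE, "maternal")
    add(n_p_ov, TRUE, "paternal"); add(n_p_no, FALSE, "paternal")
    list(frags = fragment_set(f), hap = hap)
  }
  block <- list(start = 100, end = 200)

  x <- mk_hap_frags(10, 10, 10, 10)
  r <- asas_test(block, x$frags, x$hap, min_total = 40)
  expect_equal(r$chisq, 0)
  expect_equal(r$p_value, 1)

  x <- mk_hap_frags(30, 10, 10, 30)
  r <- asas_test(block, x$frags, x$hap, min_total = 40)
  expect_equal(r$chisq, 20)
  expect_equal(r$p_value, 7.744e-6, tolerance = 1e-3)
  expect_identical(unname(r$table), c(30L, 10L, 10L, 30L))
  # agreement with the standard uncorrected chi-square test
  ref <- stats::chisq.test(matrix(c(30, 10, 10, 30), 2), correct = FALSE)
  expect_equal(r$p_value, ref$p.value)

  # below the gene count floor
  x <- mk_hap_frags(10, 5, 5, 10)
  expect_identical(asas_test(block, x$frags, x$hap, min_total = 40)$status,
                   "too_few")
  # zero margin
  x <- mk_hap_frags(20, 0, 20, 0)
  expect_identical(asas_test(block, x$frags, x$hap, min_total = 40)$status,
                   "zero_margin")
})

test_that("BH step-up matches the direct definition and p.adjust", {
  expect_identical(bh_fdr(c(0.001, 0.01, 0.2, 0.9), q = 0.1),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), q = 0.1), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0, 5), q = 0.1), rep(TRUE, 5))
  expect_identical(bh_fdr(numeric(0)), logical(0))

  # direct step-up definition, written independently
  direct_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
    sig <- logical(m)
    if (k > 0) sig[o[1:k]] <- TRUE
    sig
  }
  set.seed(65)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), direct_bh(p, q))
    # cross-check against stats::p.adjust
    expect_identical(bh_fdr(p, q), stats::p.adjust(p, "BH") <= q)
  }
})

test_that("allele_flip is a locality-preserving involution", {
  f <- hap_frag("a", "A", "T")
  flipped <- allele_flip(f, SITES2)
  expect_identical(substr(flipped$mates[[1]]$calls, 50, 50), "G")
  expect_identical(substr(flipped$mates[[1]]$calls, 150, 150), "C")
  # all other positions untouched
  keep <- setdiff(1:200, c(50, 150))
  expect_identical(strsplit(flipped$mates[[1]]$calls, "")[[1]][keep],
                   strsplit(f$mates[[1]]$calls, "")[[1]][keep])
  # involution
  back <- allele_flip(flipped, SITES2)
  expect_identical(back$mates[[1]]$calls, f$mates[[1]]$calls)
  # non-allelic base needs the haplotype and is flagged
  g <- hap_frag("b", "T", "T")
  expect_error(allele_flip(g, SITES2), "non-allelic")
  gf <- allele_flip(g, SITES2, haplotype = "maternal")
  expect_identical(attr(gf, "n_flagged"), 1L)
  expect_identical(substr(gf$mates[[1]]$calls, 50, 50), "G")  # opposite allele
})

test_that("retention rate is 1 on unique loci and drops at het-divergent duplicates", {
  # unique locus: error-free reads flip and map straight back
  w <- sim_world(seed = 66, n_genes = 4, genome_length = 15000,
                 het_density = 2e-3, error_rate = 0, n_fragments = 60,
                 isoforms_per_gene = c(1L, 1L))
  lib <- simulate_library(w$genome, w$ann, w$sites, w$cfg)
  hap <- assign_haplotypes(lib$fragments, w$sites)
  aligner <- make_toy_aligner(w$genome, w$ann, max_mismatch = 4L)
  r <- retention_rate(lib$fragments, hap, w$sites, aligner)
  expect_gt(r$n_flipped, 5)
  expect_equal(r$rate, 1.0)
  expect_true(r$testable)

  # genome with two copies differing only at the het site: the flipped read
  # matches the duplicate exactly and multimaps or migrates
  set.seed(66)
  locus <- random_dna(400)
  copy <- locus
  substr(copy, 200, 200) <- "G"  # duplicate carries the alt allele
  stopifnot(substr(locus, 200, 200) != "G")
  genome <- Biostrings::DNAStringSet(paste0(
    random_dna(100), locus, random_dna(100), copy, random_dna(100)))
  names(genome) <- "chr1"
  sites <- structure(data.frame(
    chrom = "chr1", pos = 300L, ref = substr(locus, 200, 200), alt = "G",
    maternal = substr(locus, 200, 200), paternal = "G",
    stringsAsFactors = FALSE), class = c("phased_sites", "data.frame"))
  # maternal read over the het site at pos 300 (locus copy 1)
  reads <- fragment_set(lapply(1:5, function(i) {
    s <- 300L - 60L + i * 10L
    frag(paste0("r", i), blk(s, s + 99L),
         substr(paste0(random_dna(0), as.character(genome[[1]])),
                s, s + 99L))
  }))
  hap2 <- assign_haplotypes(reads, sites)
  expect_true(all(hap2 == "maternal"))
  al2 <- make_toy_aligner(genome, NULL, max_mismatch = 1L)
  r2 <- retention_rate(reads, hap2, sites, al2)
  expect_lt(r2$rate, 1)
  expect_false(r2$testable)

  # no flippable reads
  r3 <- retention_rate(reads, rep("no_site", 5), sites, al2)
  expect_true(is.na(r3$rate))
  expect_false(r3$testable)
})

test_that("exclusion filters remove HLA names, low counts and low retention", {
  gs <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4", "G5"),
    gene_name = c("HLA-A", "ACTB", "GAPDH", "TP53", "MYC"),
    n_assigned = c(100L, 19L, 39L, 100L, 100L),
    retention_rate = c(1, 1, 1, 0.85, 0.95))
  ase <- exclusion_filters(gs, min_reads = 20L)
  expect_identical(ase$reason,
                   c("hla_name", "too_few_reads", NA, "low_retention", NA))
  asas <- exclusion_filters(gs, min_reads = 40L)
  # 39 assigned reads: excluded for ASAS though fine for ASE
  expect_identical(asas$reason[3], "too_few_reads")
  expect_true(ase$testable[3])
})

test_that("hypergeometric enrichment matches exact enumeration", {
  expect_equal(enrichment_test(0, 5, 4, 10), 1.0)
  expect_equal(enrichment_test(4, 5, 4, 10), choose(5, 4) / choose(10, 4))
  expect_equal(enrichment_test(4, 5, 4, 10), 0.02381, tolerance = 1e-4)
  # around the expectation the upper tail sits near 0.5
  # (N=100, K=20, n=25 -> E[X]=5)
  p <- enrichment_test(5, 20, 25, 100)
  expect_gt(p, 0.3); expect_lt(p, 0.8)
  # exact enumeration oracle
  enum <- sum(vapply(5:20, function(k)
    choose(20, k) * choose(80, 25 - k), 1)) / choose(100, 25)
  expect_equal(p, enum)
  expect_error(enrichment_test(6, 5, 4, 10), "inconsistent")
})

test_that("planted allelic imbalance is detected and balanced genes are not", {
  w <- sim_world(seed = 67, n_genes = 12, genome_length = 60000,
                 het_density = 3e-3, error_rate = 0, n_fragments = 1500,
                 allelic_ratio = c(G001 = 0.8, G002 = 0.8),
                 isoforms_per_gene = c(1L, 1L))
  lib <- simulate_library(w$genome, w$ann, w$sites, w$cfg)
  gi <- build_base_index(w$ann, "gene")
  a <- assign_fragments(lib$fragments, gi)
  res <- ase_scan(lib$fragments, ifelse(a$unambiguous, a$feature, NA),
                  w$sites)
  planted <- res[res$gene_id %in% c("G001", "G002"), ]
  expect_true(all(planted$significant[!is.na(planted$p_value)]))
  # maternal fraction estimate near truth
  for (i in which(!is.na(planted$p_value))) {
    n <- planted$n_maternal[i] + planted$n_paternal[i]
    expect_lt(abs(planted$maternal_fraction[i] - 0.8),
              3 * sqrt(0.8 * 0.2 / n))
  }
})

test_that("planted haplotype-specific exon skipping is found at the right block", {
  # gene with an inclusion (t1) and a skipping (t2) isoform; maternal
  # fragments use t1, paternal use t2
  w <- sim_world(seed = 68, n_genes = 6, genome_length = 40000,
                 het_density = 4e-3, error_rate = 0, n_fragments = 1200,
                 isoforms_per_gene = c(2L, 2L),
                 fragment_length = list(mean = 220, sd = 60, min = 40))
  # pick a gene whose second isoform skips an exon
  gid <- NULL
  for (g in w$ann$genes$gene_id[w$ann$genes$biotype == "protein_coding"]) {
    tids <- transcripts_of(w$ann, g)
    if (length(tids) != 2) next
    e1 <- w$ann$exons[w$ann$exons$transcript_id == tids[1], ]
    e2 <- w$ann$exons[w$ann$exons$transcript_id == tids[2], ]
    if (nrow(e1) == nrow(e2) + 1) { gid <- g; break }
  }
  expect_false(is.null(gid))
  usage <- list(matrix(c(0.95, 0.05, 0.05, 0.95), nrow = 2, byrow = TRUE))
  names(usage) <- gid
  cfg <- w$cfg; cfg$isoform_usage <- usage
  lib <- simulate_library(w$genome, w$ann, w$sites, cfg)
  gi <- build_base_index(w$ann, "gene")
  a <- assign_fragments(lib$fragments, gi)
  res <- asas_scan(lib$fragments, ifelse(a$unambiguous, a$feature, NA),
                   w$sites, w$ann, min_total = 40)
  expect_gt(nrow(res), 0)
  # the skipped exon of the planted gene
  tids <- transcripts_of(w$ann, gid)
  e1 <- w$ann$exons[w$ann$exons$transcript_id == tids[1], ]
  e2 <- w$ann$exons[w$ann$exons$transcript_id == tids[2], ]
  skipped <- e1[!(e1$start %in% e2$start & e1$end %in% e2$end), ]
  hit <- res[res$gene_id == gid & res$start == skipped$start[1], ]
  expect_identical(nrow(hit), 1L)
  expect_true(hit$significant)
  # other genes stay quiet at the nominal rate
  null_blocks <- res[res$gene_id != gid, ]
  if (nrow(null_blocks) > 0) {
    expect_lte(mean(null_blocks$p_value < 0.05),
               0.05 + 3 * sqrt(0.05 * 0.95 / nrow(null_blocks)) + 0.05)
  }
})
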