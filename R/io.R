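#' Write a genome to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write / read a paired FASTQ library
#'
#' Mates go to `<prefix>_1.fastq` and `<prefix>_2.fastq` with `/1` / `/2`
#' name suffixes.
#'
#' @param library a `read_library` data.frame.
#' @param prefix output path prefix.
#' @return (invisibly) the two file paths.
#' @export
write_fastq_pair <- function(library, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    lines <- as.vector(rbind(
      paste0("@", library$id, "/", k),
      library[[paste0("seq", k)]],
      "+",
      library[[paste0("qual", k)]]))
    writeLines(lines, paths[k])
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @param path1,path2 mate FASTQ files.
#' @return for `read_fastq_pair()`, a `read_library` data.frame.
#' @export
read_fastq_pair <- function(path1, path2) {
  parse_one <- function(p) {
    x <- readLines(p)
    stopifnot(length(x) %% 4 == 0)
    i <- seq(1, length(x), by = 4)
    data.frame(id = sub("/[12]$", "", sub("^@", "", x[i])),
               seq = x[i + 1], qual = x[i + 3], stringsAsFactors = FALSE)
  }
  a <- parse_one(path1)
  b <- parse_one(path2)
  stopifnot(identical(a$id, b$id))
  out <- data.frame(id = a$id, seq1 = a$seq, qual1 = a$qual,
                    seq2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
  class(out) <- c("read_library", "data.frame")
  attr(out, "read_length") <- nchar(out$seq1[1])
  out
}

#' Write / read annotation as GTF
#'
#' Emits gene, transcript and exon rows with `gene_id`, `transcript_id`,
#' `gene_type` and `gene_name` attributes; 1-based inclusive coordinates.
#'
#' @param annotation a [tx_annotation()].
#' @param path output file.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  attr_of <- function(gid, tid = NULL) {
    gi <- match(gid, g$gene_id)
    a <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                 gid, g$biotype[gi], g$gene_name[gi])
    if (!is.null(tid)) a <- sprintf('%s transcript_id "%s";', a, tid)
    a
  }
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], "sim", "gene", g$start[i], g$end[i],
                            ".", g$strand[i], ".", attr_of(g$gene_id[i]),
                            sep = "\t"))
    for (tid in transcripts_of(annotation, g$gene_id[i])) {
      ex <- exons_of(annotation, tid)
      lines <- c(lines,
                 paste(g$chrom[i], "sim", "transcript", min(ex$start),
                       max(ex$end), ".", g$strand[i], ".",
                       attr_of(g$gene_id[i], tid), sep = "\t"),
                 paste(ex$chrom, "sim", "exon", ex$start, ex$end, ".",
                       g$strand[i], ".", attr_of(g$gene_id[i], tid),
                       sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gtf
#' @return for `read_gtf()`, a [tx_annotation()].
#' @export
read_gtf <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "#")]
  f <- strsplit(x, "\t", fixed = TRUE)
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]*)"'), a))
    vapply(m, function(v) if (length(v) == 2) v[2] else NA_character_, "")
  }
  typ <- vapply(f, `[[`, "", 3)
  att <- vapply(f, `[[`, "", 9)
  gid <- attr1(att, "gene_id")
  tid <- attr1(att, "transcript_id")
  gi <- typ == "gene"
  genes <- data.frame(
    gene_id = gid[gi],
    gene_name = attr1(att[gi], "gene_name"),
    biotype = attr1(att[gi], "gene_type"),
    chrom = vapply(f[gi], `[[`, "", 1),
    strand = vapply(f[gi], `[[`, "", 7),
    start = as.integer(vapply(f[gi], `[[`, "", 4)),
    end = as.integer(vapply(f[gi], `[[`, "", 5)),
    stringsAsFactors = FALSE)
  ti <- typ == "transcript"
  transcripts <- data.frame(transcript_id = tid[ti], gene_id = gid[ti],
                            stringsAsFactors = FALSE)
  ei <- typ == "exon"
  exons <- data.frame(
    transcript_id = tid[ei],
    chrom = vapply(f[ei], `[[`, "", 1),
    start = as.integer(vapply(f[ei], `[[`, "", 4)),
    end = as.integer(vapply(f[ei], `[[`, "", 5)),
    stringsAsFactors = FALSE)
  tx_annotation(genes, transcripts, exons)
}

#' Write / read phased sites as VCF
#'
#' The GT field is phased maternal|paternal: allele code 0 is the reference
#' base, 1 the alternate, and the left-hand code is the maternal allele.
#'
#' @param sites a [generate_diplotype()] result.
#' @param path output file.
#' @export
write_vcf <- function(sites, path) {
  gt <- paste0(ifelse(sites$maternal == sites$ref, "0", "1"), "|",
               ifelse(sites$paternal == sites$ref, "0", "1"))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sample1", sep = "\t"),
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
          ".", "GT", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf
#' @return for `read_phased_vcf()`, a `phased_sites` data.frame; unphased
#'   genotypes, indels and multi-allelic records are dropped, with counts in
#'   attribute `"dropped"`.
#' @export
read_phased_vcf <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "#")]
  f <- strsplit(x, "\t", fixed = TRUE)
  chrom <- vapply(f, `[[`, "", 1)
  pos <- as.integer(vapply(f, `[[`, "", 2))
  ref <- vapply(f, `[[`, "", 4)
  alt <- vapply(f, `[[`, "", 5)
  gt <- sub(":.*$", "", vapply(f, `[[`, "", 10))
  indel <- nchar(ref) > 1 | (nchar(alt) > 1 & !grepl(",", alt))
  multi <- grepl(",", alt)
  unphased <- !grepl("^[01]\\|[01]$", gt)
  keep <- !indel & !multi & !unphased
  m_code <- substr(gt[keep], 1, 1)
  p_code <- substr(gt[keep], 3, 3)
  out <- data.frame(
    chrom = chrom[keep], pos = pos[keep], ref = ref[keep], alt = alt[keep],
    maternal = ifelse(m_code == "0", ref[keep], alt[keep]),
    paternal = ifelse(p_code == "0", ref[keep], alt[keep]),
    stringsAsFactors = FALSE)
  class(out) <- c("phased_sites", "data.frame")
  attr(out, "dropped") <- c(indel = sum(indel), multi_allelic = sum(multi),
                            unphased = sum(unphased & !indel & !multi))
  out
}

#' Write / read aligned fragments as SAM
#'
#' One line per mate; junctions are encoded as `N` CIGAR operations, and
#' `SEQ` is stored in reference-forward orientation as SAM requires.
#'
#' @param fragments a [fragment_set()].
#' @param genome the reference [Biostrings::DNAStringSet] (for `@SQ`
#'   headers).
#' @param path output file.
#' @export
write_sam <- function(fragments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)))
  lines <- unlist(lapply(fragments, function(f) {
    paired <- length(f$mates) == 2
    vapply(seq_along(f$mates), function(j) {
      m <- f$mates[[j]]
      fwd <- if (j == 1) f$strand == "+" else f$strand == "-"
      flag <- 0L
      if (paired) {
        flag <- flag + 1L + 2L + (if (j == 1) 64L else 128L)
        mate_fwd <- !fwd
        if (!mate_fwd) flag <- flag + 32L
      }
      if (!fwd) flag <- flag + 16L
      w <- m$blocks[, 2] - m$blocks[, 1] + 1L
      cig <- paste0(w, "M")
      if (length(w) > 1) {
        gaps <- m$blocks[-1, 1] - m$blocks[-nrow(m$blocks), 2] - 1L
        cig <- c(rbind(utils::head(cig, -1), paste0(gaps, "N")), cig[length(cig)])
      }
      other <- if (paired) f$mates[[if (j == 1) 2 else 1]] else NULL
      paste(f$id, flag, f$chrom, m$blocks[1, 1], 60,
            paste(cig, collapse = ""),
            if (paired) "=" else "*",
            if (paired) other$blocks[1, 1] else 0,
            0, m$calls, m$quals, sep = "\t")
    }, "")
  }))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_sam
#' @return for `read_sam()`, a [fragment_set()] (mates paired by name;
#'   only `M`, `=`, `X` and `N` CIGAR operations are supported).
#' @export
read_sam <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "@")]
  f <- strsplit(x, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  recs <- lapply(seq_along(f), function(i) {
    pos <- as.integer(f[[i]][4])
    cig <- f[[i]][6]
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    if (any(!op %in% c("M", "=", "X", "N"))) {
      stop("unsupported CIGAR op in: ", cig)
    }
    starts <- ends <- integer(0)
    at <- pos
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X")) {
        starts <- c(starts, at); ends <- c(ends, at + len[k] - 1L)
      }
      at <- at + len[k]
    }
    # collapse adjacent matched stretches (e.g. 10M5N20M keeps two blocks)
    list(chrom = f[[i]][3],
         blocks = cbind(start = starts, end = ends),
         calls = f[[i]][10], quals = f[[i]][11],
         mate1 = bitwAnd(flag[i], 64L) > 0 || bitwAnd(flag[i], 1L) == 0,
         rev = bitwAnd(flag[i], 16L) > 0)
  })
  frags <- lapply(split(seq_along(recs), qname), function(ii) {
    ii <- ii[order(!vapply(recs[ii], `[[`, TRUE, "mate1"))]
    r1 <- recs[[ii[1]]]
    strand <- if (r1$rev) "-" else "+"
    mates <- lapply(recs[ii], function(r)
      list(blocks = r$blocks, calls = r$calls, quals = r$quals))
    aligned_fragment(qname[ii[1]], r1$chrom, strand, mates)
  })
  fragment_set(unname(frags[unique(qname)]))
}
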