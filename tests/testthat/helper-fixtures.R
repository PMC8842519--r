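# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; nothing is read from stored binary data.

# ---- toy annotation --------------------------------------------------------

# A small two-gene annotation: GA (+, chr1) with two isoforms, GB (-, chr1)
# with one isoform; 7 exons, 3 transcripts in total.
toy_gtf_lines <- function() {
  a <- 'gene_id "GA"; gene_name "ALPHA";'
  at1 <- 'gene_id "GA"; transcript_id "GA.t1"; gene_name "ALPHA";'
  at2 <- 'gene_id "GA"; transcript_id "GA.t2"; gene_name "ALPHA";'
  b <- 'gene_id "GB"; gene_name "BETA";'
  bt1 <- 'gene_id "GB"; transcript_id "GB.t1"; gene_name "BETA";'
  c(
    sprintf("chr1\ttest\tgene\t101\t1000\t.\t+\t.\t%s", a),
    sprintf("chr1\ttest\ttranscript\t101\t1000\t.\t+\t.\t%s", at1),
    sprintf("chr1\ttest\texon\t101\t200\t.\t+\t.\t%s", at1),
    sprintf("chr1\ttest\texon\t401\t500\t.\t+\t.\t%s", at1),
    sprintf("chr1\ttest\texon\t901\t1000\t.\t+\t.\t%s", at1),
    sprintf("chr1\ttest\ttranscript\t101\t500\t.\t+\t.\t%s", at2),
    sprintf("chr1\ttest\texon\t101\t200\t.\t+\t.\t%s", at2),
    sprintf("chr1\ttest\texon\t401\t500\t.\t+\t.\t%s", at2),
    sprintf("chr1\ttest\tgene\t2001\t3000\t.\t-\t.\t%s", b),
    sprintf("chr1\ttest\ttranscript\t2001\t3000\t.\t-\t.\t%s", bt1),
    sprintf("chr1\ttest\texon\t2001\t2100\t.\t-\t.\t%s", bt1),
    sprintf("chr1\ttest\texon\t2901\t3000\t.\t-\t.\t%s", bt1))
}

toy_annotation <- function() {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(toy_gtf_lines(), path)
  read_annotation(path)
}

# Build a fusion_annotation directly from exon specs:
# exons = tibble(gene_id, transcript_id, chrom, strand, start, end)
make_db <- function(exons) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  read_annotation(path)
}

# segment tibble row builder
seg <- function(read_id, rs, re, chrom = "chr1", gs, ge, dir = 1L) {
  tibble::tibble(read_id = read_id, read_length = NA_integer_,
                 read_start = as.integer(rs), read_end = as.integer(re),
                 direction = as.integer(dir), target_name = chrom,
                 genome_start = as.integer(gs), genome_end = as.integer(ge),
                 mapq = 60L)
}

# per-read classification row (shape of classify_reads() output after
# filtering)
read_row <- function(read, class, gene = NA, head = NA, tail = NA,
                     rt = FALSE) {
  tibble::tibble(read_id = read, class = class, n_genes = NA_integer_,
                 gene_id = gene, head_gene = head, tail_gene = tail,
                 score = 1, rt_junction = rt, filter_reason = NA_character_)
}

# ---- independent chaining oracle -------------------------------------------

# Exhaustive-enumeration oracle for the chaining score: tries every subset
# of match indices, orders it by read start, checks the parent relation
# between consecutive members, and scores it. Independent of the package's
# DP implementation.
oracle_parent_ok <- function(m, p, c) {
  before <- m$read_end[p] <= m$read_start[c]
  if (!before) return(FALSE)
  if (m$direction[p] != m$direction[c]) return(TRUE)
  if (m$target_name[p] != m$target_name[c]) return(TRUE)
  m$direction[c] * (m$genome_end[c] - m$genome_start[p]) > 0
}

oracle_penalty <- function(m, c, p) {
  if (m$transcript_id[c] == m$transcript_id[p]) 1
  else if (m$gene_id[c] == m$gene_id[p]) 0.9
  else 0.5
}

oracle_chain_score <- function(m) {
  n <- nrow(m)
  w <- pmax(0, (pmin(m$genome_end, m$exon_end) -
                  pmax(m$genome_start, m$exon_start)) /
              pmax(m$genome_end - m$genome_start,
                   m$exon_end - m$exon_start)) *
    (m$genome_end - m$genome_start)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    idx <- idx[order(m$read_start[idx], m$genome_start[idx])]
    ok <- TRUE
    score <- w[idx[1]]
    if (length(idx) > 1L) {
      for (j in 2:length(idx)) {
        if (!oracle_parent_ok(m, idx[j - 1L], idx[j])) { ok <- FALSE; break }
        score <- score + w[idx[j]] * oracle_penalty(m, idx[j], idx[j - 1L])
      }
    }
    if (ok && score > best) best <- score
  }
  best
}

# random chaining instance: a handful of non-overlapping read segments, each
# annotated by 1-3 exons
random_chain_instance <- function(max_entries = 8L) {
  n_seg <- sample.int(4L, 1L)
  rs <- integer(n_seg); re <- integer(n_seg)
  pos <- 0L
  for (i in seq_len(n_seg)) {
    rs[i] <- pos
    re[i] <- pos + sample(40:120, 1L)
    pos <- re[i] + sample(0:30, 1L)  # 0 gap: adjacent segments allowed
  }
  rows <- list()
  for (i in seq_len(n_seg)) {
    chrom <- sample(c("chr1", "chr2"), 1L)
    dir <- sample(c(1L, -1L), 1L)
    gs <- sample.int(5000L, 1L)
    ge <- gs + (re[i] - rs[i])
    for (k in seq_len(sample.int(3L, 1L))) {
      es <- gs + sample(-80:80, 1L)
      ee <- es + sample(40:160, 1L)
      if (ee <= gs || es >= ge) next  # exon must overlap the segment
      rows[[length(rows) + 1L]] <- tibble::tibble(
        read_id = "r1", read_start = rs[i], read_end = re[i],
        direction = dir, target_name = chrom,
        genome_start = gs, genome_end = ge,
        exon_start = es, exon_end = ee,
        gene_id = sample(c("gA", "gB", "gC"), 1L),
        transcript_id = sample(c("t1", "t2", "t3", "t4"), 1L),
        exon_rank = 1L, n_exons = 3L)
    }
  }
  m <- dplyr::bind_rows(rows)
  if (nrow(m) > max_entries) m <- m[seq_len(max_entries), ]
  m
}

# ---- independent Fisher-tail oracle ----------------------------------------

# Brute-force hypergeometric upper tail: population 2n with K successes,
# n draws, P(X >= x0), summed term by term from exact log-binomials.
oracle_hyper_tail <- function(x0, K, n) {
  xs <- max(0L, x0):min(n, K)
  if (length(xs) == 0L || x0 > min(n, K)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(2 * n - K, n - xs) - lchoose(2 * n, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
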