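test_that("reciprocal overlap divides by the larger interval", {
  expect_equal(reciprocal_overlap(0, 100, 0, 100), 1.0)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0.0)  # disjoint, clamped
  expect_equal(reciprocal_overlap(0, 100, 50, 250), 0.25)  # 50 / 200
  expect_equal(reciprocal_overlap(0, 0, 0, 0), 0)          # degenerate
})

test_that("switch penalty orders isoform and gene switches", {
  expect_equal(switch_penalty("gA", "t1", "gA", "t1"), 1)
  expect_equal(switch_penalty("gA", "t1", "gA", "t2"), 0.9)
  expect_equal(switch_penalty("gA", "t1", "gB", "t3"), 0.5)
})

test_that("parent relation follows read order and mapping direction", {
  ip <- longfuse:::is_parent
  # colinear forward: p read before c, p genome before c
  expect_true(ip(100L, 1L, "chr1", 1000L, 150L, 1L, "chr1", 2000L))
  # c genome entirely before p genome, both forward: sign test fails
  expect_false(ip(100L, 1L, "chr1", 5000L, 150L, 1L, "chr1", 2000L))
  # opposite directions: no genomic-order restriction (inversion case)
  expect_true(ip(100L, 1L, "chr1", 5000L, 150L, -1L, "chr1", 2000L))
  # different chromosomes, same direction: allowed (translocation case)
  expect_true(ip(100L, 1L, "chr1", 5000L, 150L, 1L, "chr2", 2000L))
  # adjacent half-open read intervals do not overlap: parent allowed
  expect_true(ip(100L, 1L, "chr1", 1000L, 100L, 1L, "chr1", 2000L))
  # overlapping read intervals: not a parent
  expect_false(ip(100L, 1L, "chr1", 1000L, 99L, 1L, "chr1", 2000L))
  # reverse mapping advances toward lower coordinates
  expect_true(ip(100L, -1L, "chr1", 2000L, 150L, -1L, "chr1", 1500L))
  expect_false(ip(100L, -1L, "chr1", 1500L, 150L, -1L, "chr1", 2000L))
})

test_that("singleton base case scores overlap times genome length", {
  m <- tibble::tibble(
    read_id = "r1", read_start = 0L, read_end = 100L, direction = 1L,
    target_name = "chr1", genome_start = 0L, genome_end = 100L,
    exon_start = 0L, exon_end = 80L, gene_id = "gA", transcript_id = "t1",
    exon_rank = 1L, n_exons = 1L)
  ch <- chain_exons(m)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$score, 0.8 * 100)
})

test_that("a single-isoform read chains all its exons without penalty", {
  db <- toy_annotation()
  # perfect read over GA.t1: segments equal to the three exons
  s <- dplyr::bind_rows(
    seg("r", 0, 100, gs = 100, ge = 200),
    seg("r", 100, 200, gs = 400, ge = 500),
    seg("r", 200, 300, gs = 900, ge = 1000))
  M <- annotate_segments(s, db)
  ch <- chain_exons(M)
  ga1 <- ch[ch$transcript_id == "GA.t1", ]
  expect_equal(nrow(ga1), 3L)
  # exact exon hits: overlap 1, no switch -> score = summed exon lengths
  expect_equal(unique(ch$score), 300)
})

test_that("empty input yields no chain and an intergenic read", {
  expect_equal(nrow(chain_exons(NULL)), 0L)
  cls <- classify_reads(chain_exons(NULL), read_ids = "lonely")
  expect_equal(cls$class, "intergenic")
  expect_equal(cls$n_genes, 0L)
})

test_that("chaining score equals exhaustive enumeration on random instances", {
  withr::local_seed(97)
  n_checked <- 0L
  while (n_checked < 500L) {
    m <- random_chain_instance()
    if (nrow(m) == 0L) next
    n_checked <- n_checked + 1L
    got <- unique(chain_exons(m)$score)
    want <- oracle_chain_score(m)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("adding a match never decreases the optimal score", {
  withr::local_seed(131)
  n_checked <- 0L
  while (n_checked < 100L) {
    m <- random_chain_instance()
    if (nrow(m) < 2L) next
    n_checked <- n_checked + 1L
    full <- unique(chain_exons(m)$score)
    drop1 <- unique(chain_exons(m[-sample.int(nrow(m), 1L), ])$score)
    expect_gte(full + 1e-9, drop1)
    expect_gte(full, 0)
  }
})

test_that("penalties prefer one isoform over two, one gene over two", {
  base <- tibble::tibble(
    read_id = "r1", read_start = c(0L, 100L), read_end = c(100L, 200L),
    direction = 1L, target_name = "chr1",
    genome_start = c(0L, 1000L), genome_end = c(100L, 1100L),
    exon_start = c(0L, 1000L), exon_end = c(100L, 1100L),
    exon_rank = c(1L, 2L), n_exons = 2L)
  score_for <- function(genes, txs) {
    m <- base
    m$gene_id <- genes
    m$transcript_id <- txs
    unique(chain_exons(m)$score)
  }
  s_iso <- score_for(c("gA", "gA"), c("t1", "t1"))
  s_tx <- score_for(c("gA", "gA"), c("t1", "t2"))
  s_gene <- score_for(c("gA", "gB"), c("t1", "t3"))
  expect_gt(s_iso, s_tx)
  expect_gt(s_tx, s_gene)
  expect_equal(s_iso, 200)
  expect_equal(s_tx, 100 + 0.9 * 100)
  expect_equal(s_gene, 100 + 0.5 * 100)
})

test_that("read classification follows the gene content of the chain", {
  ch1 <- tibble::tibble(
    read_id = "r1", chain_pos = 1:2, gene_id = c("gA", "gA"),
    transcript_id = "t1", exon_start = c(0L, 200L), exon_end = c(100L, 300L),
    exon_rank = 1:2, n_exons = 2L, read_start = c(0L, 100L),
    read_end = c(100L, 200L), target_name = "chr1",
    genome_start = c(0L, 200L), genome_end = c(100L, 300L),
    direction = 1L, score = 200)
  ch2 <- ch1
  ch2$read_id <- "r2"
  ch2$gene_id <- c("gA", "gB")
  cls <- classify_reads(dplyr::bind_rows(ch1, ch2))
  expect_equal(cls$class[cls$read_id == "r1"], "normal")
  expect_equal(cls$gene_id[cls$read_id == "r1"], "gA")
  expect_equal(cls$class[cls$read_id == "r2"], "chimeric")
  expect_equal(cls$head_gene[cls$read_id == "r2"], "gA")
  expect_equal(cls$tail_gene[cls$read_id == "r2"], "gB")
})

test_that("low-complexity stripping uses a strict 70% single-base bound", {
  mk_read <- function(seq) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- "r1"
    x
  }
  chain_row <- function(rs, re, gene = "gA") {
    tibble::tibble(
      read_id = "r1", chain_pos = 1L, gene_id = gene, transcript_id = "t1",
      exon_start = 0L, exon_end = 100L, exon_rank = 1L, n_exons = 1L,
      read_start = rs, read_end = re, target_name = "chr1",
      genome_start = 0L, genome_end = 100L, direction = 1L, score = 1)
  }
  # 71 of 100 bases 'A' -> removed
  seq71 <- paste0(strrep("A", 71),
                  paste(rep(c("C", "G", "T"), length.out = 29), collapse = ""))
  out <- strip_low_complexity(chain_row(0L, 100L), mk_read(seq71))
  expect_equal(nrow(out), 0L)
  # exactly 70 of 100 -> kept
  seq70 <- paste0(strrep("A", 70),
                  paste(rep(c("C", "G", "T"), length.out = 30), collapse = ""))
  out <- strip_low_complexity(chain_row(0L, 100L), mk_read(seq70))
  expect_equal(nrow(out), 1L)
  # lowercase sequences are treated case-insensitively
  out <- strip_low_complexity(chain_row(0L, 100L),
                              mk_read(tolower(seq71)))
  expect_equal(nrow(out), 0L)
  # interval past the end of the read errors
  expect_error(strip_low_complexity(chain_row(0L, 200L), mk_read(seq70)),
               "exceeds")
})

test_that("removing a poly-A chained gene reclassifies the read as normal", {
  two_gene <- tibble::tibble(
    read_id = "r1", chain_pos = 1:2, gene_id = c("gA", "gB"),
    transcript_id = c("t1", "t2"), exon_start = c(0L, 500L),
    exon_end = c(100L, 600L), exon_rank = 1L, n_exons = 1L,
    read_start = c(0L, 100L), read_end = c(100L, 200L),
    target_name = "chr1", genome_start = c(0L, 500L),
    genome_end = c(100L, 600L), direction = 1L, score = 150)
  reads <- Biostrings::DNAStringSet(paste0(
    paste(rep(c("A", "C", "G", "T"), 25), collapse = ""),  # balanced
    strrep("A", 100)))                                     # pure poly-A
  names(reads) <- "r1"
  stripped <- strip_low_complexity(two_gene, reads)
  expect_equal(stripped$gene_id, "gA")
  cls <- classify_reads(stripped)
  expect_equal(cls$class, "normal")
})
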