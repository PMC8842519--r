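test_that("expression counts single-gene chains only", {
  rc <- dplyr::bind_rows(
    purrr::map(1:5, ~ read_row(paste0("n", .x), "normal", gene = "A")),
    read_row("n6", "normal", gene = "B"),
    read_row("c1", "chimeric", head = "A", tail = "B"),
    read_row("i1", "intergenic"))
  expr <- estimate_expression(rc)
  expect_equal(gene_expression(expr, "A"), 5L)
  expect_equal(gene_expression(expr, "B"), 1L)
  expect_equal(gene_expression(expr, "Z"), 0L)  # unseen gene
  expect_equal(sum(expr$expression), sum(rc$class == "normal"))
})

test_that("clustering applies the support threshold and head majority", {
  rc <- dplyr::bind_rows(
    purrr::map(1:3, ~ read_row(paste0("ab", .x), "chimeric",
                               head = "A", tail = "B")),
    read_row("ba1", "chimeric", head = "B", tail = "A"),
    purrr::map(1:2, ~ read_row(paste0("cd", .x), "chimeric",
                               head = "C", tail = "D")))
  cl <- cluster_chimeras(rc, min_support = 3L)
  expect_equal(nrow(cl), 2L)
  ab <- cl[cl$n_support == 4L, ]
  # majority orientation wins: 3 of 4 chains put A first
  expect_equal(ab$head_gene, "A")
  expect_equal(ab$tail_gene, "B")
  expect_false(ab$low_support)
  expect_true(cl$low_support[cl$n_support == 2L])
  expect_equal(nrow(cluster_chimeras(read_row("x", "normal", gene = "A"))), 0L)
})

test_that("FiN score matches its closed form across regimes", {
  expect_equal(fin_score(10, 4, 5), 1.0)
  expect_equal(fin_score(3, 0, 0), 3.0)      # homozygous regime
  expect_equal(fin_score(1, 99, 99), 1 / 199)  # random-pairing regime
})

test_that("ff-igf evaluates partner-promiscuity per its definition", {
  mk <- function(head, tail, n, low = FALSE) {
    tibble::tibble(head_gene = head, tail_gene = tail, n_support = n,
                   read_ids = list(character()), rt_junction_frac = 0,
                   low_support = low)
  }
  # A:B with one shared promiscuous partner X, |PG_A| = |PG_B| = 1, |F| = 10
  clusters <- dplyr::bind_rows(
    mk("A", "B", 1L),
    mk("A", "X", 2L), mk("B", "X", 2L),
    purrr::map(1:7, ~ mk(sprintf("Q%d", .x), sprintf("R%d", .x), 5L)))
  out <- ffigf_scores(clusters)
  ab <- out$ff_igf[out$head_gene == "A" & out$tail_gene == "B"]
  expect_equal(ab, log(2) * log(10 / 3), tolerance = 1e-12)
  # empty partner intersection forces a zero score
  qr <- out$ff_igf[out$head_gene == "Q1"]
  expect_equal(qr, log(1 + 0) * log(10 / 3))  # 0 by log(1) = 0
  # a lone cluster with no partner sets scores 0
  lone <- ffigf_scores(mk("A", "B", 1L))
  expect_equal(lone$ff_igf, 0)
})

test_that("random-pairing p-value equals the brute-force tail sum", {
  # paper-style case: two well-expressed genes, few chimeric reads
  p <- random_pairing_pvalue(3, 1000, 1000, p_rp = 0.01)
  n <- floor(1000 + 3 + 0.5)
  k <- floor(n * 0.01 + 0.5)
  expect_equal(p, oracle_hyper_tail(3, K = 3 + k, n = n), tolerance = 1e-9)

  withr::local_seed(77)
  for (i in seq_len(100L)) {
    e_a <- sample.int(2000L, 1L)
    e_b <- sample.int(2000L, 1L)
    n_ab <- sample.int(50L, 1L)
    p_rp <- stats::runif(1, 0.001, 0.2)
    got <- random_pairing_pvalue(n_ab, e_a, e_b, p_rp)
    n <- floor((e_a + e_b) / 2 + n_ab + 0.5)
    k <- min(n, floor(n * p_rp + 0.5))
    want <- oracle_hyper_tail(n_ab, K = n_ab + k, n = n)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("degenerate and closed-form tail cases behave", {
  # observing at least zero chimeras is certain
  expect_equal(random_pairing_pvalue(0, 100, 100, 0.01), 1)
  # E_A = E_B = 0, N = 5, p_rp small: k = 0, closed-form tail
  p <- random_pairing_pvalue(5, 0, 0, 0.01)
  expect_equal(p, choose(5, 5) * choose(5, 0) / choose(10, 5),
               tolerance = 1e-12)
  expect_lt(p, 0.01)  # null rejected: fusion-compatible
})

test_that("more chimeric support never weakens the evidence", {
  for (e in c(0L, 10L, 500L)) {
    p <- random_pairing_pvalue(1:30, e, e, 0.01)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("Benjamini-Yekutieli adjustment matches hand computation", {
  expect_equal(fdr_correct(0.03)$q_value, 0.03)  # m = 1 identity
  out <- fdr_correct(c(0.001, 0.02, 0.9))
  cm <- 1 + 1 / 2 + 1 / 3
  expect_equal(out$q_value,
               c(3 * cm * 0.001, 3 * cm / 2 * 0.02, min(1, cm * 0.9)),
               tolerance = 1e-12)
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))
  expect_false(any(fdr_correct(rep(1, 5))$reject))
  expect_equal(nrow(fdr_correct(numeric())), 0L)
  # adjusted values are monotone along the sorted p-values
  withr::local_seed(7)
  p <- sort(stats::runif(20))
  expect_true(all(diff(fdr_correct(p)$q_value) >= -1e-12))
})

test_that("read-through rules bracket each printed threshold", {
  # two same-strand genes on chr1 whose body gap is controlled by `gap`
  rt_db <- function(gap) {
    make_db(tibble::tibble(
      gene_id = c("H", "T"), transcript_id = c("H.t", "T.t"),
      chrom = "chr1", strand = "+",
      start = c(0L, 1000L + gap), end = c(1000L, 2000L + gap)))
  }
  cl <- tibble::tibble(head_gene = "H", tail_gene = "T", n_support = 4L,
                       read_ids = list(character()), rt_junction_frac = 1.0,
                       low_support = FALSE, fin = 0.2)
  expect_true(is_read_through(cl, rt_db(499999L)))
  expect_false(is_read_through(cl, rt_db(500001L)))  # distance bound strict
  cl_fin <- cl; cl_fin$fin <- 0.6
  expect_false(is_read_through(cl_fin, rt_db(1000L)))  # FiN below 0.5 only
  cl_ratio <- cl; cl_ratio$rt_junction_frac <- 0.8
  expect_false(is_read_through(cl_ratio, rt_db(1000L)))  # ratio strictly > 0.8
  cl_ratio$rt_junction_frac <- 0.81
  expect_true(is_read_through(cl_ratio, rt_db(1000L)))
  # opposite strands never read through
  db_mixed <- make_db(tibble::tibble(
    gene_id = c("H", "T"), transcript_id = c("H.t", "T.t"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(0L, 2000L), end = c(1000L, 3000L)))
  expect_false(is_read_through(cl, db_mixed))
})

test_that("cluster characterization partitions labels and ranks fusions", {
  db <- make_db(tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E", "F"),
    transcript_id = paste0(c("A", "B", "C", "D", "E", "F"), ".t"),
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr2"),
    strand = "+",
    start = c(0L, 0L, 5000L, 8000L, 20000L, 50000L),
    end = c(1000L, 1000L, 6000L, 9000L, 21000L, 51000L)))
  rc <- dplyr::bind_rows(
    # A:B - strong fusion, cross-chromosome, silenced members
    purrr::map(1:20, ~ read_row(paste0("f", .x), "chimeric",
                                head = "A", tail = "B")),
    # C:D - read-through: adjacent, FiN small, junction structure present
    purrr::map(1:4, ~ read_row(paste0("r", .x), "chimeric",
                               head = "C", tail = "D", rt = TRUE)),
    purrr::map(1:60, ~ read_row(paste0("nc", .x), "normal", gene = "C")),
    purrr::map(1:60, ~ read_row(paste0("nd", .x), "normal", gene = "D")),
    # E:F - random pairing: single chain, well-expressed members
    read_row("rp1", "chimeric", head = "E", tail = "F"),
    purrr::map(1:50, ~ read_row(paste0("ne", .x), "normal", gene = "E")),
    purrr::map(1:50, ~ read_row(paste0("nf", .x), "normal", gene = "F")))
  expr <- estimate_expression(rc)
  clusters <- cluster_chimeras(rc, min_support = 3L)
  out <- characterize_clusters(clusters, expr, db)
  lab <- function(h, t) out$label[out$head_gene == h & out$tail_gene == t]
  expect_equal(lab("A", "B"), "PASS:GF")
  expect_equal(lab("C", "D"), "PASS:RT")
  expect_equal(lab("E", "F"), "FAIL:LowSupport")
  expect_true(all(out$label %in%
                    c("PASS:GF", "PASS:RT", "FAIL:RP", "FAIL:LowSupport")))
  expect_true(all(!is.na(out$label)))
  # read-throughs are excluded from testing; fusions carry p and q
  expect_true(is.na(out$p_value[out$label == "PASS:RT"]))
  expect_false(is.na(out$p_value[out$label == "PASS:GF"]))
  expect_equal(out$rank[out$label == "PASS:GF"], 1L)
})

test_that("fusion calls are ranked by descending ff-igf", {
  db <- make_db(tibble::tibble(
    gene_id = LETTERS[1:6], transcript_id = paste0(LETTERS[1:6], ".t"),
    chrom = rep(c("chr1", "chr2"), 3L), strand = "+",
    start = seq(0L, 50000L, by = 10000L),
    end = seq(1000L, 51000L, by = 10000L)))
  rc <- dplyr::bind_rows(
    purrr::map(1:10, ~ read_row(paste0("x", .x), "chimeric",
                                head = "A", tail = "B")),
    purrr::map(1:2, ~ read_row(paste0("xc", .x), "chimeric",
                               head = "A", tail = "C")),
    purrr::map(1:2, ~ read_row(paste0("xd", .x), "chimeric",
                               head = "B", tail = "C")),
    purrr::map(1:10, ~ read_row(paste0("y", .x), "chimeric",
                                head = "D", tail = "E")))
  clusters <- cluster_chimeras(rc, min_support = 3L)
  out <- characterize_clusters(clusters, estimate_expression(rc), db)
  gf <- out[out$label == "PASS:GF", ]
  expect_equal(gf$rank, seq_len(nrow(gf)))
  expect_true(all(diff(gf$ff_igf) <= 1e-12))
})
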