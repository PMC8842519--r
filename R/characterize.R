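#' Pipeline thresholds and test parameters
#'
#' Collects every tunable threshold of the fusion caller with its default.
#' Defaults follow the published method: clusters need at least 3 supporting
#' chimeric chains; read-throughs require same-chromosome, same-strand genes
#' less than 500 kb apart, FiN below 0.5 and a junction-chain ratio above
#' 0.8; chain segments over 70% a single base are removed; segments merge
#' across gaps strictly below 10 nt. The random-pairing probability `p_rp`
#' (default 0.01) and the FDR level (default 0.05) are modelling choices, not
#' published constants, and are exposed here.
#'
#' @param min_support Minimum chimeric chains per retained cluster.
#' @param p_rp Assumed probability that a sequenced read is a random pairing.
#' @param fdr_level Benjamini-Yekutieli FDR level for calling fusions.
#' @param rt_max_distance Maximum inter-gene distance (bp) for read-throughs.
#' @param rt_fin_max Maximum FiN score for read-throughs.
#' @param rt_chain_ratio_min Minimum fraction of cluster chains with the
#'   read-through junction structure.
#' @param max_single_base_frac Low-complexity removal threshold.
#' @param merge_max_gap Segment-merge gap bound (nt, strict).
#' @return A named list of class `fusion_config`.
#' @export
fusion_config <- function(min_support = 3L, p_rp = 0.01, fdr_level = 0.05,
                          rt_max_distance = 500000L, rt_fin_max = 0.5,
                          rt_chain_ratio_min = 0.8,
                          max_single_base_frac = 0.70, merge_max_gap = 10L) {
  stopifnot(min_support >= 1L, p_rp > 0, p_rp < 1, fdr_level > 0,
            rt_max_distance > 0, rt_fin_max > 0, rt_chain_ratio_min > 0)
  structure(list(
    min_support = as.integer(min_support), p_rp = p_rp,
    fdr_level = fdr_level, rt_max_distance = as.integer(rt_max_distance),
    rt_fin_max = rt_fin_max, rt_chain_ratio_min = rt_chain_ratio_min,
    max_single_base_frac = max_single_base_frac,
    merge_max_gap = as.integer(merge_max_gap)), class = "fusion_config")
}

#' Estimate gene expression from single-gene chains
#'
#' A gene's expression `E_G` is its count of normal-classified (single-gene)
#' exon chains. Chimeric and intergenic reads contribute nothing. Genes never
#' observed have expression 0 on lookup via [gene_expression()].
#'
#' @param read_classes Per-read tibble from [classify_reads()] (reads dropped
#'   by the chimera filters should already be excluded or flagged; only rows
#'   with class "normal" are counted).
#' @return Tibble (gene_id, expression).
#' @export
estimate_expression <- function(read_classes) {
  read_classes |>
    dplyr::filter(.data$class == "normal") |>
    dplyr::count(.data$gene_id, name = "expression")
}

#' Look up gene expression with zero default
#'
#' @param expr Expression tibble from [estimate_expression()].
#' @param gene_ids Character vector.
#' @return Integer vector of expression counts (0 for unseen genes).
#' @export
gene_expression <- function(expr, gene_ids) {
  m <- match(gene_ids, expr$gene_id)
  out <- expr$expression[m]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Cluster chimeric chains by gene pair
#'
#' One cluster per unordered gene pair. The head gene is the gene appearing
#' first on the read for the majority of supporting chains (ties broken
#' toward the lexicographically smaller gene id). Clusters supported by
#' fewer than `min_support` chains are flagged low-support and excluded from
#' scoring and testing downstream.
#'
#' @param read_classes Per-read tibble restricted to surviving chimeric
#'   reads (class "chimeric", not filter-dropped).
#' @param min_support Minimum supporting chains (default 3).
#' @return Tibble with head_gene, tail_gene, n_support, read_ids (list),
#'   rt_junction_frac, low_support.
#' @export
cluster_chimeras <- function(read_classes, min_support = 3L) {
  chim <- dplyr::filter(read_classes, .data$class == "chimeric")
  if (nrow(chim) == 0L) {
    return(tibble::tibble(
      head_gene = character(), tail_gene = character(), n_support = integer(),
      read_ids = list(), rt_junction_frac = numeric(),
      low_support = logical()))
  }
  chim |>
    dplyr::mutate(g1 = pmin(.data$head_gene, .data$tail_gene),
                  g2 = pmax(.data$head_gene, .data$tail_gene)) |>
    dplyr::group_by(.data$g1, .data$g2) |>
    dplyr::summarise(
      n_support = dplyr::n(),
      n_g1_first = sum(.data$head_gene == .data$g1),
      read_ids = list(.data$read_id),
      rt_junction_frac = mean(.data$rt_junction),
      .groups = "drop") |>
    dplyr::mutate(
      head_gene = dplyr::if_else(.data$n_g1_first * 2L >= .data$n_support,
                                 .data$g1, .data$g2),
      tail_gene = dplyr::if_else(.data$head_gene == .data$g1,
                                 .data$g2, .data$g1),
      low_support = .data$n_support < min_support) |>
    dplyr::select("head_gene", "tail_gene", "n_support", "read_ids",
                  "rt_junction_frac", "low_support") |>
    dplyr::arrange(.data$head_gene, .data$tail_gene)
}

#' FiN score: fusion reads relative to normal reads
#'
#' `FiN = N_AB / (1 + E_A + E_B)`. Near the fusion read count for homozygous
#' fusions (member genes no longer transcribed alone), around 0 for random
#' pairings between well-expressed genes, and small but non-zero for
#' read-throughs.
#'
#' @param n_ab Supporting chimeric chain count (vectorised).
#' @param e_a,e_b Member-gene expression counts.
#' @return Numeric FiN scores.
#' @export
fin_score <- function(n_ab, e_a, e_b) {
  n_ab / (1 + e_a + e_b)
}

#' ff-igf score: fusion frequency, inverse gene frequency
#'
#' A gene can take part in at most two genuine fusions (one per haplotype),
#' so genes seen in many chimeric clusters are suspect. With `PG_G` the set
#' of partner genes X whose cluster with G has more than one supporting
#' chain, and `F` the set of retained clusters,
#' `ff-igf = log(1 + |PG_A inter PG_B|) * log(|F| / (1 + |PG_A| + |PG_B|))`
#' (natural logarithms). Partner sets are computed over all clusters,
#' including low-support ones; `|F|` counts retained clusters only.
#'
#' @param clusters Cluster tibble from [cluster_chimeras()].
#' @return `clusters` with an `ff_igf` column (NA for low-support clusters).
#' @export
ffigf_scores <- function(clusters) {
  if (nrow(clusters) == 0L) {
    clusters$ff_igf <- numeric()
    return(clusters)
  }
  n_f <- sum(!clusters$low_support)
  multi <- dplyr::filter(clusters, .data$n_support > 1L)
  pg_tab <- tibble::tibble(
    g = c(multi$head_gene, multi$tail_gene),
    x = c(multi$tail_gene, multi$head_gene))
  pg <- lapply(split(pg_tab$x, pg_tab$g), unique)
  pg_of <- function(g) {
    s <- pg[[g]]
    if (is.null(s)) character() else s
  }
  clusters$ff_igf <- purrr::map2_dbl(
    clusters$head_gene, clusters$tail_gene, function(a, b) {
      pga <- pg_of(a); pgb <- pg_of(b)
      log(1 + length(intersect(pga, pgb))) *
        log(n_f / (1 + length(pga) + length(pgb)))
    })
  clusters$ff_igf[clusters$low_support] <- NA_real_
  clusters
}

# round half up; stats::round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)

#' One-tailed random-pairing test
#'
#' Tests, per cluster, the null hypothesis that the observed chimeric chain
#' count `N_AB` is what random pairing at rate `p_rp` would produce given
#' the member genes' expression: with `n = round(mean(E_A, E_B) + N_AB)` and
#' `k = round(n * p_rp)` expected random pairings, the p-value is the
#' one-tailed Fisher exact upper-tail probability of at least `N_AB`
#' chimeras in the 2x2 table `[[N_AB, k], [n - N_AB, n - k]]` — the
#' hypergeometric survival probability at `N_AB - 1` with population `2n`,
#' `n` draws and `N_AB + k` successes. Rounding is half-up.
#'
#' @param n_ab Observed chimeric chain counts (vectorised).
#' @param e_a,e_b Member-gene expression counts.
#' @param p_rp Random-pairing probability in (0, 1).
#' @return p-values in `[0, 1]`.
#' @export
random_pairing_pvalue <- function(n_ab, e_a, e_b, p_rp = 0.01) {
  stopifnot(p_rp > 0, p_rp < 1)
  n <- round_half_up((e_a + e_b) / 2 + n_ab)
  k <- round_half_up(n * p_rp)
  if (any(k > n)) {
    warning("expected random-pairing count exceeded table size; clamped",
            call. = FALSE)
    k <- pmin(k, n)
  }
  p <- stats::phyper(n_ab - 1, m = n_ab + k, n = 2 * n - (n_ab + k),
                     k = n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Adjusts random-pairing p-values with the Benjamini-Yekutieli step-up
#' procedure, which controls the FDR under arbitrary dependence — the
#' cluster tests are dependent through shared member genes and the global
#' random-pairing rate.
#'
#' @param p_values Numeric vector of p-values.
#' @param fdr_level Rejection level for the adjusted values.
#' @return Tibble (p_value, q_value, reject); empty input gives empty output.
#' @export
fdr_correct <- function(p_values, fdr_level = 0.05) {
  if (length(p_values) == 0L) {
    return(tibble::tibble(p_value = numeric(), q_value = numeric(),
                          reject = logical()))
  }
  q <- stats::p.adjust(p_values, method = "BY")
  tibble::tibble(p_value = p_values, q_value = q, reject = q < fdr_level)
}

#' Read-through test for a chimeric cluster
#'
#' A cluster is a read-through candidate when all three hold: (1) the member
#' genes are on the same chromosome and strand with gene bodies less than
#' `rt_max_distance` apart (strictly; adjacent bodies have distance 0);
#' (2) FiN is below `rt_fin_max`; (3) the fraction of supporting chains
#' whose junction joins the head gene's second-to-last exon to the tail
#' gene's second exon exceeds `rt_chain_ratio_min`. Read-throughs are
#' identified before statistical testing because their expression cannot be
#' separated from random pairing by the test.
#'
#' @param clusters Cluster tibble with `fin` and `rt_junction_frac` columns.
#' @param db A `fusion_annotation`.
#' @param config A [fusion_config()].
#' @return Logical vector, one per cluster.
#' @export
is_read_through <- function(clusters, db, config = fusion_config()) {
  if (nrow(clusters) == 0L) return(logical())
  g <- db$genes
  a <- g[match(clusters$head_gene, g$gene_id), ]
  b <- g[match(clusters$tail_gene, g$gene_id), ]
  gap <- pmax(0, pmax(a$body_start, b$body_start) -
                pmin(a$body_end, b$body_end))
  near <- !is.na(a$chrom) & !is.na(b$chrom) &
    a$chrom == b$chrom & a$strand == b$strand &
    gap < config$rt_max_distance
  near & clusters$fin < config$rt_fin_max &
    clusters$rt_junction_frac > config$rt_chain_ratio_min
}

#' Score, test, classify and rank chimeric clusters
#'
#' Runs the full cluster characterization: FiN and ff-igf scores,
#' read-through identification, the one-tailed random-pairing test with
#' Benjamini-Yekutieli correction on the remaining retained clusters, and
#' final labels — `PASS:GF` (null rejected: gene fusion), `PASS:RT`
#' (read-through), `FAIL:RP` (random pairing), `FAIL:LowSupport`. Fusion
#' calls are ranked by descending ff-igf.
#'
#' @param clusters Cluster tibble from [cluster_chimeras()].
#' @param expr Expression tibble from [estimate_expression()].
#' @param db A `fusion_annotation`.
#' @param config A [fusion_config()].
#' @return Cluster tibble with e_head, e_tail, fin, ff_igf, p_value,
#'   q_value, label and rank columns, ordered PASS:GF (by rank) first.
#' @export
characterize_clusters <- function(clusters, expr, db,
                                  config = fusion_config()) {
  if (nrow(clusters) == 0L) {
    return(dplyr::mutate(clusters, e_head = integer(), e_tail = integer(),
                         fin = numeric(), ff_igf = numeric(),
                         p_value = numeric(), q_value = numeric(),
                         label = character(), rank = integer()))
  }
  cl <- clusters
  cl$e_head <- gene_expression(expr, cl$head_gene)
  cl$e_tail <- gene_expression(expr, cl$tail_gene)
  cl$fin <- fin_score(cl$n_support, cl$e_head, cl$e_tail)
  cl <- ffigf_scores(cl)

  cl$label <- NA_character_
  cl$label[cl$low_support] <- "FAIL:LowSupport"
  retained <- !cl$low_support
  rt <- retained & is_read_through(cl, db, config)
  cl$label[rt] <- "PASS:RT"

  tested <- retained & !rt
  cl$p_value <- NA_real_
  cl$q_value <- NA_real_
  if (any(tested)) {
    p <- random_pairing_pvalue(cl$n_support[tested], cl$e_head[tested],
                               cl$e_tail[tested], config$p_rp)
    adj <- fdr_correct(p, config$fdr_level)
    cl$p_value[tested] <- adj$p_value
    cl$q_value[tested] <- adj$q_value
    cl$label[tested] <- dplyr::if_else(adj$reject, "PASS:GF", "FAIL:RP")
  }

  gf <- cl$label == "PASS:GF"
  cl$rank <- NA_integer_
  if (any(gf)) {
    ord <- order(-cl$ff_igf[gf], cl$head_gene[gf], cl$tail_gene[gf])
    cl$rank[which(gf)[ord]] <- seq_len(sum(gf))
  }
  label_order <- c("PASS:GF", "PASS:RT", "FAIL:RP", "FAIL:LowSupport")
  cl |>
    dplyr::arrange(match(.data$label, label_order), .data$rank,
                   dplyr::desc(.data$n_support), .data$head_gene,
                   .data$tail_gene)
}
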