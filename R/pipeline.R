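#' Call gene fusions from long-read alignments
#'
#' Runs the full fusion-calling pipeline: PAF segments are merged and
#' annotated with overlapping exons, each read is reduced to its optimal
#' exon chain and classified (normal / chimeric / intergenic), ambiguous
#' chimeric chains are filtered (overlapping genes, homologs, segmental
#' duplications), low-complexity chain segments are stripped when read
#' sequences are supplied, chimeric chains are clustered per gene pair, and
#' clusters are scored, tested against random pairing and labelled
#' `PASS:GF`, `PASS:RT`, `FAIL:RP` or `FAIL:LowSupport`.
#'
#' @param paf PAF file path(s), or a segment tibble as returned by
#'   [read_paf()] (a `strand` column of "+"/"-" is also accepted in place
#'   of `direction`).
#' @param annotation GTF file path or a `fusion_annotation` object.
#' @param reads Optional read sequences: FASTA/FASTQ path or named
#'   `DNAStringSet`. When given, the low-complexity filter is applied.
#' @param sd Optional segmental-duplication index ([read_sd_pairs()]) or
#'   table path.
#' @param homologs Optional homolog index ([read_homolog_pairs()],
#'   [build_homolog_index()]) or gene-pair TSV path.
#' @param config A [fusion_config()].
#' @return A `fusion_calls` object: list with `calls` (cluster-level tibble
#'   with scores, p/q-values, labels and ranks), `reads` (per-read
#'   assignments), `expression`, `counts` (stage-by-stage accounting) and
#'   `config`.
#' @export
#' @examples
#' cfg <- simulate_config(seed = 42, n_chroms = 2, genes_per_chrom = 6,
#'                        n_fusions = 2, n_homozygous = 1,
#'                        n_read_throughs = 1, mean_expression = 30)
#' ref <- make_toy_reference(cfg)
#' sim <- simulate_reads(ref, cfg)
#' res <- call_fusions(sim$paf, ref$db, reads = sim$reads)
#' res$calls
call_fusions <- function(paf, annotation, reads = NULL, sd = NULL,
                         homologs = NULL, config = fusion_config()) {
  db <- if (is.character(annotation)) read_annotation(annotation)
        else annotation
  segments <- if (is.character(paf)) read_paf(paf) else tibble::as_tibble(paf)
  if (!"direction" %in% names(segments) && "strand" %in% names(segments)) {
    segments$direction <- ifelse(segments$strand == "+", 1L, -1L)
  }
  if (is.character(sd)) sd <- read_sd_pairs(sd)
  if (is.character(homologs)) homologs <- read_homolog_pairs(homologs)
  if (is.character(reads)) reads <- read_reads(reads)

  all_reads <- unique(segments$read_id)
  merged <- merge_segments(segments, config$merge_max_gap)
  M <- annotate_segments(merged, db)
  chains <- chain_exons(M)
  if (!is.null(reads)) {
    chains <- strip_low_complexity(chains, reads,
                                   config$max_single_base_frac)
  }
  read_classes <- classify_reads(chains, read_ids = all_reads)
  read_classes <- filter_chimeric_chains(read_classes, chains, db,
                                         homologs = homologs, sd = sd)
  kept <- dplyr::filter(read_classes, is.na(.data$filter_reason))
  expression <- estimate_expression(kept)
  clusters <- cluster_chimeras(kept, config$min_support)
  calls <- characterize_clusters(clusters, expression, db, config)

  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  cluster_label <- calls |>
    dplyr::mutate(key = pair_key(.data$head_gene, .data$tail_gene)) |>
    dplyr::select("key", cluster_head = "head_gene",
                  cluster_tail = "tail_gene", cluster_label = "label")
  read_assignments <- read_classes |>
    dplyr::mutate(key = dplyr::if_else(
      .data$class == "chimeric" & is.na(.data$filter_reason),
      pair_key(.data$head_gene, .data$tail_gene), NA_character_)) |>
    dplyr::left_join(cluster_label, by = "key") |>
    dplyr::select("read_id", "class", "gene_id", "head_gene", "tail_gene",
                  "filter_reason", "cluster_head", "cluster_tail",
                  "cluster_label")

  counts <- c(
    list(reads_in = length(all_reads)),
    as.list(table(read_classes$class)),
    list(dropped = as.list(table(read_classes$filter_reason))),
    list(clusters = as.list(table(calls$label))))

  structure(list(calls = calls, reads = read_assignments,
                 expression = expression, counts = counts,
                 config = config, db_genes = db$genes),
            class = "fusion_calls")
}

#' @export
print.fusion_calls <- function(x, ...) {
  lab <- table(factor(x$calls$label,
                      c("PASS:GF", "PASS:RT", "FAIL:RP", "FAIL:LowSupport")))
  cat("<fusion_calls> ", x$counts$reads_in, " reads (",
      x$counts$normal %||% 0L, " normal, ",
      x$counts$chimeric %||% 0L, " chimeric, ",
      x$counts$intergenic %||% 0L, " intergenic)\n", sep = "")
  cat("  gene fusions: ", lab[["PASS:GF"]],
      " | read-throughs: ", lab[["PASS:RT"]],
      " | random pairings: ", lab[["FAIL:RP"]],
      " | low support: ", lab[["FAIL:LowSupport"]], "\n", sep = "")
  gf <- dplyr::filter(x$calls, .data$label == "PASS:GF")
  if (nrow(gf) > 0L) {
    cat("  top calls:\n")
    top <- utils::head(gf, 5L)
    cat(sprintf("    %d. %s:%s  N=%d  FiN=%.3f  ff-igf=%.3f\n", top$rank,
                top$head_gene, top$tail_gene, top$n_support, top$fin,
                top$ff_igf), sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cluster-level fusion calls
#'
#' One row per chimeric cluster with gene names and genomic regions joined
#' in, ready for reporting.
#'
#' @param x A `fusion_calls` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fusion_calls <- function(x, ...) {
  g <- x$db_genes
  region <- function(ids) {
    m <- match(ids, g$gene_id)
    sprintf("%s:%d-%d", g$chrom[m], g$body_start[m], g$body_end[m])
  }
  x$calls |>
    dplyr::mutate(
      head_name = g$gene_name[match(.data$head_gene, g$gene_id)],
      tail_name = g$gene_name[match(.data$tail_gene, g$gene_id)],
      head_region = region(.data$head_gene),
      tail_region = region(.data$tail_gene)) |>
    dplyr::select("head_gene", "tail_gene", "head_name", "tail_name",
                  "head_region", "tail_region", n_ab = "n_support",
                  e_head = "e_head", e_tail = "e_tail", fin = "fin",
                  ff_igf = "ff_igf", "p_value", "q_value", "label", "rank")
}

#' One-row run summary
#'
#' @param x A `fusion_calls` object.
#' @param ... Unused.
#' @return A one-row tibble with read and cluster counts.
#' @export
glance.fusion_calls <- function(x, ...) {
  lab <- table(factor(x$calls$label,
                      c("PASS:GF", "PASS:RT", "FAIL:RP", "FAIL:LowSupport")))
  tibble::tibble(
    n_reads = x$counts$reads_in,
    n_normal = x$counts$normal %||% 0L,
    n_chimeric = x$counts$chimeric %||% 0L,
    n_intergenic = x$counts$intergenic %||% 0L,
    n_fusion_calls = unname(lab[["PASS:GF"]]),
    n_read_through = unname(lab[["PASS:RT"]]),
    n_random_pairing = unname(lab[["FAIL:RP"]]),
    n_low_support = unname(lab[["FAIL:LowSupport"]]))
}

#' Plot FiN against ff-igf for all characterized clusters
#'
#' Reproduces the standard diagnostic view of a run: each retained cluster
#' as a point, FiN on the x axis (log10), ff-igf on the y axis, coloured by
#' final label. Fusions separate to high FiN, read-throughs sit at
#' intermediate FiN, random pairings near zero.
#'
#' @param object A `fusion_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_calls <- function(object, ...) {
  dat <- dplyr::filter(object$calls, .data$label != "FAIL:LowSupport")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fin, y = .data$ff_igf,
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "FiN score", y = "ff-igf score", colour = "call") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fusion_calls
#' @param x A `fusion_calls` object.
#' @export
plot_fusion_scores <- function(x, ...) autoplot.fusion_calls(x, ...)

#' Write fusion-call outputs to a directory
#'
#' Writes `fusions.tsv` (one row per cluster, as [tidy.fusion_calls()]),
#' `reads.tsv` (per-read assignments) and `summary.json` (parameters and
#' stage-by-stage counts, including per-rule filter accounting).
#'
#' @param x A `fusion_calls` object.
#' @param dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_fusion_calls <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fusions = file.path(dir, "fusions.tsv"),
                reads = file.path(dir, "reads.tsv"),
                summary = file.path(dir, "summary.json"))
  readr::write_tsv(tidy(x), paths$fusions)
  readr::write_tsv(x$reads, paths$reads)
  jsonlite::write_json(list(longfuse_version =
                              as.character(utils::packageVersion("longfuse")),
                            parameters = unclass(x$config),
                            counts = x$counts),
                       paths$summary, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
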